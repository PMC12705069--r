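#' Inverse-variance-weighted fixed-effects meta-analysis
#'
#' Combines per-variant effect estimates across studies with weights
#' `w_i = 1 / se_i^2`: combined `beta = sum(w_i beta_i) / sum(w_i)`,
#' `se = sum(w_i)^(-1/2)`. A variant missing from some studies is combined
#' from the studies that carry it only (`k_studies` records how many);
#' `n_total` sums the contributing sample sizes. The p-value is recomputed
#' from the combined z. Cochran's Q is emitted as a diagnostic column but
#' never used for filtering. Study records with `se <= 0` are dropped with
#' a warning.
#'
#' When the tables carry a `feature_id` column (cis scans of many
#' features), combination is per (feature, variant) pair; `feature_id` may
#' also be used to restrict to one feature.
#'
#' @param studies list of data.frames with `variant_id`, `beta`, `se` and
#'   optionally `feature_id`, `n`, positional columns (carried over); or
#'   the study objects of [simulate_eqtl_studies()] (`list(study_id, n,
#'   cis)`).
#' @param feature_id optional feature to restrict to.
#' @return a data.frame: (feature_id,) variant_id, carried columns, beta,
#'   se, z, chisq, p, n_total, k_studies, cochran_q.
#' @export
ivw_meta <- function(studies, feature_id = NULL) {
  stopifnot(length(studies) >= 1)
  tabs <- lapply(studies, function(s) {
    d <- if (is.list(s) && !is.data.frame(s) && !is.null(s$cis)) {
      tab <- as.data.frame(s$cis)
      if (!"n" %in% names(tab))
        tab$n <- attr(s$cis, "n", exact = TRUE) %||% s$n
      tab
    } else as.data.frame(s)
    if (!is.null(feature_id) && "feature_id" %in% names(d))
      d <- d[d$feature_id == feature_id, , drop = FALSE]
    if (!"n" %in% names(d)) d$n <- NA_real_
    bad <- d$se <= 0
    if (any(bad)) {
      warning(sum(bad), " record(s) with non-positive se dropped")
      d <- d[!bad, , drop = FALSE]
    }
    d
  })
  keep <- Reduce(intersect, lapply(tabs, names))
  stacked <- do.call(rbind, lapply(tabs, function(d) d[, keep, drop = FALSE]))
  if (nrow(stacked) == 0L) return(stacked)
  key <- if ("feature_id" %in% keep)
    paste(stacked$feature_id, stacked$variant_id, sep = "\r") else
      stacked$variant_id
  w <- 1 / stacked$se^2
  sw <- rowsum(w, key)
  swb <- rowsum(w * stacked$beta, key)
  swb2 <- rowsum(w * stacked$beta^2, key)
  k <- rowsum(rep(1, length(w)), key)
  n_tot <- rowsum(stacked$n, key)
  beta <- swb / sw
  first <- stacked[!duplicated(key), , drop = FALSE]
  first <- first[match(rownames(sw), if ("feature_id" %in% keep)
    paste(first$feature_id, first$variant_id, sep = "\r") else
      first$variant_id), , drop = FALSE]
  carry_cols <- intersect(c("feature_id", "variant_id", "chrom", "pos",
                            "ref", "alt", "maf"), keep)
  out <- cbind(
    first[, carry_cols, drop = FALSE],
    data.frame(beta = drop(beta), se = drop(1 / sqrt(sw)),
               n_total = drop(n_tot), k_studies = drop(k),
               cochran_q = drop(swb2 - swb^2 / sw))
  )
  out <- finish_sumstats(out)
  rownames(out) <- NULL
  out[order(match(out$variant_id, tabs[[1]]$variant_id)), , drop = FALSE]
}
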