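#' Map cis-QTLs by per-variant linear association
#'
#' Residualizes phenotypes and dosages on the covariates (with intercept)
#' and, for every feature, regresses the residualized phenotype on each
#' residualized variant dosage inside the cis window. By the
#' Frisch-Waugh-Lovell theorem the slopes and standard errors equal those
#' of the full multiple regression including the covariates; degrees of
#' freedom are `n - 1 - ncol(design)` (design = intercept + covariates).
#' P-values are two-sided t. The window is measured from the nearest edge of
#' an interval anchor (peak) or from the point anchor (gene TSS); variants
#' with in-sample MAF below `maf_min` are excluded, and zero-variance
#' dosages are skipped.
#'
#' @param panel a `genotype_panel` carrying the analysis cohort.
#' @param phenos features x samples matrix (normalized stage).
#' @param covariates samples x covariates numeric matrix, or `NULL`.
#' @param anchors data.frame keyed by `feature_id` with `chrom` plus either
#'   `start`/`end` (BED interval) or `tss` (point).
#' @param cis_window window in basepairs (200 kb is the peak default;
#'   use 1 Mb for gene TSS anchors).
#' @param maf_min minimum in-sample minor allele frequency.
#' @return a long data.frame of class `cis_results` with columns
#'   feature_id, variant_id, pos, maf, beta, se, z, chisq, p, is_lead and
#'   attributes `n` (samples) and `df` (residual degrees of freedom). The
#'   lead variant per feature minimizes p, ties broken by smaller position
#'   then lexicographic id.
#' @export
map_cis_qtl <- function(panel, phenos, covariates = NULL, anchors,
                        cis_window = 200000, maf_min = 0.05) {
  stopifnot(inherits(panel, "genotype_panel"), is.matrix(phenos))
  n <- nrow(panel$dosages)
  if (ncol(phenos) != n) stop("samples not aligned between panel and phenos")
  design <- if (is.null(covariates)) matrix(1, n, 1) else {
    stopifnot(nrow(covariates) == n)
    cbind(1, as.matrix(covariates))
  }
  df <- n - 1L - ncol(design)
  if (df < 1) stop("not enough residual degrees of freedom")

  G <- panel$dosages
  freq <- colMeans(G) / 2
  maf <- pmin(freq, 1 - freq)
  Q <- qr.Q(qr(design))
  Gr <- G - Q %*% crossprod(Q, G)
  Yr <- t(phenos) - Q %*% crossprod(Q, t(phenos))
  ssG <- colSums(Gr^2)
  usable <- maf >= maf_min & ssG > 1e-12
  pos <- panel$variants$pos

  out <- vector("list", nrow(phenos))
  feats <- rownames(phenos)
  for (i in seq_along(feats)) {
    a <- anchors[anchors$feature_id == feats[i], , drop = FALSE]
    if (nrow(a) != 1L) next
    inwin <- if (!is.null(a$tss) && !is.na(a$tss[1])) {
      abs(pos - a$tss[1]) <= cis_window
    } else {
      pos > a$start[1] - cis_window & pos <= a$end[1] + cis_window
    }
    J <- which(inwin & usable)
    if (length(J) == 0L) next
    y <- Yr[, i]
    gy <- crossprod(Gr[, J, drop = FALSE], y)
    beta <- drop(gy) / ssG[J]
    sigma2 <- pmax(sum(y^2) - beta^2 * ssG[J], 0) / df
    se <- sqrt(sigma2 / ssG[J])
    tstat <- beta / se
    p <- 2 * stats::pt(-abs(tstat), df)
    res <- data.frame(
      feature_id = feats[i],
      variant_id = panel$variants$id[J], pos = pos[J], maf = maf[J],
      beta = beta, se = se, z = tstat, chisq = tstat^2, p = p,
      stringsAsFactors = FALSE, row.names = NULL
    )
    lead <- order(res$p, res$pos, res$variant_id)[1]
    res$is_lead <- seq_len(nrow(res)) == lead
    out[[i]] <- res
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(feature_id = character(), variant_id = character(),
                      pos = integer(), maf = numeric(), beta = numeric(),
                      se = numeric(), z = numeric(), chisq = numeric(),
                      p = numeric(), is_lead = logical())
  structure(res, class = c("cis_results", "data.frame"), n = n, df = df)
}

#' Per-feature lead variants of a cis scan
#' @param cis a `cis_results` data.frame.
#' @return the lead rows (one per feature).
#' @export
cis_leads <- function(cis) {
  cis[cis$is_lead, , drop = FALSE]
}
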