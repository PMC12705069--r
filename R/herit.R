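#' Stratified heritability regression with category enrichment
#'
#' Regresses per-variant GWAS chi-square statistics on `N x l_jc` for every
#' annotation category (intercept estimated), in the spirit of stratified
#' LD score regression. The per-variant heritability contribution is
#' `v_j = sum_c tau_c 1{j in c}` (overlap-aware); category heritability is
#' `h2_c = sum_{j in c} v_j`, and
#' `enrichment_c = (h2_c / h2_total) / (m_c / m_total)`. Standard errors
#' come from a delete-one block jackknife over contiguous variant blocks;
#' the enrichment p-value is one-sided for enrichment > 1 under a normal
#' approximation.
#'
#' @param disease a `sumstats` data.frame aligned to the panel variants.
#' @param scores an `ld_scores` object.
#' @param n_blocks jackknife blocks (contiguous variants).
#' @return a `herit_estimate` list: `tau`, `h2` (per category), `h2_total`,
#'   `se_total`, `enrichment` data.frame (category, m, h2, enrichment, se,
#'   p), `intercept`, `n_blocks`.
#' @export
stratified_h2_regression <- function(disease, scores, n_blocks = 20) {
  stopifnot(inherits(scores, "ld_scores"))
  X <- scores$scores
  stopifnot(nrow(X) == nrow(disease))
  N <- disease$n[1]
  A <- scores$annot
  m_c <- scores$m_c
  w <- 1 / pmax(X[, 1], 1)

  fit_fun <- function(keep) {
    tau <- wls_tau(disease$chisq[keep], N * X[keep, , drop = FALSE], w[keep])
    v <- drop(A %*% tau$coef)
    h2_c <- drop(crossprod(A, v))
    list(tau = tau$coef, intercept = tau$intercept, h2_c = h2_c,
         h2_total = sum(v))
  }
  full <- fit_fun(rep(TRUE, nrow(X)))
  m_tot <- nrow(X)
  enr_full <- (full$h2_c / full$h2_total) / (m_c / m_tot)

  blocks <- jackknife_blocks(nrow(X), n_blocks)
  loo <- lapply(blocks, function(b) fit_fun(!seq_len(nrow(X)) %in% b))
  loo_tot <- vapply(loo, `[[`, numeric(1), "h2_total")
  loo_enr <- t(vapply(loo, function(f)
    (f$h2_c / f$h2_total) / (m_c / m_tot), numeric(length(m_c))))
  se_enr <- apply(loo_enr, 2, jackknife_se)
  p_enr <- stats::pnorm((enr_full - 1) / se_enr, lower.tail = FALSE)

  structure(list(
    tau = full$tau, intercept = full$intercept,
    h2 = stats::setNames(full$h2_c, colnames(A)),
    h2_total = full$h2_total, se_total = jackknife_se(loo_tot),
    enrichment = data.frame(category = colnames(A), m = m_c, h2 = full$h2_c,
                            enrichment = enr_full, se = se_enr, p = p_enr,
                            row.names = NULL),
    n_blocks = length(blocks)
  ), class = "herit_estimate")
}

#' Mediated heritability regression
#'
#' Fits `E[chisq_j] = 1 + N sum_c tau_c l_jc + N sum_d omega_d E_jd`
#' (intercept estimated) jointly over the annotation LD scores and one or
#' more mediation score sets. The heritability mediated by set d is
#' `h2_med_d = omega_d x total_d` (total_d = the set's summed cis-genetic
#' variance); non-mediated heritability aggregates the tau side; their sum
#' is the SNP heritability of the fit, and ratios are reported against it.
#' Negative omega estimates are reported as-is with a warning (no
#' truncation). Block-jackknife standard errors cover every derived
#' quantity, including the per-set leave-one-block estimates needed by
#' [mediated_h2_enrichment()].
#'
#' @param disease a `sumstats` data.frame aligned to the panel variants.
#' @param ld an `ld_scores` object.
#' @param score_sets a `mediation_scores` object or list of them.
#' @param n_blocks jackknife blocks.
#' @return a `mediated_h2` list: `omega`, `tau`, `h2_med` (per set),
#'   `h2_med_total`, `h2_nonmed`, `h2_snp`, `ratio` (per set),
#'   `ratio_total`, SEs (`se_*`), `loo` (leave-one-block draws), and
#'   `n_blocks`.
#' @export
mediated_h2_regression <- function(disease, ld, score_sets, n_blocks = 20) {
  if (inherits(score_sets, "mediation_scores")) score_sets <- list(score_sets)
  labels <- vapply(score_sets, `[[`, character(1), "label")
  E <- vapply(score_sets, `[[`, numeric(nrow(ld$scores)), "scores")
  totals <- vapply(score_sets, `[[`, numeric(1), "total")
  N <- disease$n[1]
  X <- cbind(ld$scores, E)
  q_tau <- ncol(ld$scores)
  w <- 1 / pmax(ld$scores[, 1], 1)
  A <- ld$annot

  fit_fun <- function(keep) {
    fit <- wls_tau(disease$chisq[keep], N * X[keep, , drop = FALSE], w[keep])
    tau <- fit$coef[seq_len(q_tau)]
    omega <- fit$coef[-seq_len(q_tau)]
    h2_med <- omega * totals
    h2_nonmed <- sum(A %*% tau)
    h2_snp <- h2_nonmed + sum(h2_med)
    c(omega = unname(omega), h2_med = unname(h2_med),
      h2_nonmed = h2_nonmed, h2_snp = h2_snp,
      ratio = unname(if (abs(h2_snp) > 0) h2_med / h2_snp else
        rep(NA_real_, length(h2_med))),
      ratio_total = if (abs(h2_snp) > 0) sum(h2_med) / h2_snp else NA_real_,
      tau = unname(tau))
  }
  full <- fit_fun(rep(TRUE, nrow(X)))
  k <- length(score_sets)
  if (any(full[seq_len(k)] < 0))
    warning("negative omega estimate(s) reported without truncation")

  blocks <- jackknife_blocks(nrow(X), n_blocks)
  loo <- t(vapply(blocks, function(b)
    fit_fun(!seq_len(nrow(X)) %in% b), numeric(length(full))))
  se <- apply(loo, 2, jackknife_se)

  pick <- function(prefix, k1 = k) {
    idx <- if (k1 == 1) prefix else paste0(prefix, seq_len(k1))
    stats::setNames(full[idx], if (prefix %in% c("omega", "h2_med", "ratio"))
      labels else idx)
  }
  structure(list(
    labels = labels,
    omega = pick("omega"), h2_med = pick("h2_med"),
    h2_med_total = sum(full[paste0("h2_med", if (k == 1) "" else seq_len(k))]),
    h2_nonmed = full[["h2_nonmed"]], h2_snp = full[["h2_snp"]],
    ratio = pick("ratio"), ratio_total = full[["ratio_total"]],
    tau = full[grep("^tau", names(full))],
    se = stats::setNames(se, names(full)),
    se_ratio_total = se[which(names(full) == "ratio_total")],
    se_h2_snp = se[which(names(full) == "h2_snp")],
    loo = loo, n_blocks = length(blocks)
  ), class = "mediated_h2")
}

# weighted least squares of chisq on scaled scores with estimated
# intercept; two passes — the first with the supplied LD-redundancy
# weights, the second adding inverse-variance weights from the fitted
# noncentral chi-square means (var(chisq) ~ 2(2 mu - 1))
wls_tau <- function(chisq, X, w) {
  D <- cbind(1, X)
  one_pass <- function(wt) {
    sw <- sqrt(wt)
    fit <- stats::lm.fit(D * sw, chisq * sw)
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    cf
  }
  cf <- one_pass(w)
  mu <- pmax(drop(D %*% cf), 1)
  cf <- one_pass(w / (2 * (2 * mu - 1)))
  list(intercept = cf[1], coef = cf[-1])
}

jackknife_blocks <- function(m, n_blocks) {
  n_blocks <- max(2L, min(n_blocks, m))
  unname(split(seq_len(m), cut(seq_len(m), n_blocks, labels = FALSE)))
}

#' Union/intersection decomposition of mediated heritability
#'
#' From the separate caQTL and eQTL mediated-heritability estimates and
#' the joint (union) estimate: `intersection = h_ca + h_e - h_union`,
#' `just_ca = h_union - h_e`, `just_e = h_union - h_ca`, and
#' `shared_fraction = intersection / h_e`. The identities
#' `just_ca + just_e + intersection = h_union` and
#' `intersection = h_ca + h_e - h_union` hold exactly by construction;
#' negative components from noisy inputs are passed through.
#'
#' @param h_ca,h_e,h_union mediated heritability of the caQTL set, the
#'   eQTL set, and their union (joint fit).
#' @return a `mediated_decomposition` list.
#' @export
decompose_mediated_h2 <- function(h_ca, h_e, h_union) {
  stopifnot(is.finite(h_ca), is.finite(h_e), is.finite(h_union))
  intersection <- h_ca + h_e - h_union
  structure(list(
    h_ca = h_ca, h_e = h_e, h_union = h_union,
    just_ca = h_union - h_e, just_e = h_union - h_ca,
    intersection = intersection,
    shared_fraction = if (h_e != 0) intersection / h_e else NA_real_
  ), class = "mediated_decomposition")
}

#' Mediated-heritability enrichment of feature subsets
#'
#' `enrichment = (subset h2_med / total h2_med) / prop_features` for each
#' subset, with jackknife SEs when leave-one-block draws are supplied,
#' one-sided p-values for enrichment > 1, and Benjamini-Hochberg adjusted
#' q-values thresholded at `alpha` (a Storey-style adjustment is exposed
#' via `method = "storey"`).
#'
#' @param subset_h2 named vector of subset mediated heritabilities.
#' @param total_h2 total mediated heritability.
#' @param prop_features named vector: proportion of features per subset.
#' @param loo_subset optional blocks x subsets matrix of leave-one-block
#'   subset estimates; `loo_total` the matching total draws.
#' @param loo_total see above.
#' @param alpha significance level on the adjusted values.
#' @param method `"BH"` (default) or `"storey"`.
#' @return data.frame: subset, h2_med, prop_features, enrichment, se, p,
#'   q, significant, undefined.
#' @export
mediated_h2_enrichment <- function(subset_h2, total_h2, prop_features,
                                   loo_subset = NULL, loo_total = NULL,
                                   alpha = 0.05, method = c("BH", "storey")) {
  method <- match.arg(method)
  undefined <- total_h2 <= 0 | prop_features <= 0
  enr <- ifelse(undefined, NA_real_,
                (subset_h2 / total_h2) / prop_features)
  se <- rep(NA_real_, length(enr))
  if (!is.null(loo_subset) && !is.null(loo_total)) {
    loo_enr <- sweep(loo_subset / loo_total, 2, prop_features, "/")
    se <- vapply(seq_along(enr), function(j)
      jackknife_se(loo_enr[, j]), numeric(1))
  }
  p <- stats::pnorm((enr - 1) / se, lower.tail = FALSE)
  q <- if (method == "BH") stats::p.adjust(p, "BH") else storey_q(p)
  data.frame(
    subset = names(subset_h2) %||% seq_along(subset_h2),
    h2_med = unname(subset_h2), prop_features = unname(prop_features),
    enrichment = unname(enr), se = se, p = unname(p), q = unname(q),
    significant = unname(!is.na(q) & q < alpha),
    undefined = unname(undefined), row.names = NULL
  )
}

# Storey-style q-values with pi0 estimated at lambda = 0.5
storey_q <- function(p) {
  ok <- !is.na(p)
  q <- rep(NA_real_, length(p))
  if (!any(ok)) return(q)
  pi0 <- min(1, mean(p[ok] > 0.5, na.rm = TRUE) / 0.5)
  q[ok] <- pi0 * stats::p.adjust(p[ok], "BH")
  q
}
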