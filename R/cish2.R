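#' Cis-heritability by Haseman-Elston regression
#'
#' Standardizes the cis-window dosages, forms the cis genetic relatedness
#' `A_ij = (1/m_cis) sum_k x_ik x_jk`, and regresses the phenotype products
#' `y_i y_j` on `A_ij` over the `i < j` pairs (with intercept). The slope
#' estimates `h2_cis`; it is clipped to [0, 1] for reporting with the raw
#' value retained. The SE is the analytic OLS standard error over pairs
#' (pairs share individuals, so it is an approximation; the
#' likelihood-based estimator [estimate_cis_h2_reml()] serves as a small-n
#' cross-check).
#'
#' @param panel a `genotype_panel`.
#' @param y phenotype vector (one per sample); standardized internally.
#' @param anchor one-row data.frame with `chrom` + `start`/`end` or `tss`.
#' @param window cis window in basepairs.
#' @param maf_min minimum in-sample MAF for cis variants.
#' @return list: `h2` (clipped), `h2_raw`, `se`, `m_cis`, `n`.
#' @export
estimate_cis_h2 <- function(panel, y, anchor, window = 200000,
                            maf_min = 0.05) {
  sel <- cis_variant_idx(panel, anchor, window, maf_min)
  if (length(sel) == 0L) stop("no cis variants in the window")
  n <- nrow(panel$dosages)
  stopifnot(length(y) == n, n >= 30)
  Xs <- standardize_dosages(panel$dosages[, sel, drop = FALSE])
  A <- tcrossprod(Xs) / length(sel)
  ys <- (y - mean(y)) / stats::sd(y)
  P <- tcrossprod(ys)
  ut <- upper.tri(A)
  a <- A[ut]; pr <- P[ut]
  fit <- stats::lm.fit(cbind(1, a), pr)
  h2_raw <- unname(fit$coefficients[2])
  rss <- sum(fit$residuals^2)
  se <- sqrt(rss / (length(a) - 2) / sum((a - mean(a))^2))
  list(h2 = min(max(h2_raw, 0), 1), h2_raw = h2_raw, se = se,
       m_cis = length(sel), n = n)
}

#' Cis-heritability by direct likelihood maximization
#'
#' Restricted maximum likelihood for the one-component model
#' `y ~ N(mu, sigma2 (h2 A + (1 - h2) I))` with `A` the cis relatedness of
#' [estimate_cis_h2()]: the mean is removed by an orthonormal contrast
#' projection and the profile likelihood in `h2` is maximized on [0, 1].
#' Intended as an independent small-sample cross-check of the closed-form
#' Haseman-Elston estimator.
#'
#' @inheritParams estimate_cis_h2
#' @return list: `h2`, `sigma2`, `loglik`, `m_cis`, `n`.
#' @export
estimate_cis_h2_reml <- function(panel, y, anchor, window = 200000,
                                 maf_min = 0.05) {
  sel <- cis_variant_idx(panel, anchor, window, maf_min)
  if (length(sel) == 0L) stop("no cis variants in the window")
  n <- nrow(panel$dosages)
  Xs <- standardize_dosages(panel$dosages[, sel, drop = FALSE])
  A <- tcrossprod(Xs) / length(sel)
  # orthonormal basis of the space orthogonal to the intercept
  K <- qr.Q(qr(cbind(1, diag(n))))[, 2:n, drop = FALSE]
  yk <- drop(crossprod(K, y))
  Ak <- crossprod(K, A %*% K)
  e <- eigen(Ak, symmetric = TRUE)
  y2 <- drop(crossprod(e$vectors, yk))^2
  negll <- function(h2) {
    lam <- h2 * e$values + (1 - h2)
    lam <- pmax(lam, 1e-12)
    s2 <- mean(y2 / lam)
    0.5 * (sum(log(lam)) + (n - 1) * log(s2))
  }
  opt <- stats::optimize(negll, c(0, 1))
  lam <- pmax(opt$minimum * e$values + (1 - opt$minimum), 1e-12)
  list(h2 = opt$minimum, sigma2 = mean(y2 / lam), loglik = -opt$objective,
       m_cis = length(sel), n = n)
}

# indices of usable cis variants around an interval or point anchor
cis_variant_idx <- function(panel, anchor, window, maf_min) {
  pos <- panel$variants$pos
  inwin <- if (!is.null(anchor$tss) && !is.na(anchor$tss[1])) {
    abs(pos - anchor$tss[1]) <= window
  } else {
    pos > anchor$start[1] - window & pos <= anchor$end[1] + window
  }
  freq <- colMeans(panel$dosages) / 2
  maf <- pmin(freq, 1 - freq)
  poly <- apply(panel$dosages, 2, stats::sd) > 0
  which(inwin & maf >= maf_min & poly)
}
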