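#' Peak-to-TSS distance stratification of cis-heritability
#'
#' Splits colocalized caQTL-eQTL pairs into peak-to-TSS distance quintiles
#' (ties assigned to the lower quintile) and tests the qualitative pattern
#' that expression cis-heritability decays with distance while chromatin
#' accessibility cis-heritability does not:
#' \itemize{
#' \item one-sided rank-sum tests of each later quintile against the first
#'   (alternative: later quintile smaller), separately for eQTL and caQTL
#'   `h2_cis`;
#' \item a one-sided paired rank test per quintile (alternative:
#'   caQTL > eQTL);
#' \item ordinary least squares of eQTL `h2_cis` on caQTL `h2_cis` and
#'   distance in units of 100 kb.
#' }
#'
#' @param pairs data.frame with `distance`, `caqtl_h2`, `eqtl_h2`
#'   (>= 10 rows).
#' @return a `distance_analysis` list: `pairs` (with quintile), `rank_p`
#'   (data.frame: quintile 2-5 x {eqtl, caqtl}), `paired_p` (per
#'   quintile), `regression` (term, estimate, se, p), `skipped` quintiles.
#' @export
distance_stratified_h2 <- function(pairs) {
  stopifnot(nrow(pairs) >= 10,
            all(c("distance", "caqtl_h2", "eqtl_h2") %in% names(pairs)))
  n <- nrow(pairs)
  rk <- rank(pairs$distance, ties.method = "min")
  pairs$quintile <- pmin(5L, (5L * (rk - 1L)) %/% n + 1L)

  counts <- table(factor(pairs$quintile, levels = 1:5))
  skipped <- as.integer(names(counts)[counts < 2])
  one_sided <- function(v, k) {
    if (k %in% skipped || 1L %in% skipped) return(NA_real_)
    stats::wilcox.test(v[pairs$quintile == k], v[pairs$quintile == 1],
                       alternative = "less", exact = FALSE)$p.value
  }
  rank_p <- data.frame(
    quintile = 2:5,
    eqtl = vapply(2:5, function(k) one_sided(pairs$eqtl_h2, k), numeric(1)),
    caqtl = vapply(2:5, function(k) one_sided(pairs$caqtl_h2, k), numeric(1))
  )
  paired_p <- vapply(1:5, function(k) {
    if (k %in% skipped) return(NA_real_)
    idx <- pairs$quintile == k
    d <- pairs$caqtl_h2[idx] - pairs$eqtl_h2[idx]
    if (all(d == 0)) return(0.5)
    stats::wilcox.test(pairs$caqtl_h2[idx], pairs$eqtl_h2[idx],
                       paired = TRUE, alternative = "greater",
                       exact = FALSE)$p.value
  }, numeric(1))

  fit <- stats::lm(eqtl_h2 ~ caqtl_h2 + I(distance / 1e5), data = pairs)
  sm <- summary(fit)$coefficients
  regression <- data.frame(
    term = c("intercept", "caqtl_h2", "distance_100kb"),
    estimate = sm[, 1], se = sm[, 2], p = sm[, 4], row.names = NULL
  )
  structure(list(pairs = pairs, rank_p = rank_p, paired_p = paired_p,
                 regression = regression, skipped = skipped),
            class = "distance_analysis")
}
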