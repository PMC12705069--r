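#' Derive a reproducible sub-seed
#'
#' All stochastic operations in the package draw their randomness from a
#' single integer master seed via this hierarchical derivation, so that
#' changing one stage's label never perturbs another stage's stream.
#' The derivation is a small multiplicative hash of the label (and an
#' optional index) folded into the master seed, reduced modulo 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param label character scope label, e.g. `"gwas"`.
#' @param index optional integer index for repeated draws in one scope.
#' @return an integer in `[1, 2^31 - 2]` usable with [set.seed()].
#' @export
derive_seed <- function(seed, label, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.double(seed %% m)
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% m
  h <- (h * 131 + (index %% m)) %% m
  as.integer(h %% (m - 2)) + 1L
}

#' Stable log-sum-exp
#' @param x numeric vector of log-scale values.
#' @return `log(sum(exp(x)))` computed without overflow.
#' @keywords internal
logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b, -Inf when the difference underflows
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

# two-sided / upper-tail chi-square(1) p-value from z
chisq_p <- function(chisq) stats::pchisq(chisq, df = 1, lower.tail = FALSE)

# fill beta/se/z/chisq/p columns consistently from beta, se, n
finish_sumstats <- function(df) {
  stopifnot(all(c("beta", "se") %in% names(df)))
  df$z <- df$beta / df$se
  df$chisq <- df$z^2
  df$p <- chisq_p(df$chisq)
  df
}

# delete-one-block jackknife over a list of leave-one-out estimates
# returns list(se); est_full is the full-sample estimate
jackknife_se <- function(loo, est_full = NULL) {
  loo <- loo[is.finite(loo)]
  b <- length(loo)
  if (b < 2L) return(NA_real_)
  sqrt((b - 1) / b * sum((loo - mean(loo))^2))
}
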