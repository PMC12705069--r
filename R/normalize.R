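#' TMM library-size normalization and CPM
#'
#' Trimmed-mean-of-M-values normalization of a raw count matrix (features x
#' samples) via edgeR, returning per-sample scaling factors (geometric mean
#' 1, reference sample = library whose 75th-percentile count fraction is
#' closest to the mean) and counts-per-million computed against the
#' factor-adjusted library sizes.
#'
#' @param counts features x samples integer matrix, stage `"raw_counts"`.
#' @param trim_m,trim_a trimming fractions for the log-ratio (M) and
#'   absolute-intensity (A) values.
#' @return list with `norm` (data.frame: sample_id, lib_size, factor) and
#'   `cpm` (matrix, stage `"cpm"`).
#' @export
tmm_normalize <- function(counts, trim_m = 0.3, trim_a = 0.05) {
  stopifnot(is.matrix(counts), ncol(counts) >= 2)
  zero <- colSums(counts) == 0
  if (any(zero))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[zero], collapse = ", "))
  f <- edgeR::calcNormFactors(counts, method = "TMM",
                              logratioTrim = trim_m, sumTrim = trim_a)
  lib <- colSums(counts)
  cpm <- t(t(counts) / (lib * f)) * 1e6
  structure_stage <- function(x, s) { attr(x, "stage") <- s; x }
  list(
    norm = data.frame(sample_id = colnames(counts) %||%
                        paste0("S", seq_along(lib)),
                      lib_size = lib, factor = f, row.names = NULL),
    cpm = structure_stage(cpm, "cpm")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Filter features on CPM and count support
#'
#' Drops a feature iff the fraction of samples where (CPM < `cpm_min` OR
#' count < `count_min`) exceeds `max_fail_frac` (strict inequality: a
#' feature failing in exactly that fraction of samples is kept).
#'
#' @param counts raw count matrix (features x samples).
#' @param cpm CPM matrix aligned with `counts`.
#' @param cpm_min,count_min per-sample support thresholds.
#' @param max_fail_frac maximum tolerated fraction of failing samples.
#' @return character vector of retained feature ids, in input order.
#' @export
filter_features <- function(counts, cpm, cpm_min = 0.8, count_min = 10,
                            max_fail_frac = 0.2) {
  if (!identical(dim(counts), dim(cpm)) ||
      !identical(rownames(counts), rownames(cpm)))
    stop("counts and cpm matrices are not aligned")
  fail <- rowMeans(cpm < cpm_min | counts < count_min)
  rownames(counts)[fail <= max_fail_frac]
}

#' Rank-based inverse normal transform
#'
#' Per feature (row), replaces values by `qnorm((rank - 0.5) / n)` with
#' average ranks for ties, yielding near-standard-normal margins.
#' Constant rows become all zeros with a warning.
#'
#' @param x features x samples numeric matrix.
#' @return transformed matrix, stage `"normalized"`.
#' @export
inverse_normal_transform <- function(x) {
  stopifnot(is.matrix(x), !anyNA(x))
  n <- ncol(x)
  out <- t(apply(x, 1, function(row) {
    if (stats::sd(row) == 0) return(rep(0, n))
    stats::qnorm((rank(row, ties.method = "average") - 0.5) / n)
  }))
  if (any(apply(x, 1, stats::sd) == 0))
    warning("constant feature(s) set to zero after inverse normal transform")
  dimnames(out) <- dimnames(x)
  attr(out, "stage") <- "normalized"
  out
}

#' Choose the number of phenotype PCs by parallel analysis
#'
#' Permutation-based (Buja-Eyuboglu) selection: each feature's values are
#' independently permuted across samples `n_perm` times; the retained
#' number of PCs is the count of leading observed eigenvalues exceeding the
#' `(1 - alpha)` permutation quantile of the same-rank eigenvalue, stopping
#' at the first failure. Eigenvalues are those of the samples x features
#' covariance (computed on whichever dimension is smaller — the nonzero
#' spectrum is the same).
#'
#' @param x features x samples matrix (normalized stage).
#' @param n_perm number of permutations (>= 19).
#' @param alpha per-rank significance level.
#' @param seed integer seed.
#' @return integer `K >= 0`.
#' @export
select_num_pcs <- function(x, n_perm = 30, alpha = 0.05, seed = 1L) {
  stopifnot(is.matrix(x))
  if (n_perm < 19) stop("n_perm must be >= 19")
  set.seed(derive_seed(seed, "parallel_analysis"))
  obs <- pa_eigenvalues(x)
  perm <- matrix(NA_real_, n_perm, length(obs))
  for (b in seq_len(n_perm)) {
    xp <- t(apply(x, 1, sample))
    perm[b, ] <- pa_eigenvalues(xp)
  }
  thresh <- apply(perm, 2, stats::quantile, probs = 1 - alpha)
  ok <- obs > thresh
  if (!ok[1]) return(0L)
  which.max(!c(ok, FALSE)) - 1L
}

# eigenvalues of the feature covariance via the smaller-dimension dual
pa_eigenvalues <- function(x) {
  xc <- x - rowMeans(x)
  n <- ncol(xc); p <- nrow(xc)
  S <- if (p <= n) tcrossprod(xc) / (n - 1) else crossprod(xc) / (n - 1)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  ev[seq_len(min(n - 1, p))]
}
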