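#' Per-variant LD scores for annotation categories
#'
#' For every variant j and category c, `l_jc = sum over k in c of
#' r2_adj(j, k)` where r-squared is computed from the panel dosages within
#' the smaller of the stated window and the variant's LD block, and the
#' finite-sample bias adjustment `r2_adj = r2 - (1 - r2) / (n - 2)` is
#' applied (the self term contributes exactly 1).
#'
#' @param panel a `genotype_panel`.
#' @param annotations named list: category -> variant ids or integer
#'   indices. A category `all` covering every variant is a conventional
#'   first entry.
#' @param window maximum pair distance in basepairs.
#' @return an `ld_scores` list: `scores` (variants x categories matrix),
#'   `annot` (binary membership matrix), `m_c` (per-category counts),
#'   `variant_id`, `pos`, `n`.
#' @export
compute_ld_scores <- function(panel, annotations, window = 1e6) {
  A <- annotation_matrix(panel, annotations)
  if (any(colSums(A) == 0))
    warning("annotation category with no variants: ",
            paste(colnames(A)[colSums(A) == 0], collapse = ", "))
  scores <- r2adj_weighted_sums(panel, A, window)
  structure(list(scores = scores, annot = A, m_c = colSums(A),
                 variant_id = panel$variants$id, pos = panel$variants$pos,
                 n = nrow(panel$dosages), window = window),
            class = "ld_scores")
}

#' Per-variant mediation ("expression") scores
#'
#' For a set of molecular features with per-variant cis effects `alpha`
#' (variants x features; true effects in test mode, shrinkage-estimated in
#' pipeline mode), the score of variant j is
#' `E_j = sum_k r2_adj(j, k) * s_k` with `s_k = sum_g alpha_kg^2`, using
#' the same adjusted r-squared and block/window masking as the LD scores.
#' The feature-set total `sum_k s_k` (the summed cis-genetic variance of
#' the set, equal to `sum_g h2_cis_g` in the no-LD convention) is recorded:
#' the mediated-heritability regression multiplies its slope by it.
#'
#' @param panel a `genotype_panel`.
#' @param alpha variants x features matrix of cis effects (standardized
#'   scale), or a per-variant vector of summed squared effects.
#' @param label name of the feature set.
#' @param window maximum pair distance in basepairs.
#' @return a `mediation_scores` list: `scores` (per-variant vector),
#'   `total`, `label`.
#' @export
compute_mediation_scores <- function(panel, alpha, label = "set",
                                     window = 1e6) {
  s <- if (is.matrix(alpha)) rowSums(alpha^2) else as.numeric(alpha)
  stopifnot(length(s) == nrow(panel$variants))
  sc <- r2adj_weighted_sums(panel, matrix(s, ncol = 1), window,
                            weighted = TRUE)
  structure(list(scores = drop(sc), total = sum(s), label = label),
            class = "mediation_scores")
}

# membership matrix from a named list of ids/indices
annotation_matrix <- function(panel, annotations) {
  m <- nrow(panel$variants)
  A <- matrix(0, m, length(annotations),
              dimnames = list(panel$variants$id, names(annotations)))
  for (j in seq_along(annotations)) {
    v <- annotations[[j]]
    idx <- if (is.character(v)) match(v, panel$variants$id) else as.integer(v)
    idx <- idx[!is.na(idx)]
    A[idx, j] <- 1
  }
  A
}

# for column weights W (variants x q): out_j = sum_k r2adj_jk * W_k within
# block and window; W binary gives LD scores, continuous gives mediation
# scores
r2adj_weighted_sums <- function(panel, W, window, weighted = FALSE) {
  n <- nrow(panel$dosages)
  pos <- panel$variants$pos
  out <- matrix(0, nrow(panel$variants), ncol(W),
                dimnames = list(panel$variants$id, colnames(W)))
  for (blk in panel$ld_blocks) {
    R2 <- blk$R^2
    R2a <- R2 - (1 - R2) / (n - 2)
    d <- abs(outer(pos[blk$idx], pos[blk$idx], "-"))
    R2a[d > window] <- 0
    out[blk$idx, ] <- R2a %*% W[blk$idx, , drop = FALSE]
  }
  out
}
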