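#' Simulate an LD-structured genotype panel
#'
#' Generates unphased dosages for `n_samples` diploid individuals at
#' `n_variants` biallelic sites on one chromosome. Each of the two haplotypes
#' per individual is a first-order binary Markov chain along the variant
#' positions: the correlation between the alleles at adjacent variants at
#' genomic distance `d` is `exp(-d / ld_decay)` (clipped to the range the two
#' marginal allele frequencies admit). Because conditional expectations of
#' binary variables are linear, correlation multiplies along the chain, so
#' pairwise LD decays approximately exponentially with distance. Dosage is
#' the haplotype sum; per-block empirical LD correlation matrices are stored.
#'
#' @param n_samples number of diploid individuals (>= 2).
#' @param n_variants number of variants.
#' @param region_length chromosome length in basepairs; positions are drawn
#'   uniformly without replacement and sorted.
#' @param maf_range length-2 interval inside (0, 0.5] from which each
#'   variant's minor (= alternate) allele frequency is drawn.
#' @param ld_decay exponential LD decay scale in basepairs (> 0).
#' @param n_blocks number of contiguous LD blocks (equal variant counts).
#' @param ld_decay_sd log-normal SD of per-segment multipliers on
#'   `ld_decay` (one segment per block): recombination-hotspot-like
#'   heterogeneity, giving LD scores genuine variation along the region.
#'   0 gives homogeneous decay.
#' @param seed integer seed; the draw is deterministic given it.
#' @return an object of class `genotype_panel`: a list with `variants`
#'   (data.frame: id, chrom, pos, ref, alt, maf), `sample_ids`, `dosages`
#'   (samples x variants matrix of 0/1/2), `ld_blocks` (list of
#'   `list(idx, R)`), and the generating parameters (so independent cohorts
#'   can be re-drawn on the same variant frame, see [resample_genotypes()]).
#' @export
simulate_genotype_panel <- function(n_samples, n_variants, region_length,
                                    maf_range = c(0.05, 0.5),
                                    ld_decay = 20000, n_blocks = 10,
                                    ld_decay_sd = 0.75, seed = 1L) {
  stopifnot(n_samples >= 2, n_variants >= 1, region_length >= n_variants)
  if (ld_decay <= 0) stop("ld_decay must be positive")
  if (n_variants < n_blocks) stop("n_variants must be >= n_blocks")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("maf_range must lie within (0, 0.5]")

  set.seed(derive_seed(seed, "genotype_panel"))
  pos <- sort(sample.int(region_length, n_variants))
  segment <- if (n_blocks <= 1L) rep(1L, n_variants) else
    cut(seq_len(n_variants), n_blocks, labels = FALSE)
  decay <- ld_decay * exp(stats::rnorm(n_blocks, 0, ld_decay_sd))[segment]
  maf <- draw_maf_walk(pos, maf_range, decay)
  variants <- data.frame(
    id = sprintf("var%05d", seq_len(n_variants)),
    chrom = "chr1", pos = pos,
    ref = "A", alt = "G",
    maf = maf, stringsAsFactors = FALSE
  )
  H <- draw_haplotypes(2L * n_samples, variants, decay)
  dosages <- H[seq_len(n_samples), , drop = FALSE] +
    H[n_samples + seq_len(n_samples), , drop = FALSE]
  sample_ids <- sprintf("S%04d", seq_len(n_samples))
  dimnames(dosages) <- list(sample_ids, variants$id)

  panel <- structure(list(
    variants = variants, sample_ids = sample_ids, dosages = dosages,
    ld_blocks = NULL,
    params = list(region_length = region_length, ld_decay = ld_decay,
                  decay_bp = decay, n_blocks = n_blocks, seed = seed)
  ), class = "genotype_panel")
  panel$ld_blocks <- panel_ld_blocks(dosages, n_blocks)
  panel
}

# allele frequencies as a bounded random walk whose step size shrinks with
# the target adjacent LD: variants in tight LD carry similar frequencies,
# which keeps the requested correlation inside the Frechet-feasible range
# for the binary pair (and mirrors real data, where strong LD implies
# near-identical allele frequencies)
draw_maf_walk <- function(pos, maf_range, decay) {
  m <- length(pos)
  decay <- rep_len(decay, m)
  maf <- numeric(m)
  maf[1] <- stats::runif(1, maf_range[1], maf_range[2])
  if (m == 1L) return(maf)
  span <- maf_range[2] - maf_range[1]
  for (k in 2:m) {
    r <- exp(-(pos[k] - pos[k - 1]) / decay[k])
    step <- stats::rnorm(1, 0, 0.4 * span * (1 - r) + 0.002)
    maf[k] <- reflect_into(maf[k - 1] + step, maf_range[1], maf_range[2])
  }
  maf
}

reflect_into <- function(x, lo, hi) {
  while (x < lo || x > hi) {
    if (x < lo) x <- 2 * lo - x
    if (x > hi) x <- 2 * hi - x
  }
  x
}

# alleles for n_hap haplotypes as a binary Markov chain with the target
# adjacent correlation; the alt allele carries frequency maf
draw_haplotypes <- function(n_hap, variants, decay) {
  m <- nrow(variants)
  decay <- rep_len(decay, m)
  maf <- variants$maf
  H <- matrix(0L, n_hap, m)
  H[, 1] <- stats::rbinom(n_hap, 1L, maf[1])
  if (m == 1L) return(H)
  for (k in 2:m) {
    f1 <- maf[k - 1]; f2 <- maf[k]
    d <- variants$pos[k] - variants$pos[k - 1]
    r <- exp(-d / decay[k])
    r_max <- (min(f1, f2) - f1 * f2) / sqrt(f1 * (1 - f1) * f2 * (1 - f2))
    r <- min(r, r_max)
    p11 <- f1 * f2 + r * sqrt(f1 * (1 - f1) * f2 * (1 - f2))
    p_given1 <- p11 / f1
    p_given0 <- (f2 - p11) / (1 - f1)
    pr <- ifelse(H[, k - 1] == 1L, p_given1, p_given0)
    H[, k] <- stats::rbinom(n_hap, 1L, pmin(pmax(pr, 0), 1))
  }
  H
}

# contiguous equal-count blocks with empirical correlation matrices;
# monomorphic columns get zero correlation and unit diagonal
panel_ld_blocks <- function(dosages, n_blocks) {
  m <- ncol(dosages)
  cut_idx <- if (n_blocks <= 1L) list(seq_len(m)) else
    split(seq_len(m), cut(seq_len(m), n_blocks, labels = FALSE))
  lapply(unname(cut_idx), function(idx) {
    R <- suppressWarnings(stats::cor(dosages[, idx, drop = FALSE]))
    R[!is.finite(R)] <- 0
    diag(R) <- 1
    list(idx = idx, R = R)
  })
}

#' Draw an independent cohort on an existing variant frame
#'
#' Re-runs the haplotype generator of [simulate_genotype_panel()] with the
#' same variant positions, allele frequencies and LD decay but a fresh seed,
#' giving an independent sample from the same population — used to give each
#' simulated QTL study its own individuals sharing true effects.
#'
#' @param panel a `genotype_panel`.
#' @param n_samples cohort size.
#' @param seed integer seed.
#' @return a `genotype_panel` with the same `variants` table.
#' @export
resample_genotypes <- function(panel, n_samples, seed) {
  stopifnot(inherits(panel, "genotype_panel"), n_samples >= 2)
  set.seed(derive_seed(seed, "resample_genotypes"))
  H <- draw_haplotypes(2L * n_samples, panel$variants,
                       panel$params$decay_bp %||% panel$params$ld_decay)
  dosages <- H[seq_len(n_samples), , drop = FALSE] +
    H[n_samples + seq_len(n_samples), , drop = FALSE]
  sample_ids <- sprintf("R%04d", seq_len(n_samples))
  dimnames(dosages) <- list(sample_ids, panel$variants$id)
  out <- panel
  out$sample_ids <- sample_ids
  out$dosages <- dosages
  out$ld_blocks <- panel_ld_blocks(dosages, panel$params$n_blocks)
  out
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d samples x %d variants, %d LD blocks\n",
              nrow(x$dosages), ncol(x$dosages), length(x$ld_blocks)))
  invisible(x)
}

# column-standardized dosages (monomorphic columns -> 0)
standardize_dosages <- function(dosages) {
  mu <- colMeans(dosages)
  sdv <- apply(dosages, 2, stats::sd)
  sdv[sdv == 0] <- Inf
  sweep(sweep(dosages, 2, mu, "-"), 2, sdv, "/")
}
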