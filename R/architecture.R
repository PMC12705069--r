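#' Simulate a ground-truth regulatory architecture
#'
#' Builds the causal model linking genotypes to chromatin accessibility,
#' gene expression and disease liability:
#' \itemize{
#' \item each peak independently receives (with probability `p_causal_peak`)
#'   one causal variant, uniform among the variants inside its interval,
#'   with accessibility effect `b_ca ~ N(0, sigma_ca^2)` on the
#'   standardized-dosage scale;
#' \item each (peak, gene) pair within `wiring_window` of each other gets a
#'   wiring weight `w ~ N(0, wiring_scale^2) * exp(-distance / wiring_decay)`;
#'   per context, each edge is active with probability
#'   `prop_active_per_context` (the first context always keeps an edge's
#'   activity draw; contexts are independent);
#' \item disease liability receives gene-level effects
#'   `gamma_g ~ N(0, gamma_scale^2)` on a random fraction
#'   `prop_disease_genes` of genes, peak-level effects
#'   `delta_p ~ N(0, delta_scale^2)` on a fraction `prop_disease_peaks` of
#'   causal peaks, and optional direct (non-mediated) variant effects.
#' }
#'
#' The three disease-effect layers (expression path, accessibility path,
#' direct path) are orthogonalized sequentially in the LD metric
#' (`<a, b> = sum over blocks of a' R b`), so the stored heritability truths
#' are exactly additive: `h2_snp = h2_med_eqtl + h2_acc_only + h2_direct`
#' and `h2_med_caqtl = h2_med_eqtl + h2_acc_only`. When `h2_snp_target` is
#' given, effects are rescaled so the disease liability (variance 1) has
#' exactly that SNP heritability; with `prop_mediated_target` the split
#' between the peak-mediated and direct components is also exact.
#'
#' @param panel a `genotype_panel`.
#' @param peaks,genes feature tables as from [simulate_features()].
#' @param p_causal_peak probability a peak has a causal variant.
#' @param sigma_ca SD of the causal accessibility effect.
#' @param wiring_decay exponential decay scale (bp) of wiring magnitude;
#'   `Inf` disables distance attenuation.
#' @param wiring_scale SD of the raw wiring weight.
#' @param wiring_window maximum peak-to-TSS distance (bp) for an edge.
#' @param contexts character vector of context labels.
#' @param prop_active_per_context probability an edge is active in a context.
#' @param gamma_scale,delta_scale SDs of gene- and peak-level disease effects.
#' @param prop_disease_genes,prop_disease_peaks fractions of features with
#'   disease effects.
#' @param direct_scale,prop_direct SD and fraction for direct (non-mediated)
#'   per-variant disease effects.
#' @param peak_noise_var,gene_noise_var non-genetic variances of the latent
#'   accessibility and expression phenotypes.
#' @param h2_snp_target,prop_mediated_target optional exact calibration of
#'   the disease architecture (see Details).
#' @param disease_context context whose wiring carries disease mediation.
#' @param seed integer seed.
#' @return an object of class `regulatory_model`.
#' @export
simulate_regulatory_model <- function(panel, peaks, genes,
                                      p_causal_peak = 0.8, sigma_ca = 0.6,
                                      wiring_decay = 50000,
                                      wiring_scale = 0.6,
                                      wiring_window = 200000,
                                      contexts = "ctx1",
                                      prop_active_per_context = 0.7,
                                      gamma_scale = 0.1, delta_scale = 0.1,
                                      prop_disease_genes = 0.3,
                                      prop_disease_peaks = 0.3,
                                      direct_scale = 0, prop_direct = 0.05,
                                      peak_noise_var = 0.64,
                                      gene_noise_var = 0.5,
                                      h2_snp_target = NULL,
                                      prop_mediated_target = NULL,
                                      disease_context = contexts[1],
                                      seed = 1L) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (nrow(peaks) == 0L) stop("empty peak list")
  stopifnot(disease_context %in% contexts)
  set.seed(derive_seed(seed, "regulatory_model"))
  m <- nrow(panel$variants)
  pos <- panel$variants$pos

  ## causal variant per peak (at most one; uniform among contained variants)
  peak_causal <- data.frame(peak_id = peaks$id, variant_idx = NA_integer_,
                            b_ca = 0, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(peaks))) {
    inside <- which(pos > peaks$start[i] & pos <= peaks$end[i])
    if (length(inside) > 0L && stats::runif(1) < p_causal_peak) {
      peak_causal$variant_idx[i] <-
        if (length(inside) == 1L) inside else sample(inside, 1L)
      peak_causal$b_ca[i] <- stats::rnorm(1, 0, sigma_ca)
    }
  }

  ## distance-decaying wiring with per-context activity masks
  wiring <- make_wiring(peaks, genes, wiring_decay, wiring_scale,
                        wiring_window, contexts, prop_active_per_context)

  ## disease effect layers
  gamma <- stats::setNames(numeric(nrow(genes)), genes$id)
  idx_g <- which(stats::runif(nrow(genes)) < prop_disease_genes)
  gamma[idx_g] <- stats::rnorm(length(idx_g), 0, gamma_scale)
  delta <- stats::setNames(numeric(nrow(peaks)), peaks$id)
  idx_p <- which(stats::runif(nrow(peaks)) < prop_disease_peaks)
  delta[idx_p] <- stats::rnorm(length(idx_p), 0, delta_scale)
  beta_direct <- numeric(m)
  if (direct_scale > 0) {
    idx_d <- which(stats::runif(m) < prop_direct)
    beta_direct[idx_d] <- stats::rnorm(length(idx_d), 0, direct_scale)
  }

  build_regulatory_model(panel, peaks, genes, peak_causal, wiring, gamma,
                         delta, beta_direct, peak_noise_var, gene_noise_var,
                         h2_snp_target, prop_mediated_target, contexts,
                         disease_context, seed)
}

#' Assemble a regulatory model from explicit components
#'
#' Deterministic counterpart of [simulate_regulatory_model()]: given a
#' causal-variant table, wiring table (with per-context `active_*`
#' columns), disease effect vectors and noise variances, derives every
#' truth field (per-variant cis effects, disease effect vector with
#' orthogonalized layers, cis and SNP heritabilities). Useful for
#' planting bespoke architectures in experiments.
#'
#' @param panel a `genotype_panel`.
#' @param peaks,genes feature tables.
#' @param peak_causal data.frame: peak_id, variant_idx, b_ca (`NA`
#'   variant_idx = no causal).
#' @param wiring data.frame: peak_id, gene_id, distance, weight, plus one
#'   logical `active_<context>` column per context.
#' @param gamma,delta named disease effect vectors over genes and peaks.
#' @param beta_direct per-variant direct disease effects.
#' @param peak_noise_var,gene_noise_var latent noise variances.
#' @param h2_snp_target,prop_mediated_target optional exact calibration.
#' @param contexts,disease_context context labels.
#' @param seed recorded seed (bookkeeping only).
#' @return a `regulatory_model`.
#' @export
build_regulatory_model <- function(panel, peaks, genes, peak_causal, wiring,
                                   gamma, delta, beta_direct,
                                   peak_noise_var = 0.64,
                                   gene_noise_var = 0.5,
                                   h2_snp_target = NULL,
                                   prop_mediated_target = NULL,
                                   contexts, disease_context = contexts[1],
                                   seed = NA_integer_) {
  m <- nrow(panel$variants)

  ## per-variant cis effects (alpha) per context, and for peaks
  alpha_peaks <- numeric(m) # b_ca at each peak's causal variant
  ok <- !is.na(peak_causal$variant_idx)
  alpha_peaks[peak_causal$variant_idx[ok]] <-
    alpha_peaks[peak_causal$variant_idx[ok]] + peak_causal$b_ca[ok]
  alpha_genes <- lapply(stats::setNames(contexts, contexts), function(ctx)
    gene_alpha_matrix(m, genes, peak_causal, wiring, ctx))

  ## raw disease effect vectors on the standardized-variant scale
  W <- wiring[wiring[[paste0("active_", disease_context)]], , drop = FALSE]
  causal_of <- stats::setNames(peak_causal$variant_idx, peak_causal$peak_id)
  b_of <- stats::setNames(peak_causal$b_ca, peak_causal$peak_id)
  beta_gamma <- numeric(m) # variant -> accessibility -> expression -> disease
  if (nrow(W) > 0L) {
    contrib <- b_of[W$peak_id] * W$weight * gamma[W$gene_id]
    k <- causal_of[W$peak_id]
    keep <- !is.na(k) & contrib != 0
    if (any(keep)) {
      agg <- tapply(contrib[keep], k[keep], sum)
      beta_gamma[as.integer(names(agg))] <- as.numeric(agg)
    }
  }
  beta_delta <- numeric(m) # variant -> accessibility -> disease
  kk <- peak_causal$variant_idx[ok]
  beta_delta[kk] <- beta_delta[kk] +
    peak_causal$b_ca[ok] * delta[peak_causal$peak_id[ok]]

  calib <- calibrate_disease_effects(panel, beta_gamma, beta_delta,
                                     beta_direct, h2_snp_target,
                                     prop_mediated_target)

  h2_cis_peaks <- ifelse(ok, peak_causal$b_ca^2 /
                           (peak_causal$b_ca^2 + peak_noise_var), 0)
  h2_cis_genes <- sapply(contexts, function(ctx)
    gene_h2_cis(panel, alpha_genes[[ctx]], wiring, ctx,
                peak_noise_var, gene_noise_var))
  if (is.null(dim(h2_cis_genes)))
    h2_cis_genes <- matrix(h2_cis_genes, ncol = length(contexts),
                           dimnames = list(genes$id, contexts))

  structure(list(
    peaks = peaks, genes = genes, peak_causal = peak_causal,
    wiring = wiring, gamma = gamma, delta = delta,
    alpha_peaks = alpha_peaks, alpha_genes = alpha_genes,
    beta = calib$beta, beta_components = calib$components,
    h2_snp = calib$h2_snp, h2_med_caqtl = calib$h2_med_caqtl,
    h2_med_eqtl = calib$h2_med_eqtl,
    h2_cis_peaks = stats::setNames(h2_cis_peaks, peaks$id),
    h2_cis_genes = h2_cis_genes,
    peak_noise_var = peak_noise_var, gene_noise_var = gene_noise_var,
    contexts = contexts, disease_context = disease_context, seed = seed
  ), class = "regulatory_model")
}

make_wiring <- function(peaks, genes, wiring_decay, wiring_scale,
                        wiring_window, contexts, prop_active) {
  mid <- (peaks$start + peaks$end) / 2
  cand <- expand.grid(pi = seq_len(nrow(peaks)), gi = seq_len(nrow(genes)))
  d <- peak_tss_distance_vec(peaks[cand$pi, , drop = FALSE],
                             genes[cand$gi, , drop = FALSE])
  keep <- d <= wiring_window
  cand <- cand[keep, , drop = FALSE]; d <- d[keep]
  decay <- if (is.finite(wiring_decay)) exp(-d / wiring_decay) else 1
  wiring <- data.frame(
    peak_id = peaks$id[cand$pi], gene_id = genes$id[cand$gi],
    distance = d,
    weight = stats::rnorm(nrow(cand), 0, wiring_scale) * decay,
    stringsAsFactors = FALSE
  )
  for (ctx in contexts)
    wiring[[paste0("active_", ctx)]] <-
      stats::runif(nrow(wiring)) < prop_active
  wiring
}

gene_alpha_matrix <- function(m, genes, peak_causal, wiring, ctx) {
  A <- matrix(0, m, nrow(genes), dimnames = list(NULL, genes$id))
  W <- wiring[wiring[[paste0("active_", ctx)]], , drop = FALSE]
  if (nrow(W) == 0L) return(A)
  causal_of <- stats::setNames(peak_causal$variant_idx, peak_causal$peak_id)
  b_of <- stats::setNames(peak_causal$b_ca, peak_causal$peak_id)
  k <- causal_of[W$peak_id]
  keep <- !is.na(k)
  if (any(keep)) {
    idx <- cbind(as.integer(k[keep]), match(W$gene_id[keep], genes$id))
    contrib <- b_of[W$peak_id[keep]] * W$weight[keep]
    for (r in seq_len(nrow(idx)))
      A[idx[r, 1], idx[r, 2]] <- A[idx[r, 1], idx[r, 2]] + contrib[r]
  }
  A
}

gene_h2_cis <- function(panel, alpha, wiring, ctx, peak_noise_var,
                        gene_noise_var) {
  W <- wiring[wiring[[paste0("active_", ctx)]], , drop = FALSE]
  genic <- apply(alpha, 2, function(a) qform_blocks(panel, a, a))
  prop_noise <- stats::setNames(numeric(ncol(alpha)), colnames(alpha))
  if (nrow(W) > 0L) {
    pn <- tapply(W$weight^2 * peak_noise_var, W$gene_id, sum)
    prop_noise[names(pn)] <- pn
  }
  genic / (genic + prop_noise + gene_noise_var)
}

# LD-metric bilinear form <a, b> = sum over blocks of a' R b
qform_blocks <- function(panel, a, b) {
  tot <- 0
  for (blk in panel$ld_blocks) {
    ai <- a[blk$idx]; bi <- b[blk$idx]
    if (all(ai == 0) || all(bi == 0)) next
    tot <- tot + drop(crossprod(ai, blk$R %*% bi))
  }
  tot
}

# sequential Gram-Schmidt in the LD metric + optional exact calibration
calibrate_disease_effects <- function(panel, beta_gamma, beta_delta,
                                      beta_direct, h2_snp_target,
                                      prop_mediated_target) {
  q <- function(a, b = a) qform_blocks(panel, a, b)
  qg <- q(beta_gamma)
  # accessibility-only component, orthogonal to the expression path
  bd <- beta_delta
  if (qg > 0) bd <- bd - (q(beta_gamma, beta_delta) / qg) * beta_gamma
  qd <- q(bd)
  bmed <- beta_gamma + bd
  qmed <- qg + qd
  # direct component, orthogonal to the mediated span
  bdir <- beta_direct
  if (qg > 0) bdir <- bdir - (q(beta_gamma, bdir) / qg) * beta_gamma
  if (qd > 0) bdir <- bdir - (q(bd, bdir) / qd) * bd
  qdir <- q(bdir)

  if (!is.null(h2_snp_target) && !is.null(prop_mediated_target)) {
    s_med <- if (qmed > 0)
      sqrt(h2_snp_target * prop_mediated_target / qmed) else 0
    s_dir <- if (qdir > 0)
      sqrt(h2_snp_target * (1 - prop_mediated_target) / qdir) else 0
    beta_gamma <- s_med * beta_gamma; bd <- s_med * bd; bdir <- s_dir * bdir
  } else if (!is.null(h2_snp_target)) {
    tot <- qmed + qdir
    s <- if (tot > 0) sqrt(h2_snp_target / tot) else 0
    beta_gamma <- s * beta_gamma; bd <- s * bd; bdir <- s * bdir
  }
  beta <- beta_gamma + bd + bdir
  h2_e <- q(beta_gamma); h2_acc <- q(bd); h2_dir <- q(bdir)
  list(beta = beta,
       components = list(expression = beta_gamma, accessibility_only = bd,
                         direct = bdir),
       h2_snp = h2_e + h2_acc + h2_dir,
       h2_med_caqtl = h2_e + h2_acc,
       h2_med_eqtl = h2_e)
}

#' @export
print.regulatory_model <- function(x, ...) {
  cat(sprintf(
    "regulatory_model: %d peaks (%d causal), %d genes, %d contexts\n",
    nrow(x$peaks), sum(!is.na(x$peak_causal$variant_idx)), nrow(x$genes),
    length(x$contexts)))
  cat(sprintf("  h2_snp = %.4f, h2_med(caQTL) = %.4f, h2_med(eQTL) = %.4f\n",
              x$h2_snp, x$h2_med_caqtl, x$h2_med_eqtl))
  invisible(x)
}
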