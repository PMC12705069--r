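#' Simulate GWAS summary statistics from the multivariate normal law
#'
#' Draws per-variant association z-scores for the disease trait directly
#' from the asymptotic sampling distribution of marginal GWAS effects:
#' within each LD block, `z ~ MVN(sqrt(n_gwas) * R beta_block, R)`. Effect
#' estimates are `beta = z / sqrt(n_gwas)` with `se = 1 / sqrt(n_gwas)`
#' (standardized-trait, standardized-genotype scale). Blocks whose empirical
#' correlation matrix is not positive semi-definite are repaired by clipping
#' negative eigenvalues at zero and renormalizing the diagonal (with a
#' warning).
#'
#' @param panel a `genotype_panel`.
#' @param model a `regulatory_model` carrying the disease effect vector.
#' @param n_gwas GWAS sample size.
#' @param seed integer seed.
#' @return a `sumstats` data.frame: variant_id, chrom, pos, ref, alt, beta,
#'   se, z, chisq, p, n; attributes `trait_id`, `trait_type`, `study_id`.
#' @export
simulate_gwas_summary <- function(panel, model, n_gwas, seed = 1L) {
  stopifnot(inherits(panel, "genotype_panel"),
            inherits(model, "regulatory_model"), n_gwas >= 2)
  set.seed(derive_seed(seed, "gwas_summary"))
  beta <- model$beta
  z <- numeric(length(beta))
  for (blk in panel$ld_blocks) {
    R <- blk$R
    mu <- sqrt(n_gwas) * drop(R %*% beta[blk$idx])
    L <- chol_psd(R)
    z[blk$idx] <- mu + drop(crossprod(L, stats::rnorm(nrow(R))))
  }
  out <- data.frame(
    variant_id = panel$variants$id, chrom = panel$variants$chrom,
    pos = panel$variants$pos, ref = panel$variants$ref,
    alt = panel$variants$alt,
    beta = z / sqrt(n_gwas), se = 1 / sqrt(n_gwas),
    n = n_gwas, stringsAsFactors = FALSE
  )
  out <- finish_sumstats(out)
  structure(out, class = c("sumstats", "data.frame"),
            trait_id = "disease", trait_type = "disease",
            study_id = "gwas_sim")
}

# upper-triangular factor of a correlation matrix, repairing indefiniteness
# by eigenvalue clipping at 0 and diagonal renormalization
chol_psd <- function(R) {
  ch <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(ch)) # tolerate numerically semi-definite empirical R
    ch <- tryCatch(chol(R + 1e-8 * diag(nrow(R))), error = function(e) NULL)
  if (!is.null(ch)) return(ch)
  warning("LD block not positive semi-definite; clipped eigenvalues at 0")
  e <- eigen(R, symmetric = TRUE)
  v <- pmax(e$values, 0)
  Rfix <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(Rfix)); d[d == 0] <- 1
  Rfix <- Rfix / tcrossprod(d)
  chol(Rfix + 1e-10 * diag(nrow(R)))
}

#' Simulate several eQTL studies sharing true effects
#'
#' For each requested sample size an independent cohort is drawn from the
#' panel's population ([resample_genotypes()]), expression phenotypes are
#' simulated under the shared regulatory model, processed through the
#' standard normalization path (TMM, CPM/count filter, inverse normal
#' transform) and cis-mapped around gene TSSs. Studies therefore share the
#' true effects but have independent individuals and noise.
#'
#' @param panel a `genotype_panel`.
#' @param model a `regulatory_model`.
#' @param sample_sizes integer vector of per-study sample sizes (>= 10).
#' @param context context label whose wiring is active in these studies.
#' @param cis_window cis window around the TSS (bp).
#' @param mean_depth,dispersion count model parameters.
#' @param seed integer seed.
#' @return list of studies, each `list(study_id, n, cis)` where `cis` is a
#'   `cis_results` table.
#' @export
simulate_eqtl_studies <- function(panel, model, sample_sizes, context,
                                  cis_window = 1e6, mean_depth = 50,
                                  dispersion = 0.1, seed = 1L) {
  stopifnot(all(sample_sizes >= 10))
  anchors <- data.frame(feature_id = model$genes$id,
                        chrom = model$genes$chrom, tss = model$genes$tss,
                        stringsAsFactors = FALSE)
  lapply(seq_along(sample_sizes), function(i) {
    ni <- sample_sizes[i]
    cohort <- resample_genotypes(panel, ni, derive_seed(seed, "eqtl_cohort", i))
    phen <- simulate_molecular_phenotypes(
      cohort, model, context, mean_depth = mean_depth,
      dispersion = dispersion, seed = derive_seed(seed, "eqtl_pheno", i))
    cis <- qtl_scan_counts(cohort, phen$expression, anchors, cis_window)
    list(study_id = sprintf("study%02d_%s", i, context), n = ni, cis = cis)
  })
}

# counts -> TMM/CPM -> filter -> INT -> cis scan (no latent covariates)
qtl_scan_counts <- function(cohort, counts, anchors, cis_window,
                            maf_min = 0.05) {
  tn <- tmm_normalize(counts)
  keep <- filter_features(counts, tn$cpm)
  if (length(keep) == 0L) stop("no features pass the CPM/count filter")
  y <- inverse_normal_transform(log2(tn$cpm[keep, , drop = FALSE] + 1))
  map_cis_qtl(cohort, y, covariates = NULL, anchors = anchors,
              cis_window = cis_window, maf_min = maf_min)
}
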