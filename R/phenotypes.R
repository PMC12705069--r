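#' Simulate molecular phenotype count matrices
#'
#' Generates raw ATAC-style (peak accessibility) and RNA-style (gene
#' expression) count matrices for one context. Latent peak activity is
#' `a_p = b_ca * dosage_std + N(0, peak_noise_var)`; latent expression is
#' `x_g = sum over active edges of w_pg * a_p + N(0, gene_noise_var)`.
#' Counts are negative binomial with mean
#' `lib_s * base_f * exp(eta * latent)` — a per-sample library-size factor,
#' a per-feature baseline abundance centred on `mean_depth`, and an
#' exponential link on the latent value. `dispersion = 0` gives Poisson
#' counts.
#'
#' @param panel a `genotype_panel` (the cohort to phenotype).
#' @param model a `regulatory_model`.
#' @param context one of `model$contexts`.
#' @param mean_depth median expected count per feature.
#' @param dispersion negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); 0 for Poisson.
#' @param eta scale of the latent value on the log-mean.
#' @param seed integer seed.
#' @return list with `accessibility` and `expression`: integer count
#'   matrices (features x samples, stage `"raw_counts"`) carrying the truth
#'   latent matrices as attribute `"latent"`.
#' @export
simulate_molecular_phenotypes <- function(panel, model, context,
                                          mean_depth = 50, dispersion = 0.1,
                                          eta = 0.5, seed = 1L) {
  stopifnot(inherits(panel, "genotype_panel"),
            inherits(model, "regulatory_model"))
  if (!context %in% model$contexts) stop("unknown context: ", context)
  set.seed(derive_seed(seed, paste0("phenotypes_", context)))
  n <- nrow(panel$dosages)
  Xs <- standardize_dosages(panel$dosages)

  pc <- model$peak_causal
  n_peaks <- nrow(pc)
  A <- matrix(stats::rnorm(n * n_peaks, 0, sqrt(model$peak_noise_var)),
              n, n_peaks, dimnames = list(panel$sample_ids, pc$peak_id))
  ok <- !is.na(pc$variant_idx)
  if (any(ok))
    A[, ok] <- A[, ok] + Xs[, pc$variant_idx[ok], drop = FALSE] %*%
      diag(pc$b_ca[ok], nrow = sum(ok))

  W <- model$wiring[model$wiring[[paste0("active_", context)]], ,
                    drop = FALSE]
  genes <- model$genes$id
  Wmat <- matrix(0, n_peaks, length(genes),
                 dimnames = list(pc$peak_id, genes))
  if (nrow(W) > 0L)
    Wmat[cbind(match(W$peak_id, pc$peak_id), match(W$gene_id, genes))] <-
      Wmat[cbind(match(W$peak_id, pc$peak_id), match(W$gene_id, genes))] +
      W$weight
  X <- A %*% Wmat +
    matrix(stats::rnorm(n * length(genes), 0, sqrt(model$gene_noise_var)),
           n, length(genes))
  dimnames(X) <- list(panel$sample_ids, genes)

  lib <- exp(stats::rnorm(n, 0, 0.2))
  acc <- latent_to_counts(t(A), lib, mean_depth, dispersion, eta)
  expr <- latent_to_counts(t(X), lib, mean_depth, dispersion, eta)
  list(accessibility = acc, expression = expr)
}

# features x samples latent matrix -> NB counts with stage and truth attrs
latent_to_counts <- function(latent, lib, mean_depth, dispersion, eta) {
  nf <- nrow(latent); ns <- ncol(latent)
  base <- mean_depth * exp(stats::rnorm(nf, 0, 0.7) - 0.245) # lognormal, mean ~ mean_depth
  mu <- (base * exp(eta * latent)) %*% diag(lib, nrow = ns)
  counts <- if (dispersion <= 0) {
    matrix(stats::rpois(length(mu), mu), nf, ns)
  } else {
    matrix(stats::rnbinom(length(mu), size = 1 / dispersion, mu = mu), nf, ns)
  }
  dimnames(counts) <- dimnames(latent)
  structure(counts, stage = "raw_counts", latent = latent)
}

#' Stage tag of a phenotype matrix
#' @param x a matrix produced by the simulation or normalization steps.
#' @return one of `"raw_counts"`, `"cpm"`, `"normalized"` (or `NULL`).
#' @export
pm_stage <- function(x) attr(x, "stage", exact = TRUE)
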