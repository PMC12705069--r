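#' Colocalization discrimination study
#'
#' Simulates independent loci under the shared-causal and distinct-causal
#' generative models and records the posterior each receives. Shared loci
#' carry one variant that is causal for both the disease (summary
#' statistics drawn from the multivariate normal law at `n_gwas`) and a
#' molecular phenotype (mapped by actual regression in a cohort of
#' `n_qtl`); distinct loci place the two causal variants at low LD
#' (r-squared below `r2_max_distinct`).
#'
#' @param n_shared,n_distinct locus counts.
#' @param n_gwas GWAS sample size.
#' @param n_qtl QTL cohort size.
#' @param h2_cis cis-heritability of the molecular phenotype.
#' @param chisq_gwas expected GWAS chi-square at the causal variant.
#' @param r2_max_distinct LD ceiling between the two causal variants of a
#'   distinct locus.
#' @param seed integer seed.
#' @return data.frame: locus, type (shared/distinct), pp_shared,
#'   pp_distinct, colocalized.
#' @export
experiment_coloc_discrimination <- function(n_shared = 100,
                                            n_distinct = 100,
                                            n_gwas = 50000, n_qtl = 400,
                                            h2_cis = 0.3, chisq_gwas = 30,
                                            r2_max_distinct = 0.05,
                                            seed = 1L) {
  one_locus <- function(i, shared) {
    p <- simulate_genotype_panel(n_qtl, 120, 3e5, c(0.1, 0.5),
                                 ld_decay = 15000, n_blocks = 2,
                                 seed = derive_seed(seed, "locus", i))
    set.seed(derive_seed(seed, "locus_draw", i))
    m <- nrow(p$variants)
    k1 <- sample(30:(m - 30), 1)
    k2 <- k1
    if (!shared) {
      cand <- which(vapply(seq_len(m), function(j)
        ld_r2(p, p$variants$id[k1], p$variants$id[j]), numeric(1)) <
          r2_max_distinct)
      cand <- cand[abs(cand - k1) > 5]
      k2 <- if (length(cand) > 0) sample(cand, 1) else
        return(NULL) # no low-LD partner available; skip locus
    }
    beta <- numeric(m)
    beta[k1] <- sqrt(chisq_gwas / n_gwas) * sample(c(-1, 1), 1)
    z <- numeric(m)
    for (blk in p$ld_blocks) {
      mu <- sqrt(n_gwas) * drop(blk$R %*% beta[blk$idx])
      z[blk$idx] <- mu + drop(crossprod(chol_psd(blk$R),
                                        stats::rnorm(length(blk$idx))))
    }
    gw <- finish_sumstats(data.frame(
      variant_id = p$variants$id, pos = p$variants$pos,
      beta = z / sqrt(n_gwas), se = 1 / sqrt(n_gwas), n = n_gwas))
    Xs <- standardize_dosages(p$dosages)
    y <- Xs[, k2] * sqrt(h2_cis) +
      stats::rnorm(n_qtl, 0, sqrt(1 - h2_cis))
    cis <- map_cis_qtl(p, matrix(y, 1, dimnames = list("f", NULL)), NULL,
                       data.frame(feature_id = "f", chrom = "chr1",
                                  tss = p$variants$pos[k2]),
                       cis_window = 3e5)
    cr <- colocalize_region(gw, cis)
    data.frame(type = if (shared) "shared" else "distinct",
               pp_shared = unname(cr$pp["shared"]),
               pp_distinct = unname(cr$pp["two_distinct"]),
               colocalized = cr$colocalized)
  }
  res <- c(lapply(seq_len(n_shared), one_locus, shared = TRUE),
           lapply(n_shared + seq_len(n_distinct), one_locus, shared = FALSE))
  out <- do.call(rbind, res)
  out$locus <- seq_len(nrow(out))
  out
}

#' Null-calibration study
#'
#' With every disease and molecular effect set to zero: per replicate, a
#' null GWAS is drawn and candidate loci counted; a null molecular cohort
#' is mapped and the cis p-values collected (on a weak-LD panel so the
#' Kolmogorov-Smirnov uniformity test applies to near-independent tests);
#' one replicate also runs the full mediated-heritability fit to check the
#' ratio against its jackknife SE.
#'
#' @param n_reps replicates.
#' @param seed integer seed.
#' @return list: `per_rep` (data.frame: rep, ks_p, n_candidate_loci),
#'   `mediated` (ratio, se from the first replicate's fit).
#' @export
experiment_null_calibration <- function(n_reps = 20, seed = 1L) {
  per_rep <- vector("list", n_reps)
  mediated <- NULL
  for (r in seq_len(n_reps)) {
    p <- simulate_genotype_panel(300, 600, 3e6, c(0.1, 0.5),
                                 ld_decay = 500, n_blocks = 12,
                                 seed = derive_seed(seed, "null_panel", r))
    f <- simulate_features(p, 40, 20, 400,
                           seed = derive_seed(seed, "null_feats", r))
    m <- simulate_regulatory_model(
      p, f$peaks, f$genes, p_causal_peak = 0.8, sigma_ca = 0.6,
      gamma_scale = 0, delta_scale = 0, direct_scale = 0,
      seed = derive_seed(seed, "null_model", r))
    stopifnot(m$h2_snp == 0)
    gw <- simulate_gwas_summary(p, m, 50000,
                                seed = derive_seed(seed, "null_gwas", r))
    ## molecular null: counts driven only by noise (zero out causal effects)
    m0 <- m; m0$peak_causal$b_ca[] <- 0
    cohort <- resample_genotypes(p, 150, derive_seed(seed, "null_cohort", r))
    ph <- simulate_molecular_phenotypes(cohort, m0, m0$contexts[1],
                                        seed = derive_seed(seed, "null_ph", r))
    anchors <- data.frame(feature_id = f$peaks$id, chrom = f$peaks$chrom,
                          start = f$peaks$start, end = f$peaks$end)
    cis <- qtl_scan_counts(cohort, ph$accessibility, anchors, 2e5)
    ks <- suppressWarnings(stats::ks.test(cis$p, "punif"))$p.value
    loci <- select_candidate_loci(gw, cis)
    per_rep[[r]] <- data.frame(rep = r, ks_p = ks,
                               n_candidate_loci = nrow(loci))
    if (r == 1L) {
      ld <- compute_ld_scores(p, list(all = seq_len(600)), window = 3e6)
      ms <- compute_mediation_scores(p, m$alpha_peaks^2, "caQTL",
                                     window = 3e6)
      fit <- suppressWarnings(mediated_h2_regression(gw, ld, ms, 20))
      mediated <- list(ratio = fit$ratio_total, se = fit$se_ratio_total,
                       h2_snp = fit$h2_snp, se_h2_snp = fit$se_h2_snp)
    }
  }
  list(per_rep = do.call(rbind, per_rep), mediated = mediated)
}

#' Mediated-heritability recovery study
#'
#' Simulates disease architectures calibrated to SNP heritability 0.3 with
#' a stated proportion mediated through chromatin accessibility (the rest
#' acting directly on variants), then estimates the mediated proportion
#' with the LD-score / mediation-score regression using the true cis
#' effects as scores.
#'
#' @param props mediated proportions to simulate.
#' @param n_reps replicates per proportion.
#' @param n_gwas GWAS sample size.
#' @param seed integer seed.
#' @return data.frame: prop, rep, ratio, h2_snp, h2_med, true_ratio.
#' @export
experiment_mediated_recovery <- function(props = c(0, 0.3, 0.6),
                                         n_reps = 20, n_gwas = 50000,
                                         seed = 1L) {
  m_var <- 1500; region <- 3e6
  out <- list()
  for (prop in props) {
    for (r in seq_len(n_reps)) {
      sd0 <- derive_seed(seed, sprintf("recovery_%g", prop), r)
      p <- simulate_genotype_panel(500, m_var, region, c(0.05, 0.5),
                                   10000, 20, seed = sd0)
      f <- simulate_features(p, 140, 40, 400, seed = sd0 + 1L)
      mod <- simulate_regulatory_model(
        p, f$peaks, f$genes, p_causal_peak = 0.9,
        gamma_scale = 0, delta_scale = 1, prop_disease_peaks = 0.5,
        direct_scale = 1, prop_direct = 0.3,
        h2_snp_target = 0.3, prop_mediated_target = prop, seed = sd0 + 2L)
      gw <- simulate_gwas_summary(p, mod, n_gwas, seed = sd0 + 3L)
      ld <- compute_ld_scores(p, list(all = seq_len(m_var)), window = region)
      ms <- compute_mediation_scores(p, mod$alpha_peaks^2, "caQTL",
                                     window = region)
      fit <- suppressWarnings(mediated_h2_regression(gw, ld, ms, 20))
      out[[length(out) + 1L]] <- data.frame(
        prop = prop, rep = r, ratio = fit$ratio_total,
        h2_snp = fit$h2_snp, h2_med = fit$h2_med_total,
        true_ratio = if (mod$h2_snp > 0) mod$h2_med_caqtl / mod$h2_snp else 0)
    }
  }
  do.call(rbind, out)
}

#' Peak-to-TSS distance pattern study
#'
#' Simulates architectures with exponential wiring decay, pairs each gene
#' with its dominant wired peak, estimates both members' cis-heritability
#' by Haseman-Elston regression on the normalized counts, and runs the
#' distance stratification. Records, per simulation, whether the eQTL
#' cis-heritability declines across distance quintiles, the paired
#' caQTL > eQTL comparisons, and the regression signs (+ for caQTL
#' heritability, - for distance).
#'
#' @param n_sims simulations.
#' @param n_cohort molecular cohort size.
#' @param wiring_decay exponential decay scale (bp).
#' @param seed integer seed.
#' @return list: `per_sim` data.frame (sign/ordering indicators and the
#'   regression estimates), `pairs` (pooled pairs with quintiles).
#' @export
experiment_distance_pattern <- function(n_sims = 50, n_cohort = 400,
                                        wiring_decay = 3e4, seed = 1L) {
  per_sim <- vector("list", n_sims)
  all_pairs <- vector("list", n_sims)
  for (s in seq_len(n_sims)) {
    sd0 <- derive_seed(seed, "distance", s)
    p <- simulate_genotype_panel(n_cohort, 500, 2e6, c(0.1, 0.5),
                                 10000, 10, seed = sd0)
    f <- simulate_features(p, 60, 60, 400, seed = sd0 + 1L)
    mod <- simulate_regulatory_model(
      p, f$peaks, f$genes, p_causal_peak = 1, sigma_ca = 0.9,
      wiring_decay = wiring_decay, wiring_scale = 1.2,
      wiring_window = 2e5, prop_active_per_context = 1,
      gamma_scale = 0, delta_scale = 0, gene_noise_var = 0.3,
      seed = sd0 + 2L)
    ph <- simulate_molecular_phenotypes(p, mod, mod$contexts[1],
                                        seed = sd0 + 3L)
    pairs <- dominant_pairs(mod)
    if (nrow(pairs) < 10) next
    pairs$caqtl_h2 <- he_h2_features(p, ph$accessibility, pairs$peak_id,
                                     anchor_table(f$peaks), 2e5)
    pairs$eqtl_h2 <- he_h2_features(p, ph$expression, pairs$gene_id,
                                    anchor_table(f$genes), 1e6)
    keep <- is.finite(pairs$caqtl_h2) & is.finite(pairs$eqtl_h2)
    pairs <- pairs[keep, , drop = FALSE]
    if (nrow(pairs) < 10) next
    da <- distance_stratified_h2(pairs)
    med <- tapply(da$pairs$eqtl_h2, da$pairs$quintile, stats::median)
    medc <- tapply(da$pairs$caqtl_h2, da$pairs$quintile, stats::median)
    cf <- da$regression
    per_sim[[s]] <- data.frame(
      sim = s,
      eqtl_decreasing = all(diff(med) < 0),
      eqtl_first_vs_last = med[1] > med[length(med)],
      caqtl_flat = da$rank_p$caqtl[4] > 0.05 || is.na(da$rank_p$caqtl[4]),
      paired_all_greater = all(tapply(
        da$pairs$caqtl_h2 - da$pairs$eqtl_h2, da$pairs$quintile,
        stats::median) > 0),
      beta_caqtl = cf$estimate[cf$term == "caqtl_h2"],
      beta_distance = cf$estimate[cf$term == "distance_100kb"],
      signs_ok = cf$estimate[cf$term == "caqtl_h2"] > 0 &
        cf$estimate[cf$term == "distance_100kb"] < 0)
    all_pairs[[s]] <- da$pairs
  }
  list(per_sim = do.call(rbind, per_sim),
       pairs = do.call(rbind, all_pairs))
}

# for each gene, the wired causal peak with the largest |weight * b_ca|
dominant_pairs <- function(mod) {
  W <- mod$wiring[mod$wiring[[paste0("active_", mod$contexts[1])]], ,
                  drop = FALSE]
  b_of <- stats::setNames(mod$peak_causal$b_ca, mod$peak_causal$peak_id)
  has_causal <- !is.na(stats::setNames(mod$peak_causal$variant_idx,
                                       mod$peak_causal$peak_id))
  W <- W[has_causal[W$peak_id], , drop = FALSE]
  if (nrow(W) == 0L)
    return(data.frame(peak_id = character(), gene_id = character(),
                      distance = numeric()))
  W$drive <- abs(W$weight * b_of[W$peak_id])
  W <- W[order(W$gene_id, -W$drive), ]
  W <- W[!duplicated(W$gene_id) & W$drive > 0, , drop = FALSE]
  W[, c("peak_id", "gene_id", "distance")]
}

anchor_table <- function(feat) {
  if ("tss" %in% names(feat))
    data.frame(feature_id = feat$id, chrom = feat$chrom, tss = feat$tss)
  else
    data.frame(feature_id = feat$id, chrom = feat$chrom,
               start = feat$start, end = feat$end)
}

# HE cis-h2 (clipped) for selected features of a count matrix
he_h2_features <- function(cohort, counts, feature_ids, anchors, window) {
  tn <- tmm_normalize(counts)
  y <- inverse_normal_transform(log2(tn$cpm + 1))
  vapply(feature_ids, function(fid) {
    a <- anchors[anchors$feature_id == fid, , drop = FALSE]
    if (nrow(a) != 1L || !fid %in% rownames(y)) return(NA_real_)
    tryCatch(estimate_cis_h2(cohort, y[fid, ], a, window)$h2,
             error = function(e) NA_real_)
  }, numeric(1))
}

#' Staged eQTL-colocalization conversion study
#'
#' Plants a context-specific architecture with three kinds of
#' disease-associated regulatory loci: genes with strong primary-context
#' wiring (detectable in a single eQTL study), genes with weak
#' primary-context wiring (detectable only after meta-analysis roughly
#' triples the sample size), and genes wired only in a second context
#' (detectable only in that context's eQTL study). Disease risk acts
#' through the peaks' accessibility, so every locus carries a GWAS signal
#' regardless of expression wiring. The study then runs the three-stage
#' accounting — primary study, inverse-variance meta-analysis, additional
#' context — and reports the cumulative eQTL-colocalized locus sets.
#'
#' @param n_primary,n_meta,n_context eQTL study sample sizes (primary,
#'   additional meta-analyzed studies, second-context study).
#' @param h2_strong,h2_weak,h2_context latent gene cis-heritabilities of
#'   the three planted kinds (the count layer roughly halves the
#'   realized heritability of the normalized phenotype).
#' @param n_per_kind loci per kind.
#' @param n_gwas GWAS sample size.
#' @param h2_snp disease SNP heritability spread over the planted loci
#'   (sets the per-locus GWAS signal strength).
#' @param seed integer seed.
#' @return list: `hits` (cumulative locus-id sets per stage), `staged`
#'   (counts), `loci` (candidate loci), `strictly_growing` flag.
#' @export
experiment_staged_conversion <- function(n_primary = 373,
                                         n_meta = c(190, 147, 418),
                                         n_context = 400,
                                         h2_strong = 0.3, h2_weak = 0.06,
                                         h2_context = 0.3,
                                         n_per_kind = 6, n_gwas = 50000,
                                         h2_snp = 0.15, seed = 1L) {
  region <- 6e6; m_var <- 2000
  # dense LD so every strong signal has close proxies (the overlap filter
  # needs a non-lead variant at >= 0.8x the lead chi-square)
  p <- simulate_genotype_panel(500, m_var, region, c(0.1, 0.5),
                               60000, 20, ld_decay_sd = 0.3,
                               seed = derive_seed(seed, "sc_panel"))
  n_loci <- 3L * n_per_kind
  pos <- p$variants$pos
  ## planted peaks: evenly spaced anchor variants, far enough apart that
  ## candidate windows never overlap
  anchor_idx <- round(seq(40, m_var - 40, length.out = n_loci))
  peaks <- data.frame(
    chrom = "chr1", start = pos[anchor_idx] - 200L,
    end = pos[anchor_idx] + 200L,
    id = sprintf("peak%04d", seq_len(n_loci)), stringsAsFactors = FALSE)
  ## one gene per peak, offset 10-150 kb
  set.seed(derive_seed(seed, "sc_genes"))
  offs <- sample(c(-1, 1), n_loci, TRUE) *
    round(stats::runif(n_loci, 1e4, 1.5e5))
  genes <- data.frame(
    id = sprintf("gene%04d", seq_len(n_loci)), chrom = "chr1",
    tss = pmax(1, pos[anchor_idx] + offs), strand = "+",
    stringsAsFactors = FALSE)

  b_ca <- 1.2
  peak_causal <- data.frame(peak_id = peaks$id, variant_idx = anchor_idx,
                            b_ca = b_ca, stringsAsFactors = FALSE)
  kind <- rep(c("strong", "weak", "context"), each = n_per_kind)
  h2_g <- c(strong = h2_strong, weak = h2_weak, context = h2_context)[kind]
  gene_noise_var <- 0.3; peak_noise_var <- 0.64
  w <- sqrt(gene_noise_var * h2_g /
              (b_ca^2 * (1 - h2_g) - peak_noise_var * h2_g))
  wiring <- data.frame(
    peak_id = peaks$id, gene_id = genes$id,
    distance = abs(offs), weight = w,
    active_lcl = kind != "context", active_other = kind == "context",
    stringsAsFactors = FALSE)
  gamma <- stats::setNames(numeric(n_loci), genes$id)
  delta <- stats::setNames(rep(1, n_loci), peaks$id)
  model <- build_regulatory_model(
    p, peaks, genes, peak_causal, wiring, gamma, delta,
    beta_direct = numeric(m_var), peak_noise_var = peak_noise_var,
    gene_noise_var = gene_noise_var, h2_snp_target = h2_snp,
    contexts = c("lcl", "other"), disease_context = "lcl",
    seed = seed)

  disease <- simulate_gwas_summary(p, model, n_gwas,
                                   seed = derive_seed(seed, "sc_gwas"))
  ca_cohort <- resample_genotypes(p, 100, derive_seed(seed, "sc_ca"))
  ca_ph <- simulate_molecular_phenotypes(ca_cohort, model, "lcl",
                                         seed = derive_seed(seed, "sc_caph"))
  ca_cis <- qtl_scan_counts(ca_cohort, ca_ph$accessibility,
                            anchor_table(peaks), 2e5)
  studies <- simulate_eqtl_studies(p, model, c(n_primary, n_meta), "lcl",
                                   cis_window = 1e6,
                                   seed = derive_seed(seed, "sc_eqtl"))
  ctx_study <- simulate_eqtl_studies(p, model, n_context, "other",
                                     cis_window = 1e6,
                                     seed = derive_seed(seed, "sc_ctx"))[[1]]

  cfg <- pipeline_config(seed = seed)
  loci <- select_candidate_loci(disease, ca_cis)
  loci <- unique(loci[, c("lead_variant", "lead_pos", "window_start",
                          "window_end")])
  priors <- coloc_priors()
  hits <- function(res) unique(res$locus_id[res$colocalized])
  e1 <- survey_qtl_coloc(disease, studies[[1]]$cis, loci, priors, cfg)
  meta_tab <- ivw_meta(studies)
  e2 <- survey_qtl_coloc(disease, meta_tab, loci, priors, cfg)
  e3 <- survey_qtl_coloc(disease, ctx_study$cis, loci, priors, cfg)
  cum <- list(primary = hits(e1),
              meta = union(hits(e1), hits(e2)),
              contexts = Reduce(union, list(hits(e1), hits(e2), hits(e3))))
  n <- vapply(cum, length, integer(1))
  list(hits = cum,
       staged = data.frame(stage = names(n), n_eqtl_colocalized = n,
                           row.names = NULL),
       loci = loci,
       ca_hits = hits(survey_qtl_coloc(disease, ca_cis, loci, priors, cfg)),
       strictly_growing = n[1] < n[2] && n[2] < n[3])
}
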