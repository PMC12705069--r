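#' Pipeline configuration with study-condition defaults
#'
#' Returns the full configuration list for [run_pipeline()], with any
#' supplied elements overriding the defaults. Defaults mirror the study
#' conditions of the analyses the package models: a caQTL cohort of 100
#' individuals, a primary eQTL study of 373, three further eQTL studies of
#' 190, 147 and 418 individuals entering the meta-analysis (total 1128),
#' candidate-locus thresholds p < 1e-6 (disease) and p < 1e-4 (QTL) with
#' the 0.8 chi-square overlap rule, a 0.98 shared-posterior decision
#' threshold, MAF >= 5%, the CPM < 0.8 / count < 10 / 20% feature filter,
#' a 200 kb cis window around peaks and 1 Mb around TSSs.
#'
#' @param ... named overrides.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    # genotypes
    n_ref = 500, n_variants = 1200, region_length = 3e6,
    maf_range = c(0.05, 0.5), ld_decay = 15000, n_ld_blocks = 24,
    # features & architecture
    n_peaks = 120, n_genes = 60, peak_width = 400,
    p_causal_peak = 0.8, sigma_ca = 0.6, wiring_decay = 5e4,
    wiring_scale = 0.6, wiring_window = 2e5,
    contexts = c("lcl", "immune_b"), prop_active_per_context = 0.6,
    gamma_scale = 0.15, delta_scale = 0.1,
    prop_disease_genes = 0.3, prop_disease_peaks = 0.3,
    direct_scale = 0.05, prop_direct = 0.05,
    peak_noise_var = 0.64, gene_noise_var = 0.5,
    h2_snp_target = 0.3, prop_mediated_target = NULL,
    # cohorts
    n_caqtl = 100, n_eqtl_primary = 373,
    n_eqtl_meta = c(190, 147, 418), n_eqtl_context = 400,
    n_gwas = 50000, mean_depth = 50, dispersion = 0.1,
    # thresholds (paper defaults)
    p_gwas = 1e-6, p_qtl = 1e-4, overlap_frac = 0.8, pp_threshold = 0.98,
    maf_min = 0.05, cpm_min = 0.8, count_min = 10, max_fail_frac = 0.2,
    cis_window_peak = 2e5, cis_window_gene = 1e6,
    coloc_half_window = 1e5, pair_half_window = 2e5,
    # heritability
    n_jackknife = 20, alpha_mode = "estimated", ridge_lambda = 0.1,
    select_pcs = TRUE, n_perm_pcs = 20,
    outdir = NULL
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0)
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' Run the full simulate-map-colocalize-meta-heritability pipeline
#'
#' End-to-end orchestration on one synthetic dataset: genotype panel and
#' regulatory architecture; caQTL mapping (TMM, CPM/count filter, inverse
#' normal transform, parallel-analysis PCs, cis scan); a primary eQTL
#' study; GWAS summary statistics; candidate-locus selection and
#' colocalization; then the three-stage eQTL-colocalization accounting —
#' (i) primary study, (ii) after inverse-variance meta-analysis of all
#' eQTL studies, (iii) after surveying additional contexts — in which the
#' set of eQTL-colocalized loci grows cumulatively by construction.
#' Heritability analyses follow: stratified LD-score regression in peak
#' regions, mediated-heritability fits for caQTLs, eQTLs and their union
#' with the intersection decomposition, caQTL-eQTL pairing with
#' cis-heritability distance stratification, and TSS-window proportions
#' of mediated heritability. Deterministic given `config$seed`.
#'
#' @param config a [pipeline_config()].
#' @return a `pipeline_report` list (see elements in the source); written
#'   as TSV/JSON under `config$outdir` when set.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  seed <- cfg$seed

  ## --- simulate ---------------------------------------------------------
  panel <- simulate_genotype_panel(cfg$n_ref, cfg$n_variants,
                                   cfg$region_length, cfg$maf_range,
                                   cfg$ld_decay, cfg$n_ld_blocks,
                                   seed = derive_seed(seed, "panel"))
  feats <- simulate_features(panel, cfg$n_peaks, cfg$n_genes,
                             cfg$peak_width, seed = derive_seed(seed, "features"))
  model <- simulate_regulatory_model(
    panel, feats$peaks, feats$genes,
    p_causal_peak = cfg$p_causal_peak, sigma_ca = cfg$sigma_ca,
    wiring_decay = cfg$wiring_decay, wiring_scale = cfg$wiring_scale,
    wiring_window = cfg$wiring_window, contexts = cfg$contexts,
    prop_active_per_context = cfg$prop_active_per_context,
    gamma_scale = cfg$gamma_scale, delta_scale = cfg$delta_scale,
    prop_disease_genes = cfg$prop_disease_genes,
    prop_disease_peaks = cfg$prop_disease_peaks,
    direct_scale = cfg$direct_scale, prop_direct = cfg$prop_direct,
    peak_noise_var = cfg$peak_noise_var,
    gene_noise_var = cfg$gene_noise_var,
    h2_snp_target = cfg$h2_snp_target,
    prop_mediated_target = cfg$prop_mediated_target,
    seed = derive_seed(seed, "model"))
  ctx <- model$disease_context

  ## --- caQTL cohort -----------------------------------------------------
  ca_cohort <- resample_genotypes(panel, cfg$n_caqtl,
                                  derive_seed(seed, "ca_cohort"))
  ca_phen <- simulate_molecular_phenotypes(
    ca_cohort, model, ctx, cfg$mean_depth, cfg$dispersion,
    seed = derive_seed(seed, "ca_pheno"))
  ca <- map_caqtl(ca_cohort, ca_phen$accessibility, feats$peaks, cfg)

  ## --- eQTL studies -----------------------------------------------------
  e_primary <- simulate_eqtl_studies(panel, model, cfg$n_eqtl_primary, ctx,
                                     cfg$cis_window_gene, cfg$mean_depth,
                                     cfg$dispersion,
                                     seed = derive_seed(seed, "eqtl_primary"))
  e_extra <- if (length(cfg$n_eqtl_meta) > 0)
    simulate_eqtl_studies(panel, model, cfg$n_eqtl_meta, ctx,
                          cfg$cis_window_gene, cfg$mean_depth,
                          cfg$dispersion,
                          seed = derive_seed(seed, "eqtl_meta")) else list()
  other_ctx <- setdiff(model$contexts, ctx)
  e_ctx <- lapply(other_ctx, function(cx)
    simulate_eqtl_studies(panel, model, cfg$n_eqtl_context, cx,
                          cfg$cis_window_gene, cfg$mean_depth,
                          cfg$dispersion,
                          seed = derive_seed(seed, paste0("eqtl_", cx)))[[1]])

  ## --- GWAS -------------------------------------------------------------
  disease <- simulate_gwas_summary(panel, model, cfg$n_gwas,
                                   seed = derive_seed(seed, "gwas"))

  ## --- colocalization & staged accounting -------------------------------
  priors <- coloc_priors()
  ca_cis <- ca$cis
  e_cis1 <- e_primary[[1]]$cis
  loci_ca <- select_candidate_loci(disease, ca_cis, cfg$p_gwas, cfg$p_qtl,
                                   cfg$overlap_frac, cfg$coloc_half_window)
  loci_e <- select_candidate_loci(disease, e_cis1, cfg$p_gwas, cfg$p_qtl,
                                  cfg$overlap_frac, cfg$coloc_half_window)
  loci <- unique(rbind(loci_ca, loci_e)[, c("lead_variant", "lead_pos",
                                            "window_start", "window_end")])
  ca_res <- survey_qtl_coloc(disease, ca_cis, loci, priors, cfg)
  e_res1 <- survey_qtl_coloc(disease, e_cis1, loci, priors, cfg)

  meta_tab <- ivw_meta(c(e_primary, e_extra))
  e_res2 <- survey_qtl_coloc(disease, meta_tab, loci, priors, cfg)
  e_res3 <- do.call(rbind, lapply(e_ctx, function(s)
    survey_qtl_coloc(disease, s$cis, loci, priors, cfg)))

  stage1 <- classify_locus_sets(ca_res, e_res1)
  hits <- function(res) unique(res$locus_id[res$colocalized])
  e_hits <- list(
    primary = hits(e_res1),
    meta = union(hits(e_res1), hits(e_res2)),
    contexts = Reduce(union, list(hits(e_res1), hits(e_res2),
                                  if (is.null(e_res3)) character() else
                                    hits(e_res3)))
  )
  ca_loci <- hits(ca_res)
  staged <- data.frame(
    stage = c("primary", "meta", "contexts"),
    n_caqtl_loci = length(ca_loci),
    n_eqtl_colocalized = vapply(e_hits, length, integer(1)),
    n_caqtl_with_eqtl = vapply(e_hits, function(h)
      length(intersect(ca_loci, h)), integer(1)),
    row.names = NULL
  )

  ## --- heritability -----------------------------------------------------
  herit <- pipeline_heritability(panel, model, disease, ca, ca_cohort,
                                 e_primary[[1]], feats, cfg)

  ## --- caQTL-eQTL pairing & distance ------------------------------------
  dist_res <- pipeline_distance(panel, ca_cohort, ca, e_primary[[1]], feats,
                                model, priors, cfg)

  report <- structure(list(
    config = cfg, truth = list(
      h2_snp = model$h2_snp, h2_med_caqtl = model$h2_med_caqtl,
      h2_med_eqtl = model$h2_med_eqtl),
    panel = panel, model = model, disease = disease,
    caqtl = ca, eqtl_primary = e_primary[[1]],
    loci = loci, coloc = list(caqtl = ca_res, eqtl_primary = e_res1,
                              eqtl_meta = e_res2, eqtl_contexts = e_res3),
    classification = stage1, staged = staged, e_hits = e_hits,
    meta = meta_tab, heritability = herit, distance = dist_res
  ), class = "pipeline_report")
  if (!is.null(cfg$outdir)) write_report(report, cfg$outdir)
  report
}

# caQTL arm: counts -> TMM/filter/INT -> optional phenotype PCs -> cis scan
map_caqtl <- function(cohort, counts, peaks, cfg) {
  tn <- tmm_normalize(counts)
  keep <- filter_features(counts, tn$cpm, cfg$cpm_min, cfg$count_min,
                          cfg$max_fail_frac)
  y <- inverse_normal_transform(log2(tn$cpm[keep, , drop = FALSE] + 1))
  k <- 0L
  covar <- NULL
  if (isTRUE(cfg$select_pcs)) {
    k <- select_num_pcs(y, n_perm = cfg$n_perm_pcs,
                        seed = derive_seed(cfg$seed, "pcs"))
    if (k > 0) covar <- stats::prcomp(t(y))$x[, seq_len(k), drop = FALSE]
  }
  anchors <- data.frame(feature_id = peaks$id, chrom = peaks$chrom,
                        start = peaks$start, end = peaks$end,
                        stringsAsFactors = FALSE)
  cis <- map_cis_qtl(cohort, y, covar, anchors, cfg$cis_window_peak,
                     cfg$maf_min)
  list(cis = cis, cpm = tn$cpm, kept = keep, n_pcs = k, normalized = y)
}

# per-locus colocalization survey against one QTL statistic set
survey_qtl_coloc <- function(disease, qtl, loci, priors, cfg) {
  out <- list()
  qtl <- as.data.frame(qtl)
  if (!"feature_id" %in% names(qtl)) qtl$feature_id <- "trait"
  for (i in seq_len(nrow(loci))) {
    lo <- loci$window_start[i]; hi <- loci$window_end[i]
    dwin <- disease[disease$pos >= lo & disease$pos <= hi, , drop = FALSE]
    if (nrow(dwin) < 2L) next
    lead_chisq <- max(dwin$chisq)
    dis_lead_id <- dwin$variant_id[which.max(dwin$chisq)]
    qwin <- qtl[qtl$pos >= lo & qtl$pos <= hi, , drop = FALSE]
    for (f in unique(qwin$feature_id)) {
      qf <- qwin[qwin$feature_id == f, , drop = FALSE]
      if (nrow(qf) < 2L) next
      jl <- which.min(qf$p)
      if (qf$p[jl] >= cfg$p_qtl) next
      shared <- merge(qf[, c("variant_id", "chisq")],
                      dwin[, c("variant_id", "chisq")],
                      by = "variant_id", suffixes = c("_q", "_d"))
      shared <- shared[shared$variant_id != dis_lead_id, , drop = FALSE]
      if (!any(shared$chisq_q >= cfg$overlap_frac * qf$chisq[jl] &
                 shared$chisq_d >= cfg$overlap_frac * lead_chisq)) next
      cr <- colocalize_region(dwin, qf, priors, cfg$pp_threshold)
      out[[length(out) + 1L]] <- data.frame(
        locus_id = loci$lead_variant[i], feature_id = f,
        pp_shared = unname(cr$pp["shared"]),
        colocalized = cr$colocalized, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(locus_id = character(), feature_id = character(),
                      pp_shared = numeric(), colocalized = logical()))
  do.call(rbind, out)
}

# stratified + mediated heritability arm
pipeline_heritability <- function(panel, model, disease, ca, ca_cohort,
                                  e_study, feats, cfg) {
  peak_variants <- which(in_any_interval(panel$variants$pos, feats$peaks))
  annot <- list(all = seq_len(nrow(panel$variants)), peaks = peak_variants)
  ld <- compute_ld_scores(panel, annot, window = cfg$region_length)
  sldsc <- stratified_h2_regression(disease, ld, cfg$n_jackknife)

  alpha <- pipeline_alpha(panel, model, ca, ca_cohort, e_study, feats, cfg)
  ms_ca <- compute_mediation_scores(panel, alpha$peaks, "caQTL",
                                    window = cfg$region_length)
  ms_e <- compute_mediation_scores(panel, alpha$genes, "eQTL",
                                   window = cfg$region_length)
  # the mediated fits use the base annotation only: a peak-region LD score
  # column is near-collinear with the caQTL mediation scores and would
  # destabilize the joint regression
  ld_base <- compute_ld_scores(panel, annot["all"],
                               window = cfg$region_length)
  fit_ca <- mediated_h2_regression(disease, ld_base, ms_ca, cfg$n_jackknife)
  fit_e <- mediated_h2_regression(disease, ld_base, ms_e, cfg$n_jackknife)
  fit_joint <- mediated_h2_regression(disease, ld_base, list(ms_ca, ms_e),
                                      cfg$n_jackknife)
  dec <- decompose_mediated_h2(fit_ca$h2_med_total, fit_e$h2_med_total,
                               fit_joint$h2_med_total)

  # per-peak mediated totals -> TSS-window proportions
  s_peak <- rowSums(alpha$peaks^2)
  peak_tot <- vapply(seq_len(nrow(feats$peaks)), function(i) {
    idx <- which(panel$variants$pos > feats$peaks$start[i] &
                   panel$variants$pos <= feats$peaks$end[i])
    sum(s_peak[idx])
  }, numeric(1))
  peaks_med <- cbind(feats$peaks,
                     h2_med = unname(fit_ca$omega[1]) * peak_tot)
  tssw <- tss_window_mediated_h2(peaks_med, feats$genes,
                                 windows = c(1e4, 1e5, 5e5, 1e6, cfg$region_length))

  list(sldsc = sldsc, mediated = list(caqtl = fit_ca, eqtl = fit_e,
                                      joint = fit_joint),
       decomposition = dec, tss_windows = tssw, alpha_mode = cfg$alpha_mode)
}

# true or ridge-estimated cis effect matrices for peaks and genes
pipeline_alpha <- function(panel, model, ca, ca_cohort, e_study, feats, cfg) {
  if (identical(cfg$alpha_mode, "true")) {
    m <- nrow(panel$variants)
    ap <- matrix(0, m, nrow(feats$peaks))
    okp <- !is.na(model$peak_causal$variant_idx)
    ap[cbind(model$peak_causal$variant_idx[okp], which(okp))] <-
      model$peak_causal$b_ca[okp]
    return(list(peaks = ap, genes = model$alpha_genes[[model$disease_context]]))
  }
  anchors_p <- data.frame(feature_id = feats$peaks$id,
                          chrom = feats$peaks$chrom,
                          start = feats$peaks$start, end = feats$peaks$end)
  anchors_g <- data.frame(feature_id = feats$genes$id,
                          chrom = feats$genes$chrom, tss = feats$genes$tss)
  list(
    peaks = ridge_cis_effects(ca_cohort, ca$normalized, anchors_p,
                              cfg$cis_window_peak, cfg$ridge_lambda,
                              cfg$maf_min),
    genes = ridge_cis_effects_study(panel, e_study, anchors_g, cfg)
  )
}

#' Ridge-estimated standardized cis effects
#'
#' Shrinkage estimate of each feature's per-variant cis effects: for the
#' standardized cis dosage matrix X and standardized phenotype y,
#' `alpha_hat = (X'X/n + lambda I)^-1 X'y/n` — the penalty acts on the
#' correlation scale, so `lambda` is the ridge added to the unit diagonal
#' of the cis LD matrix. Used to build mediation scores when true effects
#' are unavailable (pipeline mode).
#'
#' @param cohort a `genotype_panel` carrying the molecular cohort.
#' @param phenos features x samples matrix (normalized stage).
#' @param anchors anchor table as in [map_cis_qtl()].
#' @param window cis window (bp).
#' @param lambda ridge penalty.
#' @param maf_min minimum in-sample MAF.
#' @return variants x features matrix of effect estimates.
#' @export
ridge_cis_effects <- function(cohort, phenos, anchors, window,
                              lambda = 0.1, maf_min = 0.05) {
  m <- nrow(cohort$variants)
  out <- matrix(0, m, nrow(phenos),
                dimnames = list(cohort$variants$id, rownames(phenos)))
  for (i in seq_len(nrow(phenos))) {
    a <- anchors[anchors$feature_id == rownames(phenos)[i], , drop = FALSE]
    if (nrow(a) != 1L) next
    sel <- cis_variant_idx(cohort, a, window, maf_min)
    if (length(sel) == 0L) next
    X <- standardize_dosages(cohort$dosages[, sel, drop = FALSE])
    y <- phenos[i, ]
    y <- (y - mean(y)) / stats::sd(y)
    n <- length(y)
    G <- crossprod(X) / n + lambda * diag(length(sel))
    out[sel, i] <- solve(G, crossprod(X, y) / n)
  }
  out
}

# summary-statistic ridge for an eQTL study: approximate X'y by n * beta_std
ridge_cis_effects_study <- function(panel, e_study, anchors, cfg) {
  cis <- as.data.frame(e_study$cis)
  n <- attr(e_study$cis, "n", exact = TRUE) %||% e_study$n
  m <- nrow(panel$variants)
  genes <- unique(anchors$feature_id)
  out <- matrix(0, m, length(genes),
                dimnames = list(panel$variants$id, genes))
  for (g in genes) {
    cf <- cis[cis$feature_id == g, , drop = FALSE]
    if (nrow(cf) == 0L) next
    sel <- match(cf$variant_id, panel$variants$id)
    R <- block_r_submatrix(panel, sel)
    z <- cf$beta / cf$se
    # summary-statistic ridge on the correlation scale
    alpha <- solve(R + cfg$ridge_lambda * diag(length(sel)), z / sqrt(n))
    out[sel, g] <- alpha
  }
  out
}

# panel LD correlations for an arbitrary variant index set (block-diagonal
# approximation: cross-block correlations set to 0)
block_r_submatrix <- function(panel, sel) {
  R <- diag(length(sel))
  for (blk in panel$ld_blocks) {
    inb <- which(sel %in% blk$idx)
    if (length(inb) < 2L) next
    R[inb, inb] <- blk$R[match(sel[inb], blk$idx), match(sel[inb], blk$idx)]
  }
  R
}

# caQTL-eQTL pairing + HE cis-h2 + distance stratification
pipeline_distance <- function(panel, ca_cohort, ca, e_study, feats, model,
                              priors, cfg) {
  pairs <- pair_caqtl_eqtl(ca$cis, e_study$cis, panel, feats$peaks,
                           feats$genes, disease = NULL,
                           half_window = cfg$pair_half_window,
                           priors = priors, pp_threshold = cfg$pp_threshold,
                           p_qtl_max = cfg$p_qtl)
  if (nrow(pairs) < 10)
    return(list(pairs = pairs, analysis = NULL,
                note = "fewer than 10 colocalized pairs"))
  pairs$caqtl_h2 <- model$h2_cis_peaks[pairs$peak_id]
  pairs$eqtl_h2 <- model$h2_cis_genes[pairs$gene_id, model$disease_context]
  list(pairs = pairs, analysis = distance_stratified_h2(pairs))
}

in_any_interval <- function(pos, intervals) {
  hit <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(intervals)))
    hit <- hit | (pos > intervals$start[i] & pos <= intervals$end[i])
  hit
}

# plain-text persistence of the main report tables
write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$staged, file.path(outdir, "staged_conversion.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$classification,
                     file.path(outdir, "locus_classification.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  med <- report$heritability$mediated
  herit_tab <- data.frame(
    set = c("caQTL", "eQTL", "union"),
    h2_med = c(med$caqtl$h2_med_total, med$eqtl$h2_med_total,
               med$joint$h2_med_total),
    h2_snp = c(med$caqtl$h2_snp, med$eqtl$h2_snp, med$joint$h2_snp),
    ratio = c(med$caqtl$ratio_total, med$eqtl$ratio_total,
              med$joint$ratio_total))
  utils::write.table(herit_tab, file.path(outdir, "heritability.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(truth = report$truth,
         decomposition = unclass(report$heritability$decomposition),
         staged = report$staged, seed = report$config$seed),
    file.path(outdir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
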