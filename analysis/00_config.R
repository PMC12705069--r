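# Shared settings for the numbered analysis scripts. Each script is a thin
# driver over the qtlmediate package: it rebuilds the simulated cohort
# deterministically from this seed, runs one analysis stage, and writes
# its tables under results/.

suppressMessages(library(qtlmediate))

SEED <- 20260919L
CFG <- pipeline_config(seed = SEED)
RESULTS <- file.path("results")
dir.create(RESULTS, showWarnings = FALSE, recursive = TRUE)

write_tsv <- function(df, name) {
  path <- file.path(RESULTS, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path)
}

# deterministic rebuild of the simulated study (fast; every script calls it)
build_study <- function(cfg = CFG) {
  panel <- simulate_genotype_panel(cfg$n_ref, cfg$n_variants,
                                   cfg$region_length, cfg$maf_range,
                                   cfg$ld_decay, cfg$n_ld_blocks,
                                   seed = derive_seed(cfg$seed, "panel"))
  feats <- simulate_features(panel, cfg$n_peaks, cfg$n_genes,
                             cfg$peak_width,
                             seed = derive_seed(cfg$seed, "features"))
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
    seed = derive_seed(cfg$seed, "model"))
  list(panel = panel, feats = feats, model = model)
}
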