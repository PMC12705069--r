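# Small shared fixtures, built once per test run.

# 300 samples x 200 variants, moderate LD
fix_panel <- simulate_genotype_panel(300, 200, 5e5, c(0.1, 0.5),
                                     ld_decay = 20000, n_blocks = 4,
                                     seed = 42)

# near-independent variants (weak LD) for calibration-style checks
fix_panel_nold <- simulate_genotype_panel(300, 150, 3e6, c(0.1, 0.5),
                                          ld_decay = 500, n_blocks = 3,
                                          seed = 43)

fix_features <- simulate_features(fix_panel, 25, 12, 400, seed = 44)

fix_model <- simulate_regulatory_model(
  fix_panel, fix_features$peaks, fix_features$genes,
  p_causal_peak = 0.9, sigma_ca = 0.7, contexts = c("a", "b"),
  gamma_scale = 0.15, delta_scale = 0.1, direct_scale = 0.05,
  h2_snp_target = 0.3, seed = 45)

# hand-built 5-variant candidate-locus tables
toy_locus_tables <- function(qtl_chisq) {
  dis <- data.frame(variant_id = paste0("v", 1:5),
                    pos = c(100, 10000, 20000, 30000, 40000),
                    chisq = c(40, 35, 2, 1, 1))
  dis$p <- pchisq(dis$chisq, 1, lower.tail = FALSE)
  dis$n <- 1000
  qtl <- data.frame(feature_id = "f1", variant_id = paste0("v", 1:5),
                    pos = dis$pos, chisq = qtl_chisq)
  qtl$p <- pchisq(qtl$chisq, 1, lower.tail = FALSE)
  list(disease = dis, qtl = qtl)
}

# single-feature phenotype matrix helper
one_feature <- function(y, id = "f") matrix(y, 1, dimnames = list(id, NULL))
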