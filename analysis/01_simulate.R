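#!/usr/bin/env Rscript
# Stage 1 — simulate the study and export a plain-text fixture.
#
# Generates the LD-structured genotype panel, the regulatory architecture
# (causal peak variants, distance-decaying peak-to-gene wiring with a
# context-specific mask, disease effects), one caQTL cohort's ATAC-style
# counts, and GWAS summary statistics; exports everything with the truth
# ledger so later stages (and readers) can inspect the raw inputs.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(), value = TRUE)[1])), "00_config.R"))

study <- build_study()
message(sprintf("panel: %d samples x %d variants; %d peaks, %d genes",
                nrow(study$panel$dosages), nrow(study$panel$variants),
                nrow(study$feats$peaks), nrow(study$feats$genes)))
message(sprintf("truth: h2_snp %.3f, h2_med(caQTL) %.3f, h2_med(eQTL) %.3f",
                study$model$h2_snp, study$model$h2_med_caqtl,
                study$model$h2_med_eqtl))

ca_cohort <- resample_genotypes(study$panel, CFG$n_caqtl,
                                derive_seed(SEED, "ca_cohort"))
ca_phen <- simulate_molecular_phenotypes(
  ca_cohort, study$model, study$model$disease_context,
  CFG$mean_depth, CFG$dispersion, seed = derive_seed(SEED, "ca_pheno"))
disease <- simulate_gwas_summary(study$panel, study$model, CFG$n_gwas,
                                 seed = derive_seed(SEED, "gwas"))

export_fixture(list(
  panel = study$panel, peaks = study$feats$peaks, genes = study$feats$genes,
  counts = list(atac = ca_phen$accessibility,
                rna = ca_phen$expression),
  sumstats = list(disease = disease),
  truth = list(seed = SEED, h2_snp = study$model$h2_snp,
               h2_med_caqtl = study$model$h2_med_caqtl,
               h2_med_eqtl = study$model$h2_med_eqtl)
), file.path(RESULTS, "fixture"), overwrite = TRUE)
message("fixture exported to ", file.path(RESULTS, "fixture"))
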