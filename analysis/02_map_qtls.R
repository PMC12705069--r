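#!/usr/bin/env Rscript
# Stage 2 — map caQTLs and eQTLs.
#
# caQTL arm: TMM normalization, the CPM < 0.8 / count < 10 / 20% feature
# filter, inverse normal transform, parallel-analysis selection of latent
# phenotype PCs, and per-variant cis association in a 200 kb window
# around each peak (MAF >= 5%). eQTL arm: the primary expression study
# mapped in a 1 Mb window around each TSS. Writes the full long-format
# association tables and the per-feature lead variants.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(), value = TRUE)[1])), "00_config.R"))

study <- build_study()
ca_cohort <- resample_genotypes(study$panel, CFG$n_caqtl,
                                derive_seed(SEED, "ca_cohort"))
ca_phen <- simulate_molecular_phenotypes(
  ca_cohort, study$model, study$model$disease_context,
  CFG$mean_depth, CFG$dispersion, seed = derive_seed(SEED, "ca_pheno"))
ca <- qtlmediate:::map_caqtl(ca_cohort, ca_phen$accessibility,
                             study$feats$peaks, CFG)
message(sprintf("caQTL scan: %d peaks kept, %d phenotype PCs, %d tests",
                length(ca$kept), ca$n_pcs, nrow(ca$cis)))

e_primary <- simulate_eqtl_studies(
  study$panel, study$model, CFG$n_eqtl_primary,
  study$model$disease_context, CFG$cis_window_gene, CFG$mean_depth,
  CFG$dispersion, seed = derive_seed(SEED, "eqtl_primary"))[[1]]
message(sprintf("eQTL scan (n=%d): %d tests", e_primary$n,
                nrow(e_primary$cis)))

write_tsv(as.data.frame(ca$cis), "caqtl_cis.tsv")
write_tsv(as.data.frame(e_primary$cis), "eqtl_primary_cis.tsv")
write_tsv(cis_leads(ca$cis), "caqtl_leads.tsv")
write_tsv(cis_leads(e_primary$cis), "eqtl_primary_leads.tsv")
message(sprintf("lead p < 1e-4: %d caQTL peaks, %d eGenes",
                sum(cis_leads(ca$cis)$p < 1e-4),
                sum(cis_leads(e_primary$cis)$p < 1e-4)))
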