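#!/usr/bin/env Rscript
# Stage 3 — candidate loci and Bayesian colocalization.
#
# Selects disease loci by the three-condition filter (lead disease
# p < 1e-6; lead QTL p < 1e-4 in the 200 kb window; a corroborating
# variant at >= 0.8x both lead chi-squares), evaluates the
# five-configuration shared-variant posterior for each (locus, feature)
# pair, and classifies loci as caQTL-only / eQTL-only / both / none.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(), value = TRUE)[1])), "00_config.R"))

caqtl <- read.delim(file.path(RESULTS, "caqtl_cis.tsv"))
eqtl <- read.delim(file.path(RESULTS, "eqtl_primary_cis.tsv"))
study <- build_study()
disease <- simulate_gwas_summary(study$panel, study$model, CFG$n_gwas,
                                 seed = derive_seed(SEED, "gwas"))

loci_ca <- select_candidate_loci(disease, caqtl, CFG$p_gwas, CFG$p_qtl,
                                 CFG$overlap_frac, CFG$coloc_half_window)
loci_e <- select_candidate_loci(disease, eqtl, CFG$p_gwas, CFG$p_qtl,
                                CFG$overlap_frac, CFG$coloc_half_window)
loci <- unique(rbind(loci_ca, loci_e)[, c("lead_variant", "lead_pos",
                                          "window_start", "window_end")])
message(sprintf("%d candidate loci (%d via caQTLs, %d via eQTLs)",
                nrow(loci), nrow(loci_ca), nrow(loci_e)))

priors <- coloc_priors()
ca_res <- qtlmediate:::survey_qtl_coloc(disease, caqtl, loci, priors, CFG)
e_res <- qtlmediate:::survey_qtl_coloc(disease, eqtl, loci, priors, CFG)
cls <- classify_locus_sets(ca_res, e_res)
message("locus classification:")
print(table(cls$label))

write_tsv(loci, "candidate_loci.tsv")
write_tsv(ca_res, "coloc_caqtl.tsv")
write_tsv(e_res, "coloc_eqtl_primary.tsv")
write_tsv(cls, "locus_classification.tsv")
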