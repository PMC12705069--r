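#!/usr/bin/env Rscript
# Stage 4 — eQTL meta-analysis and the staged conversion accounting.
#
# Meta-analyzes the primary eQTL study with three further studies
# (inverse-variance-weighted fixed effects; a variant missing from some
# studies is combined from the rest), surveys an additional simulated
# cellular context, and reports the cumulative growth of the
# eQTL-colocalized locus set: primary study -> meta-analysis -> other
# contexts.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(), value = TRUE)[1])), "00_config.R"))

study <- build_study()
ctx <- study$model$disease_context
disease <- simulate_gwas_summary(study$panel, study$model, CFG$n_gwas,
                                 seed = derive_seed(SEED, "gwas"))
loci <- read.delim(file.path(RESULTS, "candidate_loci.tsv"))
e_res1 <- read.delim(file.path(RESULTS, "coloc_eqtl_primary.tsv"))
ca_res <- read.delim(file.path(RESULTS, "coloc_caqtl.tsv"))

e_primary <- simulate_eqtl_studies(study$panel, study$model,
                                   CFG$n_eqtl_primary, ctx,
                                   CFG$cis_window_gene, CFG$mean_depth,
                                   CFG$dispersion,
                                   seed = derive_seed(SEED, "eqtl_primary"))
e_extra <- simulate_eqtl_studies(study$panel, study$model, CFG$n_eqtl_meta,
                                 ctx, CFG$cis_window_gene, CFG$mean_depth,
                                 CFG$dispersion,
                                 seed = derive_seed(SEED, "eqtl_meta"))
meta_tab <- ivw_meta(c(e_primary, e_extra))
message(sprintf("meta-analysis over %d studies, total n = %d",
                1 + length(e_extra), max(meta_tab$n_total)))

other_ctx <- setdiff(study$model$contexts, ctx)
e_ctx <- lapply(other_ctx, function(cx)
  simulate_eqtl_studies(study$panel, study$model, CFG$n_eqtl_context, cx,
                        CFG$cis_window_gene, CFG$mean_depth,
                        CFG$dispersion,
                        seed = derive_seed(SEED, paste0("eqtl_", cx)))[[1]])

priors <- coloc_priors()
e_res2 <- qtlmediate:::survey_qtl_coloc(disease, meta_tab, loci, priors, CFG)
e_res3 <- do.call(rbind, lapply(e_ctx, function(s)
  qtlmediate:::survey_qtl_coloc(disease, s$cis, loci, priors, CFG)))

hits <- function(res) unique(res$locus_id[res$colocalized])
cum <- list(primary = hits(e_res1),
            meta = union(hits(e_res1), hits(e_res2)),
            contexts = Reduce(union, list(hits(e_res1), hits(e_res2),
                                          if (is.null(e_res3)) character()
                                          else hits(e_res3))))
staged <- data.frame(stage = names(cum),
                     n_eqtl_colocalized = lengths(cum),
                     n_caqtl_colocalized = length(hits(ca_res)),
                     row.names = NULL)
message("staged eQTL colocalization (cumulative):")
print(staged)

write_tsv(meta_tab, "eqtl_meta.tsv")
write_tsv(e_res2, "coloc_eqtl_meta.tsv")
if (!is.null(e_res3)) write_tsv(e_res3, "coloc_eqtl_contexts.tsv")
write_tsv(staged, "staged_conversion.tsv")
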