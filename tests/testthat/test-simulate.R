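test_that("genotype panel respects declared frequencies, coding and determinism", {
  p <- fix_panel
  expect_true(all(p$dosages %in% 0:2))
  expect_false(is.unsorted(p$variants$pos, strictly = TRUE))
  expect_false(any(duplicated(p$variants$id)))
  expect_true(all(p$variants$maf > 0 & p$variants$maf <= 0.5))
  # empirical frequency close to declared at n >= 300
  emp <- colMeans(p$dosages) / 2
  expect_lt(max(abs(emp - p$variants$maf)), 0.08)
  p2 <- simulate_genotype_panel(300, 200, 5e5, c(0.1, 0.5),
                                ld_decay = 20000, n_blocks = 4, seed = 42)
  expect_identical(p$dosages, p2$dosages)
  # invalid arguments rejected
  expect_error(simulate_genotype_panel(100, 50, 1e5, ld_decay = 0))
  expect_error(simulate_genotype_panel(100, 5, 1e5, n_blocks = 10))
})

test_that("LD structure matches the exponential-decay target", {
  # no-LD limit: distant variants are near-independent
  p0 <- simulate_genotype_panel(2000, 80, 3e6, c(0.1, 0.5), ld_decay = 1,
                                n_blocks = 2, ld_decay_sd = 0, seed = 7)
  R <- cor(p0$dosages)
  expect_lt(mean(abs(R[upper.tri(R)])), 0.05)
  # adjacent-variant correlation tracks exp(-d/ld_decay) (Monte Carlo
  # average over seeds, homogeneous decay)
  devs <- vapply(1:8, function(s) {
    p <- simulate_genotype_panel(1000, 120, 3e5, c(0.1, 0.5),
                                 ld_decay = 20000, n_blocks = 2,
                                 ld_decay_sd = 0, seed = s)
    d <- diff(p$variants$pos)
    r <- vapply(2:120, function(k)
      cor(p$dosages[, k - 1], p$dosages[, k]), numeric(1))
    mean(abs(r - exp(-d / 20000)))
  }, numeric(1))
  expect_lt(mean(devs), 0.1)
  # mean r2 non-increasing with binned distance
  p <- fix_panel
  R2 <- cor(p$dosages)^2
  d <- abs(outer(p$variants$pos, p$variants$pos, "-"))
  ut <- upper.tri(R2)
  bins <- cut(d[ut], breaks = quantile(d[ut], 0:8 / 8), include.lowest = TRUE)
  mr2 <- tapply(R2[ut], bins, mean)
  expect_lte(cor(seq_along(mr2), mr2, method = "spearman"), 0)
})

test_that("LD block matrices are symmetric with unit diagonal", {
  for (blk in fix_panel$ld_blocks) {
    expect_equal(blk$R, t(blk$R))
    expect_equal(unname(diag(blk$R)), rep(1, nrow(blk$R)))
    expect_gte(min(eigen(blk$R, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
  }
})

test_that("regulatory model stores conserved, additive heritability truths", {
  m <- fix_model
  expect_true(m$h2_med_eqtl <= m$h2_med_caqtl + 1e-12)
  expect_true(m$h2_med_caqtl <= m$h2_snp + 1e-12)
  expect_equal(m$h2_snp, 0.3, tolerance = 1e-8)
  expect_true(all(m$h2_cis_peaks >= 0 & m$h2_cis_peaks <= 1))
  expect_true(all(m$h2_cis_genes >= 0 & m$h2_cis_genes <= 1))
  # null disease: all truths zero
  m0 <- simulate_regulatory_model(
    fix_panel, fix_features$peaks, fix_features$genes,
    gamma_scale = 0, delta_scale = 0, direct_scale = 0, seed = 9)
  expect_identical(m0$h2_snp, 0)
  expect_identical(m0$h2_med_caqtl, 0)
  expect_error(simulate_regulatory_model(fix_panel, fix_features$peaks[0, ],
                                         fix_features$genes))
  # truth conservation across seeds
  for (s in 1:5) {
    ms <- simulate_regulatory_model(
      fix_panel, fix_features$peaks, fix_features$genes,
      gamma_scale = 0.2, delta_scale = 0.15, direct_scale = 0.1,
      h2_snp_target = 0.4, seed = s)
    expect_true(ms$h2_med_eqtl <= ms$h2_med_caqtl + 1e-12)
    expect_true(ms$h2_med_caqtl <= ms$h2_snp + 1e-12)
    expect_true(ms$h2_snp <= 1)
  }
})

test_that("wiring magnitude decays with distance only when decay is finite", {
  pooled <- function(decay) {
    w <- lapply(1:6, function(s) {
      mm <- simulate_regulatory_model(
        fix_panel, fix_features$peaks, fix_features$genes,
        wiring_decay = decay, wiring_window = 3e5, seed = 100 + s)
      mm$wiring[, c("distance", "weight")]
    })
    do.call(rbind, w)
  }
  no_decay <- pooled(Inf)
  expect_lt(abs(cor(abs(no_decay$weight), no_decay$distance)), 0.08)
  strong <- pooled(2e4)
  expect_lt(cor(abs(strong$weight), strong$distance), -0.2)
})

test_that("gene cis-heritability matches the generative variance identity", {
  # hand-built architecture on an exact-identity LD panel: one gene wired
  # to one causal peak, h2 = (wb)^2 / ((wb)^2 + w^2 va + vx)
  p <- fix_panel_nold
  p$ld_blocks <- lapply(p$ld_blocks, function(b)
    list(idx = b$idx, R = diag(length(b$idx))))
  peaks <- data.frame(chrom = "chr1", start = p$variants$pos[10] - 200,
                      end = p$variants$pos[10] + 200, id = "pk1")
  genes <- data.frame(id = "g1", chrom = "chr1",
                      tss = p$variants$pos[10] + 5000, strand = "+")
  b <- 0.8; w <- 0.5; va <- 0.64; vx <- 0.5
  mod <- build_regulatory_model(
    p, peaks, genes,
    peak_causal = data.frame(peak_id = "pk1", variant_idx = 10L, b_ca = b),
    wiring = data.frame(peak_id = "pk1", gene_id = "g1", distance = 5000,
                        weight = w, active_a = TRUE),
    gamma = c(g1 = 0), delta = c(pk1 = 0), beta_direct = numeric(150),
    peak_noise_var = va, gene_noise_var = vx, contexts = "a")
  expect_equal(unname(mod$h2_cis_genes["g1", "a"]),
               (w * b)^2 / ((w * b)^2 + w^2 * va + vx), tolerance = 1e-12)
  expect_equal(unname(mod$h2_cis_peaks["pk1"]), b^2 / (b^2 + va))
})

test_that("molecular phenotypes track latents in the noiseless limit", {
  # correlation between log CPM and latent is capped near
  # sqrt(1 - 1/n_features) by the compositional normalization, so the
  # noiseless check uses a feature-rich model
  p <- simulate_genotype_panel(300, 400, 1e6, c(0.1, 0.5), 20000, 4,
                               seed = 46)
  f <- simulate_features(p, 220, 10, 400, seed = 47)
  m <- simulate_regulatory_model(p, f$peaks, f$genes, p_causal_peak = 0.9,
                                 sigma_ca = 0.7, seed = 48)
  ph <- simulate_molecular_phenotypes(p, m, "ctx1", mean_depth = 20000,
                                      dispersion = 0, seed = 3)
  counts <- ph$accessibility
  expect_identical(pm_stage(counts), "raw_counts")
  expect_true(all(counts >= 0) && all(counts == round(counts)))
  latent <- attr(counts, "latent")
  lcpm <- log(t(t(counts) / colSums(counts)) * 1e6 + 0.5)
  cors <- vapply(seq_len(nrow(counts)), function(i)
    cor(lcpm[i, ], latent[i, ]), numeric(1))
  expect_gt(median(cors), 0.99)
  expect_error(simulate_molecular_phenotypes(fix_panel, fix_model, "zzz"))
})

test_that("a gene wired only to context-inactive edges has no genetic variance", {
  p <- fix_panel_nold
  peaks <- data.frame(chrom = "chr1", start = p$variants$pos[10] - 200,
                      end = p$variants$pos[10] + 200, id = "pk1")
  genes <- data.frame(id = "g1", chrom = "chr1",
                      tss = p$variants$pos[10] + 5000, strand = "+")
  mod <- build_regulatory_model(
    p, peaks, genes,
    peak_causal = data.frame(peak_id = "pk1", variant_idx = 10L, b_ca = 1),
    wiring = data.frame(peak_id = "pk1", gene_id = "g1", distance = 5000,
                        weight = 1, active_a = FALSE, active_b = TRUE),
    gamma = c(g1 = 0), delta = c(pk1 = 0), beta_direct = numeric(150),
    contexts = c("a", "b"))
  expect_identical(sum(abs(mod$alpha_genes[["a"]])), 0)
  expect_identical(unname(mod$h2_cis_genes["g1", "a"]), 0)
  expect_gt(mod$h2_cis_genes["g1", "b"], 0)
})

test_that("GWAS summary statistics obey their record invariants", {
  gw <- simulate_gwas_summary(fix_panel, fix_model, 50000, seed = 5)
  expect_equal(gw$chisq, gw$z^2, tolerance = 1e-12)
  expect_equal(gw$z, gw$beta / gw$se, tolerance = 1e-12)
  expect_equal(gw$p, pchisq(gw$chisq, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_true(all(gw$se > 0))
  gw2 <- simulate_gwas_summary(fix_panel, fix_model, 50000, seed = 5)
  expect_identical(gw, gw2)
})

test_that("null GWAS yields mean chi-square near 1 at genome scale", {
  p <- simulate_genotype_panel(150, 10000, 2e7, c(0.1, 0.5),
                               ld_decay = 10000, n_blocks = 25, seed = 11)
  f <- simulate_features(p, 30, 10, 400, seed = 12)
  m0 <- simulate_regulatory_model(p, f$peaks, f$genes, gamma_scale = 0,
                                  delta_scale = 0, direct_scale = 0,
                                  seed = 13)
  gw <- simulate_gwas_summary(p, m0, 50000, seed = 14)
  expect_gt(mean(gw$chisq), 0.9)
  expect_lt(mean(gw$chisq), 1.1)
})

test_that("single causal variant without LD has the closed-form mean z", {
  p <- fix_panel_nold
  p$ld_blocks <- lapply(p$ld_blocks, function(b)
    list(idx = b$idx, R = diag(length(b$idx))))
  f <- simulate_features(p, 10, 5, 400, seed = 20)
  mod <- simulate_regulatory_model(p, f$peaks, f$genes, gamma_scale = 0,
                                   delta_scale = 0, direct_scale = 0,
                                   seed = 21)
  k <- 75L
  mod$beta <- numeric(150); mod$beta[k] <- 0.05
  n <- 20000
  zs <- vapply(1:200, function(s)
    simulate_gwas_summary(p, mod, n, seed = 1000 + s)$z[k], numeric(1))
  expect_lt(abs(mean(zs) - sqrt(n) * 0.05), 3 / sqrt(200))
})

test_that("eQTL studies share true effects but not noise", {
  p <- simulate_genotype_panel(300, 250, 8e5, c(0.1, 0.5), 20000, 5,
                               seed = 30)
  f <- simulate_features(p, 30, 15, 400, seed = 31)
  mod <- simulate_regulatory_model(p, f$peaks, f$genes, p_causal_peak = 1,
                                   sigma_ca = 0.9, wiring_scale = 1.2,
                                   prop_active_per_context = 1,
                                   gene_noise_var = 0.3, seed = 32)
  studies <- simulate_eqtl_studies(p, mod, c(500, 500), "ctx1",
                                   cis_window = 5e5, seed = 33)
  expect_length(studies, 2)
  expect_length(simulate_eqtl_studies(p, mod, 60, "ctx1",
                                      cis_window = 5e5, seed = 34), 1)
  # heritable genes give correlated effect estimates across studies
  herit_genes <- rownames(mod$h2_cis_genes)[mod$h2_cis_genes[, 1] > 0.1]
  m1 <- as.data.frame(studies[[1]]$cis)
  m2 <- as.data.frame(studies[[2]]$cis)
  m1 <- m1[m1$feature_id %in% herit_genes, c("feature_id", "variant_id", "beta")]
  m2 <- m2[m2$feature_id %in% herit_genes, c("feature_id", "variant_id", "beta")]
  mm <- merge(m1, m2, by = c("feature_id", "variant_id"))
  expect_gt(nrow(mm), 100)
  expect_gt(cor(mm$beta.x, mm$beta.y), 0.5)
})

test_that("fixture export round-trips bit-exactly", {
  dir <- withr::local_tempdir()
  ph <- simulate_molecular_phenotypes(fix_panel, fix_model, "a", seed = 40)
  gw <- simulate_gwas_summary(fix_panel, fix_model, 50000, seed = 41)
  bundle <- list(panel = fix_panel, peaks = fix_features$peaks,
                 genes = fix_features$genes,
                 counts = list(atac = ph$accessibility),
                 sumstats = list(disease = gw),
                 truth = list(h2_snp = fix_model$h2_snp,
                              h2_med_caqtl = fix_model$h2_med_caqtl))
  export_fixture(bundle, file.path(dir, "fx"))
  expect_error(export_fixture(bundle, file.path(dir, "fx")), "not empty")
  back <- import_fixture(file.path(dir, "fx"))
  expect_identical(unname(back$dosages), unname(fix_panel$dosages))
  expect_identical(back$genes$tss, fix_features$genes$tss)
  expect_identical(unname(back$counts$atac),
                   matrix(as.integer(ph$accessibility),
                          nrow(ph$accessibility)))
  expect_identical(back$sumstats$disease$beta, gw$beta)
  expect_identical(back$truth$h2_snp, fix_model$h2_snp)
  # BED sanity
  bed <- read.delim(file.path(dir, "fx", "peaks.bed"), header = FALSE)
  expect_gte(ncol(bed), 4)
  expect_true(all(bed$V2 < bed$V3))
})
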