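test_that("LD and mediation scores equal the brute-force double loop", {
  p <- simulate_genotype_panel(300, 50, 1e5, c(0.1, 0.5), 20000, 1,
                               seed = 4)
  n <- 300
  R2 <- cor(p$dosages)^2
  R2a <- R2 - (1 - R2) / (n - 2)
  ld <- compute_ld_scores(p, list(all = 1:50, sub = 1:20), window = 1e5)
  expect_equal(unname(ld$scores[, "all"]), unname(rowSums(R2a)),
               tolerance = 1e-10)
  expect_equal(unname(ld$scores[, "sub"]), unname(rowSums(R2a[, 1:20])),
               tolerance = 1e-10)
  set.seed(5)
  s <- runif(50)^2
  ms <- compute_mediation_scores(p, s, "toy", window = 1e5)
  expect_equal(unname(ms$scores), unname(drop(R2a %*% s)), tolerance = 1e-10)
  expect_equal(ms$total, sum(s))
  # window masking: distant pairs contribute nothing
  ld_w <- compute_ld_scores(p, list(all = 1:50), window = 1)
  expect_equal(unname(ld_w$scores[, 1]), rep(1, 50), tolerance = 1e-10)
  # alpha = 0 -> zero scores
  expect_identical(sum(compute_mediation_scores(p, numeric(50))$scores), 0)
  expect_warning(compute_ld_scores(p, list(all = 1:50, empty = integer())),
                 "empty")
})

test_that("LD scores hit the independence and perfect-LD limits", {
  p <- simulate_genotype_panel(2000, 60, 3e6, c(0.1, 0.5), ld_decay = 1,
                               n_blocks = 1, ld_decay_sd = 0, seed = 8)
  ld <- compute_ld_scores(p, list(all = 1:60), window = 3e6)
  expect_lt(max(abs(ld$scores[, 1] - 1)), 0.05)
  # duplicated variant column contributes r2 ~ 1
  p$dosages[, 2] <- p$dosages[, 1]
  p$ld_blocks <- qtlmediate:::panel_ld_blocks(p$dosages, 1)
  ld2 <- compute_ld_scores(p, list(all = 1:60), window = 3e6)
  expect_gt(ld2$scores[1, 1], 1.9)
})

test_that("no-LD mediation scores conserve the total cis variance", {
  # the unbiased r2 adjustment makes off-diagonal terms mean-zero in the
  # independence limit, so the score total matches the summed cis
  # variance up to finite-sample noise
  set.seed(9)
  s <- rexp(150)
  ms <- compute_mediation_scores(fix_panel_nold, s, window = 3e6)
  expect_lt(abs(sum(ms$scores) - sum(s)) / sum(s), 0.1)
})

test_that("stratified regression recovers enrichment and its degenerate case", {
  p <- simulate_genotype_panel(400, 800, 2e6, c(0.1, 0.5), 10000, 16,
                               seed = 21)
  m <- 800
  inpeak <- seq_len(m) %in% seq(10, 790, by = 8) # 98 "peak" variants
  ld <- compute_ld_scores(p, list(all = seq_len(m), peaks = which(inpeak)),
                          window = 2e6)
  run_one <- function(seed, causal_in_peaks) {
    set.seed(seed)
    beta <- numeric(m)
    idx <- if (causal_in_peaks) which(inpeak) else seq_len(m)
    beta[idx] <- rnorm(length(idx), 0, sqrt(0.3 / length(idx)))
    z <- numeric(m)
    for (blk in p$ld_blocks) {
      mu <- sqrt(50000) * drop(blk$R %*% beta[blk$idx])
      z[blk$idx] <- mu + drop(crossprod(qtlmediate:::chol_psd(blk$R),
                                        rnorm(length(blk$idx))))
    }
    qtlmediate:::finish_sumstats(
      data.frame(variant_id = p$variants$id, pos = p$variants$pos,
                 beta = z / sqrt(50000), se = 1 / sqrt(50000), n = 50000))
  }
  # all causal variants inside peaks: enrichment ~ 1/prop over reps
  enr <- vapply(1:8, function(s) {
    fit <- suppressWarnings(
      stratified_h2_regression(run_one(100 + s, TRUE), ld, 20))
    fit$enrichment$enrichment[fit$enrichment$category == "peaks"]
  }, numeric(1))
  truth <- 1 / mean(inpeak)
  expect_lt(abs(mean(enr) - truth), 2 * sd(enr) / sqrt(8) + 0.15 * truth)
  # the all-variants category has enrichment exactly 1
  fit <- suppressWarnings(stratified_h2_regression(run_one(3, FALSE), ld, 20))
  expect_equal(fit$enrichment$enrichment[fit$enrichment$category == "all"], 1,
               tolerance = 1e-9)
})

test_that("null GWAS gives a total h2 estimate compatible with zero", {
  p <- simulate_genotype_panel(400, 800, 2e6, c(0.1, 0.5), 10000, 16,
                               seed = 22)
  set.seed(23)
  z <- numeric(800)
  for (blk in p$ld_blocks)
    z[blk$idx] <- drop(crossprod(qtlmediate:::chol_psd(blk$R),
                                 rnorm(length(blk$idx))))
  gw <- qtlmediate:::finish_sumstats(
    data.frame(variant_id = p$variants$id, pos = p$variants$pos,
               beta = z / sqrt(50000), se = 1 / sqrt(50000), n = 50000))
  ld <- compute_ld_scores(p, list(all = 1:800), window = 2e6)
  fit <- suppressWarnings(stratified_h2_regression(gw, ld, 20))
  expect_lt(abs(fit$h2_total), 2 * fit$se_total + 0.02)
})

test_that("Haseman-Elston estimates are calibrated at the null and at 0.4", {
  p <- simulate_genotype_panel(500, 60, 2e5, c(0.1, 0.5), 15000, 1,
                               seed = 9)
  anch <- data.frame(chrom = "chr1", tss = 1e5)
  set.seed(10)
  nulls <- replicate(60, estimate_cis_h2(p, rnorm(500), anch, 2e5)$h2_raw)
  expect_lt(abs(mean(nulls)), 3 * sd(nulls) / sqrt(60) + 0.01)
  Xs <- scale(p$dosages)
  set.seed(11)
  h2s <- replicate(60, {
    b <- rnorm(60)
    g <- drop(Xs %*% b); g <- g * sqrt(0.4) / sd(g)
    estimate_cis_h2(p, g + rnorm(500, 0, sqrt(0.6)), anch, 2e5)$h2_raw
  })
  expect_gt(mean(h2s), 0.3)
  expect_lt(mean(h2s), 0.5)
  expect_error(estimate_cis_h2(p, rnorm(500),
                               data.frame(chrom = "chr1", tss = 5e7), 1e3))
})

test_that("HE and the likelihood-based estimator agree on varying truths", {
  p <- simulate_genotype_panel(60, 10, 1.5e5, c(0.1, 0.5), 2000, 1,
                               ld_decay_sd = 0, seed = 10)
  Xs <- scale(p$dosages)
  anch <- data.frame(chrom = "chr1", tss = 7e4)
  set.seed(3)
  est <- t(replicate(50, {
    h2 <- runif(1, 0.05, 0.95)
    b <- rnorm(10)
    g <- drop(Xs %*% b); g <- g * sqrt(h2) / sd(g)
    y <- g + rnorm(60, 0, sqrt(1 - h2))
    c(estimate_cis_h2(p, y, anch, 2e5)$h2,
      estimate_cis_h2_reml(p, y, anch, 2e5)$h2)
  }))
  expect_gt(cor(est[, 1], est[, 2]), 0.8)
})

test_that("the mediated regression is null-calibrated and collinearity-stable", {
  p <- simulate_genotype_panel(500, 800, 2e6, c(0.05, 0.5), 10000, 16,
                               seed = 30)
  f <- simulate_features(p, 80, 30, 400, seed = 31)
  mod <- simulate_regulatory_model(p, f$peaks, f$genes, p_causal_peak = 0.9,
                                   gamma_scale = 0, delta_scale = 0,
                                   direct_scale = 1, prop_direct = 0.3,
                                   h2_snp_target = 0.3, seed = 32)
  gw <- simulate_gwas_summary(p, mod, 50000, seed = 33)
  ld <- compute_ld_scores(p, list(all = 1:800), window = 2e6)
  ms <- compute_mediation_scores(p, mod$alpha_peaks^2, "caQTL", window = 2e6)
  # disease effects independent of the scored features: ratio ~ 0
  fit <- suppressWarnings(mediated_h2_regression(gw, ld, ms, 20))
  expect_lt(abs(fit$ratio_total), 2 * fit$se_ratio_total + 0.05)
  # two identical score sets: summed mediated h2 matches the single fit
  mod2 <- simulate_regulatory_model(p, f$peaks, f$genes, p_causal_peak = 0.9,
                                    gamma_scale = 0, delta_scale = 1,
                                    prop_disease_peaks = 0.6,
                                    direct_scale = 1, prop_direct = 0.3,
                                    h2_snp_target = 0.3,
                                    prop_mediated_target = 0.5, seed = 34)
  gw2 <- simulate_gwas_summary(p, mod2, 50000, seed = 35)
  ms2 <- compute_mediation_scores(p, mod2$alpha_peaks^2, "caQTL",
                                  window = 2e6)
  single <- suppressWarnings(mediated_h2_regression(gw2, ld, ms2, 20))
  twin <- suppressWarnings(mediated_h2_regression(
    gw2, ld, list(ms2, compute_mediation_scores(
      p, mod2$alpha_peaks^2, "copy", window = 2e6)), 20))
  expect_lt(abs(twin$h2_med_total - single$h2_med_total),
            2 * (single$se[["h2_med"]] + 1e-6) + 0.05)
})

test_that("decomposition identities hold exactly for any inputs", {
  d <- decompose_mediated_h2(0.3, 0.2, 0.35)
  expect_equal(d$intersection, 0.15)
  expect_equal(d$just_ca, 0.15)
  expect_equal(d$just_e, 0.05)
  expect_equal(d$shared_fraction, 0.75)
  set.seed(12)
  for (i in 1:50) {
    x <- rnorm(3)
    d <- decompose_mediated_h2(x[1], x[2], x[3])
    expect_equal(d$just_ca + d$just_e + d$intersection, d$h_union)
    expect_identical(d$intersection, d$h_ca + d$h_e - d$h_union)
  }
  # disjoint and fully nested special cases
  expect_equal(decompose_mediated_h2(0.2, 0.1, 0.3)$intersection, 0)
  nest <- decompose_mediated_h2(0.3, 0.1, 0.3)
  expect_equal(nest$just_e, 0)
  expect_equal(nest$intersection, 0.1)
})

test_that("subset enrichment is 1 for the full set and flags degeneracy", {
  enr <- mediated_h2_enrichment(c(full = 0.2), 0.2, c(full = 1))
  expect_equal(enr$enrichment, 1)
  flagged <- mediated_h2_enrichment(c(a = 0.1, b = 0), 0,
                                    c(a = 0.5, b = 0))
  expect_true(all(flagged$undefined))
  # partition proportions of mediated h2 sum to 1
  parts <- c(q1 = 0.12, q2 = 0.05, q3 = 0.03)
  enr2 <- mediated_h2_enrichment(parts, sum(parts),
                                 c(q1 = 0.4, q2 = 0.3, q3 = 0.3))
  expect_equal(sum(enr2$h2_med) / sum(parts), 1, tolerance = 1e-9)
  # concentrated mediation in a 20% subset -> enrichment near 5
  conc <- mediated_h2_enrichment(c(top = 0.2, rest = 0), 0.2,
                                 c(top = 0.2, rest = 0.8))
  expect_equal(conc$enrichment, c(5, 0))
})

test_that("peak annotation applies the 1 bp overlap rule and signatures", {
  peaks <- data.frame(chrom = "chr1",
                      start = c(100, 500, 900, 1300, 1700),
                      end = c(200, 600, 1000, 1400, 1800),
                      id = paste0("p", 1:5))
  set.seed(13)
  cpm <- matrix(rexp(5 * 10, rate = 1 / (5 * (5:1))), 5, 10,
                dimnames = list(peaks$id, NULL))
  marks <- list(
    H3K27ac = data.frame(chrom = "chr1", start = c(199, 550),
                         end = c(300, 560)),   # 1 bp overlap with p1
    H3K4me3 = data.frame(chrom = "chr1", start = 540, end = 590),
    H3K4me1 = data.frame(chrom = "chr1", start = 950, end = 990))
  ann <- annotate_peak_subsets(peaks, cpm, marks)
  expect_true(ann$H3K27ac[1])    # exactly 1 bp
  expect_true(ann$promoter_like[2])
  expect_false(ann$enhancer_like[2])
  expect_true(ann$enhancer_like[1])
  expect_true(ann$atac_only[4] && ann$atac_only[5])
  expect_false(ann$atac_only[3]) # H3K4me1 only
  expect_identical(sort(unique(ann$quintile)), 1:5)
  # quintile 1 holds the strongest peak
  expect_identical(ann$quintile[which.max(ann$strength)], 1L)
})

test_that("peak-to-TSS distances follow the frozen coordinate conventions", {
  pk <- list(chrom = "chr1", start = 100, end = 200)
  expect_identical(peak_tss_distance(pk, list(chrom = "chr1", tss = 150)), 0)
  expect_identical(peak_tss_distance(pk, list(chrom = "chr1", tss = 500)),
                   301)
  expect_identical(peak_tss_distance(pk, list(chrom = "chr1", tss = 50)),
                   51)
  expect_error(peak_tss_distance(pk, list(chrom = "chr2", tss = 150)),
               "chromosome")
})

test_that("TSS-window proportions hit their limiting values", {
  peaks <- data.frame(chrom = "chr1", start = c(1000, 50000, 200000),
                      end = c(1400, 50400, 200400), id = paste0("p", 1:3),
                      h2_med = c(0.1, 0.2, 0))
  genes <- data.frame(id = "g", chrom = "chr1", tss = 1200, strand = "+")
  res <- tss_window_mediated_h2(peaks, genes, c(10, 1e5, 1e7))
  expect_equal(res$prop_h2med, c(0.1 / 0.3, 1, 1))
  expect_equal(res$prop_h2med[res$window == 1e7], 1)
  tiny <- tss_window_mediated_h2(peaks[2:3, ], genes, c(10))
  expect_equal(tiny$prop_h2med, 0)
  expect_false(is.unsorted(res$prop_h2med))
})

test_that("distance stratification handles null and degenerate patterns", {
  set.seed(14)
  n <- 100
  pairs <- data.frame(distance = sort(runif(n, 0, 2e5)),
                      caqtl_h2 = runif(n, 0.2, 0.6),
                      eqtl_h2 = NA)
  pairs$eqtl_h2 <- pairs$caqtl_h2
  da <- suppressWarnings(distance_stratified_h2(pairs))
  expect_identical(as.vector(table(da$pairs$quintile)), rep(20L, 5))
  expect_true(all(da$paired_p == 0.5)) # identical members
  # flat eQTL h2: first-vs-later tests rarely significant
  sig <- replicate(20, {
    pairs$eqtl_h2 <- runif(n, 0.1, 0.3)
    mean(distance_stratified_h2(pairs)$rank_p$eqtl < 0.05)
  })
  expect_lt(mean(sig), 0.2)
  # ties assigned to the lower quintile
  tied <- data.frame(distance = c(rep(0, 30), 1:70),
                     caqtl_h2 = runif(100), eqtl_h2 = runif(100))
  dt <- distance_stratified_h2(tied)
  expect_true(all(dt$pairs$quintile[tied$distance == 0] == 1))
  expect_error(distance_stratified_h2(pairs[1:5, ]))
})
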