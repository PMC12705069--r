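test_that("TMM factors behave like library-size compensation", {
  set.seed(1)
  counts <- matrix(rnbinom(200 * 10, mu = 60, size = 5), 200, 10,
                   dimnames = list(paste0("f", 1:200), paste0("s", 1:10)))
  # identical columns -> unit factors, identical CPM columns
  same <- counts[, rep(1, 6)]
  colnames(same) <- paste0("s", 1:6)
  tn <- tmm_normalize(same)
  expect_equal(tn$norm$factor, rep(1, 6))
  expect_equal(tn$cpm[, 1], tn$cpm[, 4])
  # doubling one library leaves its CPM essentially unchanged (the
  # precision weights in weighted TMM depend on library size, so the
  # compensation is near-exact rather than bitwise)
  doubled <- counts; doubled[, 3] <- 2L * doubled[, 3]
  cpm1 <- tmm_normalize(counts)$cpm
  cpm2 <- tmm_normalize(doubled)$cpm
  expect_equal(cpm1[, 3], cpm2[, 3], tolerance = 0.01)
  # factors multiply to one
  expect_equal(prod(tmm_normalize(counts)$norm$factor)^(1 / 10), 1,
               tolerance = 1e-6)
  bad <- counts; bad[, 2] <- 0L
  expect_error(tmm_normalize(bad), "s2")
})

test_that("feature filter drops only above the failure-fraction boundary", {
  n <- 10
  counts <- matrix(50L, 4, n,
                   dimnames = list(paste0("f", 1:4), paste0("s", 1:n)))
  cpm <- matrix(5, 4, n, dimnames = dimnames(counts))
  # f2 fails in exactly 20% of samples (kept, strict inequality);
  # f3 fails in 25%+ (dropped); f4 fails via low counts
  cpm[2, 1:2] <- 0.5
  cpm[3, 1:3] <- 0.5
  counts[4, 1:3] <- 5L
  kept <- filter_features(counts, cpm, cpm_min = 0.8, count_min = 10,
                          max_fail_frac = 0.2)
  expect_identical(kept, c("f1", "f2"))
  expect_error(filter_features(counts[1:3, ], cpm), "aligned")
})

test_that("inverse normal transform matches frozen quantiles and is rank-invariant", {
  x <- matrix(c(5, 1, 9), 1)
  got <- inverse_normal_transform(x)
  expect_equal(drop(got), c(0, qnorm(1 / 6), qnorm(5 / 6)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(drop(got), c(0, -0.9674216, 0.9674216), tolerance = 1e-6,
               ignore_attr = TRUE)
  # any strictly monotone transform leaves the output unchanged
  expect_equal(inverse_normal_transform(exp(x)), got,
               ignore_attr = TRUE)
  # near-zero mean, unit-ish sd for odd n without ties
  y <- matrix(rnorm(31), 1)
  ty <- inverse_normal_transform(y)
  expect_lt(abs(mean(ty)), 1e-10)
  expect_warning(inverse_normal_transform(matrix(rep(1, 5), 1)), "constant")
})

test_that("parallel analysis finds planted factors and rejects pure noise", {
  set.seed(10)
  noise <- matrix(rnorm(60 * 50), 60, 50)
  k0 <- vapply(1:10, function(s)
    select_num_pcs(noise + matrix(rnorm(60 * 50), 60, 50), n_perm = 30,
                   seed = s), integer(1))
  expect_gte(sum(k0 == 0), 8)
  # three strong planted factors
  k3 <- vapply(1:6, function(s) {
    set.seed(100 + s)
    L <- matrix(rnorm(60 * 3), 60, 3)
    FS <- matrix(rnorm(3 * 50), 3, 50)
    select_num_pcs(L %*% FS + 0.3 * matrix(rnorm(60 * 50), 60, 50),
                   n_perm = 30, seed = s)
  }, integer(1))
  expect_gte(sum(k3 == 3), 5)
  expect_identical(select_num_pcs(noise, n_perm = 30, seed = 4),
                   select_num_pcs(noise, n_perm = 30, seed = 4))
  expect_error(select_num_pcs(noise, n_perm = 5), "19")
})

test_that("cis mapping equals the full multiple regression with covariates", {
  p <- fix_panel
  set.seed(20)
  covar <- matrix(rnorm(300 * 3), 300, 3)
  y <- rnorm(300)
  anch <- data.frame(feature_id = "f", chrom = "chr1",
                     tss = p$variants$pos[100])
  cis <- map_cis_qtl(p, one_feature(y), covar, anch, cis_window = 5e4)
  expect_gt(nrow(cis), 5)
  for (i in seq_len(nrow(cis))) {
    j <- match(cis$variant_id[i], p$variants$id)
    sm <- summary(lm(y ~ p$dosages[, j] + covar))$coefficients
    expect_equal(cis$beta[i], sm[2, 1], tolerance = 1e-8)
    expect_equal(cis$se[i], sm[2, 2], tolerance = 1e-8)
    expect_equal(cis$p[i], sm[2, 4], tolerance = 1e-8)
  }
  # lead has the minimum p
  expect_equal(cis$p[cis$is_lead], min(cis$p))
})

test_that("cis mapping enforces the MAF threshold and the window", {
  p <- fix_panel
  # plant a rare variant by editing dosages
  p$dosages[, 100] <- c(rep(1L, 24), rep(0L, 276)) # maf 0.04
  y <- rnorm(300)
  anch <- data.frame(feature_id = "f", chrom = "chr1",
                     tss = p$variants$pos[100])
  cis <- map_cis_qtl(p, one_feature(y), NULL, anch, cis_window = 5e4,
                     maf_min = 0.05)
  expect_false(p$variants$id[100] %in% cis$variant_id)
  expect_true(all(abs(cis$pos - p$variants$pos[100]) <= 5e4))
  # interval anchors measure from the nearest edge
  anch2 <- data.frame(feature_id = "f", chrom = "chr1",
                      start = p$variants$pos[100], end = p$variants$pos[105])
  cis2 <- map_cis_qtl(p, one_feature(y), NULL, anch2, cis_window = 5e4)
  expect_true(all(cis2$pos > anch2$start - 5e4 & cis2$pos <= anch2$end + 5e4))
})

test_that("null phenotypes give uniform cis p-values", {
  set.seed(30)
  y <- rnorm(300)
  anch <- data.frame(feature_id = "f", chrom = "chr1", tss = 1.5e6)
  cis <- map_cis_qtl(fix_panel_nold, one_feature(y), NULL, anch,
                     cis_window = 3e6)
  expect_gt(nrow(cis), 100)
  expect_gt(ks.test(cis$p, "punif")$p.value, 0.01)
})

test_that("an orthogonal covariate leaves effect estimates unchanged", {
  p <- fix_panel
  set.seed(31)
  y <- rnorm(300)
  anch <- data.frame(feature_id = "f", chrom = "chr1",
                     tss = p$variants$pos[50])
  base <- map_cis_qtl(p, one_feature(y), NULL, anch, cis_window = 4e4)
  G <- p$dosages[, match(base$variant_id, p$variants$id), drop = FALSE]
  raw <- rnorm(300)
  orth <- residuals(lm(raw ~ y + G)) # orthogonal to phenotype and dosages
  with_cov <- map_cis_qtl(p, one_feature(y), matrix(orth), anch,
                          cis_window = 4e4)
  expect_equal(base$beta, with_cov$beta, tolerance = 1e-8)
})

test_that("the planted cis signal is recovered by the lead variant", {
  p <- simulate_genotype_panel(100, 120, 3e5, c(0.1, 0.5), 20000, 2,
                               seed = 55)
  Xs <- scale(p$dosages)
  anch <- data.frame(feature_id = "f", chrom = "chr1",
                     tss = p$variants$pos[60])
  hits <- vapply(1:40, function(s) {
    set.seed(700 + s)
    y <- Xs[, 60] * sqrt(0.3) + rnorm(100, 0, sqrt(0.7))
    cis <- map_cis_qtl(p, one_feature(y), NULL, anch, cis_window = 3e5)
    lead <- cis$variant_id[cis$is_lead]
    lead == p$variants$id[60] ||
      ld_r2(p, lead, p$variants$id[60]) > 0.8
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("null lead p-values match the effective-test expectation", {
  # weak-LD panel: each feature scans ~m near-independent variants, so
  # P(lead p < t) ~ 1 - (1 - t)^m
  p <- fix_panel_nold
  anch <- data.frame(feature_id = "f", chrom = "chr1", tss = 1.5e6)
  set.seed(60)
  leads <- vapply(1:300, function(s) {
    y <- rnorm(300)
    min(map_cis_qtl(p, one_feature(y), NULL, anch, cis_window = 3e6)$p)
  }, numeric(1))
  m_eff <- 150
  for (t in c(0.01, 0.001)) {
    expected <- 1 - (1 - t)^m_eff
    obs <- mean(leads < t)
    expect_lt(abs(obs - expected),
              3 * sqrt(expected * (1 - expected) / 300) + 0.01)
  }
})
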