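test_that("FLD separation matches hand arithmetic and degenerate cases", {
  expect_equal(fld_score(0, 2, 1, 1), 2)            # 4 / (1 + 1)
  expect_equal(fld_score(c(1, 1), c(1, 1), diag(2), diag(2)), 0)
})

test_that("2-D FLD matches a brute-force direction-scan oracle", {
  set.seed(13)
  for (i in 1:10) {
    mu1 <- runif(2, 0, 5); mu2 <- runif(2, 5, 10)
    a1 <- matrix(runif(4, -0.5, 0.5), 2); c1 <- crossprod(a1) + diag(2)
    a2 <- matrix(runif(4, -0.5, 0.5), 2); c2 <- crossprod(a2) + diag(2)
    angles <- seq(0, pi, length.out = 2001)
    scan <- max(vapply(angles, function(a) {
      w <- c(cos(a), sin(a))
      drop((w %*% (mu2 - mu1))^2 / (w %*% (c1 + c2) %*% w))
    }, numeric(1)))
    expect_equal(fld_score(mu1, mu2, c1, c2), scan, tolerance = 1e-4)
  }
})

test_that("fld_filter fails collapsed clusters and passes clean ones", {
  cm <- simulate_cluster_model(100, collapsed = rep(c(FALSE, TRUE), 50),
                               seed = 14)
  f <- fld_filter(cm)
  expect_true(all(f$pass[seq(1, 99, 2)]))
  expect_true(all(!f$pass[seq(2, 100, 2)]))
})

test_that("r/r' ratio follows the centroid-radius interpolation", {
  cl <- symmetric_cluster()
  geom <- derive_cluster_geometry(cl)
  expect_equal(r_ratio(c(cl$ab_x, cl$ab_y), geom, 0.5), 1)
  expect_equal(r_ratio(c(geom$o_x, geom$o_y), geom, 0.5), 0)
  # intermediate AF: oracle interpolates radii linearly in AF
  af <- 0.75
  r_expected <- geom$r_ab + (af - 0.5) / 0.5 * (geom$r_aa - geom$r_ab)
  pt <- c(geom$o_x + 4, geom$o_y + 1)
  r_obs <- sqrt(sum((pt - c(geom$o_x, geom$o_y))^2))
  expect_equal(r_ratio(pt, geom, af), r_obs / r_expected)
})

test_that("r-filter requires the configured fraction of replicates", {
  cfg <- qc_config()
  # 13 replicates at the 0.8 / 80% operating point: 11 must pass
  ratios <- data.frame(snp_id = "s1",
                       r_ratio = c(rep(1, 11), 0.5, 0.5))
  expect_true(r_filter(ratios, cfg)$pass)
  ratios10 <- data.frame(snp_id = "s1",
                         r_ratio = c(rep(1, 10), 0.5, 0.5, 0.5))
  expect_false(r_filter(ratios10, cfg)$pass)
  all_good <- data.frame(snp_id = "s1", r_ratio = rep(1, 13))
  expect_true(r_filter(all_good, cfg)$pass)
})

test_that("MAF filter thresholds and hard-drops out-of-range estimates", {
  cfg <- qc_config(maf_min = 0.05)
  tab <- data.frame(snp_id = rep(c("a", "b", "c"), each = 2),
                    pool_id = rep(c("p1", "p2"), 3),
                    af = c(0.5, 0.5, 0.97, 0.97, -0.02, 0.03))
  res <- maf_filter(tab, c(p1 = 100, p2 = 100), cfg)
  res <- res[match(c("a", "b", "c"), res$snp_id), ]
  expect_equal(res$pass, c(TRUE, FALSE, FALSE))
  expect_equal(res$hard_drop, c(FALSE, FALSE, TRUE))
  expect_equal(res$maf[2], 0.03)
})

test_that("hist-filter scores the pool-consistency variance", {
  cfg <- qc_config(hist_var_max = 0.01)
  pooled <- rbind(rep(0.5, 4), c(0.6, 0.4, 0.6, 0.4))
  indiv <- matrix(0.5, 2, 4)
  h <- hist_filter(pooled, indiv, cfg)
  expect_equal(h$hist_var[1], 0)
  expect_equal(h$hist_var[2], var(c(0.1, -0.1, 0.1, -0.1)))
  expect_equal(h$hist_var[2], 0.04 / 3)
  expect_equal(h$pass, c(TRUE, FALSE))
  expect_error(hist_filter(pooled[, 1, drop = FALSE],
                           indiv[, 1, drop = FALSE], cfg), "2 pools")
})

test_that("PFP counts null SNPs among the top-ranked pooled tests", {
  n <- 10000
  pooled_p <- seq_len(n) / n            # top 5 SNPs are ranks 1..5
  expected_p <- rep(0.5, n)
  expected_p[1:2] <- 1e-6               # 2 of the top 5 truly significant
  expect_equal(proportion_false_positives(pooled_p, expected_p), 3 / 5)
  expected_p[1:5] <- 1e-6
  expect_equal(proportion_false_positives(pooled_p, expected_p), 0)
  expect_error(proportion_false_positives(runif(10), runif(10)), "empty")
})

test_that("genomic-control lambda is the scaled chi-square median", {
  expect_equal(gc_lambda(rep(qchisq(0.5, 1), 5)), 1)
  x <- rchisq(11, 1)
  expect_equal(gc_lambda(2 * x), 2 * gc_lambda(x))
  set.seed(15)
  expect_equal(gc_lambda(rchisq(1e5, 1)), 1, tolerance = 0.02)
  expect_error(gc_lambda(numeric(0)), "no finite")
})

test_that("stricter cut-offs never retain more SNPs", {
  st <- simulate_pool_study(sim_config(
    n_snps = 2000, n_individuals = 100, n_pools = 4, n_replicates = 3,
    pool_noise_sd = 0.02, corrupt_fraction = 0.1, seed = 16))
  paf <- estimate_pool_af(st$clusters, st$replicates)
  counts <- vapply(c(0.5, 2, 3.6, 8), function(fm) {
    v <- apply_qc(paf, clusters = st$clusters,
                  pool_sizes = st$pool_sizes,
                  individual_af = st$individual_af,
                  config = qc_config(fld_min = fm))
    sum(v$pass)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  counts_maf <- vapply(c(0.01, 0.05, 0.1, 0.2), function(mm) {
    v <- apply_qc(paf, clusters = st$clusters,
                  pool_sizes = st$pool_sizes,
                  config = qc_config(maf_min = mm))
    sum(v$pass)
  }, numeric(1))
  expect_true(all(diff(counts_maf) <= 0))
})

test_that("tightening the hist cut-off lowers the null inflation factor", {
  st <- simulate_pool_study(sim_config(
    n_snps = 4000, n_individuals = 250, n_pools = 2, n_replicates = 3,
    pool_noise_sd = 0.02, corrupt_fraction = 0.15, seed = 17))
  paf <- estimate_pool_af(st$clusters, st$replicates)
  m <- poolancestry:::.pool_af_matrix(paf$pools)
  h <- hist_filter(m, st$individual_af, snp_id = rownames(m))
  # null pool-vs-pool chi-square, uncorrected for pooling error
  ct <- corrected_chi2(m[, 1], 250, m[, 2], 250)
  ok <- !ct$excluded
  sweep <- tune_cutoff_by_lambda(h$hist_var[ok],
                                 cutoffs = c(0.05, 1e-3, 2e-4),
                                 chi2 = ct$naive[ok], pass = "le")
  expect_true(all(diff(sweep$n_retained) <= 0))
  expect_lt(sweep$lambda[3], sweep$lambda[1])
})

test_that("consistency ranking flags discordant SNPs", {
  pooled <- c(50, 10, 9, 1, 0.5)
  indiv <- c(2, 10, 9.5, 1, 0.4)
  r <- snp_consistency_ranks(pooled, indiv, n = 2)
  expect_equal(r$worst[1], 1)          # greatest corrected-chi2 difference
  expect_false(1 %in% r$best)
})
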