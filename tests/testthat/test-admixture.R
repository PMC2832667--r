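test_that("regression SNP selection enforces QC and call-rate rules", {
  qc <- data.frame(snp_id = paste0("s", 1:6),
                   pass = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE))
  p1 <- data.frame(snp_id = paste0("s", 1:6),
                   call_rate = c(1, 0.79, 1, 1, 0.9, 1))
  p2 <- data.frame(snp_id = paste0("s", 1:6),
                   call_rate = c(1, 1, 0.8, 1, 1, 1))
  sel <- select_regression_snps(qc, list(p1, p2))
  # oracle by explicit set intersection; call rate is exclusive at 0.8
  expect_setequal(sel, c("s1", "s5", "s6"))
  qc$pass <- FALSE
  expect_error(select_regression_snps(qc, list(p1, p2)), "no SNPs")
})

test_that("noiseless admixture regression is exact", {
  set.seed(21)
  x <- cbind(a = runif(500, 0.1, 0.9), b = runif(500, 0.1, 0.9))
  fit <- fit_admixture(drop(x %*% c(0.8, 0.2)), x)
  expect_equal(unname(fit$beta), c(0.8, 0.2), tolerance = 1e-10)
  expect_equal(fit$intercept, 0, tolerance = 1e-10)
  fit2 <- fit_admixture(drop(x %*% c(0.7, 0.2)) + 0.05, x)
  expect_equal(unname(fit2$beta), c(0.7, 0.2), tolerance = 1e-10)
  expect_equal(fit2$intercept, 0.05, tolerance = 1e-10)
  expect_equal(fit2$n_snp, 500)
  expect_equal(fit2$two_c, 0.1, tolerance = 1e-9)
})

test_that("collinear reference panels trigger a warning but still fit", {
  set.seed(22)
  x1 <- runif(200, 0.1, 0.9)
  x <- cbind(x1, x1 + rnorm(200, 0, 1e-7))
  expect_warning(fit <- fit_admixture(x1, x), "collinear")
  expect_s3_class(fit, "admixture_fit")
})

test_that("admixture recovery from a full synthetic study", {
  st <- simulate_pool_study(sim_config(
    n_snps = 2e4, n_individuals = 250, n_pools = 2, n_replicates = 3,
    drift_fst = 0.15, pool_noise_sd = 0.02, seed = 23))
  paf <- estimate_pool_af(st$clusters, st$replicates)
  m <- poolancestry:::.pool_af_matrix(paf$pools)
  pooled <- rowMeans(m)
  fit <- fit_admixture(pooled, st$ref_afs)
  expect_equal(unname(fit$beta), c(0.82, 0.18), tolerance = 0.02)
  expect_true(all(abs(fit$beta - c(0.82, 0.18)) < 3 * fit$se + 0.01))
})

test_that("pooling noise barely moves the admixture estimate", {
  base <- sim_config(n_snps = 2e4, n_individuals = 250, seed = 24,
                     pool_noise_sd = 0)
  noisy <- sim_config(n_snps = 2e4, n_individuals = 250, seed = 24,
                      pool_noise_sd = 0.02)
  betas <- lapply(list(base, noisy), function(cfg) {
    st <- simulate_pool_study(cfg)
    paf <- estimate_pool_af(st$clusters, st$replicates)
    m <- poolancestry:::.pool_af_matrix(paf$pools)
    fit_admixture(rowMeans(m), st$ref_afs)$beta
  })
  expect_lt(max(abs(betas[[1]] - betas[[2]])), 0.02)
})

test_that("pseudopopulation combines references by the fitted weights", {
  x <- cbind(a = c(0.2, 0.5, 0.9), b = c(0.6, 0.5, 0.1))
  fit <- fit_admixture(drop(x %*% c(1, 0)) + rep(0, 3), x)
  ps <- build_pseudopopulation(fit, x)
  expect_equal(ps$af, x[, 1], tolerance = 1e-9)
  expect_equal(ps$n_effective, 120L)
  expect_equal(ps$pooling_variance, 0)
  # three references use the 210-individual convention
  set.seed(25)
  x3 <- matrix(runif(60, 0.2, 0.8), ncol = 3)
  y3 <- drop(x3 %*% c(0.5, 0.3, 0.2))
  ps3 <- build_pseudopopulation(fit_admixture(y3, x3), x3)
  expect_equal(ps3$n_effective, 210L)
  # beta = (0.5, 0.5): a SNP with refs 0.2 / 0.6 combines to 0.4
  set.seed(26)
  xm <- rbind(c(0.2, 0.6), matrix(runif(38, 0.1, 0.9), ncol = 2))
  fit5 <- fit_admixture(drop(xm %*% c(0.5, 0.5)), xm)
  expect_equal(build_pseudopopulation(fit5, xm)$af[1], 0.4,
               tolerance = 1e-8)
})

test_that("panel combination weights by sample size", {
  pa <- data.frame(snp_id = c("s1", "s2"), chrom = 1, pos = c(100, 200),
                   allele_a = "A", allele_b = "G",
                   af = c(0.2, 0.3), call_rate = 1, n = 90)
  pb <- data.frame(snp_id = c("s1", "s2"), chrom = 1, pos = c(100, 200),
                   allele_a = "A", allele_b = "G",
                   af = c(0.4, 0.6), call_rate = 1, n = c(90, 45))
  m <- combine_reference_panels(pa, pb)
  expect_equal(m$af, c(0.3, 0.4))
  expect_equal(m$n, c(180, 135))
  pb$snp_id <- c("s3", "s4")
  expect_error(combine_reference_panels(pa, pb), "no SNPs")
  pc <- data.frame(snp_id = "s1", chrom = 1, pos = 100,
                   allele_a = "C", allele_b = "G",
                   af = 0.4, call_rate = 1, n = 90)
  expect_message(expect_error(combine_reference_panels(pa, pc), "no rows|share"),
                 "allele mismatch")
})

test_that("allele-orientation checker warns on skewed panels", {
  expect_silent(check_allele_orientation(list(a = runif(5000, 0, 1))))
  expect_warning(check_allele_orientation(list(skew = rep(0.9, 100))),
                 "deviates")
})

test_that("unmodeled ancestry shows up as shortfall and intercept", {
  st <- simulate_pool_study(sim_config(
    n_snps = 3e4, n_individuals = 250,
    admixture_proportions = c(0.738, 0.162),   # 10% missing ancestry
    drift_fst = 0.15, pool_noise_sd = 0.02, seed = 26))
  paf <- estimate_pool_af(st$clusters, st$replicates)
  m <- poolancestry:::.pool_af_matrix(paf$pools)
  fit <- fit_admixture(rowMeans(m), st$ref_afs)
  expect_equal(fit$sum_beta, 0.9, tolerance = 0.02)
  expect_equal(fit$two_c, 0.1, tolerance = 0.02)
})
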