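test_that("cluster_angle returns the major-axis orientation", {
  expect_equal(cluster_angle(matrix(c(4, 0, 0, 1), 2)), 0)
  expect_equal(cluster_angle(matrix(c(2, 1, 1, 2), 2)), 45)
  expect_equal(cluster_angle(matrix(c(1, 0, 0, 4), 2)), 90)
  expect_error(cluster_angle(matrix(c(-1, 0, 0, 1), 2)), "negative")
  # isotropic covariance: fallback convention
  expect_equal(cluster_angle(diag(2), fallback = 90), 90)
})

test_that("compute_origin solves the homozygous-line intersection", {
  o <- compute_origin(c(10, 1), 0, c(1, 10), 90)
  expect_equal(o$origin, c(1, 1))
  expect_equal(o$x_axis, c(1, 0))
  expect_equal(o$y_axis, c(0, 1))
  expect_error(compute_origin(c(10, 1), 30, c(1, 10), 30), "parallel")
})

test_that("compute_origin matches an independent line-intersection oracle", {
  # oracle: solve y = tan(a)(x - px) + py for both lines as a 2x2 system
  set.seed(5)
  for (i in 1:20) {
    aa <- runif(2, 5, 15); bb <- runif(2, 5, 15)
    ta <- runif(1, 1, 40); tb <- runif(1, 55, 89)
    m1 <- tan(ta * pi / 180); m2 <- tan(tb * pi / 180)
    x_star <- (bb[2] - aa[2] + m1 * aa[1] - m2 * bb[1]) / (m1 - m2)
    y_star <- aa[2] + m1 * (x_star - aa[1])
    o <- compute_origin(aa, ta, bb, tb)
    expect_equal(o$origin, c(x_star, y_star), tolerance = 1e-10)
  }
})

test_that("normalization factor calibrates the heterozygote to AF 0.5", {
  expect_equal(normalization_factor(3, 3), 1)
  expect_equal(normalization_factor(2, 1), 2)
  expect_equal(normalization_factor(1, 2), 1 / normalization_factor(2, 1))
  expect_error(normalization_factor(0, 1), "quadrant")
  # calibration contract: with NF = x'/y', the AB centroid maps to 0.5
  geom <- derive_cluster_geometry(symmetric_cluster())
  expect_equal(estimate_replicate_af(c(7, 7), geom), 0.5, tolerance = 1e-12)
})

test_that("replicate AF obeys the three-point contract", {
  cl <- symmetric_cluster()
  geom <- derive_cluster_geometry(cl)
  expect_equal(estimate_replicate_af(c(cl$aa_x, cl$aa_y), geom), 1)
  expect_equal(estimate_replicate_af(c(cl$bb_x, cl$bb_y), geom), 0)
  expect_equal(estimate_replicate_af(c(cl$ab_x, cl$ab_y), geom), 0.5)
  # a point at the origin has no defined angle
  expect_true(is.na(estimate_replicate_af(c(geom$o_x, geom$o_y), geom)))
})

test_that("AF is monotone in angular position between AA and BB", {
  geom <- derive_cluster_geometry(symmetric_cluster())
  angles <- seq(0.5, 89.5, length.out = 50)
  pts_af <- vapply(angles, function(a) {
    p <- c(geom$o_x + 6 * cos(a * pi / 180),
           geom$o_y + 6 * sin(a * pi / 180))
    estimate_replicate_af(p, geom)
  }, numeric(1))
  expect_true(all(diff(pts_af) < 0))
  expect_true(all(pts_af > 0 & pts_af < 1))
})

test_that("allelic imbalance is NF-compensated; disabling NF biases AB", {
  st <- simulate_pool_study(sim_config(
    n_snps = 100, n_individuals = 50, n_pools = 1, n_replicates = 2,
    pool_noise_sd = 0, radial_noise_sd = 0, allelic_imbalance = 2,
    seed = 3))
  geom <- st$geometry
  # AB centroid sits off the 45-degree diagonal under imbalance ...
  expect_gt(median(abs(st$clusters$ab_x - st$clusters$ab_y)), 1)
  af_ab <- vapply(seq_len(nrow(geom)), function(i)
    estimate_replicate_af(c(st$clusters$ab_x[i], st$clusters$ab_y[i]),
                          geom[i, ]), numeric(1))
  expect_equal(af_ab, rep(0.5, 100), tolerance = 1e-10)
  # ... and without the NF correction the heterozygote AF is biased
  geom_nonf <- geom
  geom_nonf$nf <- 1
  af_nonf <- vapply(seq_len(nrow(geom)), function(i)
    estimate_replicate_af(c(st$clusters$ab_x[i], st$clusters$ab_y[i]),
                          geom_nonf[i, ]), numeric(1))
  expect_gt(median(abs(af_nonf - 0.5)), 0.02)
})

test_that("aggregate_replicates computes mean and standard error", {
  a <- aggregate_replicates(c(0.4, 0.5, 0.6))
  expect_equal(a$af, 0.5)
  expect_equal(a$se, sd(c(0.4, 0.5, 0.6)) / sqrt(3))
  one <- aggregate_replicates(0.5)
  expect_equal(one$af, 0.5)
  expect_true(is.na(one$se) && one$flagged)
  expect_error(aggregate_replicates(numeric(0)), "no replicate")
})

test_that("replicate SE tracks the injected noise (Monte Carlo)", {
  cl <- symmetric_cluster()
  geom <- derive_cluster_geometry(cl)
  reps <- simulate_pool_replicates(0.5, geom, n_replicates = 1000,
                                   noise_sd = 0.03, seed = 9)
  paf <- estimate_pool_af(cl, reps)
  expect_equal(paf$pools$se, 0.03 / sqrt(1000), tolerance = 0.1)
})

test_that("zero-noise simulation round-trips exactly through estimation", {
  st <- tiny_study(n_snps = 300, seed = 11)
  paf <- estimate_pool_af(st$clusters, st$replicates)
  m <- poolancestry:::.pool_af_matrix(paf$pools)
  expect_lt(max(abs(m - st$true_pool_af[, colnames(m)])), 1e-10)
  expect_true(all(paf$pools$se < 1e-7))
})
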