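test_that("sampling variance sums the two binomial terms", {
  expect_equal(sampling_variance(0.5, 250, 0.5, 250), 0.001)
  expect_equal(sampling_variance(0, 100, 0.5, 210),
               0.25 / 420)
  expect_error(sampling_variance(0.5, 0, 0.5, 100), "positive")
})

test_that("pooling error variance is that of the weighted mean", {
  expect_equal(pooled_error_variance(0.01, 100), 1e-4)
  expect_equal(pooled_error_variance(c(0.01, 0.01), c(100, 100)), 5e-5)
  expect_error(pooled_error_variance(c(0.01, NA), c(100, 100)), "missing")
})

test_that("naive chi-square matches the contingency-table oracle", {
  # constructed allele counts with integer-valued frequencies
  cases <- list(c(0.6, 100, 0.4, 100), c(0.3, 250, 0.25, 120),
                c(0.9, 50, 0.5, 200))
  for (cs in cases) {
    p1 <- cs[1]; n1 <- cs[2]; p2 <- cs[3]; n2 <- cs[4]
    tab <- matrix(c(2 * n1 * p1, 2 * n1 * (1 - p1),
                    2 * n2 * p2, 2 * n2 * (1 - p2)),
                  nrow = 2, byrow = TRUE)
    oracle <- suppressWarnings(
      chisq.test(tab, correct = FALSE)$statistic)
    got <- corrected_chi2(p1, n1, p2, n2)
    expect_equal(got$naive, unname(oracle), tolerance = 1e-9)
    expect_equal(got$corrected, got$naive)   # no pooling error
  }
})

test_that("deflation never exceeds the naive statistic", {
  set.seed(31)
  p1 <- runif(500); p2 <- runif(500)
  v1 <- runif(500, 0, 1e-3); v2 <- runif(500, 0, 1e-3)
  ct <- corrected_chi2(p1, 300, p2, 120, v1, v2)
  expect_true(all(ct$corrected <= ct$naive + 1e-12))
  expect_true(all(ct$corrected >= 0))
  # equal frequencies give exactly zero
  ct0 <- corrected_chi2(0.4, 100, 0.4, 100, 1e-4, 1e-4)
  expect_equal(ct0$naive, 0)
  expect_equal(ct0$corrected, 0)
})

test_that("negative estimated MAF excludes the SNP", {
  ct <- corrected_chi2(c(-0.01, 0.5, 1.02), 100,
                       c(0.5, 0.5, 0.5), 100)
  expect_equal(ct$excluded, c(TRUE, FALSE, TRUE))
  expect_true(all(is.na(ct$naive[c(1, 3)])))
})

test_that("GC correction scales statistics and floors lambda at 1", {
  g <- gc_correct(3.841459, lambda = 1)
  expect_equal(g$p, 0.05, tolerance = 1e-4)
  g2 <- gc_correct(2 * 3.841459, lambda = 2)
  expect_equal(g2$p, gc_correct(3.841459, lambda = 1)$p)
  glow <- gc_correct(c(1, 2), lambda = 0.5)
  expect_equal(glow$lambda, 1)
  # null calibration: corrected statistics give uniform P-values
  set.seed(32)
  x <- rchisq(2e4, 1)
  gnull <- gc_correct(x)
  expect_gt(ks.test(gnull$p, "punif")$p.value, 0.01)
})

test_that("corrected AF difference shrinks with pooling error", {
  expect_equal(corrected_af_difference(0, 1e-3, 0.2), 0)
  # no pooling error: corrected difference ~ raw difference near p1 = p2
  p1 <- 0.5001; p2 <- 0.4999; n <- 500
  ct <- corrected_chi2(p1, n, p2, n)
  d <- corrected_af_difference(ct$corrected, ct$V, p1 - p2)
  expect_equal(d, p1 - p2, tolerance = 1e-6)
  # monotone shrinkage in var_e
  ves <- c(0, 1e-4, 1e-3, 1e-2)
  ds <- vapply(ves, function(ve) {
    ct <- corrected_chi2(0.6, n, 0.4, n, ve, 0)
    abs(corrected_af_difference(ct$corrected, ct$V, 0.2))
  }, numeric(1))
  expect_true(all(diff(ds) < 0))
  expect_true(all(ds <= 0.2 + 1e-9))
})

test_that("LD neighbors match a brute-force all-pairs oracle", {
  g <- block_ld_genotypes(n_ind = 120, n_blocks = 4, block_size = 5,
                          seed = 33)
  map <- data.frame(snp_id = paste0("s", 1:20),
                    chrom = rep(c(1, 1, 2, 2), each = 5),
                    pos = rep(c(1e6, 30e6), 10)[1:20] +
                      rep(1:5, 4) * 1e5)
  nb <- ld_neighbors(g, map, window = 20e6, r2_min = 0.5)
  # oracle: all-pairs r2 with explicit distance check
  for (i in 1:20) {
    expected <- character(0)
    for (j in setdiff(1:20, i)) {
      if (map$chrom[i] != map$chrom[j]) next
      if (abs(map$pos[i] - map$pos[j]) > 20e6) next
      r2 <- suppressWarnings(cor(g[, i], g[, j])^2)
      if (is.finite(r2) && r2 > 0.5) expected <- c(expected, map$snp_id[j])
    }
    expect_setequal(nb[[map$snp_id[i]]], expected)
  }
  # duplicate SNP 1 Mb away is always a neighbor
  g2 <- cbind(g[, 1], g[, 1])
  map2 <- data.frame(snp_id = c("a", "b"), chrom = 1, pos = c(1e6, 2e6))
  expect_equal(ld_neighbors(g2, map2)[["a"]], "b")
  # isolated SNP has no neighbors
  map3 <- data.frame(snp_id = c("a", "b"), chrom = c(1, 2), pos = 1e6)
  expect_length(ld_neighbors(g2, map3)[["a"]], 0)
})

test_that("LD categorization applies the encouraging/discouraging rules", {
  p <- c(n1 = 0.01, n2 = 0.04, n3 = 0.2, n4 = 0.05, n5 = 0.5, n6 = 0.9,
         n7 = 0.07)
  nb <- list(enc = c("n1", "n2", "n3", "n4"),
             disc = c("n5", "n6"),
             inc = c("n7", "n5", "n6"),   # one P < 0.1 but none < 0.05
             lonely = character(0))
  cat <- categorize_aims(p, nb)
  expect_equal(unname(cat),
               c("encouraging", "discouraging", "inconclusive",
                 "inconclusive"))
})

test_that("distance pruning keeps the best-P SNP of each 4 Mb clump", {
  rec <- data.frame(snp_id = c("a", "b", "c", "d"),
                    chrom = c(1, 1, 1, 2),
                    pos = c(1e6, 4e6, 9.1e6, 1e6),
                    gc_p = c(1e-6, 1e-5, 1e-4, 1e-3),
                    category = "inconclusive")
  pr <- prune_by_distance(rec)
  expect_equal(pr$kept, c(TRUE, FALSE, TRUE, TRUE))  # 3 Mb clump, then 5.1 Mb
  rec2 <- rec
  rec2$pos <- c(1e6, 6e6, 11e6, 1e6)                 # 5 Mb apart: keep both
  expect_true(all(prune_by_distance(rec2)$kept))
  # chain of SNPs 3 Mb apart: greedy oracle computed by hand
  chain <- data.frame(snp_id = paste0("s", 1:5), chrom = 1,
                      pos = (0:4) * 3e6 + 1,
                      gc_p = c(0.5, 1e-8, 0.3, 0.2, 1e-7),
                      category = "inconclusive")
  pr3 <- prune_by_distance(chain)
  # s2 kept (best), removes s1, s3; s5 kept (next best), removes s4
  expect_equal(pr3$kept, c(FALSE, TRUE, FALSE, FALSE, TRUE))
  # discouraging SNPs never enter
  chain$category[2] <- "discouraging"
  expect_false(prune_by_distance(chain)$kept[2])
})

test_that("candidate selection applies both list rules and tie-breaks", {
  set.seed(34)
  n <- 30
  rec <- data.frame(snp_id = sprintf("s%02d", 1:n),
                    gc_p = sort(runif(n, 1e-8, 1e-4)),
                    kept = TRUE, stringsAsFactors = FALSE)
  cat_f <- setNames(rep("encouraging", n), rec$snp_id)
  cat_u <- cat_f
  cat_f[c("s01", "s02", "s03", "s04", "s05")] <- "discouraging"
  nb <- setNames(rep(list(character(0)), n), rec$snp_id)
  sel <- select_candidates(rec, cat_f, cat_u, nb)
  expect_length(sel$top_p, 25)
  expect_setequal(sel$top_p, rec$snp_id[6:30])   # best 25 of the rest
  expect_length(sel$ld_supported, 0)             # no SNP has 2 LD neighbors
  # list 2: neighbor support count ranks, ties by P then id
  nb2 <- nb
  nb2[["s10"]] <- c("s11", "s12", "s13")
  nb2[["s20"]] <- c("s21", "s22")
  nb2[["s25"]] <- c("s26", "s27")
  pv <- setNames(rec$gc_p, rec$snp_id)
  cat_all <- setNames(rep("encouraging", n), rec$snp_id)
  sel2 <- select_candidates(rec, cat_all, cat_all, nb2,
                            p_unfiltered = pv, p_support = 1)
  expect_equal(sel2$ld_supported[1], "s10")      # 3 supporting neighbors
  expect_equal(sel2$ld_supported[2], "s20")      # tie on 2: smaller P wins
  expect_equal(sel2$ld_supported[3], "s25")
})

test_that("find_aims ties the stages together on a planted study", {
  rf <- simulate_reference_afs(sim_config(n_snps = 3000, seed = 35))
  interior <- which(rf$truth$af_admixed > 0.3 & rf$truth$af_admixed < 0.7)
  idx <- interior[seq(1, length(interior), length.out = 8)]
  plant <- data.frame(snp_index = idx, delta = 0.3)
  st <- simulate_pool_study(sim_config(n_snps = 3000, seed = 35,
                                       pool_noise_sd = 0.02,
                                       planted_aims = plant))
  res <- run_pipeline(study = st)
  planted_ids <- st$map$snp_id[idx]
  rec <- res$aims$records
  expect_true(all(rec$corrected_chi2 <= rec$naive_chi2 + 1e-9))
  expect_gt(mean(planted_ids %in% res$aims$candidates$top_p), 0.7)
  # accounting: every simulated SNP is tested or logged with a reason
  expect_setequal(c(rec$snp_id, res$exclusions$snp_id), st$map$snp_id)
  expect_true(all(nzchar(res$exclusions$reason)))
})
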