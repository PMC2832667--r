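## Synthetic-data generator: drifted reference panels, admixed cohorts,
## per-SNP intensity-cluster models and noisy pool replicates, with full
## ground truth, so every downstream stage can be exercised without
## external array data.

#' Simulation configuration
#'
#' Collects and validates the parameters of the synthetic pooled-genotyping
#' study generator.  The defaults describe a two-way admixed cohort
#' (82%/18% ancestry split), pools genotyped in triplicate, and
#' allele-frequency-scale pool noise of 0.02 -- the regime in which pooled
#' arrays are useful for ancestry work.
#'
#' @param n_snps Number of autosomal SNPs.
#' @param n_individuals Individuals per pool.
#' @param n_pools Number of pools drawn from the admixed population.
#' @param n_replicates Array replicates hybridized per pool.
#' @param admixture_proportions Ancestry proportions for the *modeled*
#'   reference populations; must lie in `[0, 1]` and sum to at most 1.
#'   Any shortfall is assigned to an extra "missing ancestry" population
#'   that the generator simulates but does not expose as a reference
#'   panel.
#' @param drift_fst Per-reference-population drift (Balding-Nichols F),
#'   each in `[0, 1)`; recycled to the number of reference populations.
#' @param missing_drift_fst Drift of the unmodeled missing-ancestry
#'   population, if any.
#' @param ancestral_af_range Interval within `(0, 1)` from which ancestral
#'   allele frequencies are drawn uniformly; the default `[0.05, 0.95]`
#'   keeps the panel-wide mean allele frequency at 0.5, matching the
#'   orientation convention the admixture regression relies on.
#' @param pool_noise_sd Standard deviation, on the allele-frequency scale,
#'   of the angular measurement noise of a single pool replicate.
#' @param radial_noise_sd Relative standard deviation of the replicate's
#'   intensity radius around the expected individual-sample radius.
#' @param intensity_noise Scale of the intensity-cluster covariances.
#' @param allelic_imbalance A-probe intensity multiplier (k-correction
#'   stressor); 1 means balanced probes.
#' @param corrupt_fraction Fraction of SNPs corrupted to exercise the QC
#'   filters (modes: noisy replicates, collapsed heterozygote cluster,
#'   dim hybridization signal).
#' @param corrupt_noise_sd Replicate AF noise for "noisy"-mode corrupt SNPs.
#' @param ref_panel_size Nominal diploid sample size recorded for each
#'   generated reference panel.
#' @param planted_aims Optional data frame with columns `snp_index` and
#'   `delta`: allele-frequency shifts applied to the admixed population at
#'   selected SNPs, i.e. planted ancestry informative markers whose truth
#'   is known.
#' @param seed Integer seed; every generator output is reproducible given
#'   the seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_snps = 10000,
                       n_individuals = 250,
                       n_pools = 2,
                       n_replicates = 3,
                       admixture_proportions = c(0.82, 0.18),
                       drift_fst = 0.15,
                       missing_drift_fst = 0.15,
                       ancestral_af_range = c(0.05, 0.95),
                       pool_noise_sd = 0.02,
                       radial_noise_sd = 0.05,
                       intensity_noise = 0.5,
                       allelic_imbalance = 1,
                       corrupt_fraction = 0,
                       corrupt_noise_sd = 0.15,
                       ref_panel_size = 60,
                       planted_aims = NULL,
                       seed = 1L) {
  stopifnot(n_snps >= 1, n_individuals >= 0, n_pools >= 1,
            n_replicates >= 1)
  if (any(admixture_proportions < 0 | admixture_proportions > 1))
    stop("admixture proportions must lie in [0, 1]")
  if (sum(admixture_proportions) > 1 + 1e-8)
    stop("admixture proportions must sum to at most 1")
  if (any(drift_fst < 0 | drift_fst >= 1) ||
      missing_drift_fst < 0 || missing_drift_fst >= 1)
    stop("drift F must lie in [0, 1)")
  if (length(ancestral_af_range) != 2 ||
      ancestral_af_range[1] <= 0 || ancestral_af_range[2] >= 1 ||
      ancestral_af_range[1] >= ancestral_af_range[2])
    stop("ancestral_af_range must be an increasing interval within (0, 1)")
  if (corrupt_fraction < 0 || corrupt_fraction > 1)
    stop("corrupt_fraction must lie in [0, 1]")
  if (!is.null(planted_aims))
    stopifnot(is.data.frame(planted_aims),
              all(c("snp_index", "delta") %in% names(planted_aims)),
              all(planted_aims$snp_index >= 1),
              all(planted_aims$snp_index <= n_snps))
  structure(list(
    n_snps = as.integer(n_snps),
    n_individuals = as.integer(n_individuals),
    n_pools = as.integer(n_pools),
    n_replicates = as.integer(n_replicates),
    admixture_proportions = admixture_proportions,
    drift_fst = rep_len(drift_fst, length(admixture_proportions)),
    missing_drift_fst = missing_drift_fst,
    ancestral_af_range = ancestral_af_range,
    pool_noise_sd = pool_noise_sd,
    radial_noise_sd = radial_noise_sd,
    intensity_noise = intensity_noise,
    allelic_imbalance = allelic_imbalance,
    corrupt_fraction = corrupt_fraction,
    corrupt_noise_sd = corrupt_noise_sd,
    ref_panel_size = as.integer(ref_panel_size),
    planted_aims = planted_aims,
    seed = as.integer(seed)), class = "sim_config")
}

## Balding-Nichols draw: population AF ~ Beta(p(1-F)/F, (1-p)(1-F)/F)
## around ancestral p; F = 0 returns p exactly.
.drift_afs <- function(p, f) {
  if (f == 0) return(p)
  stats::rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
}

#' Simulate drifted reference-panel allele frequencies
#'
#' Draws ancestral allele frequencies uniformly on the configured range
#' and derives each reference population's frequencies under the
#' Balding-Nichols Beta model with that population's drift F.  When the
#' configured admixture proportions sum to less than 1, an additional
#' "missing ancestry" population is generated from its *own, independent*
#' ancestral draw (so it is uncorrelated with the reference panels but has
#' the same mean allele frequency of ~0.5).
#'
#' @param config A [sim_config()].
#' @param seed Optional seed; defaults to `config$seed`. Use `NA` to leave
#'   the RNG state untouched (for callers that manage seeding).
#' @return A list with `afs` (n_snps x n_populations matrix; reference
#'   columns `ref1`, `ref2`, ... plus `missing` when configured),
#'   `proportions` (full mixing vector summing to 1), `ancestral`, and
#'   `truth` (data frame: `snp_id`, `ancestral`, one `af_*` column per
#'   population, and `af_admixed`).
#' @export
simulate_reference_afs <- function(config, seed = config$seed) {
  if (!is.na(seed)) set.seed(seed)
  n <- config$n_snps
  k <- length(config$admixture_proportions)
  rng <- config$ancestral_af_range
  anc <- stats::runif(n, rng[1], rng[2])
  afs <- vapply(seq_len(k),
                function(j) .drift_afs(anc, config$drift_fst[j]),
                numeric(n))
  colnames(afs) <- paste0("ref", seq_len(k))
  props <- config$admixture_proportions
  shortfall <- 1 - sum(props)
  if (shortfall > 1e-8) {
    anc_missing <- stats::runif(n, rng[1], rng[2])
    afs <- cbind(afs, missing = .drift_afs(anc_missing,
                                           config$missing_drift_fst))
    props <- c(props, shortfall)
  }
  admixed <- as.vector(afs %*% props)
  truth <- data.frame(snp_id = .snp_ids(n), ancestral = anc,
                      stringsAsFactors = FALSE)
  for (j in seq_len(ncol(afs)))
    truth[[paste0("af_", colnames(afs)[j])]] <- afs[, j]
  truth$af_admixed <- admixed
  list(afs = afs, proportions = props, ancestral = anc, truth = truth)
}

.snp_ids <- function(n) sprintf("snp%06d", seq_len(n))

#' Simulate genotypes of an admixed cohort
#'
#' Each of an individual's two allele copies independently selects its
#' source population with the given proportions and is then a Bernoulli
#' draw at that population's allele frequency; equivalently, genotypes are
#' Binomial(2, p_mix) with p_mix the proportion-weighted mixture frequency
#' (which is how the draw is vectorised).
#'
#' @param afs n_snps x n_populations matrix (or vector for one
#'   population) of allele frequencies.
#' @param proportions Mixing proportions over the columns of `afs`; must
#'   sum to 1.
#' @param n_individuals Cohort size (0 gives an empty matrix).
#' @param seed Optional integer seed; `NULL` leaves the RNG state as-is.
#' @return Integer matrix (n_individuals x n_snps) of 0/1/2 counts of
#'   allele A.
#' @export
simulate_admixed_genotypes <- function(afs, proportions, n_individuals,
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.vector(afs)) afs <- matrix(afs, ncol = 1)
  if (any(proportions < 0 | proportions > 1))
    stop("proportions must lie in [0, 1]")
  if (abs(sum(proportions) - 1) > 1e-8)
    stop("proportions must sum to 1 (include the missing-ancestry ",
         "component)")
  n_snps <- nrow(afs)
  if (n_individuals == 0)
    return(matrix(integer(0), nrow = 0, ncol = n_snps))
  p_mix <- as.vector(afs %*% proportions)
  g <- stats::rbinom(n_individuals * n_snps, 2L,
                     rep(p_mix, each = n_individuals))
  matrix(as.integer(g), nrow = n_individuals, ncol = n_snps)
}

## Covariance matrix elongated along `angle` (degrees).
.oriented_cov <- function(angle, s_major, s_minor) {
  a <- angle / DEG
  c2 <- cos(a)^2; s2 <- sin(a)^2; cs <- cos(a) * sin(a)
  list(cxx = s_major^2 * c2 + s_minor^2 * s2,
       cxy = (s_major^2 - s_minor^2) * cs,
       cyy = s_major^2 * s2 + s_minor^2 * c2)
}

#' Simulate per-SNP intensity-cluster models
#'
#' Places the three genotype-class clusters in probe-intensity space with
#' AA toward the A-probe (x) axis, BB toward the B-probe (y) axis and AB
#' between them, each elongated along its own direction from the
#' coordinate origin (so the homozygous-line intersection is
#' well-conditioned).  An allelic-imbalance multiplier scales all A-probe
#' coordinates, pushing the AB centroid off the diagonal -- the situation
#' the normalization factor NF is designed to correct.  SNPs marked
#' `collapsed` get their AB centroid dragged onto the AA cluster with
#' inflated covariances, emulating a failed assay.
#'
#' @param n_snps Number of SNPs.
#' @param intensity Radius of the homozygous centroids (arbitrary
#'   intensity units).
#' @param spread Major-axis standard deviation of each cluster.
#' @param allelic_imbalance Scalar or per-SNP multiplier on A-probe (x)
#'   intensities.
#' @param angle_jitter SD (degrees) of per-SNP jitter on cluster
#'   directions.
#' @param collapsed Logical vector (recycled) marking SNPs whose
#'   heterozygote cluster collapses onto AA.
#' @param seed Optional integer seed.
#' @return Cluster-model data frame accepted by
#'   [derive_cluster_geometry()].
#' @export
simulate_cluster_model <- function(n_snps, intensity = 10, spread = 0.5,
                                   allelic_imbalance = 1,
                                   angle_jitter = 2,
                                   collapsed = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (spread <= 0) stop("cluster spread must be positive")
  collapsed <- rep_len(collapsed, n_snps)
  k <- rep_len(allelic_imbalance, n_snps)
  a_aa <- pmax(1, 6 + stats::rnorm(n_snps, 0, angle_jitter))
  a_bb <- pmin(89, 84 + stats::rnorm(n_snps, 0, angle_jitter))
  a_ab <- 45 + stats::rnorm(n_snps, 0, angle_jitter)
  r_hom <- intensity * (1 + stats::rnorm(n_snps, 0, 0.03))
  r_het <- 0.95 * r_hom

  out <- data.frame(snp_id = .snp_ids(n_snps), stringsAsFactors = FALSE)
  place <- function(angle, radius) {
    list(x = radius * cos(angle / DEG), y = radius * sin(angle / DEG))
  }
  for (cls in c("aa", "ab", "bb")) {
    ang <- switch(cls, aa = a_aa, ab = a_ab, bb = a_bb)
    rad <- if (cls == "ab") r_het else r_hom
    p <- place(ang, rad)
    cv <- .oriented_cov(ang, spread, spread * 0.35)
    out[[paste0(cls, "_x")]] <- p$x * k
    out[[paste0(cls, "_y")]] <- p$y
    ## x-scaling of the covariance keeps it consistent with the scaled
    ## point cloud: C' = S C S with S = diag(k, 1)
    out[[paste0(cls, "_cxx")]] <- cv$cxx * k^2
    out[[paste0(cls, "_cxy")]] <- cv$cxy * k
    out[[paste0(cls, "_cyy")]] <- cv$cyy
  }
  if (any(collapsed)) {
    i <- which(collapsed)
    out$ab_x[i] <- 0.9 * out$aa_x[i] + 0.1 * out$ab_x[i]
    out$ab_y[i] <- 0.9 * out$aa_y[i] + 0.1 * out$ab_y[i]
    for (col in grep("_c[xy][xy]$", names(out), value = TRUE))
      out[[col]][i] <- out[[col]][i] * 6
  }
  out
}

#' Simulate replicate pool-intensity points
#'
#' Generates, for each SNP, `n_replicates` intensity points whose polar
#' transform maps back to the true pooled allele frequency plus angular
#' (allele-frequency-scale) noise, at a radius matching the expected
#' individual-sample signal times a radial noise factor.  With zero noise
#' the round trip through [estimate_pool_af()] is exact.
#'
#' @param true_af Per-SNP true pooled allele frequency, in `[0, 1]`.
#' @param geometry Per-SNP geometry from [derive_cluster_geometry()]
#'   aligned with `true_af`.
#' @param n_replicates Number of replicates (>= 1).
#' @param noise_sd Angular noise SD on the AF scale (scalar or per SNP).
#' @param radial_sd Relative radial noise SD.
#' @param radial_factor Multiplier on the expected radius (scalar or per
#'   SNP); small values emulate dim, failing hybridizations.
#' @param pool_id Pool identifier stored in the output.
#' @param seed Optional integer seed.
#' @return Data frame with columns `snp_id`, `pool_id`, `replicate_id`,
#'   `x`, `y`.
#' @export
simulate_pool_replicates <- function(true_af, geometry, n_replicates,
                                     noise_sd = 0, radial_sd = 0,
                                     radial_factor = 1,
                                     pool_id = "pool1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_replicates < 1) stop("n_replicates must be at least 1")
  if (any(true_af < 0 | true_af > 1)) stop("true_af must lie in [0, 1]")
  n <- length(true_af)
  stopifnot(nrow(geometry) == n)
  noise_sd <- rep_len(noise_sd, n)
  radial_factor <- rep_len(radial_factor, n)
  idx <- rep(seq_len(n), times = n_replicates)
  af_t <- true_af[idx] + stats::rnorm(length(idx), 0, noise_sd[idx])
  d <- .oblique_direction_for_af(af_t, geometry$nf[idx])
  dx <- d$x * geometry$ux[idx] + d$y * geometry$vx[idx]
  dy <- d$x * geometry$uy[idx] + d$y * geometry$vy[idx]
  len <- sqrt(dx^2 + dy^2)
  radius <- .expected_radius(af_t, geometry$r_aa[idx], geometry$r_ab[idx],
                             geometry$r_bb[idx]) *
    radial_factor[idx] * (1 + stats::rnorm(length(idx), 0, radial_sd))
  data.frame(snp_id = geometry$snp_id[idx],
             pool_id = pool_id,
             replicate_id = rep(seq_len(n_replicates), each = n),
             x = geometry$o_x[idx] + radius * dx / len,
             y = geometry$o_y[idx] + radius * dy / len,
             stringsAsFactors = FALSE)
}

## Genomic map: spread SNPs evenly over a 2.8 Gb, 22-chromosome genome.
.make_snp_map <- function(n_snps, n_chrom = 22, genome_size = 2.8e9) {
  chrom <- rep(seq_len(n_chrom), length.out = n_snps)
  chrom <- sort(chrom)
  per_chrom <- tabulate(chrom, n_chrom)
  chrom_len <- genome_size / n_chrom
  pos <- unlist(lapply(seq_len(n_chrom), function(c) {
    m <- per_chrom[c]
    if (m == 0) return(integer(0))
    as.integer(round(seq(1, chrom_len, length.out = m)))
  }))
  data.frame(snp_id = .snp_ids(n_snps), chrom = chrom, pos = pos,
             stringsAsFactors = FALSE)
}

#' Simulate a complete pooled-genotyping study
#'
#' End-to-end generator: reference panels (plus any missing-ancestry
#' component), admixed pool cohorts and their true and individual-genotype
#' allele frequencies, per-SNP cluster models, replicate intensity points
#' (with optional corruption), and a genomic map.  Everything the pipeline
#' consumes, with ground truth attached.
#'
#' Corrupt SNPs are split evenly between three failure modes: `noisy`
#' (replicate AF noise at `corrupt_noise_sd`), `collapsed` (heterozygote
#' cluster collapsed onto AA) and `dim` (hybridization radius at 30% of
#' expectation).
#'
#' @param config A [sim_config()].
#' @return A list of class `pool_study`: `config`, `map`, `panels` (list
#'   of reference-panel data frames), `ref_afs`, `truth`, `clusters`,
#'   `geometry`, `replicates`, `individual_af` (n_snps x n_pools matrix
#'   of cohort allele frequencies), `true_pool_af`, `pool_sizes`, and
#'   `corrupt` (per-SNP flag and mode).
#' @export
simulate_pool_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_snps
  refs <- simulate_reference_afs(config, seed = NA)
  map <- .make_snp_map(n)

  ## corruption assignment
  mode <- rep("clean", n)
  if (config$corrupt_fraction > 0) {
    n_bad <- round(config$corrupt_fraction * n)
    bad <- sample.int(n, n_bad)
    mode[bad] <- sample(c("noisy", "collapsed", "dim"), n_bad,
                        replace = TRUE)
  }

  clusters <- simulate_cluster_model(
    n, spread = config$intensity_noise,
    allelic_imbalance = config$allelic_imbalance,
    collapsed = mode == "collapsed")
  geometry <- derive_cluster_geometry(clusters)

  ## admixed population AF, with any planted AIM shifts
  p_admix <- refs$truth$af_admixed
  if (!is.null(config$planted_aims)) {
    i <- config$planted_aims$snp_index
    p_admix[i] <- pmin(pmax(p_admix[i] + config$planted_aims$delta,
                            0.02), 0.98)
  }

  pool_ids <- paste0("pool", seq_len(config$n_pools))
  noise_sd <- ifelse(mode == "noisy", config$corrupt_noise_sd,
                     config$pool_noise_sd)
  radial_factor <- ifelse(mode == "dim", 0.3, 1)

  individual_af <- matrix(NA_real_, n, config$n_pools,
                          dimnames = list(NULL, pool_ids))
  true_pool_af <- individual_af
  replicates <- vector("list", config$n_pools)
  for (p in seq_len(config$n_pools)) {
    ## pool cohort allele count ~ Binomial(2n, p_admix): identical in law
    ## to summing simulate_admixed_genotypes() over the pool's members
    af_p <- stats::rbinom(n, 2L * config$n_individuals, p_admix) /
      (2 * config$n_individuals)
    individual_af[, p] <- af_p
    true_pool_af[, p] <- af_p
    replicates[[p]] <- simulate_pool_replicates(
      af_p, geometry, config$n_replicates,
      noise_sd = noise_sd, radial_sd = config$radial_noise_sd,
      radial_factor = radial_factor, pool_id = pool_ids[p])
  }
  replicates <- do.call(rbind, replicates)

  ref_cols <- grep("^ref", colnames(refs$afs), value = TRUE)
  alleles <- matrix(sample(c("A", "C", "G", "T"), 2 * n, replace = TRUE),
                    ncol = 2)
  swap <- alleles[, 1] == alleles[, 2]
  alleles[swap, 2] <- ifelse(alleles[swap, 1] == "A", "G", "A")
  panels <- lapply(ref_cols, function(cn) {
    data.frame(snp_id = map$snp_id, chrom = map$chrom, pos = map$pos,
               allele_a = alleles[, 1], allele_b = alleles[, 2],
               af = refs$afs[, cn], call_rate = 1,
               n = config$ref_panel_size, stringsAsFactors = FALSE)
  })
  names(panels) <- ref_cols

  truth <- refs$truth
  truth$af_admixed <- p_admix
  truth <- cbind(truth,
                 setNames(as.data.frame(true_pool_af),
                          paste0("af_", pool_ids)))

  structure(list(
    config = config, map = map, panels = panels,
    ref_afs = refs$afs[, ref_cols, drop = FALSE],
    proportions = refs$proportions,
    truth = truth, clusters = clusters, geometry = geometry,
    replicates = replicates, individual_af = individual_af,
    true_pool_af = true_pool_af,
    pool_sizes = stats::setNames(rep(config$n_individuals,
                                     config$n_pools), pool_ids),
    corrupt = data.frame(snp_id = map$snp_id, corrupt = mode != "clean",
                         mode = mode, stringsAsFactors = FALSE)),
    class = "pool_study")
}

#' @export
print.pool_study <- function(x, ...) {
  cat("Synthetic pooled-genotyping study\n")
  cat("  SNPs:", x$config$n_snps,
      " pools:", x$config$n_pools, "x", x$config$n_individuals,
      "individuals,", x$config$n_replicates, "replicates each\n")
  cat("  reference panels:", paste(names(x$panels), collapse = ", "), "\n")
  if (any(x$corrupt$corrupt))
    cat("  corrupt SNPs:", sum(x$corrupt$corrupt), "\n")
  invisible(x)
}
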