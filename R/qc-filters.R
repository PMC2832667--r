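## SNP-level quality control for pooled genotyping: cluster-separation
## (FLD), intensity-radius (r), minor-allele-frequency and AF-consistency
## (hist) filters, plus the two tuning metrics used to pick cut-offs
## (proportion of false positives; genomic-control inflation factor).

#' Quality-control configuration
#'
#' Thresholds for the four SNP QC filters.  The r-filter threshold and
#' pass fraction (0.8 / 80%) follow the operating point found effective
#' for triplicate pooled hybridizations; the FLD and hist cut-offs are the
#' values obtained from the packaged tuning utilities
#' ([tune_cutoff_by_pfp()], [tune_cutoff_by_lambda()]) on the shipped
#' synthetic study conditions, and the MAF floor of 0.05 matches the
#' allele-frequency error scale of pooled estimates.  All are
#' configurable.
#'
#' @param fld_min Minimum Fisher's-linear-discriminant separation between
#'   adjacent genotype clusters.
#' @param r_ratio_min Minimum r/r' intensity-radius ratio for a replicate
#'   to count as passing.
#' @param r_pass_fraction Fraction of replicates (across all pools) that
#'   must pass the r-ratio threshold.
#' @param maf_min Minimum panel-wide pooled minor allele frequency.
#' @param hist_var_max Maximum variance, across pools, of the difference
#'   between pooled and individual-genotype allele frequency (AF^2
#'   units).
#' @return List of class `qc_config`.
#' @export
qc_config <- function(fld_min = 3.6, r_ratio_min = 0.8,
                      r_pass_fraction = 0.8, maf_min = 0.05,
                      hist_var_max = 1e-3) {
  stopifnot(fld_min >= 0, r_ratio_min >= 0,
            r_pass_fraction > 0, r_pass_fraction <= 1,
            maf_min >= 0, maf_min < 0.5, hist_var_max >= 0)
  structure(list(fld_min = fld_min, r_ratio_min = r_ratio_min,
                 r_pass_fraction = r_pass_fraction, maf_min = maf_min,
                 hist_var_max = hist_var_max), class = "qc_config")
}

#' Fisher's linear discriminant separation between two clusters
#'
#' The maximum over projection directions w of the squared projected mean
#' difference over the summed projected variances,
#' `max_w (w'Δμ)^2 / (w'(C1+C2)w)`, which has the closed form
#' `Δμ' (C1+C2)^{-1} Δμ`.
#'
#' @param mu1,mu2 Cluster means (numeric vectors of equal length).
#' @param cov1,cov2 Cluster covariance matrices (or scalar variances in
#'   one dimension).
#' @return The FLD separation score (dimensionless, >= 0).
#' @examples
#' fld_score(0, 2, 1, 1)  # 4 / 2 = 2
#' @export
fld_score <- function(mu1, mu2, cov1, cov2) {
  d <- as.numeric(mu2) - as.numeric(mu1)
  s <- as.matrix(cov1) + as.matrix(cov2)
  drop(t(d) %*% solve(s, d))
}

## Vectorised FLD for 2-D clusters given flat centroid/covariance columns.
.fld2 <- function(x1, y1, cxx1, cxy1, cyy1, x2, y2, cxx2, cxy2, cyy2) {
  dx <- x2 - x1; dy <- y2 - y1
  sxx <- cxx1 + cxx2; sxy <- cxy1 + cxy2; syy <- cyy1 + cyy2
  det <- sxx * syy - sxy^2
  (dx * (syy * dx - sxy * dy) + dy * (sxx * dy - sxy * dx)) / det
}

#' FLD filter over a cluster-model table
#'
#' Scores each SNP as the *minimum* FLD separation over the adjacent
#' genotype-cluster pairs (AA-AB and AB-BB); a SNP passes when that score
#' reaches `fld_min`.  Poorly resolved or collapsed cluster models score
#' near zero.
#'
#' @param clusters Cluster-model data frame (see
#'   [derive_cluster_geometry()] for the column layout).
#' @param config A [qc_config()].
#' @return Data frame `snp_id`, `fld`, `pass`.
#' @export
fld_filter <- function(clusters, config = qc_config()) {
  f1 <- .fld2(clusters$aa_x, clusters$aa_y, clusters$aa_cxx,
              clusters$aa_cxy, clusters$aa_cyy,
              clusters$ab_x, clusters$ab_y, clusters$ab_cxx,
              clusters$ab_cxy, clusters$ab_cyy)
  f2 <- .fld2(clusters$ab_x, clusters$ab_y, clusters$ab_cxx,
              clusters$ab_cxy, clusters$ab_cyy,
              clusters$bb_x, clusters$bb_y, clusters$bb_cxx,
              clusters$bb_cxy, clusters$bb_cyy)
  fld <- pmin(f1, f2)
  data.frame(snp_id = clusters$snp_id, fld = fld,
             pass = is.finite(fld) & fld >= config$fld_min,
             stringsAsFactors = FALSE)
}

#' Intensity-radius ratio r/r' for one replicate point
#'
#' The distance of the replicate intensity from the transform origin O,
#' normalised by the distance expected for an average individual sample
#' at the same estimated allele frequency (linear interpolation of the
#' genotype-centroid radii).  Ratios well below 1 indicate weak, unreliable
#' hybridization.
#'
#' @param point Length-2 intensity point.
#' @param geometry Single-row geometry record
#'   ([derive_cluster_geometry()]).
#' @param estimated_af The replicate's estimated allele frequency.
#' @return The scalar ratio r/r' (>= 0).
#' @export
r_ratio <- function(point, geometry, estimated_af) {
  r <- sqrt((point[1] - geometry$o_x)^2 + (point[2] - geometry$o_y)^2)
  rp <- .expected_radius(estimated_af, geometry$r_aa, geometry$r_ab,
                         geometry$r_bb)
  if (!is.finite(rp) || rp <= 0) stop("degenerate model: expected radius 0")
  r / rp
}

#' r-filter across all replicates of all pools
#'
#' A SNP passes when at least `ceiling(r_pass_fraction * n_replicates)` of
#' its replicates (cases and controls combined) have r/r' at or above
#' `r_ratio_min` -- e.g. 11 of 13 replicates at the default 0.8/80%
#' operating point.
#'
#' @param replicate_table Data frame with `snp_id` and `r_ratio` (the
#'   `replicates` element of [estimate_pool_af()]).
#' @param config A [qc_config()].
#' @return Data frame `snp_id`, `n_replicates`, `n_pass`, `pass`.
#' @export
r_filter <- function(replicate_table, config = qc_config()) {
  if (nrow(replicate_table) == 0) stop("no replicates")
  key <- factor(replicate_table$snp_id)
  ok <- !is.na(replicate_table$r_ratio) &
    replicate_table$r_ratio >= config$r_ratio_min
  n_tot <- as.vector(table(key))
  n_pass <- as.vector(tapply(ok, key, sum))
  need <- ceiling(config$r_pass_fraction * n_tot)
  data.frame(snp_id = levels(key), n_replicates = n_tot,
             n_pass = n_pass, pass = n_pass >= need,
             stringsAsFactors = FALSE)
}

#' MAF filter on pooled allele-frequency estimates
#'
#' Computes the panel-wide pooled allele frequency (weighted by pool
#' size), takes the minor allele frequency, and passes SNPs with MAF at or
#' above `maf_min`.  SNPs whose estimate falls outside `[0, 1]` in *any*
#' pool (negative estimated MAF -- very rare SNPs or erroneous
#' hybridization) are hard-dropped.
#'
#' @param pool_table Per-SNP-per-pool data frame with `snp_id`, `pool_id`,
#'   `af` (the `pools` element of [estimate_pool_af()]).
#' @param pool_sizes Named vector of individuals per pool.
#' @param config A [qc_config()].
#' @return Data frame `snp_id`, `maf`, `hard_drop`, `pass`.
#' @export
maf_filter <- function(pool_table, pool_sizes, config = qc_config()) {
  w <- pool_sizes[pool_table$pool_id]
  key <- factor(pool_table$snp_id)
  tot <- as.vector(tapply(w * pool_table$af, key, sum)) /
    as.vector(tapply(w, key, sum))
  out_of_range <- pool_table$af < 0 | pool_table$af > 1 |
    !is.finite(pool_table$af)
  hard <- as.vector(tapply(out_of_range, key, any))
  maf <- pmin(tot, 1 - tot)
  data.frame(snp_id = levels(key), maf = maf, hard_drop = hard,
             pass = !hard & is.finite(maf) & maf >= config$maf_min,
             stringsAsFactors = FALSE)
}

#' hist-filter: consistency of pooled versus individual allele frequency
#'
#' For a training panel with both pooled and individual-genotype allele
#' frequencies, scores each SNP by the variance across pools of
#' (pooled AF - individual AF); inconsistent assays show large variance.
#' Once trained on one panel, the resulting verdict list is portable to
#' other panels typed on the same array.
#'
#' @param pooled_af n_snps x n_pools matrix of pooled AF estimates.
#' @param individual_af Matching matrix of individual-genotype AFs.
#' @param config A [qc_config()].
#' @param snp_id Optional SNP identifiers (defaults to rownames or index).
#' @return Data frame `snp_id`, `hist_var`, `pass`.
#' @export
hist_filter <- function(pooled_af, individual_af, config = qc_config(),
                        snp_id = NULL) {
  pooled_af <- as.matrix(pooled_af)
  individual_af <- as.matrix(individual_af)
  if (ncol(pooled_af) < 2)
    stop("hist-filter needs at least 2 pools")
  stopifnot(all(dim(pooled_af) == dim(individual_af)))
  d <- pooled_af - individual_af
  m <- rowMeans(d)
  v <- rowSums((d - m)^2) / (ncol(d) - 1)
  if (is.null(snp_id))
    snp_id <- rownames(pooled_af) %||% .snp_ids(nrow(pooled_af))
  data.frame(snp_id = snp_id, hist_var = v,
             pass = is.finite(v) & v <= config$hist_var_max,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Proportion of false positives among top-ranked pooled tests
#'
#' The fraction of the top `top_fraction` of SNPs, ranked by pooled-test
#' P-value, whose expected P-value (from individual genotyping) exceeds
#' `expected_alpha` -- i.e. top hits that individual data say are null.
#'
#' @param pooled_p,expected_p Aligned P-value vectors.
#' @param top_fraction Fraction of SNPs forming the top set (default
#'   0.05%).
#' @param expected_alpha Significance level defining a truly null SNP.
#' @return PFP in `[0, 1]`.
#' @export
proportion_false_positives <- function(pooled_p, expected_p,
                                       top_fraction = 5e-4,
                                       expected_alpha = 0.05) {
  stopifnot(length(pooled_p) == length(expected_p))
  n_top <- floor(length(pooled_p) * top_fraction)
  if (n_top < 1) stop("top set is empty at this top_fraction")
  top <- order(pooled_p)[seq_len(n_top)]
  mean(expected_p[top] > expected_alpha)
}

#' Genomic-control inflation factor
#'
#' The median of a vector of 1-df chi-square statistics divided by the
#' theoretical chi-square(1) median (0.4549...); values above 1 indicate
#' test-statistic inflation.
#'
#' @param chi2 Vector of 1-df chi-square statistics.
#' @return The inflation factor lambda.
#' @export
gc_lambda <- function(chi2) {
  chi2 <- chi2[is.finite(chi2)]
  if (length(chi2) == 0) stop("no finite chi-square statistics")
  stats::median(chi2) / stats::qchisq(0.5, df = 1)
}

#' Apply the combined SNP QC filters
#'
#' Runs whichever of the four filters the supplied inputs support and
#' combines them: a SNP passes overall only if it passes every applied
#' filter and its cluster geometry is non-degenerate.  The hist-filter is
#' applied when individual-genotype AFs are given, or a pre-trained
#' verdict (`snp_id`, `pass`) from another panel on the same array can be
#' supplied instead.
#'
#' @param pool_af A `pool_af` object from [estimate_pool_af()].
#' @param clusters Cluster-model data frame (enables the FLD filter).
#' @param pool_sizes Named vector of individuals per pool (enables the
#'   MAF filter).
#' @param individual_af Optional n_snps x n_pools matrix of
#'   individual-genotype AFs, rows aligned with the geometry table
#'   (enables hist training).
#' @param hist_verdict Optional pre-trained hist-filter verdict.
#' @param config A [qc_config()].
#' @return Data frame, one row per SNP: scores, per-filter pass flags
#'   (`NA` where a filter was not applied), overall `pass`, and a
#'   semicolon-separated `reasons` string for failures.
#' @export
apply_qc <- function(pool_af, clusters = NULL, pool_sizes = NULL,
                     individual_af = NULL, hist_verdict = NULL,
                     config = qc_config()) {
  stopifnot(inherits(pool_af, "pool_af"))
  geom <- pool_af$geometry
  out <- data.frame(snp_id = geom$snp_id, stringsAsFactors = FALSE)
  out$geometry_ok <- !geom$flagged
  out$fld <- NA_real_; out$pass_fld <- NA
  out$r_pass_count <- NA_integer_; out$pass_r <- NA
  out$maf <- NA_real_; out$pass_maf <- NA
  out$hist_var <- NA_real_; out$pass_hist <- NA

  if (!is.null(clusters)) {
    f <- fld_filter(clusters, config)
    i <- match(out$snp_id, f$snp_id)
    out$fld <- f$fld[i]; out$pass_fld <- f$pass[i]
  }
  r <- r_filter(pool_af$replicates, config)
  i <- match(out$snp_id, r$snp_id)
  out$r_pass_count <- r$n_pass[i]; out$pass_r <- r$pass[i]

  if (!is.null(pool_sizes)) {
    m <- maf_filter(pool_af$pools, pool_sizes, config)
    i <- match(out$snp_id, m$snp_id)
    out$maf <- m$maf[i]; out$pass_maf <- m$pass[i]
  }
  if (!is.null(individual_af)) {
    pooled <- .pool_af_matrix(pool_af$pools)
    h <- hist_filter(pooled[out$snp_id, , drop = FALSE],
                     as.matrix(individual_af), config,
                     snp_id = out$snp_id)
    i <- match(out$snp_id, h$snp_id)
    out$hist_var <- h$hist_var[i]; out$pass_hist <- h$pass[i]
  } else if (!is.null(hist_verdict)) {
    i <- match(out$snp_id, hist_verdict$snp_id)
    out$pass_hist <- hist_verdict$pass[i]
  }

  applied <- cbind(out$pass_fld, out$pass_r, out$pass_maf, out$pass_hist)
  fail_any <- rowSums(!applied, na.rm = TRUE) > 0
  out$pass <- out$geometry_ok & !fail_any
  labels <- c("fld", "r", "maf", "hist")
  out$reasons <- vapply(seq_len(nrow(out)), function(j) {
    rs <- labels[which(applied[j, ] %in% FALSE)]
    if (!out$geometry_ok[j]) rs <- c("geometry", rs)
    paste(rs, collapse = ";")
  }, character(1))
  out
}

## snp x pool matrix from the long pool table, rows named by snp_id.
.pool_af_matrix <- function(pools, value = "af") {
  snp <- factor(pools$snp_id)
  pl <- factor(pools$pool_id)
  m <- matrix(NA_real_, nlevels(snp), nlevels(pl),
              dimnames = list(levels(snp), levels(pl)))
  m[cbind(as.integer(snp), as.integer(pl))] <- pools[[value]]
  m
}

#' Sweep a filter cut-off against the proportion of false positives
#'
#' Tuning utility mirroring the training-panel approach to cut-off
#' selection: for each candidate cut-off, report how many SNPs would be
#' retained and the PFP computed among them.
#'
#' @param score Per-SNP filter score.
#' @param cutoffs Candidate cut-off values.
#' @param pooled_p,expected_p P-value vectors aligned with `score`.
#' @param pass Either `"ge"` (pass when score >= cut-off, as for FLD and
#'   MAF) or `"le"` (pass when score <= cut-off, as for the hist-filter).
#' @param top_fraction Passed to [proportion_false_positives()].
#' @return Data frame `cutoff`, `n_retained`, `pfp`.
#' @export
tune_cutoff_by_pfp <- function(score, cutoffs, pooled_p, expected_p,
                               pass = c("ge", "le"),
                               top_fraction = 5e-4) {
  pass <- match.arg(pass)
  res <- lapply(cutoffs, function(ct) {
    keep <- if (pass == "ge") score >= ct else score <= ct
    keep <- keep & !is.na(keep)
    pfp <- if (floor(sum(keep) * top_fraction) >= 1)
      proportion_false_positives(pooled_p[keep], expected_p[keep],
                                 top_fraction) else NA_real_
    data.frame(cutoff = ct, n_retained = sum(keep), pfp = pfp)
  })
  do.call(rbind, res)
}

#' Sweep a filter cut-off against the genomic-control inflation factor
#'
#' For panels without individual genotypes, cut-offs can be tuned by the
#' inflation factor of a null pool-versus-pool comparison: for each
#' candidate cut-off, report the number of retained SNPs and the GC lambda
#' of the retained chi-square statistics.
#'
#' @param score Per-SNP filter score.
#' @param cutoffs Candidate cut-off values.
#' @param chi2 Null-comparison chi-square statistics aligned with `score`.
#' @param pass `"ge"` or `"le"` as in [tune_cutoff_by_pfp()].
#' @return Data frame `cutoff`, `n_retained`, `lambda`.
#' @export
tune_cutoff_by_lambda <- function(score, cutoffs, chi2,
                                  pass = c("ge", "le")) {
  pass <- match.arg(pass)
  res <- lapply(cutoffs, function(ct) {
    keep <- if (pass == "ge") score >= ct else score <= ct
    keep <- keep & !is.na(keep)
    lam <- if (any(keep)) gc_lambda(chi2[keep]) else NA_real_
    data.frame(cutoff = ct, n_retained = sum(keep), lambda = lam)
  })
  do.call(rbind, res)
}

#' Rank SNPs by pooled-versus-individual test consistency
#'
#' Diagnostic used when choosing filter families: the "worst" SNPs are
#' those with the greatest corrected chi-square difference between pooled
#' and individual data; the "best" are those with the smallest difference
#' among the most significant individual-data tests.
#'
#' @param chi2_pooled,chi2_individual Aligned corrected chi-square
#'   vectors.
#' @param n Number of SNPs per list.
#' @return List with integer index vectors `worst` and `best`.
#' @export
snp_consistency_ranks <- function(chi2_pooled, chi2_individual, n = 200) {
  stopifnot(length(chi2_pooled) == length(chi2_individual))
  d <- abs(chi2_pooled - chi2_individual)
  worst <- order(d, decreasing = TRUE)[seq_len(min(n, length(d)))]
  sig <- order(chi2_individual, decreasing = TRUE)
  sig <- sig[seq_len(min(5 * n, length(sig)))]
  best <- sig[order(d[sig])][seq_len(min(n, length(sig)))]
  list(worst = worst, best = best)
}
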