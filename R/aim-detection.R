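## Ancestry-informative-marker detection: a chi-square test of pooled
## allele frequency against a pseudopopulation (or another panel),
## deflated for pooling error variance, genomic-control corrected,
## LD-categorized, distance-pruned, and distilled into candidate lists.

#' Binomial sampling variance of a case/control allele-frequency contrast
#'
#' `V = p_case(1-p_case)/(2 n_case) + p_control(1-p_control)/(2 n_control)`,
#' where `2n` is the chromosome count of each group.
#'
#' @param p_case,p_control Allele frequencies in `[0, 1]` (clip estimates
#'   before calling).
#' @param n_case,n_control Diploid sample sizes (> 0).
#' @return The sampling variance V (vectorised).
#' @export
sampling_variance <- function(p_case, n_case, p_control, n_control) {
  if (any(n_case <= 0) || any(n_control <= 0))
    stop("sample sizes must be positive")
  p_case * (1 - p_case) / (2 * n_case) +
    p_control * (1 - p_control) / (2 * n_control)
}

#' Pooling error variance of the combined allele-frequency estimate
#'
#' With several pools on one side of the contrast, the total allele
#' frequency is the pool-size-weighted average of the per-pool estimates;
#' its pooling error variance is the corresponding weighted-mean variance
#' `sum_i w_i^2 SE_i^2` with `w_i = n_i / sum(n)`.  A pseudopopulation has
#' pooling variance 0 by definition.
#'
#' @param se Per-pool standard errors of the AF estimate.
#' @param n Per-pool numbers of individuals.
#' @return `var(e_p_tot)` for the weighted-average estimate.
#' @export
pooled_error_variance <- function(se, n) {
  if (length(se) == 0 || anyNA(se)) stop("missing pool standard error")
  stopifnot(length(se) == length(n))
  w <- n / sum(n)
  sum(w^2 * se^2)
}

## Vectorised across SNPs: se and n are n_snps x n_pools matrices.
.pooled_error_variance_mat <- function(se, n) {
  w <- n / rowSums(n)
  rowSums(w^2 * se^2)
}

## Pearson chi-square of the 2x2 allele-count table implied by
## frequencies and diploid sample sizes (1 df); vectorised.
.allele_count_chi2 <- function(p1, n1, p2, n2) {
  a <- 2 * n1 * p1; b <- 2 * n1 * (1 - p1)
  c_ <- 2 * n2 * p2; d <- 2 * n2 * (1 - p2)
  tot <- a + b + c_ + d
  num <- tot * (a * d - b * c_)^2
  den <- (a + b) * (c_ + d) * (a + c_) * (b + d)
  out <- num / den
  out[p1 == p2] <- 0
  out
}

#' Pooling-deflated chi-square statistic
#'
#' Computes the standard (naive) 1-df chi-square statistic from estimated
#' allele counts and deflates it for the error variance introduced by
#' pooling: `corrected = naive * V / (V + var_e_case + var_e_control)`.
#' The corrected statistic never exceeds the naive one; with no pooling
#' error it equals it.  SNPs whose estimated allele frequency falls
#' outside `[0, 1]` in either group (negative estimated minor allele
#' frequency) cannot be tested and are flagged for exclusion.
#'
#' @param p_case,p_control Estimated allele frequencies (unclipped).
#' @param n_case,n_control Diploid sample sizes.
#' @param var_e_case,var_e_control Pooling error variances (see
#'   [pooled_error_variance()]); 0 for individually genotyped groups and
#'   pseudopopulations.
#' @return Data frame with `naive`, `corrected`, `V` (sampling variance)
#'   and logical `excluded` (negative-MAF SNPs; statistics `NA`).
#' @export
corrected_chi2 <- function(p_case, n_case, p_control, n_control,
                           var_e_case = 0, var_e_control = 0) {
  bad <- !is.finite(p_case) | !is.finite(p_control) |
    p_case < 0 | p_case > 1 | p_control < 0 | p_control > 1
  p1 <- ifelse(bad, NA_real_, p_case)
  p2 <- ifelse(bad, NA_real_, p_control)
  naive <- .allele_count_chi2(p1, n_case, p2, n_control)
  v <- sampling_variance(ifelse(bad, 0.5, p1), n_case,
                         ifelse(bad, 0.5, p2), n_control)
  v[bad] <- NA_real_
  ## ratio computed first so var_e = 0 deflates by exactly 1
  corrected <- naive * (v / (v + var_e_case + var_e_control))
  data.frame(naive = naive, corrected = corrected, V = v,
             excluded = bad)
}

#' Genomic-control corrected P-values
#'
#' Divides each 1-df chi-square statistic by the genomic-control inflation
#' factor (computed from the same vector unless supplied) and converts to
#' an upper-tail chi-square(1) P-value.  Lambda is floored at 1 so the
#' correction is never anti-conservative.
#'
#' @param chi2 Vector of corrected chi-square statistics.
#' @param lambda Optional externally computed inflation factor.
#' @return List with `p` (P-value vector) and `lambda` (the floored
#'   factor actually applied).
#' @export
gc_correct <- function(chi2, lambda = NULL) {
  if (is.null(lambda)) lambda <- gc_lambda(chi2)
  lam <- max(lambda, 1)
  list(p = stats::pchisq(chi2 / lam, df = 1, lower.tail = FALSE),
       lambda = lam)
}

#' Deflation-corrected allele-frequency difference
#'
#' Converts the deflated chi-square statistic back to the
#' allele-frequency scale: holding the pseudopopulation frequency fixed,
#' the magnitude of the corrected difference is `sqrt(corrected_chi2 * V)`
#' and its sign is that of the raw pooled-minus-reference difference.
#' The corrected difference never exceeds the raw difference in
#' magnitude (up to the chi-square linearization).
#'
#' @param corrected_chi2 Deflated chi-square statistics (>= 0).
#' @param V Sampling variances from [corrected_chi2()].
#' @param raw_diff Raw pooled-minus-reference AF differences (sign
#'   source).
#' @return Signed corrected allele-frequency differences.
#' @export
corrected_af_difference <- function(corrected_chi2, V, raw_diff) {
  sign(raw_diff) * sqrt(pmax(corrected_chi2, 0) * V)
}

#' SNPs in linkage disequilibrium with each SNP
#'
#' For every SNP, finds the other SNPs on the same chromosome within
#' `window` base pairs (boundary inclusive) whose genotype-dosage squared
#' Pearson correlation with it exceeds `r2_min` in the designated
#' reference genotype panel.
#'
#' @param genotypes Individuals x SNPs matrix of 0/1/2 dosages; columns
#'   aligned with rows of `map`.
#' @param map Data frame `snp_id`, `chrom`, `pos` (1-based).
#' @param window Physical window in bp (default 20 Mb).
#' @param r2_min r-squared threshold (exclusive).
#' @return Named list (by `snp_id`) of character vectors of neighbor
#'   SNP ids; monomorphic SNPs get empty neighbor sets.
#' @export
ld_neighbors <- function(genotypes, map, window = 20e6, r2_min = 0.5) {
  stopifnot(ncol(genotypes) == nrow(map))
  out <- stats::setNames(vector("list", nrow(map)), map$snp_id)
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    g <- genotypes[, idx, drop = FALSE]
    v <- apply(g, 2, stats::var)
    cc <- suppressWarnings(stats::cor(g))
    cc[!is.finite(cc)] <- 0
    r2 <- cc^2
    pos <- map$pos[idx]
    for (j in seq_along(idx)) {
      near <- abs(pos - pos[j]) <= window
      near[j] <- FALSE
      hit <- near & r2[j, ] > r2_min & v > 0
      out[[idx[j]]] <- map$snp_id[idx[hit]]
    }
  }
  out
}

#' Categorize a SNP by the evidence at its LD neighbors
#'
#' A SNP is "encouraging" when at least one SNP in LD with it has a
#' GC-corrected P-value below `p_strong` *and* at least half of its LD
#' neighbors have P-values below `p_weak`; "discouraging" when no
#' neighbor reaches `p_weak`; otherwise (including SNPs with no LD
#' neighbors) "inconclusive".
#'
#' @param p_values Named vector of GC-corrected P-values (names are
#'   SNP ids, covering at least the neighbors).
#' @param neighbors Named list of neighbor SNP-id vectors
#'   ([ld_neighbors()]).
#' @param snp_ids SNPs to categorize (defaults to `names(neighbors)`).
#' @param p_strong,p_weak Category thresholds (defaults 0.05 and 0.1).
#' @return Named character vector with levels `encouraging`,
#'   `inconclusive`, `discouraging`.
#' @export
categorize_aims <- function(p_values, neighbors,
                            snp_ids = names(neighbors),
                            p_strong = 0.05, p_weak = 0.1) {
  vapply(snp_ids, function(s) {
    nb <- neighbors[[s]]
    np <- p_values[nb]
    np <- np[is.finite(np)]
    if (length(np) == 0) return("inconclusive")
    if (!any(np < p_weak)) return("discouraging")
    if (any(np < p_strong) && mean(np < p_weak) >= 0.5)
      return("encouraging")
    "inconclusive"
  }, character(1))
}

#' Prune candidate AIMs to an independent panel by physical distance
#'
#' Greedy pruning: repeatedly keep the remaining SNP with the smallest
#' GC-corrected P-value and remove every other SNP on the same chromosome
#' closer than `min_separation` base pairs.  Discouraging SNPs do not
#' enter.
#'
#' @param records Data frame with `snp_id`, `chrom`, `pos`, `gc_p` and
#'   `category`.
#' @param min_separation Minimum separation in bp (default 4 Mb;
#'   distances strictly below it are pruned).
#' @return The input with a logical `kept` column (`FALSE` for pruned and
#'   discouraging SNPs).
#' @export
prune_by_distance <- function(records, min_separation = 4e6) {
  kept <- rep(FALSE, nrow(records))
  elig <- which(records$category != "discouraging" &
                  is.finite(records$gc_p))
  elig <- elig[order(records$gc_p[elig], records$snp_id[elig])]
  alive <- rep(TRUE, nrow(records))
  for (i in elig) {
    if (!alive[i]) next
    kept[i] <- TRUE
    clash <- records$chrom == records$chrom[i] &
      abs(records$pos - records$pos[i]) < min_separation
    alive[clash] <- FALSE
  }
  records$kept <- kept
  records
}

#' Select candidate AIM lists
#'
#' Two complementary lists.  List 1 ("top-P"): the `n_top` SNPs with the
#' smallest GC-corrected P-values, excluding any SNP categorized as
#' discouraging under *either* the QC-filtered or the unfiltered LD set.
#' List 2 ("LD-supported"): SNPs with P below `p_threshold`, at least
#' `min_ld_neighbors` neighbors in the unfiltered LD set, and an
#' encouraging categorization under *both* LD sets, ranked by the number
#' of unfiltered LD neighbors with P below `p_support`; ties break by
#' smaller P, then lexicographic SNP id.
#'
#' @param records Data frame with `snp_id` and `gc_p`; only rows with
#'   `kept = TRUE` (if present) are considered.
#' @param cat_filtered,cat_unfiltered Named category vectors from
#'   [categorize_aims()] under the two LD sets.
#' @param neighbors_unfiltered Unfiltered-LD neighbor list.
#' @param p_unfiltered Named P-value vector covering the unfiltered SNP
#'   set (used to count supporting neighbors); defaults to the `gc_p` of
#'   `records`.
#' @param n_top Size of each list (default 25).
#' @param p_threshold List-2 P-value ceiling (default 1e-3).
#' @param min_ld_neighbors Minimum unfiltered LD neighbors for list 2.
#' @param p_support Neighbor P-value level counted as support (default
#'   0.05).
#' @return List with character vectors `top_p` and `ld_supported`
#'   (shorter than `n_top` when fewer SNPs qualify).
#' @export
select_candidates <- function(records, cat_filtered, cat_unfiltered,
                              neighbors_unfiltered,
                              p_unfiltered = NULL,
                              n_top = 25, p_threshold = 1e-3,
                              min_ld_neighbors = 2, p_support = 0.05) {
  if (!is.null(records$kept)) records <- records[records$kept, ]
  if (is.null(p_unfiltered))
    p_unfiltered <- stats::setNames(records$gc_p, records$snp_id)
  catf <- cat_filtered[records$snp_id]
  catu <- cat_unfiltered[records$snp_id]
  catf[is.na(catf)] <- "inconclusive"
  catu[is.na(catu)] <- "inconclusive"

  ok1 <- catf != "discouraging" & catu != "discouraging"
  r1 <- records[ok1, , drop = FALSE]
  r1 <- r1[order(r1$gc_p, r1$snp_id), , drop = FALSE]
  top_p <- utils::head(r1$snp_id, n_top)

  n_nb <- vapply(records$snp_id, function(s)
    length(neighbors_unfiltered[[s]]), integer(1))
  n_support <- vapply(records$snp_id, function(s) {
    np <- p_unfiltered[neighbors_unfiltered[[s]]]
    sum(np < p_support, na.rm = TRUE)
  }, integer(1))
  ok2 <- records$gc_p < p_threshold & n_nb >= min_ld_neighbors &
    catf == "encouraging" & catu == "encouraging"
  r2 <- records[ok2, , drop = FALSE]
  o <- order(-n_support[ok2], r2$gc_p, r2$snp_id)
  ld_supported <- utils::head(r2$snp_id[o], n_top)

  list(top_p = top_p, ld_supported = ld_supported)
}

#' Scan for ancestry informative markers against a reference
#'
#' Orchestrates the AIM stage: combines multiple pools into a weighted
#' "case" allele frequency with its pooling error variance, tests it per
#' SNP against the "control" frequencies (typically a pseudopopulation,
#' whose pooling variance is 0) with the deflated chi-square statistic,
#' applies genomic control, converts statistics back to corrected
#' allele-frequency differences, optionally categorizes SNPs by LD
#' support, prunes to an independent panel by distance, and selects
#' candidate lists.
#'
#' @param pool_af A `pool_af` object, or its `pools` data frame.
#' @param pool_sizes Named vector of individuals per pool.
#' @param control_af Named vector (by SNP id) of control allele
#'   frequencies, or a `pseudopopulation` (then `control_snp_ids` gives
#'   its SNP ids).
#' @param n_control Effective diploid size of the control (taken from a
#'   `pseudopopulation` automatically).
#' @param var_e_control Pooling error variance of the control (0 for
#'   pseudopopulations and individually genotyped panels).
#' @param map Data frame `snp_id`, `chrom`, `pos`.
#' @param control_snp_ids SNP ids aligned with a `pseudopopulation`
#'   control.
#' @param ld Optional list with elements `filtered` and `unfiltered`
#'   (neighbor lists from [ld_neighbors()]); when absent, every SNP is
#'   categorized inconclusive and list 2 is empty.
#' @param snp_subset Optional SNP ids (e.g. QC-passing) to restrict the
#'   scan to.
#' @param prune Apply distance pruning (disable to reuse already
#'   genotyped SNPs at the cost of an LD-independent panel).
#' @param min_separation,n_top,p_threshold Passed to the pruning and
#'   selection steps.
#' @return List of class `aim_scan`: `records` (per-SNP table: naive and
#'   corrected chi-square, GC-corrected P, category, corrected AF
#'   difference, kept flag, candidate-list membership), `lambda`,
#'   `candidates`, and `n_excluded` (negative-MAF drops).
#' @export
find_aims <- function(pool_af, pool_sizes, control_af, n_control = NULL,
                      var_e_control = 0, map, control_snp_ids = NULL,
                      ld = NULL, snp_subset = NULL, prune = TRUE,
                      min_separation = 4e6, n_top = 25,
                      p_threshold = 1e-3) {
  pools <- if (inherits(pool_af, "pool_af")) pool_af$pools else pool_af
  if (inherits(control_af, "pseudopopulation")) {
    if (is.null(n_control)) n_control <- control_af$n_effective
    if (is.null(control_snp_ids))
      stop("control_snp_ids required with a pseudopopulation control")
    control_af <- stats::setNames(control_af$af, control_snp_ids)
  }
  if (is.null(n_control)) stop("n_control is required")

  af_m <- .pool_af_matrix(pools, "af")
  se_m <- .pool_af_matrix(pools, "se")
  snps <- rownames(af_m)
  if (!is.null(snp_subset)) snps <- intersect(snps, snp_subset)
  snps <- intersect(snps, names(control_af))
  snps <- intersect(snps, map$snp_id)
  af_m <- af_m[snps, , drop = FALSE]
  se_m <- se_m[snps, , drop = FALSE]
  n_m <- matrix(pool_sizes[colnames(af_m)], nrow(af_m), ncol(af_m),
                byrow = TRUE)

  w <- n_m / rowSums(n_m)
  p_case <- rowSums(w * af_m)
  var_e_case <- .pooled_error_variance_mat(se_m, n_m)
  n_case <- sum(pool_sizes[colnames(af_m)])
  p_ctrl <- control_af[snps]

  ct <- corrected_chi2(p_case, n_case, p_ctrl, n_control,
                       var_e_case, var_e_control)
  gc <- gc_correct(ct$corrected)
  d_af <- corrected_af_difference(ct$corrected, ct$V, p_case - p_ctrl)

  mi <- match(snps, map$snp_id)
  records <- data.frame(snp_id = snps, chrom = map$chrom[mi],
                        pos = map$pos[mi],
                        p_case = p_case, p_control = as.numeric(p_ctrl),
                        naive_chi2 = ct$naive,
                        corrected_chi2 = ct$corrected,
                        gc_p = gc$p, corrected_af_diff = d_af,
                        excluded = ct$excluded,
                        stringsAsFactors = FALSE)
  n_excluded <- sum(records$excluded)
  records <- records[!records$excluded, , drop = FALSE]

  pv <- stats::setNames(records$gc_p, records$snp_id)
  if (!is.null(ld)) {
    records$category <- unname(
      categorize_aims(pv, ld$filtered, snp_ids = records$snp_id))
    cat_unf <- categorize_aims(pv, ld$unfiltered,
                               snp_ids = records$snp_id)
  } else {
    records$category <- "inconclusive"
    cat_unf <- stats::setNames(records$category, records$snp_id)
  }
  cat_f <- stats::setNames(records$category, records$snp_id)

  if (prune) {
    records <- prune_by_distance(records, min_separation)
  } else {
    records$kept <- records$category != "discouraging"
  }

  nb_unf <- if (!is.null(ld)) ld$unfiltered else
    stats::setNames(rep(list(character(0)), nrow(records)),
                    records$snp_id)
  cand <- select_candidates(records, cat_f, cat_unf, nb_unf,
                            p_unfiltered = pv, n_top = n_top,
                            p_threshold = p_threshold)
  records$selection <- ifelse(records$snp_id %in% cand$top_p, "top-P",
                       ifelse(records$snp_id %in% cand$ld_supported,
                              "LD-supported", "none"))
  structure(list(records = records, lambda = gc$lambda,
                 candidates = cand, n_excluded = n_excluded),
            class = "aim_scan")
}

#' @export
print.aim_scan <- function(x, ...) {
  cat("AIM scan: ", nrow(x$records), " SNPs tested (",
      x$n_excluded, " excluded for negative MAF)\n", sep = "")
  cat("  GC lambda: ", round(x$lambda, 3), "\n", sep = "")
  cat("  kept after pruning: ", sum(x$records$kept), "\n", sep = "")
  cat("  candidates: ", length(x$candidates$top_p), " top-P, ",
      length(x$candidates$ld_supported), " LD-supported\n", sep = "")
  invisible(x)
}
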