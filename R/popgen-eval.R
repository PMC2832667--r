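## Panel and population evaluation: F_ST between allele-frequency
## vectors, PCA with iterative outlier removal for AIM-panel assessment,
## axis correlation, and the null maximum allele-frequency-difference
## simulation.

#' Multi-locus F_ST between two populations
#'
#' Default is the Hudson-style ratio-of-averages estimator: per locus the
#' numerator is the squared frequency difference minus the within-
#' population finite-sample terms, the denominator the between-population
#' heterozygosity, both averaged across loci before taking the ratio.
#' With `n_a`/`n_b` omitted (infinite), the finite-sample correction
#' vanishes and true population frequencies can be compared directly.  A
#' naive Wright (1 - HS/HT) option is also provided.  Tiny negative
#' estimates are clamped to 0.
#'
#' @param af_a,af_b Aligned allele-frequency vectors.
#' @param n_a,n_b Diploid sample sizes behind each vector (`Inf` for
#'   population frequencies).
#' @param method `"hudson"` (default) or `"wright"`.
#' @return F_ST in `[0, 1]`.
#' @export
fst <- function(af_a, af_b, n_a = Inf, n_b = Inf,
                method = c("hudson", "wright")) {
  method <- match.arg(method)
  stopifnot(length(af_a) == length(af_b))
  keep <- is.finite(af_a) & is.finite(af_b)
  p1 <- af_a[keep]; p2 <- af_b[keep]
  if (length(p1) == 0) stop("no loci to compare")
  if (method == "hudson") {
    c1 <- if (is.finite(n_a)) p1 * (1 - p1) / (2 * n_a - 1) else 0
    c2 <- if (is.finite(n_b)) p2 * (1 - p2) / (2 * n_b - 1) else 0
    num <- (p1 - p2)^2 - c1 - c2
    den <- p1 * (1 - p2) + p2 * (1 - p1)
    est <- sum(num) / sum(den)
  } else {
    pbar <- (p1 + p2) / 2
    ht <- 2 * pbar * (1 - pbar)
    hs <- p1 * (1 - p1) + p2 * (1 - p2)
    est <- (sum(ht) - sum(hs)) / sum(ht)
  }
  min(max(est, 0), 1)
}

#' PCA of genotypes with iterative outlier removal
#'
#' Normalizes each SNP by its estimated allele frequency (mean-center by
#' `2*p`, scale by `sqrt(p*(1-p))`), decomposes the individuals into
#' principal axes, and iteratively removes individuals lying more than
#' `sd_threshold` standard deviations from the mean along any of the top
#' `k` axes, re-fitting until no outliers remain or `max_iter` rounds
#' have run.  Monomorphic SNPs (in the current individual set) are
#' dropped each round.
#'
#' @param genotypes Individuals x SNPs matrix of 0/1/2 dosages.
#' @param k Number of leading axes to examine (reduced with a warning if
#'   fewer individuals are available).
#' @param sd_threshold Outlier threshold in SDs along an axis.
#' @param max_iter Maximum removal iterations.
#' @return List of class `pca_result`: `scores` (individuals x k, for the
#'   retained individuals), `eigenvalues` (non-increasing), `removed`
#'   (list of integer vectors of original row indices removed per
#'   iteration), `individuals` (retained original row indices).
#' @export
pca_with_outlier_removal <- function(genotypes, k = 10, sd_threshold = 6,
                                     max_iter = 5) {
  g0 <- as.matrix(genotypes)
  keep_ind <- seq_len(nrow(g0))
  removed <- list()
  fit <- NULL
  for (iter in seq_len(max_iter + 1)) {
    g <- g0[keep_ind, , drop = FALSE]
    p <- colMeans(g) / 2
    poly <- p > 0 & p < 1
    x <- sweep(g[, poly, drop = FALSE], 2, 2 * p[poly])
    x <- sweep(x, 2, sqrt(p[poly] * (1 - p[poly])), "/")
    k_eff <- min(k, nrow(x) - 1)
    if (k_eff < k && is.null(fit))
      warning("only ", k_eff, " axes available; k reduced")
    sv <- svd(x, nu = k_eff, nv = 0)
    scores <- sv$u * rep(sv$d[seq_len(k_eff)], each = nrow(x))
    fit <- list(scores = scores,
                eigenvalues = sv$d^2 / (nrow(x) - 1))
    if (iter > max_iter) break
    z <- scale(scores)
    out <- which(rowSums(abs(z) > sd_threshold, na.rm = TRUE) > 0)
    if (length(out) == 0) break
    removed <- c(removed, list(keep_ind[out]))
    keep_ind <- keep_ind[-out]
  }
  structure(list(scores = fit$scores, eigenvalues = fit$eigenvalues,
                 removed = removed, individuals = keep_ind),
            class = "pca_result")
}

#' Correlation between two inferred axes of variation
#'
#' Absolute Pearson correlation between individual coordinates on two
#' axes (the sign of an eigenvector is arbitrary); used to compare the
#' axis recovered from a small AIM panel with the "true" axis from
#' genome-wide data.
#'
#' @param axis_a,axis_b Coordinate vectors over the same individuals.
#' @return `|r|` in `[0, 1]`.
#' @export
axis_correlation <- function(axis_a, axis_b) {
  if (length(axis_a) != length(axis_b))
    stop("axes must cover the same individuals")
  abs(stats::cor(axis_a, axis_b))
}

#' Null maximum allele-frequency deviation under pure sampling
#'
#' Simulates an admixed cohort's allele counts at each SNP as
#' `Binomial(2n, p_mix)` with `p_mix` the proportion-weighted mixture of
#' the reference frequencies, and returns the maximum absolute deviation
#' of the sample allele frequency from the mixture expectation across
#' SNPs.  This is the yardstick separating real ancestry informative
#' markers from sampling noise: at genome scale the null maximum stays
#' below ~0.08 for cohorts of several hundred individuals.
#'
#' @param n_snps Number of SNPs.
#' @param n_individuals Cohort size.
#' @param proportions Mixing proportions (sum to 1).
#' @param ref_afs Optional n_snps x n_populations reference-frequency
#'   matrix; drawn uniformly on `af_range` per population when absent.
#' @param af_range Range for generated reference frequencies.
#' @param seed Optional integer seed.
#' @return The maximum absolute AF deviation (scalar).
#' @export
null_max_afdiff_sim <- function(n_snps, n_individuals, proportions,
                                ref_afs = NULL, af_range = c(0.05, 0.95),
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (abs(sum(proportions) - 1) > 1e-8)
    stop("proportions must sum to 1")
  if (is.null(ref_afs)) {
    ref_afs <- matrix(stats::runif(n_snps * length(proportions),
                                   af_range[1], af_range[2]),
                      nrow = n_snps)
  }
  p_mix <- as.vector(as.matrix(ref_afs) %*% proportions)
  n_chrom <- 2 * n_individuals
  counts <- stats::rbinom(n_snps, n_chrom, p_mix)
  max(abs(counts / n_chrom - p_mix))
}
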