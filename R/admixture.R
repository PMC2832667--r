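## Admixture-proportion estimation: least-squares regression of pooled
## allele frequencies on reference-panel frequencies, and the
## admixture-weighted pseudopopulation built from the fit.

#' Select SNPs for the admixture regression
#'
#' SNPs enter the regression when they pass the combined QC filters and
#' have a genotyping call rate above `min_call_rate` in every reference
#' population used.
#'
#' @param qc_verdicts QC verdict data frame from [apply_qc()] (needs
#'   `snp_id`, `pass`).
#' @param reference_panels List of reference-panel data frames (each with
#'   `snp_id`, `call_rate`).
#' @param min_call_rate Call-rate threshold (exclusive).
#' @return Character vector of SNP ids.
#' @export
select_regression_snps <- function(qc_verdicts, reference_panels,
                                   min_call_rate = 0.8) {
  keep <- qc_verdicts$snp_id[qc_verdicts$pass]
  for (panel in reference_panels) {
    ok <- panel$snp_id[panel$call_rate > min_call_rate]
    keep <- intersect(keep, ok)
  }
  if (length(keep) == 0)
    stop("no SNPs satisfy the QC and reference call-rate requirements")
  keep
}

#' Estimate admixture proportions by regression on reference panels
#'
#' Fits, across SNPs, ordinary least squares of the pooled allele
#' frequency on the reference-panel allele frequencies (allele A
#' orientation per the array annotation, identical in all panels).  Each
#' coefficient estimates the proportion of ancestry contributed by the
#' corresponding reference population; the intercept combines error and
#' unexplained ancestry.  No constraint forces the coefficients to be
#' non-negative or to sum to 1 -- a shortfall in the summed proportion is
#' itself informative, indicating ancestry the panels do not model.
#'
#' When mean allele frequencies are ~0.5 in every panel (which the
#' generator's symmetric ancestral-frequency range guarantees and
#' [check_allele_orientation()] verifies for external panels), the
#' unexplained ancestry is approximately twice the intercept; both are
#' reported as diagnostics.
#'
#' @param pooled_af Per-SNP pooled allele-frequency vector.
#' @param reference_afs n_snps x n_references matrix (or data frame) of
#'   reference allele frequencies, columns named by population.
#' @param condition_threshold Condition number of the design above which
#'   a collinearity warning is recorded (the fit is still returned).
#' @return An object of class `admixture_fit`: `beta` (named
#'   coefficients), `se`, `intercept`, `intercept_se`, `n_snp`,
#'   `sum_beta`, `unexplained` (1 - sum_beta), `two_c` (twice the
#'   intercept), `collinearity_warning`, and the underlying `lm` fit.
#' @export
fit_admixture <- function(pooled_af, reference_afs,
                          condition_threshold = 1e4) {
  x <- as.matrix(reference_afs)
  if (is.null(colnames(x))) colnames(x) <- paste0("ref", seq_len(ncol(x)))
  keep <- is.finite(pooled_af) & rowSums(!is.finite(x)) == 0
  y <- pooled_af[keep]
  x <- x[keep, , drop = FALSE]
  if (length(y) < ncol(x) + 1)
    stop("need more SNPs than reference populations to fit")
  kappa_x <- kappa(cbind(1, x), exact = FALSE)
  collinear <- kappa_x > condition_threshold
  if (collinear)
    warning("reference panels are nearly collinear (condition number ",
            format(kappa_x, digits = 3), "); interpret coefficients ",
            "with care")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)$coefficients
  beta <- stats::setNames(sm[-1, 1], colnames(x))
  se <- stats::setNames(sm[-1, 2], colnames(x))
  structure(list(beta = beta, se = se,
                 intercept = sm[1, 1], intercept_se = sm[1, 2],
                 n_snp = length(y), sum_beta = sum(beta),
                 unexplained = 1 - sum(beta), two_c = 2 * sm[1, 1],
                 collinearity_warning = collinear,
                 lm_fit = fit), class = "admixture_fit")
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat("Admixture-proportion fit (", x$n_snp, " SNPs)\n", sep = "")
  tab <- data.frame(beta = round(x$beta, 4), se = signif(x$se, 3))
  print(tab)
  cat("intercept: ", signif(x$intercept, 4),
      " (se ", signif(x$intercept_se, 3), ")\n", sep = "")
  cat("summed proportion: ", round(x$sum_beta, 4),
      "; unexplained ancestry: ", round(x$unexplained, 4),
      "; 2c diagnostic: ", round(x$two_c, 4), "\n", sep = "")
  if (x$collinearity_warning)
    cat("note: reference panels nearly collinear\n")
  invisible(x)
}

#' Construct the admixture-weighted pseudopopulation
#'
#' The pseudopopulation's allele frequency at each SNP is the fitted
#' combination `sum_j beta_j * P_ji + c` of the reference-panel
#' frequencies.  Its effective sample size follows the convention for
#' HapMap-style panels: 120 individuals when two reference populations
#' are used, 210 when three are; other panel counts require an explicit
#' `n_effective`.  Pooling-specific variance of the pseudopopulation is 0
#' by construction.
#'
#' @param fit An [fit_admixture()] result.
#' @param reference_afs The same reference-frequency matrix used for the
#'   fit (full SNP set allowed).
#' @param n_effective Optional override of the effective diploid sample
#'   size.
#' @return List of class `pseudopopulation`: `af` (clipped to `[0, 1]`),
#'   `n_clipped`, `n_effective`, `pooling_variance` (always 0).
#' @export
build_pseudopopulation <- function(fit, reference_afs,
                                   n_effective = NULL) {
  stopifnot(inherits(fit, "admixture_fit"))
  x <- as.matrix(reference_afs)
  if (ncol(x) != length(fit$beta))
    stop("reference_afs must have one column per fitted coefficient")
  af <- as.vector(x %*% fit$beta) + fit$intercept
  n_clip <- sum(af < 0 | af > 1, na.rm = TRUE)
  af <- pmin(pmax(af, 0), 1)
  if (is.null(n_effective)) {
    n_effective <- switch(as.character(length(fit$beta)),
                          "2" = 120L, "3" = 210L,
                          stop("no default effective size for ",
                               length(fit$beta), " reference panels; ",
                               "supply n_effective"))
  }
  structure(list(af = af, n_clipped = n_clip,
                 n_effective = as.integer(n_effective),
                 pooling_variance = 0), class = "pseudopopulation")
}

#' Combine two reference panels into one
#'
#' Sample-size-weighted merge of two panels on their shared SNPs (e.g.
#' combining two East Asian panels into a single reference): allele
#' frequency and call rate are weighted averages, sample size is the sum.
#' SNPs with mismatched allele labels are excluded with a message.
#'
#' @param panel_a,panel_b Reference-panel data frames (`snp_id`, `chrom`,
#'   `pos`, `allele_a`, `allele_b`, `af`, `call_rate`, `n`).
#' @return A merged reference-panel data frame.
#' @export
combine_reference_panels <- function(panel_a, panel_b) {
  common <- intersect(panel_a$snp_id, panel_b$snp_id)
  if (length(common) == 0) stop("panels share no SNPs")
  a <- panel_a[match(common, panel_a$snp_id), , drop = FALSE]
  b <- panel_b[match(common, panel_b$snp_id), , drop = FALSE]
  mism <- a$allele_a != b$allele_a | a$allele_b != b$allele_b
  if (any(mism)) {
    message(sum(mism), " SNP(s) excluded from panel merge due to allele ",
            "mismatch: ", paste(utils::head(common[mism], 5),
                                collapse = ", "),
            if (sum(mism) > 5) ", ..." else "")
    a <- a[!mism, , drop = FALSE]
    b <- b[!mism, , drop = FALSE]
  }
  if (nrow(a) == 0)
    stop("panels share no SNPs after allele-mismatch exclusion")
  w <- a$n + b$n
  data.frame(snp_id = a$snp_id, chrom = a$chrom, pos = a$pos,
             allele_a = a$allele_a, allele_b = a$allele_b,
             af = (a$n * a$af + b$n * b$af) / w,
             call_rate = (a$n * a$call_rate + b$n * b$call_rate) / w,
             n = w, stringsAsFactors = FALSE)
}

#' Check allele-orientation consistency of panels
#'
#' The regression interpretation of coefficients as admixture proportions
#' relies on allele A being assigned independently of the minor allele, so
#' that the expected allele frequency is ~0.5 in each panel.  This checker
#' warns when any panel's mean allele frequency deviates from 0.5 by more
#' than `tol`.
#'
#' @param af_list Named list of allele-frequency vectors (pooled and/or
#'   reference).
#' @param tol Allowed deviation of the mean from 0.5.
#' @return Invisibly, a named vector of mean allele frequencies.
#' @export
check_allele_orientation <- function(af_list, tol = 0.05) {
  means <- vapply(af_list, function(v) mean(v, na.rm = TRUE), numeric(1))
  off <- abs(means - 0.5) > tol
  if (any(off))
    warning("mean allele frequency deviates from 0.5 in: ",
            paste(names(means)[off], collapse = ", "),
            "; admixture coefficients may be biased")
  invisible(means)
}
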