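## End-to-end orchestration: allele-frequency estimation -> QC ->
## admixture regression -> pseudopopulation -> AIM scan -> evaluation,
## with TSV outputs and an exclusion log accounting for every SNP.

#' Run the full pooled-ancestry pipeline
#'
#' Accepts either in-memory objects (a `pool_study` from
#' [simulate_pool_study()], or the individual tables) or file paths from
#' [read_run_config()], and runs the stages in order: pooled AF
#' estimation, SNP QC, admixture regression on the reference panels,
#' pseudopopulation construction, the deflated-chi-square AIM scan
#' against the pseudopopulation, and an evaluation summary (F_ST between
#' the pooled panel and its pseudopopulation).  Given the same inputs and
#' seed-bearing upstream data, the run is deterministic.
#'
#' @param study Optional `pool_study`; supplies clusters, replicates,
#'   panels, pool sizes and individual AFs in one object.
#' @param clusters,replicates,panels,pool_sizes Individual inputs (used
#'   when `study` is absent): cluster-model data frame, replicate
#'   intensities, named list of reference panels, named pool sizes.
#' @param individual_af Optional individual-genotype AF matrix enabling
#'   the hist-filter.
#' @param qc A [qc_config()].
#' @param n_control Effective control size override for the AIM scan
#'   (defaults to the pseudopopulation convention).
#' @param ld Optional LD neighbor lists for AIM categorization (see
#'   [find_aims()]).
#' @param prune Distance-prune the AIM panel (default `TRUE`).
#' @param out_dir Optional directory; when given, all stage outputs are
#'   written as TSVs plus a run log and an exclusion log.
#' @return List of class `pipeline_result`: `pool_af`, `qc`,
#'   `regression_snps`, `admixture`, `pseudopopulation`, `aims`,
#'   `evaluation` (F_ST and counts), `exclusions`.
#' @export
run_pipeline <- function(study = NULL, clusters = NULL,
                         replicates = NULL, panels = NULL,
                         pool_sizes = NULL, individual_af = NULL,
                         qc = qc_config(), n_control = NULL, ld = NULL,
                         prune = TRUE, out_dir = NULL) {
  if (!is.null(study)) {
    stopifnot(inherits(study, "pool_study"))
    clusters <- study$clusters
    replicates <- study$replicates
    panels <- study$panels
    pool_sizes <- study$pool_sizes
    if (is.null(individual_af)) individual_af <- study$individual_af
  }
  if (is.null(clusters) || is.null(replicates) || is.null(panels) ||
      is.null(pool_sizes))
    stop("clusters, replicates, panels and pool_sizes are all required")

  ## stage 1: pooled allele frequencies
  paf <- estimate_pool_af(clusters, replicates)

  ## stage 2: SNP QC
  verdict <- apply_qc(paf, clusters = clusters, pool_sizes = pool_sizes,
                      individual_af = individual_af, config = qc)

  ## stage 3: admixture regression
  snps <- select_regression_snps(verdict, panels)
  ref_af <- vapply(panels, function(p) p$af[match(snps, p$snp_id)],
                   numeric(length(snps)))
  colnames(ref_af) <- names(panels)
  af_m <- .pool_af_matrix(paf$pools)
  w <- pool_sizes[colnames(af_m)]
  pooled_total <- as.vector(af_m %*% w) / sum(w)
  names(pooled_total) <- rownames(af_m)
  check_allele_orientation(c(list(pooled = pooled_total[snps]),
                             as.list(as.data.frame(ref_af))))
  fit <- fit_admixture(pooled_total[snps], ref_af)

  ## stage 4: pseudopopulation over the same SNPs
  pseudo <- build_pseudopopulation(fit, ref_af, n_effective = n_control)

  ## stage 5: AIM scan against the pseudopopulation
  map <- panels[[1]][c("snp_id", "chrom", "pos")]
  aims <- find_aims(paf, pool_sizes, pseudo, map = map,
                    control_snp_ids = snps, snp_subset = snps,
                    ld = ld, prune = prune)

  ## stage 6: evaluation
  eval_fst <- fst(pooled_total[snps], pseudo$af,
                  n_a = sum(pool_sizes), n_b = pseudo$n_effective)
  evaluation <- list(fst_pool_vs_pseudo = eval_fst,
                     n_qc_pass = sum(verdict$pass),
                     n_regression_snps = length(snps),
                     gc_lambda = aims$lambda)

  ## exclusion accounting: every input SNP is either tested or logged
  tested <- aims$records$snp_id
  all_snps <- clusters$snp_id
  excl <- setdiff(all_snps, tested)
  reason <- verdict$reasons[match(excl, verdict$snp_id)]
  reason[!nzchar(reason) | is.na(reason)] <- "negative-MAF-or-unscored"
  exclusions <- data.frame(snp_id = excl, reason = reason,
                           stringsAsFactors = FALSE)

  res <- structure(list(pool_af = paf, qc = verdict,
                        regression_snps = snps, admixture = fit,
                        pseudopopulation = pseudo, aims = aims,
                        evaluation = evaluation, exclusions = exclusions),
                   class = "pipeline_result")
  if (!is.null(out_dir)) .write_pipeline_outputs(res, out_dir)
  res
}

.write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  .write_tsv(res$pool_af$pools, file.path(out_dir, "pool_af.tsv"))
  .write_tsv(res$qc, file.path(out_dir, "qc_verdicts.tsv"))
  fit <- res$admixture
  adm <- data.frame(term = c(names(fit$beta), "intercept"),
                    estimate = c(fit$beta, fit$intercept),
                    se = c(fit$se, fit$intercept_se))
  adm$n_snp <- fit$n_snp
  .write_tsv(adm, file.path(out_dir, "admixture.tsv"))
  .write_tsv(res$aims$records, file.path(out_dir, "aims.tsv"))
  .write_tsv(res$exclusions, file.path(out_dir, "exclusions.tsv"))
  log <- c(paste("poolancestry version:",
                 as.character(utils::packageVersion("poolancestry"))),
           paste("run at:", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
           paste("regression SNPs:", length(res$regression_snps)),
           paste("summed admixture proportion:",
                 signif(fit$sum_beta, 4)),
           paste("intercept:", signif(fit$intercept, 4)),
           paste("GC lambda:", signif(res$aims$lambda, 4)),
           paste("F_ST pool vs pseudopopulation:",
                 signif(res$evaluation$fst_pool_vs_pseudo, 4)))
  writeLines(log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pooled-ancestry pipeline result\n")
  cat("  QC-passing SNPs: ", x$evaluation$n_qc_pass, "\n", sep = "")
  cat("  regression SNPs: ", x$evaluation$n_regression_snps, "\n",
      sep = "")
  cat("  admixture: ",
      paste(sprintf("%s=%.3f", names(x$admixture$beta),
                    x$admixture$beta), collapse = ", "),
      "; intercept=", signif(x$admixture$intercept, 3), "\n", sep = "")
  cat("  GC lambda: ", round(x$aims$lambda, 3),
      "; F_ST vs pseudopopulation: ",
      signif(x$evaluation$fst_pool_vs_pseudo, 3), "\n", sep = "")
  invisible(x)
}
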