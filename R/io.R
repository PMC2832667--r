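## Tabular (TSV) readers and writers for the pipeline's interchange
## formats: reference panels, cluster models, replicate intensities and
## pooled-AF tables.  All positions are 1-based; all files are plain
## tab-separated text with a header row.

.read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a reference-panel allele-frequency table
#'
#' Expects a TSV with header `snp_id`, `chrom`, `pos`, `allele_a`,
#' `allele_b`, `af`, `call_rate`, `n`.  Duplicate SNP ids and allele
#' frequencies outside `[0, 1]` are rejected with the offending id or
#' line number.
#'
#' @param path Path to the TSV file.
#' @return A validated reference-panel data frame.
#' @export
read_reference_panel <- function(path) {
  x <- .read_tsv(path)
  required <- c("snp_id", "chrom", "pos", "allele_a", "allele_b",
                "af", "call_rate", "n")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0)
    stop("reference panel ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  dup <- x$snp_id[duplicated(x$snp_id)]
  if (length(dup) > 0)
    stop("duplicate snp_id in ", path, ": ", dup[1])
  bad <- which(!is.finite(x$af) | x$af < 0 | x$af > 1)
  if (length(bad) > 0)
    stop("allele frequency outside [0, 1] in ", path, " at line ",
         bad[1] + 1)
  bad_pos <- which(!is.finite(x$pos) | x$pos < 1)
  if (length(bad_pos) > 0)
    stop("invalid 1-based position in ", path, " at line ",
         bad_pos[1] + 1)
  x[required]
}

#' Write a reference-panel table
#' @param panel Reference-panel data frame.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_reference_panel <- function(panel, path) .write_tsv(panel, path)

#' Read cluster models and replicate intensities
#'
#' The cluster-model file is long-format TSV (`snp_id`, `class`, `x`,
#' `y`, `cxx`, `cxy`, `cyy`, class in AA/AB/BB); the replicate file has
#' `snp_id`, `pool_id`, `replicate_id`, `x`, `y`.  SNPs present in only
#' one of the two files are dropped with a message.
#'
#' @param cluster_path,replicate_path Paths to the two TSVs.
#' @return List with `clusters` (wide per-SNP data frame) and
#'   `replicates`.
#' @export
read_intensity_tables <- function(cluster_path, replicate_path) {
  long <- .read_tsv(cluster_path)
  need <- c("snp_id", "class", "x", "y", "cxx", "cxy", "cyy")
  if (!all(need %in% names(long)))
    stop("cluster file lacks column(s): ",
         paste(setdiff(need, names(long)), collapse = ", "))
  long$class <- tolower(long$class)
  if (!all(long$class %in% c("aa", "ab", "bb")))
    stop("cluster class must be one of AA, AB, BB")
  complete <- names(which(table(long$snp_id) == 3))
  wide <- data.frame(snp_id = complete, stringsAsFactors = FALSE)
  for (cls in c("aa", "ab", "bb")) {
    sub <- long[long$class == cls, ]
    i <- match(complete, sub$snp_id)
    for (col in c("x", "y", "cxx", "cxy", "cyy"))
      wide[[paste0(cls, "_", col)]] <- sub[[col]][i]
  }
  reps <- .read_tsv(replicate_path)
  needr <- c("snp_id", "pool_id", "replicate_id", "x", "y")
  if (!all(needr %in% names(reps)))
    stop("replicate file lacks column(s): ",
         paste(setdiff(needr, names(reps)), collapse = ", "))
  shared <- intersect(wide$snp_id, unique(reps$snp_id))
  dropped <- length(unique(c(wide$snp_id, reps$snp_id))) - length(shared)
  if (dropped > 0)
    message(dropped, " SNP(s) present in only one of the intensity ",
            "tables were skipped")
  list(clusters = wide[wide$snp_id %in% shared, , drop = FALSE],
       replicates = reps[reps$snp_id %in% shared, , drop = FALSE])
}

#' Write cluster models in long format
#' @param clusters Wide cluster-model data frame.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_cluster_models <- function(clusters, path) {
  long <- do.call(rbind, lapply(c("aa", "ab", "bb"), function(cls) {
    data.frame(snp_id = clusters$snp_id, class = toupper(cls),
               x = clusters[[paste0(cls, "_x")]],
               y = clusters[[paste0(cls, "_y")]],
               cxx = clusters[[paste0(cls, "_cxx")]],
               cxy = clusters[[paste0(cls, "_cxy")]],
               cyy = clusters[[paste0(cls, "_cyy")]],
               stringsAsFactors = FALSE)
  }))
  long <- long[order(long$snp_id, long$class), ]
  .write_tsv(long, path)
}

#' Write replicate intensities
#' @param replicates Replicate-intensity data frame.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_replicates <- function(replicates, path) .write_tsv(replicates, path)

#' Read a flat key=value run configuration
#'
#' Lines of `key = value`; `#` starts a comment.  Unknown keys are
#' rejected.  Recognized keys: `cluster_file`, `replicate_file`,
#' `panel_<name>` (one per reference panel), `pool_sizes`
#' (`pool1=250,pool2=250`), `out_dir`, `seed`, `prune`, `n_control`,
#' and the QC thresholds `fld_min`, `r_ratio_min`, `r_pass_fraction`,
#' `maf_min`, `hist_var_max`.
#'
#' @param path Path to the configuration file.
#' @return A named list suitable for [run_pipeline()].
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  eq <- regexpr("=", lines, fixed = TRUE)
  if (any(eq < 2)) stop("malformed config line: ", lines[which(eq < 2)[1]])
  keys <- trimws(substr(lines, 1, eq - 1))
  vals <- trimws(substring(lines, eq + 1))
  known <- c("cluster_file", "replicate_file", "pool_sizes", "out_dir",
             "seed", "prune", "n_control", "fld_min", "r_ratio_min",
             "r_pass_fraction", "maf_min", "hist_var_max")
  unknown <- keys[!(keys %in% known | startsWith(keys, "panel_"))]
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- list()
  for (i in seq_along(keys)) {
    k <- keys[i]; v <- vals[i]
    if (startsWith(k, "panel_")) {
      cfg$panel_files <- c(cfg$panel_files,
                           stats::setNames(v, sub("^panel_", "", k)))
    } else if (k == "pool_sizes") {
      parts <- strsplit(strsplit(v, ",")[[1]], "=")
      cfg$pool_sizes <- stats::setNames(
        as.numeric(vapply(parts, `[[`, character(1), 2)),
        trimws(vapply(parts, `[[`, character(1), 1)))
    } else if (k %in% c("seed", "n_control")) {
      cfg[[k]] <- as.integer(v)
    } else if (k == "prune") {
      cfg[[k]] <- tolower(v) %in% c("true", "1", "yes")
    } else if (k %in% c("fld_min", "r_ratio_min", "r_pass_fraction",
                        "maf_min", "hist_var_max")) {
      cfg[[k]] <- as.numeric(v)
    } else {
      cfg[[k]] <- v
    }
  }
  for (f in c(cfg$cluster_file, cfg$replicate_file, cfg$panel_files))
    if (!file.exists(f)) stop("configured file does not exist: ", f)
  cfg
}
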