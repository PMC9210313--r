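# Tab-delimited readers/writers for all tabular artifacts, plus the run
# configuration. Count matrices travel as a main table (gene_id, chromosome,
# one column per sample) with a sidecar "<path>.meta.tsv" of sample metadata,
# so a written family round-trips exactly.

.read_tsv <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read and write count matrices
#'
#' `write_count_matrix()` writes the counts as a tab-delimited table
#' (`gene_id`, `chromosome`, one integer column per sample) plus a sidecar
#' sample-metadata table at `<path>.meta.tsv`. `read_count_matrix()` reads
#' both back and validates the result; a write-then-read round trip
#' reproduces the object exactly.
#'
#' @param m a [count_matrix()].
#' @param path file path of the main table.
#' @return `read_count_matrix()` returns a validated [count_matrix()];
#'   `write_count_matrix()` returns `path` invisibly.
#' @export
write_count_matrix <- function(m, path) {
  validate_count_matrix(m)
  main <- data.frame(gene_id = m$genes$gene_id, chromosome = m$genes$chromosome,
                     m$counts, check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(main, path)
  .write_tsv(m$samples, paste0(path, ".meta.tsv"))
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  main <- .read_tsv(path)
  meta_path <- paste0(path, ".meta.tsv")
  if (!file.exists(meta_path))
    .stopf("sample metadata sidecar not found: %s", meta_path)
  samples <- .read_tsv(meta_path)
  if (!all(c("gene_id", "chromosome") %in% names(main)))
    .stopf("count table must start with gene_id and chromosome columns")
  scols <- setdiff(names(main), c("gene_id", "chromosome"))
  if (length(scols) == 0) .stopf("count table has no sample columns")
  counts <- as.matrix(main[, scols, drop = FALSE])
  for (j in seq_along(scols)) {
    v <- main[[scols[j]]]
    if (!is.numeric(v))
      .stopf("non-numeric count in column '%s' (row %d)", scols[j],
             which(is.na(suppressWarnings(as.numeric(v))))[1])
  }
  rownames(counts) <- as.character(main$gene_id)
  storage.mode(counts) <- "integer"
  genes <- data.frame(gene_id = as.character(main$gene_id),
                      chromosome = as.character(main$chromosome),
                      stringsAsFactors = FALSE)
  count_matrix(counts, genes, samples)
}

#' Read and write allele-specific count tables
#'
#' Tab-delimited long format with columns `gene_id`, `chromosome`,
#' `individual`, `P2X`, `P4X`, `H2X`, `H4X`.
#'
#' @param tab an [allele_count_table()].
#' @param path file path.
#' @return `read_allele_table()` returns a validated [allele_count_table()].
#' @export
write_allele_table <- function(tab, path) {
  .write_tsv(as.data.frame(tab), path)
  invisible(path)
}

#' @rdname write_allele_table
#' @export
read_allele_table <- function(path) {
  allele_count_table(.read_tsv(path))
}

#' Read and write trait tables
#'
#' Tab-delimited long format with columns `trait`, `trait_class`, `genotype`,
#' `value`, `trial`, `timepoint`.
#'
#' @param tab a [trait_table()].
#' @param path file path.
#' @return `read_trait_table()` returns a validated [trait_table()].
#' @export
write_trait_table <- function(tab, path) {
  .write_tsv(as.data.frame(tab), path)
  invisible(path)
}

#' @rdname write_trait_table
#' @export
read_trait_table <- function(path) {
  df <- .read_tsv(path)
  if ("value" %in% names(df) && !is.numeric(df$value)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$value))))[1]
    .stopf("non-numeric trait value at row %d, column 'value': '%s'",
           bad, df$value[bad])
  }
  trait_table(df)
}

.config_defaults <- list(
  fdr = 0.005,            # FDR level for all exact tests
  lfc = 1.2,              # |log2 fold-change| threshold for inheritance calls
  min_cpm = 1,            # expression filter: CPM >= min_cpm
  min_parent_reads = 20,  # ASE filter: P2X + P4X >= this
  outlier_pr = 1e-5,      # dosage-outlier tail probability
  aneuploidy_p = 1e-16,   # rank-sum threshold for chromosome aneuploidy
  cv_outer = 10,          # outer cross-validation folds
  cv_inner = 10,          # inner cross-validation folds
  cv_reps = 10            # nested-CV replications
)

#' Load the analysis configuration
#'
#' Reads a flat `key = value` text file (lines starting with `#` are
#' comments) and merges it over the package defaults, which are the
#' thresholds the analysis was designed around: exact-test FDR 0.005,
#' `|log2FC| > 1.2`, CPM >= 1 expression filter, >= 20 reads summed between
#' the parents for ASE sites, dosage-outlier tail probability 1e-5,
#' aneuploidy rank-sum threshold 1e-16, and 10 replications of nested
#' cross-validation with 10-fold inner and outer splits.
#'
#' @param path optional path to a config file; `NULL` returns the defaults.
#' @return Named list of validated settings, class `triase_config`.
#' @examples
#' load_config()$fdr   # 0.005
#' @export
load_config <- function(path = NULL) {
  cfg <- .config_defaults
  if (!is.null(path)) {
    if (!file.exists(path)) .stopf("config file not found: %s", path)
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2)
        .stopf("malformed config line (expected key = value): '%s'", ln)
      key <- trimws(kv[1])
      if (!key %in% names(cfg))
        .stopf("unknown config key '%s'; known keys: %s", key,
               paste(names(cfg), collapse = ", "))
      val <- suppressWarnings(as.numeric(trimws(kv[2])))
      if (is.na(val)) .stopf("config key '%s' has non-numeric value '%s'",
                             key, trimws(kv[2]))
      cfg[[key]] <- val
    }
  }
  .validate_analysis_config(cfg)
  class(cfg) <- "triase_config"
  cfg
}

.validate_analysis_config <- function(cfg) {
  in01 <- function(x) x > 0 && x < 1
  if (!in01(cfg$fdr)) .stopf("fdr must be in (0, 1), got %g", cfg$fdr)
  if (!in01(cfg$outlier_pr)) .stopf("outlier_pr must be in (0, 1)")
  if (!in01(cfg$aneuploidy_p)) .stopf("aneuploidy_p must be in (0, 1)")
  if (cfg$lfc < 0) .stopf("lfc must be non-negative")
  if (cfg$min_cpm < 0) .stopf("min_cpm must be non-negative")
  if (cfg$min_parent_reads < 0) .stopf("min_parent_reads must be non-negative")
  for (kk in c("cv_outer", "cv_inner")) {
    if (cfg[[kk]] < 2 || cfg[[kk]] != round(cfg[[kk]]))
      .stopf("%s must be an integer >= 2", kk)
  }
  if (cfg$cv_reps < 1 || cfg$cv_reps != round(cfg$cv_reps))
    .stopf("cv_reps must be a positive integer")
  invisible(cfg)
}
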