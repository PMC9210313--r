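# Core tabular containers. Kept as light S3 wrappers around base structures
# (an integer matrix plus two data.frames; plain data.frames for the rest) so
# they interoperate with the usual matrix/data.frame toolchain.

#' Construct a count matrix with sample metadata
#'
#' @param counts integer matrix, genes x samples, with gene ids as rownames
#'   and sample ids as colnames.
#' @param genes data.frame with columns `gene_id`, `chromosome`, one row per
#'   matrix row (same order).
#' @param samples data.frame with columns `sample_id`, `genotype`, `role`
#'   (one of `"P1"`, `"P2"`, `"progeny"`), `family`, `replicate`, one row per
#'   matrix column (same order).
#'
#' @return A `count_matrix` object: `list(counts, genes, samples)`.
#' @export
count_matrix <- function(counts, genes, samples) {
  obj <- structure(list(counts = counts, genes = genes, samples = samples),
                   class = "count_matrix")
  validate_count_matrix(obj)
}

#' @rdname count_matrix
#' @param x a `count_matrix`.
#' @export
validate_count_matrix <- function(x) {
  counts <- x$counts
  if (!is.matrix(counts)) .stopf("counts must be a matrix")
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0)
    .stopf("counts must be non-negative integers; first offending cell: gene '%s', sample '%s' (value %s)",
           rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
           format(counts[bad[1, 1], bad[1, 2]]))
  if (anyDuplicated(rownames(counts)))
    .stopf("duplicate gene ids: %s",
           paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  need_g <- c("gene_id", "chromosome")
  if (!all(need_g %in% names(x$genes))) .stopf("genes table needs columns: %s", paste(need_g, collapse = ", "))
  if (!identical(as.character(x$genes$gene_id), rownames(counts)))
    .stopf("genes table must match matrix rows (same ids, same order)")
  need_s <- c("sample_id", "genotype", "role", "family", "replicate")
  if (!all(need_s %in% names(x$samples))) .stopf("samples table needs columns: %s", paste(need_s, collapse = ", "))
  if (!identical(as.character(x$samples$sample_id), colnames(counts)))
    .stopf("sample metadata must match matrix columns (same ids, same order); missing metadata for: %s",
           paste(setdiff(colnames(counts), x$samples$sample_id), collapse = ", "))
  if (!all(x$samples$role %in% c("P1", "P2", "progeny")))
    .stopf("unknown sample role(s): %s",
           paste(setdiff(x$samples$role, c("P1", "P2", "progeny")), collapse = ", "))
  dup <- duplicated(x$samples[, c("genotype", "replicate")])
  if (any(dup))
    .stopf("replicate indices must be unique within genotype (genotype '%s', replicate %s)",
           x$samples$genotype[dup][1], x$samples$replicate[dup][1])
  x
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (%d genotypes, roles: %s)\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$samples$genotype)),
              paste(sort(unique(x$samples$role)), collapse = "/")))
  invisible(x)
}

#' @rdname count_matrix
#' @param role one of `"P1"`, `"P2"`, `"progeny"`, or a genotype id.
#' @export
#' @details `samples_for()` returns the sample ids for a role or genotype id,
#'   in matrix column order.
samples_for <- function(x, role) {
  s <- x$samples
  hit <- s$role == role | s$genotype == role
  if (!any(hit)) .stopf("no samples with role or genotype '%s'", role)
  as.character(s$sample_id[hit])
}

#' Construct an allele count table
#'
#' One row per gene (or diagnostic site) per hybrid individual, holding the
#' four parent-diagnostic allele counts: `P2X`/`P4X` are the counts of the
#' diploid- and tetraploid-parent alleles in the respective parent libraries,
#' `H2X`/`H4X` the counts of those alleles in the hybrid library.
#'
#' @param df data.frame with columns `gene_id`, `chromosome`, `individual`,
#'   `P2X`, `P4X`, `H2X`, `H4X`.
#' @return The validated data.frame with class `allele_count_table`.
#' @export
allele_count_table <- function(df) {
  need <- c("gene_id", "chromosome", "individual", "P2X", "P4X", "H2X", "H4X")
  miss <- setdiff(need, names(df))
  if (length(miss)) .stopf("allele count table is missing column(s): %s", paste(miss, collapse = ", "))
  for (cc in c("P2X", "P4X", "H2X", "H4X")) {
    v <- df[[cc]]
    if (!is.numeric(v) || any(is.na(v)) || any(v < 0) || any(v != round(v)))
      .stopf("column %s must hold non-negative integers (first bad row: %d)",
             cc, which(!is.finite(v) | v < 0 | v != round(v))[1])
  }
  if (any(is.na(df$chromosome)) || any(df$chromosome == ""))
    .stopf("chromosome must be present for every row")
  df <- df[, need]
  class(df) <- c("allele_count_table", "data.frame")
  df
}

#' Construct a trait table
#'
#' Long-format phenotypes: one row per trait per genotype, parents included,
#' indexed by the same genotype vocabulary as the count matrix.
#'
#' @param df data.frame with columns `trait`, `trait_class`, `genotype`,
#'   `value`, `trial`, `timepoint`.
#' @return The validated data.frame with class `trait_table`.
#' @export
trait_table <- function(df) {
  need <- c("trait", "trait_class", "genotype", "value", "trial", "timepoint")
  miss <- setdiff(need, names(df))
  if (length(miss)) .stopf("trait table is missing column(s): %s", paste(miss, collapse = ", "))
  if (!is.numeric(df$value)) .stopf("trait values must be numeric")
  df <- df[, need]
  class(df) <- c("trait_table", "data.frame")
  df
}
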