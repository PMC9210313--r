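# Classification of hybrid expression inheritance from the three pairwise
# exact tests (P1 vs P2, P1 vs hybrid, P2 vs hybrid), per-individual
# summaries, and presence/absence (silenced/activated) calls.

#' Classify expression inheritance from three test outcomes
#'
#' Maps the outcomes of the three pairwise exact tests for one gene to a
#' single inheritance label. Inputs are vectorized. Directions follow the
#' fold-change conventions of [run_pairwise_de()]: `pp` compares P1 over P2,
#' `p2h` P1 over hybrid, `p4h` P2 over hybrid, so a negative `p2h_dir` means
#' the hybrid exceeds the diploid parent.
#'
#' The decision table is exhaustive over all outcome combinations:
#' hybrid significantly above both parents is `overdominant`, below both
#' `underdominant`; parents different with the hybrid indistinguishable from
#' one parent but different from the other is `P1_dominant`/`P2_dominant`;
#' parents different with the hybrid either significantly between them or
#' statistically indistinguishable from both is `additive`; everything else
#' (including partial patterns with no parental difference) is `conserved`.
#'
#' @param pp_sig,p2h_sig,p4h_sig logical: is each test significant.
#' @param pp_dir,p2h_dir,p4h_dir numeric: sign (or signed log2FC) of each
#'   test.
#' @return Character vector of labels from [inheritance_classes()].
#' @examples
#' classify_inheritance(TRUE, 2, FALSE, 0.1, TRUE, 2)  # P1_dominant
#' @export
classify_inheritance <- function(pp_sig, pp_dir, p2h_sig, p2h_dir,
                                 p4h_sig, p4h_dir) {
  n <- length(pp_sig)
  args <- list(pp_sig, pp_dir, p2h_sig, p2h_dir, p4h_sig, p4h_dir)
  if (any(vapply(args, length, 1L) != n))
    .stopf("all six test outcomes must have equal length")
  if (any(vapply(args, anyNA, TRUE)))
    .stopf("missing test outcome")
  label <- rep("conserved", n)
  both_h <- p2h_sig & p4h_sig
  label[both_h & p2h_dir < 0 & p4h_dir < 0] <- "overdominant"
  label[both_h & p2h_dir > 0 & p4h_dir > 0] <- "underdominant"
  between <- both_h & (sign(p2h_dir) != sign(p4h_dir))
  label[pp_sig & between] <- "additive"
  label[pp_sig & !p2h_sig & !p4h_sig] <- "additive"
  label[pp_sig & !p2h_sig & p4h_sig & !(both_h)] <- "P1_dominant"
  label[pp_sig & p2h_sig & !p4h_sig & !(both_h)] <- "P2_dominant"
  label
}

#' Build per-gene inheritance calls from three DE tables
#'
#' Joins the [run_pairwise_de()] results of the parent-parent and the two
#' parent-hybrid comparisons on their common genes and applies
#' [classify_inheritance()].
#'
#' @param de_pp,de_p2h,de_p4h results of [run_pairwise_de()] for
#'   P1 vs P2, P1 vs hybrid and P2 vs hybrid.
#' @param individual label of the hybrid individual (recorded in the output).
#' @return data.frame with `gene_id`, `individual`, `label`, and the six
#'   outcomes the label was derived from.
#' @export
inheritance_calls <- function(de_pp, de_p2h, de_p4h, individual = "H") {
  genes <- Reduce(intersect, list(de_pp$gene_id, de_p2h$gene_id, de_p4h$gene_id))
  i1 <- match(genes, de_pp$gene_id)
  i2 <- match(genes, de_p2h$gene_id)
  i3 <- match(genes, de_p4h$gene_id)
  out <- data.frame(
    gene_id = genes, individual = individual,
    pp_sig = de_pp$significant[i1], pp_dir = de_pp$log2FC[i1],
    p2h_sig = de_p2h$significant[i2], p2h_dir = de_p2h$log2FC[i2],
    p4h_sig = de_p4h$significant[i3], p4h_dir = de_p4h$log2FC[i3],
    stringsAsFactors = FALSE)
  out$label <- classify_inheritance(out$pp_sig, out$pp_dir, out$p2h_sig,
                                    out$p2h_dir, out$p4h_sig, out$p4h_dir)
  out
}

#' Summarize inheritance calls for one individual
#'
#' @param calls data.frame from [inheritance_calls()] (one individual).
#' @return List with `counts` (named vector over [inheritance_classes()],
#'   summing to `nrow(calls)`), `proportions`, `pct_nonadditive_parent_de`
#'   (percentage of parent-DE genes with dominant or transgressive
#'   inheritance) and `pct_transgressive` (percentage of all classified genes
#'   over- or underdominant).
#' @export
summarize_inheritance <- function(calls) {
  counts <- table(factor(calls$label, levels = .inheritance_classes))
  counts <- stats::setNames(as.integer(counts), .inheritance_classes)
  n <- nrow(calls)
  parent_de <- calls[calls$pp_sig, , drop = FALSE]
  nonadd <- c("P1_dominant", "P2_dominant", "overdominant", "underdominant")
  list(counts = counts,
       proportions = counts / max(n, 1),
       pct_nonadditive_parent_de =
         if (nrow(parent_de) > 0)
           100 * mean(parent_de$label %in% nonadd) else NA_real_,
       pct_transgressive =
         100 * sum(counts[c("overdominant", "underdominant")]) / max(n, 1))
}

#' Presence/absence calls: silenced and activated genes
#'
#' Compares transcript presence (CPM above the presence threshold) and
#' absence (CPM exactly 0) between parents and one hybrid, using
#' all-replicates quantifiers: a gene is `silenced` when present in every
#' replicate of at least one parent and absent from every hybrid replicate;
#' `activated` when absent from every replicate of both parents and present
#' in every hybrid replicate; otherwise `neither`.
#'
#' @param p1_cpm,p2_cpm,hybrid_cpm CPM matrices (genes x replicates, same
#'   genes in the same order).
#' @param present_cpm presence threshold (CPM > this; default 1).
#' @return Character vector (`silenced`/`activated`/`neither`) named by gene.
#' @export
classify_presence <- function(p1_cpm, p2_cpm, hybrid_cpm, present_cpm = 1) {
  stopifnot(nrow(p1_cpm) == nrow(p2_cpm), nrow(p1_cpm) == nrow(hybrid_cpm))
  all_gt <- function(m) apply(m > present_cpm, 1, all)
  all_zero <- function(m) apply(m == 0, 1, all)
  out <- rep("neither", nrow(p1_cpm))
  out[(all_gt(p1_cpm) | all_gt(p2_cpm)) & all_zero(hybrid_cpm)] <- "silenced"
  out[all_zero(p1_cpm) & all_zero(p2_cpm) & all_gt(hybrid_cpm)] <- "activated"
  stats::setNames(out, rownames(p1_cpm))
}
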