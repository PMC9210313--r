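# Library normalization, expression filtering, common-dispersion estimation,
# and the two-sample negative-binomial exact test used for all pairwise
# differential-expression comparisons (diploid parent vs tetraploid parent,
# and each parent vs each triploid hybrid individual).

#' Counts per million
#'
#' @param x a [count_matrix()] or a bare genes x samples count matrix.
#' @return Numeric matrix of the same shape; every column sums to 1e6.
#' @export
cpm <- function(x) {
  counts <- if (inherits(x, "count_matrix")) x$counts else x
  lib <- colSums(counts)
  if (any(lib <= 0))
    .stopf("zero-depth library: %s",
           paste(colnames(counts)[lib <= 0], collapse = ", "))
  sweep(counts, 2, lib, "/") * 1e6
}

#' Expression filter on CPM
#'
#' Retains genes with CPM at or above `threshold` in enough samples. With
#' `groups` (a list of sample-id vectors), the rule is: at least `threshold`
#' in every sample of at least one group — so a gene expressed in only one
#' genotype of a comparison still enters the test. Without `groups`, a plain
#' `min_samples`-out-of-all-samples rule is applied (defaulting to all
#' samples).
#'
#' @param cpm_matrix matrix from [cpm()].
#' @param threshold minimum CPM (default 1).
#' @param groups optional list of character vectors of column names.
#' @param min_samples minimum number of qualifying samples when `groups` is
#'   not given.
#' @return Character vector of retained gene ids.
#' @export
filter_min_cpm <- function(cpm_matrix, threshold = 1, groups = NULL,
                           min_samples = NULL) {
  if (threshold < 0) .stopf("threshold must be non-negative")
  if (!is.null(groups)) {
    keep <- rep(FALSE, nrow(cpm_matrix))
    for (g in groups) {
      sub <- cpm_matrix[, g, drop = FALSE]
      keep <- keep | apply(sub >= threshold, 1, all)
    }
  } else {
    if (is.null(min_samples)) min_samples <- ncol(cpm_matrix)
    keep <- rowSums(cpm_matrix >= threshold) >= min_samples
  }
  rownames(cpm_matrix)[keep]
}

#' Estimate a common negative-binomial dispersion
#'
#' Maximizes, over a single dispersion phi shared by all genes, the sum of
#' per-gene log-likelihoods conditional on each replicated group's total,
#' after rescaling every library to the geometric-mean library size (so the
#' conditioning argument of the exact test applies). The conditional
#' likelihood is free of the gene means, which is what makes a common-phi
#' estimate from few replicates stable.
#'
#' @param counts genes x samples count matrix.
#' @param groups factor or character vector assigning columns to groups.
#' @param interval search interval for phi.
#' @return Estimated dispersion phi (lower bound 1e-6 when the data show no
#'   overdispersion).
#' @export
estimate_common_dispersion <- function(counts, groups,
                                       interval = c(1e-6, 4)) {
  groups <- as.factor(groups)
  if (length(groups) != ncol(counts))
    .stopf("groups must have one entry per column")
  rep_groups <- names(which(table(groups) >= 2))
  if (length(rep_groups) == 0)
    .stopf("no group has >= 2 replicates; supply a dispersion explicitly")
  pseudo <- .equalize_libs(counts)
  ll <- function(log_phi) {
    r <- 1 / exp(log_phi)
    tot <- 0
    for (g in rep_groups) {
      y <- pseudo[, groups == g, drop = FALSE]
      m <- ncol(y)
      z <- rowSums(y)
      tot <- tot + sum(rowSums(lgamma(y + r)) - m * lgamma(r) +
                         lgamma(m * r) - lgamma(z + m * r))
    }
    tot
  }
  opt <- stats::optimize(ll, log(interval), maximum = TRUE, tol = 1e-6)
  phi <- exp(opt$maximum)
  # boundary check: no-overdispersion data push the optimum to the edge
  if (ll(log(interval[1])) >= opt$objective) phi <- interval[1]
  phi
}

#' @noRd
#' Mean-preserving rescale of every library to the geometric-mean library
#' size, rounded back to integers. The exact test conditions on group totals
#' and therefore needs (approximately) equal library sizes.
.equalize_libs <- function(counts) {
  lib <- colSums(counts)
  if (any(lib <= 0)) .stopf("zero-depth library")
  target <- .geomean(lib)
  pseudo <- round(sweep(counts, 2, target / lib, "*"))
  storage.mode(pseudo) <- "double"
  pseudo
}

#' Two-sample negative-binomial exact test
#'
#' Tests equality of mean expression between two groups of replicated NB
#' counts with common dispersion `phi`. Counts are first rescaled to a common
#' pseudo-library size; the group sums A and B are then NB with sizes
#' `nA/phi` and `nB/phi`, and conditional on `s = A + B` the distribution of
#' A is free of the unknown mean (a negative hypergeometric). The two-sided
#' p-value sums the probabilities of all partitions of `s` no more probable
#' than the observed one. At `phi = 0` this reduces to the conditional
#' binomial (Poisson-limit) test. The log2 fold-change uses a prior count of
#' 0.5 per group on per-sample means.
#'
#' @param countsA,countsB integer vectors of replicate counts for one gene.
#' @param phi common dispersion (>= 0).
#' @param libsizesA,libsizesB library sizes; defaults treat libraries as
#'   already equalized.
#' @return List with `log2FC` and `p`.
#' @examples
#' nb_exact_test(c(10, 12, 9), c(30, 28, 35), phi = 0.05)
#' @export
nb_exact_test <- function(countsA, countsB, phi,
                          libsizesA = rep(1, length(countsA)),
                          libsizesB = rep(1, length(countsB))) {
  if (phi < 0) .stopf("phi must be non-negative")
  if (any(c(countsA, countsB) < 0)) .stopf("counts must be non-negative")
  nA <- length(countsA)
  nB <- length(countsB)
  lib <- c(libsizesA, libsizesB)
  target <- .geomean(lib)
  pseudo <- round(c(countsA, countsB) * target / lib)
  a <- sum(pseudo[seq_len(nA)])
  b <- sum(pseudo[-seq_len(nA)])
  log2FC <- log2(((a + 0.5) / nA) / ((b + 0.5) / nB))
  if (a + b == 0) return(list(log2FC = 0, p = 1))
  p <- .exact_cond_p(a, b, nA, nB, phi)
  list(log2FC = log2FC, p = p)
}

#' @noRd
#' Conditional two-sided p for group totals (a, b) from nA and nB samples.
.exact_cond_p <- function(a, b, nA, nB, phi) {
  s <- a + b
  x <- 0:s
  if (phi <= 0) {
    lw <- stats::dbinom(x, s, nA / (nA + nB), log = TRUE)
  } else {
    rA <- nA / phi
    rB <- nB / phi
    lw <- lgamma(x + rA) - lgamma(x + 1) + lgamma(s - x + rB) - lgamma(s - x + 1)
  }
  lw <- lw - max(lw)
  w <- exp(lw)
  sel <- w <= w[a + 1] * (1 + 1e-8)
  min(1, sum(w[sel]) / sum(w))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment via [stats::p.adjust()], with strict input
#' validation (missing p-values are an error rather than silently dropped).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p))) .stopf("p-values must be finite (no NA/NaN)")
  if (any(p < 0 | p > 1)) .stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Pairwise differential expression
#'
#' Runs the full exact-test pipeline for one pair of genotypes: CPM
#' filtering (CPM >= `min_cpm` in every replicate of at least one of the two
#' groups), common-dispersion estimation from the two groups' replicates, a
#' negative-binomial exact test per gene, and Benjamini-Hochberg adjustment.
#' A gene is flagged significant when `q < fdr` and `|log2FC| > lfc`.
#'
#' @param m a [count_matrix()].
#' @param pair character vector of two roles or genotype ids, e.g.
#'   `c("P1", "P2")` or `c("P2", "H01")`. Fold-changes are
#'   `pair[1]` over `pair[2]`.
#' @param config a [load_config()] list (defaults used when omitted).
#' @param phi optional dispersion override; estimated from the data when
#'   `NULL`.
#' @return data.frame with one row per retained gene: `gene_id`,
#'   `comparison`, `log2FC`, `p`, `q`, `cpmA`, `cpmB`, `significant`.
#' @export
run_pairwise_de <- function(m, pair, config = load_config(), phi = NULL) {
  validate_count_matrix(m)
  if (length(pair) != 2) .stopf("pair must name exactly two groups")
  sA <- samples_for(m, pair[1])
  sB <- samples_for(m, pair[2])
  cpm_all <- cpm(m)
  keep <- filter_min_cpm(cpm_all[, c(sA, sB), drop = FALSE],
                         threshold = config$min_cpm,
                         groups = list(sA, sB))
  counts <- m$counts[keep, , drop = FALSE]
  if (is.null(phi)) {
    sub <- counts[, c(sA, sB), drop = FALSE]
    phi <- estimate_common_dispersion(sub, rep(c("A", "B"), c(length(sA), length(sB))))
  }
  libA <- colSums(m$counts[, sA, drop = FALSE])
  libB <- colSums(m$counts[, sB, drop = FALSE])
  res <- vapply(keep, function(g) {
    tt <- nb_exact_test(counts[g, sA], counts[g, sB], phi, libA, libB)
    c(tt$log2FC, tt$p)
  }, numeric(2))
  out <- data.frame(gene_id = keep,
                    comparison = paste(pair, collapse = "_vs_"),
                    log2FC = res[1, ], p = res[2, ],
                    q = bh_adjust(res[2, ]),
                    cpmA = rowMeans(cpm_all[keep, sA, drop = FALSE]),
                    cpmB = rowMeans(cpm_all[keep, sB, drop = FALSE]),
                    stringsAsFactors = FALSE)
  out$significant <- out$q < config$fdr & abs(out$log2FC) > config$lfc
  attr(out, "dispersion") <- phi
  rownames(out) <- NULL
  out
}
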