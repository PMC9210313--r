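# Chromosome-level copy-number and aneuploidy inference from allele-specific
# ratios, per-gene dosage-outlier detection, and the cumulative-dysregulation
# statistic.
#
# Noise-free arithmetic: on a chromosome where the tetraploid parent carries
# c4 copies (euploid 4) and the hybrid inherited k of them plus one diploid
# copy, the parental log-ratio log2(P2X/P4X) centers at -log2(c4/4), the
# hybrid allelic log-ratio log2(H2X/H4X) at -log2(k), their difference D at
# log2(k) - log2(c4/4), and the hybrid diploid percentage at 100/(1+k).

#' Percentage of hybrid reads from the diploid-parent allele
#'
#' `100 * H2X / (H2X + H4X)`, with zero-coverage rows returned as `NA` (they
#' are excluded from chromosome medians).
#'
#' @param H2X,H4X hybrid allele counts.
#' @return Numeric vector of percentages in `[0, 100]` (or `NA`).
#' @export
diploid_percent <- function(H2X, H4X) {
  tot <- H2X + H4X
  out <- 100 * H2X / tot
  out[tot == 0] <- NA_real_
  out
}

#' Chromosome dosage profile for one hybrid individual
#'
#' Medians over the chromosome's informative genes of the parental log-ratio
#' `log2(P2X/P4X)`, the hybrid allelic log-ratio `log2(H2X/H4X)`, their
#' per-gene difference `D` (parent minus hybrid), and the diploid
#' percentage. Genes with zero coverage on either the parental or hybrid
#' side are excluded; remaining log-ratios use a pseudo-count.
#'
#' @param table an [allele_count_table()].
#' @param chromosome,individual which chromosome/individual to profile.
#' @param pseudo pseudo-count for log-ratios (default 0.5).
#' @param min_genes minimum informative genes; fewer flags the profile
#'   low-confidence.
#' @return data.frame (one row) with the medians, `n_genes`,
#'   `low_confidence`, and the inferred `c4`, `k`, `state` from
#'   [infer_copy_numbers()].
#' @export
chromosome_profile <- function(table, chromosome, individual, pseudo = 0.5,
                               min_genes = 10) {
  rows <- table[table$chromosome == chromosome &
                  table$individual == individual, , drop = FALSE]
  if (nrow(rows) == 0)
    .stopf("no rows for chromosome '%s', individual '%s'", chromosome, individual)
  informative <- (rows$P2X + rows$P4X) > 0 & (rows$H2X + rows$H4X) > 0
  rows <- rows[informative, , drop = FALSE]
  parent_lr <- .log2_ratio(rows$P2X, rows$P4X, pseudo)
  hybrid_lr <- .log2_ratio(rows$H2X, rows$H4X, pseudo)
  dp <- diploid_percent(rows$H2X, rows$H4X)
  prof <- data.frame(
    chromosome = chromosome, individual = individual,
    median_parent_lr = stats::median(parent_lr),
    median_hybrid_lr = stats::median(hybrid_lr),
    D = stats::median(parent_lr - hybrid_lr),
    diploid_pct = stats::median(dp, na.rm = TRUE),
    n_genes = nrow(rows),
    low_confidence = nrow(rows) < min_genes,
    stringsAsFactors = FALSE)
  cn <- infer_copy_numbers(prof$D, prof$diploid_pct)
  prof$c4 <- cn$c4
  prof$k <- cn$k
  prof$state <- cn$state
  prof
}

#' Dosage profiles for all chromosomes and individuals
#'
#' @param table an [allele_count_table()].
#' @inheritParams chromosome_profile
#' @return data.frame with one [chromosome_profile()] row per chromosome x
#'   individual present in the table.
#' @export
dosage_profiles <- function(table, pseudo = 0.5, min_genes = 10) {
  combos <- unique(table[, c("chromosome", "individual")])
  out <- lapply(seq_len(nrow(combos)), function(i)
    chromosome_profile(table, combos$chromosome[i], combos$individual[i],
                       pseudo, min_genes))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Infer chromosome copy numbers from the dosage summary statistics
#'
#' The diploid percentage pins down `k` (inherited tetraploid-parent copies):
#' `k = round(100/diploid_pct - 1)`, clamped to 1..3. Given `k`, the
#' parent-minus-hybrid log-ratio difference `D = log2(k) - log2(c4/4)` pins
#' down the tetraploid parent's copy number: `c4 = round(4k / 2^D)`, clamped
#' to 1..4. The hybrid state is `deficient` for `k < 2`, `normal` for
#' `k = 2` with `c4 = 4`, `replete` for `k > 2`. Exactly one inherited
#' diploid-parent copy is assumed (diploid-parent aneuploidy is not
#' identifiable from these ratios).
#'
#' @param D median parent-minus-hybrid difference of `log2(P2X/P4X)`-type
#'   ratios (log2 units).
#' @param diploid_pct median diploid percentage, in (0, 100).
#' @return List with `c4`, `k`, `state`.
#' @examples
#' infer_copy_numbers(1.585, 25)  # c4 = 4, k = 3, replete
#' @export
infer_copy_numbers <- function(D, diploid_pct) {
  if (!is.finite(D)) .stopf("D must be finite")
  if (!is.finite(diploid_pct) || diploid_pct <= 0 || diploid_pct >= 100)
    .stopf("diploid_pct must be in (0, 100)")
  k <- as.integer(.clamp(round(100 / diploid_pct - 1), 1, 3))
  c4 <- as.integer(.clamp(round(4 * k / 2^D), 1, 4))
  state <- if (k < 2) "deficient" else if (k > 2) "replete"
           else if (c4 == 4) "normal" else "deficient"
  list(c4 = c4, k = k, state = state)
}

#' Per-chromosome aneuploidy scan
#'
#' For each chromosome, a two-sided Wilcoxon rank-sum test of its per-gene
#' values (e.g. `log2(P2X/P4X)` ratios) against the values of all other
#' chromosomes. Uses the exact null distribution for small samples and the
#' tie-corrected normal approximation otherwise; p-values are floored at
#' 1e-300.
#'
#' @param values numeric per-gene values.
#' @param chromosomes chromosome label per value.
#' @param threshold significance threshold (default 1e-16).
#' @return data.frame with `chromosome`, `p`, `significant`.
#' @export
aneuploidy_scan <- function(values, chromosomes, threshold = 1e-16) {
  chromosomes <- as.character(chromosomes)
  chroms <- unique(chromosomes)
  if (length(chroms) < 2) .stopf("need at least 2 chromosomes to scan")
  p <- vapply(chroms, function(ch) {
    x <- values[chromosomes == ch]
    y <- values[chromosomes != ch]
    max(stats::wilcox.test(x, y)$p.value, 1e-300)
  }, numeric(1))
  data.frame(chromosome = chroms, p = unname(p),
             significant = unname(p) < threshold, stringsAsFactors = FALSE)
}

#' Per-gene dosage-ratio points for one individual
#'
#' Fig-2-style coordinates: `x = log2(H2X/P2X)` (diploid allele, hybrid over
#' parent) and `y = log2(H4X/P4X)` (tetraploid allele), on depth-normalized
#' counts with a pseudo-count. Under balanced triploid dosage (`c4 = 4`,
#' `k = 2`) the cloud centers at `(log2(1/3), log2(2/3)) = (-1.585, -0.585)`.
#'
#' @param table an [allele_count_table()] for one individual.
#' @param pseudo pseudo-count.
#' @return data.frame with `gene_id`, `x`, `y`.
#' @export
dosage_ratio_points <- function(table, pseudo = 0.5) {
  lib <- c(sum(table$P2X), sum(table$P4X), sum(table$H2X) + sum(table$H4X))
  if (any(lib == 0)) .stopf("a library has zero total reads")
  target <- .geomean(lib)
  P2n <- table$P2X * target / lib[1]
  P4n <- table$P4X * target / lib[2]
  H2n <- table$H2X * target / lib[3]
  H4n <- table$H4X * target / lib[3]
  data.frame(gene_id = table$gene_id,
             x = log2((H2n + pseudo) / (P2n + pseudo)),
             y = log2((H4n + pseudo) / (P4n + pseudo)),
             stringsAsFactors = FALSE)
}

#' Flag extreme dosage-ratio outliers
#'
#' Operationalizes the "ellipse" of a bivariate dosage-ratio cloud as a
#' robust Mahalanobis region: location is the coordinate-wise median;
#' covariance is the classical covariance of the points inside the central
#' `trim` mass of an initial fit, rescaled by the chi-square consistency
#' factor for that truncation so the estimator is calibrated under
#' normality. Points whose squared Mahalanobis distance exceeds the
#' chi-square(2) quantile at `1 - pr` are flagged dysregulated.
#'
#' @param points data.frame with columns `x`, `y` (>= 30 finite rows).
#' @param pr tail probability of the ellipse (default 1e-5).
#' @param trim central mass used for the robust covariance (default 0.95).
#' @return `points` with added `md2` (squared Mahalanobis distance) and
#'   `outlier` columns.
#' @export
dosage_outliers <- function(points, pr = 1e-5, trim = 0.95) {
  xy <- as.matrix(points[, c("x", "y")])
  ok <- is.finite(xy[, 1]) & is.finite(xy[, 2])
  if (sum(ok) < 30) .stopf("need >= 30 finite points to fit the ellipse")
  center <- apply(xy[ok, ], 2, stats::median)
  dev <- sweep(xy[ok, ], 2, center)
  cov0 <- crossprod(dev) / (nrow(dev) - 1)
  if (!all(is.finite(cov0)) || det(cov0) <= 0)
    .stopf("degenerate covariance; points may be collinear or constant - add jitter or more data")
  md0 <- stats::mahalanobis(xy[ok, ], center, cov0)
  inside <- md0 <= stats::qchisq(trim, df = 2)
  dev_in <- dev[inside, , drop = FALSE]
  # consistency factor for covariance of chi-square-truncated normal points
  cons <- trim / stats::pchisq(stats::qchisq(trim, df = 2), df = 4)
  covr <- crossprod(dev_in) / (nrow(dev_in) - 1) * cons
  if (det(covr) <= 0) .stopf("degenerate robust covariance")
  md2 <- rep(NA_real_, nrow(xy))
  md2[ok] <- stats::mahalanobis(xy[ok, , drop = FALSE], center, covr)
  points$md2 <- md2
  points$outlier <- !is.na(md2) & md2 > stats::qchisq(1 - pr, df = 2)
  points
}

#' Cumulative expression dysregulation for one individual
#'
#' Scalar burden of dosage dysregulation over one individual's flagged
#' points. `mode = "count"` (default) counts flagged genes; `mode = "sum"`
#' sums the excess Mahalanobis distance beyond the flagging threshold, so it
#' grows with both the number and the extremity of outliers.
#'
#' @param points output of [dosage_outliers()].
#' @param mode `"count"` or `"sum"`.
#' @param pr the tail probability used for flagging (needed for the `"sum"`
#'   threshold).
#' @return Named list with `value` and `mode`.
#' @export
cumulative_dysregulation <- function(points, mode = c("count", "sum"),
                                     pr = 1e-5) {
  mode <- match.arg(mode)
  if (is.null(points$outlier)) .stopf("run dosage_outliers() first")
  value <- if (mode == "count") {
    sum(points$outlier, na.rm = TRUE)
  } else {
    thr <- stats::qchisq(1 - pr, df = 2)
    sum(pmax(points$md2[points$outlier] - thr, 0), na.rm = TRUE)
  }
  list(value = value, mode = mode)
}
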