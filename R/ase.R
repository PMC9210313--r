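# Allele-specific expression tests (binomial in parents and hybrid, Fisher
# across both) and the cis/trans regulatory-divergence classifier.

#' Filter allele-specific sites on parental coverage
#'
#' Retains rows with at least `min_parent_reads` reads summed between the two
#' parent libraries (both alleles are parent-diagnostic by construction of
#' the table).
#'
#' @param table an [allele_count_table()].
#' @param min_parent_reads minimum `P2X + P4X` (default 20).
#' @return The retained rows, still an [allele_count_table()].
#' @export
filter_ase_sites <- function(table, min_parent_reads = 20) {
  keep <- (table$P2X + table$P4X) >= min_parent_reads
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Two-sided exact binomial test
#'
#' Equal-or-smaller-probability-mass two-sided p-value: the sum of `P(X = j)`
#' over all `j` with `P(X = j) <= P(X = k)` under `Binomial(n, p0)`, capped
#' at 1. `n = 0` returns 1 by convention.
#'
#' @param k number of successes.
#' @param n number of trials.
#' @param p0 null success probability in (0, 1).
#' @return p-value in (0, 1].
#' @export
binomial_two_sided <- function(k, n, p0 = 0.5) {
  if (n == 0) return(1)
  if (k < 0 || k > n) .stopf("k must be in [0, n]")
  if (p0 <= 0 || p0 >= 1) .stopf("p0 must be in (0, 1)")
  min(1, stats::binom.test(k, n, p = p0)$p.value)
}

#' Two-sided Fisher exact test on a 2 x 2 table
#'
#' Sums the hypergeometric probabilities of all margin-fixed tables no more
#' probable than the observed one. An all-zero table returns 1.
#'
#' @param a,b,c,d non-negative integer cells, row-wise:
#'   `rbind(c(a, b), c(c, d))`.
#' @return p-value in (0, 1].
#' @export
fisher_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    .stopf("cells must be non-negative integers")
  if (sum(cells) == 0) return(1)
  min(1, stats::fisher.test(matrix(cells, 2, 2, byrow = TRUE))$p.value)
}

#' Classify regulatory divergence from the three ASE tests
#'
#' Maps the significance pattern of the parent binomial test (P), the hybrid
#' binomial test (H) and the parent-vs-hybrid Fisher test (F), together with
#' the signed cis and trans magnitudes, onto one regulatory class. The cis
#' magnitude is the dosage-adjusted hybrid allelic log-ratio; the trans
#' magnitude is the parental log-ratio minus cis, so cis + trans equals the
#' parental divergence by construction.
#'
#' Pattern map (P, H, F): `(1,1,0)` cis; `(1,0,1)` trans; `(0,1,1)`
#' compensatory; `(1,1,1)` cis_plus_trans when cis and trans agree in sign
#' (ties, i.e. a zero magnitude, break toward cis_plus_trans), otherwise
#' cis_times_trans; `(0,0,0)` conserved; exactly one significant test is
#' ambiguous.
#'
#' @param P_sig,H_sig,F_sig logical vectors.
#' @param cis,trans signed magnitudes in log2 units.
#' @return Character vector of labels (the classes of
#'   [regulatory_classes()] plus `"ambiguous"`).
#' @export
classify_regulatory <- function(P_sig, H_sig, F_sig, cis, trans) {
  n <- length(P_sig)
  stopifnot(length(H_sig) == n, length(F_sig) == n,
            length(cis) == n, length(trans) == n)
  nsig <- P_sig + H_sig + F_sig
  label <- rep("conserved", n)
  label[nsig == 1] <- "ambiguous"
  label[P_sig & H_sig & !F_sig] <- "cis"
  label[P_sig & !H_sig & F_sig] <- "trans"
  label[!P_sig & H_sig & F_sig] <- "compensatory"
  all3 <- P_sig & H_sig & F_sig
  opposed <- sign(cis) * sign(trans) < 0       # zero magnitudes -> not opposed
  label[all3 & !opposed] <- "cis_plus_trans"
  label[all3 & opposed] <- "cis_times_trans"
  label
}

#' Run the regulatory-divergence pipeline on an allele count table
#'
#' For every row (gene x hybrid individual) of a coverage-filtered allele
#' table, performs the three tests on depth-normalized counts, adjusts each
#' test's p-values by Benjamini-Hochberg, and classifies the pattern:
#'
#' * P: two-sided binomial on `(P2X, P2X + P4X)` with null 1/2 (after
#'   normalization the parent libraries are equal-depth).
#' * H: two-sided binomial on `(H2X, H2X + H4X)`. With
#'   `null = "dosage"` the null probability is the dosage baseline
#'   `1/(1+k)` with per-chromosome `k` (from `k_by_chrom`, default 2
#'   everywhere); with `null = "fixed"` it is the hybrid libraries'
#'   size proportion, ignoring dosage.
#' * F: Fisher exact test on `rbind(c(P2X, P4X), c(H2X, H4X))`. With
#'   `dosage_adjust_fisher = TRUE`, `H4X` is divided by `k` (rounded) first,
#'   so that a pure-dosage gene is balanced and the test isolates regulatory
#'   change.
#'
#' @param table an [allele_count_table()], ideally already passed through
#'   [filter_ase_sites()] (applied here again using
#'   `config$min_parent_reads`).
#' @param config a [load_config()] list.
#' @param null `"dosage"` or `"fixed"` hybrid-test null.
#' @param k_by_chrom named vector of inherited tetraploid copies per
#'   chromosome (e.g. from [infer_copy_numbers()]); default 2 for all.
#' @param dosage_adjust_fisher divide `H4X` by `k` before the Fisher test.
#' @return List with `calls` (per-row data.frame: tests, magnitudes, label)
#'   and `summary` (label counts per individual).
#' @export
run_regulatory_divergence <- function(table, config = load_config(),
                                      null = c("dosage", "fixed"),
                                      k_by_chrom = NULL,
                                      dosage_adjust_fisher = TRUE) {
  null <- match.arg(null)
  tab <- filter_ase_sites(table, config$min_parent_reads)
  if (nrow(tab) == 0) .stopf("no rows pass the parental coverage filter")
  k <- rep(2, nrow(tab))
  if (!is.null(k_by_chrom)) {
    miss <- setdiff(unique(tab$chromosome), names(k_by_chrom))
    if (length(miss))
      .stopf("k_by_chrom has no entry for chromosome(s): %s",
             paste(miss, collapse = ", "))
    k <- as.numeric(k_by_chrom[tab$chromosome])
  }

  # Depth-normalize to the geometric-mean library size. The two parent
  # allele columns are separate libraries; H2X and H4X come from the same
  # hybrid library and must share one scale factor or the dosage ratio
  # they carry would be erased.
  h2_tot <- sum(tab$H2X)
  h4_tot <- sum(tab$H4X)
  lib <- c(sum(tab$P2X), sum(tab$P4X), h2_tot + h4_tot)
  if (any(lib == 0)) .stopf("an allele library has zero total reads")
  target <- .geomean(lib)
  P2n <- round(tab$P2X * target / lib[1])
  P4n <- round(tab$P4X * target / lib[2])
  H2n <- round(tab$H2X * target / lib[3])
  H4n <- round(tab$H4X * target / lib[3])

  p_H0 <- if (null == "dosage") 1 / (1 + k)
          else rep(h2_tot / (h2_tot + h4_tot), nrow(tab))
  H4f <- if (dosage_adjust_fisher) pmax(round(H4n / k), 0) else H4n

  n <- nrow(tab)
  pP <- pH <- pF <- numeric(n)
  for (i in seq_len(n)) {
    pP[i] <- binomial_two_sided(P2n[i], P2n[i] + P4n[i], 0.5)
    pH[i] <- binomial_two_sided(H2n[i], H2n[i] + H4n[i], p_H0[i])
    pF[i] <- fisher_2x2(P2n[i], P4n[i], H2n[i], H4f[i])
  }
  qP <- bh_adjust(pP)
  qH <- bh_adjust(pH)
  qF <- bh_adjust(pF)

  cis <- .log2_ratio(H2n, H4n) - log2(1 / k)
  trans <- .log2_ratio(P2n, P4n) - cis
  calls <- data.frame(
    gene_id = tab$gene_id, chromosome = tab$chromosome,
    individual = tab$individual,
    p_P = pP, p_H = pH, p_F = pF, q_P = qP, q_H = qH, q_F = qF,
    P_sig = qP < config$fdr, H_sig = qH < config$fdr, F_sig = qF < config$fdr,
    cis = cis, trans = trans, stringsAsFactors = FALSE)
  calls$label <- classify_regulatory(calls$P_sig, calls$H_sig, calls$F_sig,
                                     calls$cis, calls$trans)
  summary <- as.data.frame(table(individual = calls$individual,
                                 label = factor(calls$label,
                                                levels = .regulatory_call_levels)))
  names(summary)[3] <- "n"
  list(calls = calls, summary = summary,
       settings = list(null = null, dosage_adjust_fisher = dosage_adjust_fisher,
                       fdr = config$fdr))
}
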