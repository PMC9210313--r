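#' Simulate a fully labelled triploid family
#'
#' Draws a complete synthetic dataset for one diploid x tetraploid cross with
#' triploid progeny: a gene x sample count matrix, a per-progeny
#' allele-specific count table, phenotypes, and the ground-truth labels that
#' generated them. The generative model is:
#'
#' * Per-gene baseline relative expression is log-normal (mean 1), scaled by
#'   `mean_depth`; counts are negative binomial with dispersion `phi`
#'   (variance `mu + phi mu^2`), independently per replicate.
#' * Exactly `round(frac_de * n_genes)` genes carry a parental log2
#'   difference of magnitude `de_effect` (random sign). The hybrid mean
#'   follows the gene's inheritance label: the log2 midpoint (additive), one
#'   parent's level (P1/P2 dominant), or beyond the more extreme parent by
#'   `transgressive_effect` log2 units (over/underdominant).
#' * Each gene's parental divergence is decomposed into cis and trans
#'   components according to its regulatory label. The cis effect shifts the
#'   log-odds of the diploid allele in the hybrid away from the dosage
#'   baseline `1/(1+k)`; the trans effect only separates the parents.
#'   Compensatory genes have `cis = -trans != 0` and hence no net parental
#'   difference.
#' * Allele counts are multinomial thinnings of the gene-level counts
#'   (fraction `ase_fraction` of reads is allele-informative), so gene-level
#'   and allele-level tables are mutually consistent.
#' * On chromosomes named in `aneuploidy_events`, the tetraploid parent's
#'   expression scales by `c4/4` and the hybrid's by `(1+k)/3`, with hybrid
#'   diploid-allele baseline `1/(1+k)`; the euploid state is `c4 = 4`,
#'   `k = 2`.
#' * Phenotypes are linear in the standardized `log2(CPM+1)` expression of a
#'   random causal gene set plus Gaussian noise.
#'
#' @param config a [sim_config()] object.
#' @return A list with components `counts` ([count_matrix()]), `alleles`
#'   ([allele_count_table()]), `traits` ([trait_table()]), and `truth`, a list
#'   of `genes` (per-gene labels and effect sizes), `dosage` (true `(c4, k)`
#'   per chromosome x progeny) and `causal` (causal gene effects per trait).
#' @examples
#' fam <- simulate_family(sim_config(n_genes = 200, n_progeny = 2, seed = 1))
#' table(fam$truth$genes$inheritance)
#' @export
simulate_family <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_genes
  gene_id <- sprintf("gene%05d", seq_len(n))
  chromosome <- sprintf("chr%02d", ((seq_len(n) - 1L) %% config$n_chromosomes) + 1L)

  r <- exp(stats::rnorm(n, 0, config$expr_sdlog))
  r <- r / mean(r)

  ## --- inheritance labels and parental divergence -------------------------
  n_de <- round(config$frac_de * n)
  inheritance <- rep("conserved", n)
  de_idx <- sort(sample.int(n, n_de))
  nc <- setdiff(.inheritance_classes, "conserved")
  mix_nc <- config$class_mixture[intersect(nc, names(config$class_mixture))]
  if (n_de > 0) {
    if (sum(mix_nc) <= 0)
      .stopf("frac_de > 0 requires positive mass on non-conserved classes in class_mixture")
    alloc <- .largest_remainder(n_de, mix_nc)
    inheritance[de_idx] <- sample(rep(names(mix_nc), times = alloc))
  }
  d <- rep(0, n)                       # parental log2 divergence
  d[de_idx] <- sample(c(-1, 1), n_de, replace = TRUE) * config$de_effect

  ## --- regulatory labels, constrained to be consistent with d -------------
  regulatory <- rep("conserved", n)
  div_classes <- c("cis", "trans", "cis_plus_trans", "cis_times_trans")
  mix_div <- config$reg_mixture[intersect(div_classes, names(config$reg_mixture))]
  if (n_de > 0 && sum(mix_div) > 0) {
    alloc <- .largest_remainder(n_de, mix_div)
    regulatory[de_idx] <- sample(rep(names(mix_div), times = alloc))
  }
  nd_idx <- setdiff(seq_len(n), de_idx)
  mix_nd <- config$reg_mixture[intersect(c("conserved", "compensatory"),
                                         names(config$reg_mixture))]
  if (length(nd_idx) > 0 && sum(mix_nd) > 0) {
    alloc <- .largest_remainder(length(nd_idx), mix_nd)
    regulatory[nd_idx] <- sample(rep(names(mix_nd), times = alloc))
  }
  eff <- .split_cis_trans(regulatory, d, comp_effect = config$de_effect / 2)

  ## --- chromosome dosage states -------------------------------------------
  chrom_levels <- sprintf("chr%02d", seq_len(config$n_chromosomes))
  c4 <- stats::setNames(rep(4L, config$n_chromosomes), chrom_levels)
  k <- stats::setNames(rep(2L, config$n_chromosomes), chrom_levels)
  for (ev in config$aneuploidy_events) {
    if (!ev$chromosome %in% chrom_levels)
      .stopf("aneuploidy event names unknown chromosome '%s'", ev$chromosome)
    c4[ev$chromosome] <- as.integer(ev$c4)
    k[ev$chromosome] <- as.integer(ev$k)
  }
  g_c4 <- c4[chromosome]
  g_k <- k[chromosome]

  ## --- gene-level means ----------------------------------------------------
  depth <- config$mean_depth
  mu1 <- depth * r * 2^(d / 2)         # diploid parent
  mu2 <- depth * r * 2^(-d / 2)        # tetraploid parent, before dosage scaling
  hyb <- .hybrid_mean(inheritance, mu1, mu2, config$transgressive_effect)
  mu2_dos <- mu2 * g_c4 / 4
  hyb_dos <- hyb * (1 + g_k) / 3

  ## --- count matrix --------------------------------------------------------
  nr <- config$n_replicates
  phi <- config$dispersion
  prog_ids <- sprintf("H%02d", seq_len(config$n_progeny))
  genotypes <- c("P1", "P2", prog_ids)
  roles <- c("P1", "P2", rep("progeny", config$n_progeny))
  cols <- list()
  meta <- list()
  balance <- stats::rnorm(config$n_progeny, 0, config$segregation_sd)
  for (gi in seq_along(genotypes)) {
    mu <- switch(roles[gi], P1 = mu1, P2 = mu2_dos, progeny = hyb_dos)
    if (roles[gi] == "progeny") {
      # shared segregation of the divergent parental backgrounds, then the
      # biological individuality of each sib; both shared by its replicates
      b <- balance[gi - 2L]
      if (b != 0) mu <- mu * 2^(b * d / 2)
      if (config$indiv_sdlog > 0)
        mu <- mu * exp(stats::rnorm(n, 0, config$indiv_sdlog))
    }
    for (rep_i in seq_len(nr)) {
      sid <- sprintf("%s_r%d", genotypes[gi], rep_i)
      cols[[sid]] <- .rnb(n, mu, phi)
      meta[[sid]] <- data.frame(sample_id = sid, genotype = genotypes[gi],
                                role = roles[gi], family = "F1",
                                replicate = rep_i, stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(cbind, cols)
  rownames(counts) <- gene_id
  storage.mode(counts) <- "integer"
  samples <- do.call(rbind, meta)
  rownames(samples) <- NULL
  genes <- data.frame(gene_id = gene_id, chromosome = chromosome,
                      stringsAsFactors = FALSE)
  cm <- count_matrix(counts, genes, samples)

  ## --- allele counts by multinomial thinning ------------------------------
  p1_tot <- as.integer(rowSums(counts[, samples$role == "P1", drop = FALSE]))
  p2_tot <- as.integer(rowSums(counts[, samples$role == "P2", drop = FALSE]))
  P2X <- stats::rbinom(n, p1_tot, config$ase_fraction)
  P4X <- stats::rbinom(n, p2_tot, config$ase_fraction)
  ak <- list()
  for (pid in prog_ids) {
    htot <- as.integer(rowSums(counts[, samples$genotype == pid, drop = FALSE]))
    hase <- stats::rbinom(n, htot, config$ase_fraction)
    p_dip <- 1 / (1 + g_k * 2^(-eff$cis))
    H2X <- stats::rbinom(n, hase, p_dip)
    ak[[pid]] <- data.frame(gene_id = gene_id, chromosome = chromosome,
                            individual = pid, P2X = P2X, P4X = P4X,
                            H2X = H2X, H4X = hase - H2X,
                            stringsAsFactors = FALSE)
  }
  alleles <- allele_count_table(do.call(rbind, ak))
  rownames(alleles) <- NULL

  ## --- phenotypes -----------------------------------------------------------
  geno_cpm <- genotype_cpm(cm)
  z <- .standardize_rows(log2(geno_cpm + 1))
  causal_sets <- list()
  trait_rows <- list()
  trait_classes <- c("biomass", "stem growth", "leaf growth", "architecture",
                     "composition")
  causal_pool <- if (config$causal_from_de && length(de_idx) >= config$causal_set_size)
    de_idx else seq_len(n)
  causal <- sample(causal_pool, config$causal_set_size)
  for (t in seq_len(config$n_traits)) {
    beta <- stats::rnorm(config$causal_set_size, 0, config$effect_sd)
    y <- config$trait_baseline +
      as.numeric(crossprod(z[causal, , drop = FALSE], beta)) +
      stats::rnorm(length(genotypes), 0, config$noise_sd)
    tname <- sprintf("trait%02d", t)
    causal_sets[[t]] <- data.frame(trait = tname, gene_id = gene_id[causal],
                                   effect = beta, stringsAsFactors = FALSE)
    trait_rows[[t]] <- data.frame(trait = tname,
                                  trait_class = trait_classes[(t - 1) %% 5 + 1],
                                  genotype = genotypes, value = y,
                                  trial = "synthetic", timepoint = 1L,
                                  stringsAsFactors = FALSE)
  }
  traits <- trait_table(do.call(rbind, trait_rows))
  rownames(traits) <- NULL

  truth <- list(
    genes = data.frame(gene_id = gene_id, chromosome = chromosome,
                       inheritance = inheritance, regulatory = regulatory,
                       parent_effect = d, cis_effect = eff$cis,
                       trans_effect = eff$trans, stringsAsFactors = FALSE),
    dosage = expand.grid(chromosome = chrom_levels, individual = prog_ids,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE),
    causal = do.call(rbind, causal_sets))
  truth$dosage$c4 <- c4[truth$dosage$chromosome]
  truth$dosage$k <- k[truth$dosage$chromosome]

  list(counts = cm, alleles = alleles, traits = traits, truth = truth)
}

#' @noRd
#' Decompose parental divergence d into (cis, trans) per regulatory label.
#' Divergent classes split d; compensatory genes get offsetting effects of
#' magnitude comp_effect even though d = 0.
.split_cis_trans <- function(regulatory, d, comp_effect) {
  n <- length(regulatory)
  cis <- numeric(n)
  trans <- numeric(n)
  i <- regulatory == "cis"
  cis[i] <- d[i]
  i <- regulatory == "trans"
  trans[i] <- d[i]
  i <- regulatory == "cis_plus_trans"
  a <- stats::runif(sum(i), 0.3, 0.7)           # same-sign split of d
  cis[i] <- a * d[i]
  trans[i] <- (1 - a) * d[i]
  i <- regulatory == "cis_times_trans"
  g <- stats::runif(sum(i), 0.3, 0.7)           # opposite signs, still sum to d
  cis[i] <- (1 + g) * d[i]
  trans[i] <- -g * d[i]
  i <- regulatory == "compensatory"
  s <- sample(c(-1, 1), sum(i), replace = TRUE)
  cis[i] <- s * comp_effect
  trans[i] <- -cis[i]
  list(cis = cis, trans = trans)
}

#' @noRd
.hybrid_mean <- function(label, mu1, mu2, te) {
  h <- sqrt(mu1 * mu2)                 # log2 midpoint; also the conserved level
  h[label == "P1_dominant"] <- mu1[label == "P1_dominant"]
  h[label == "P2_dominant"] <- mu2[label == "P2_dominant"]
  i <- label == "overdominant"
  h[i] <- pmax(mu1[i], mu2[i]) * 2^te
  i <- label == "underdominant"
  h[i] <- pmin(mu1[i], mu2[i]) * 2^(-te)
  h
}

#' @noRd
.standardize_rows <- function(m) {
  mu <- rowMeans(m)
  sd <- apply(m, 1, stats::sd)
  sd[sd == 0] <- 1
  (m - mu) / sd
}

#' Simulate allele counts for one gene under a known regulatory mode
#'
#' Single-gene inverse of the regulatory-divergence classifier: parent allele
#' counts are Poisson with log2 ratio `cis_effect + trans_effect`; hybrid
#' allele counts are binomial thinnings of a Poisson total with diploid-allele
#' probability `1 / (1 + k 2^(-cis_effect))`, i.e. the dosage baseline
#' `1/(1+k)` shifted by the cis effect on the log-odds scale.
#'
#' @param reg_class one of [regulatory_classes()].
#' @param cis_effect,trans_effect signed effects in log2 units. The class
#'   constrains them: `"conserved"` requires both 0, `"cis"` requires
#'   `trans_effect = 0`, `"trans"` requires `cis_effect = 0`,
#'   `"compensatory"` requires `cis_effect = -trans_effect != 0`.
#' @param depth expected allele-informative reads per parent library.
#' @param k tetraploid-parent copies inherited by the hybrid (1, 2 or 3).
#' @param seed integer seed.
#' @return Named integer vector `c(P2X, P4X, H2X, H4X)`.
#' @examples
#' simulate_allele_counts("cis", 2, 0, depth = 1000, k = 2, seed = 1)
#' @export
simulate_allele_counts <- function(reg_class, cis_effect, trans_effect,
                                   depth, k = 2L, seed = 1L) {
  if (!reg_class %in% .regulatory_classes)
    .stopf("unknown regulatory class '%s'", reg_class)
  if (depth <= 0) .stopf("depth must be positive")
  if (!k %in% 1:3) .stopf("k must be 1, 2 or 3")
  tol <- 1e-12
  ok <- switch(reg_class,
    conserved = abs(cis_effect) < tol && abs(trans_effect) < tol,
    cis = abs(trans_effect) < tol,
    trans = abs(cis_effect) < tol,
    compensatory = abs(cis_effect + trans_effect) < tol && abs(cis_effect) > tol,
    TRUE)
  if (!ok)
    .stopf("effects (cis = %g, trans = %g) are inconsistent with class '%s'",
           cis_effect, trans_effect, reg_class)
  set.seed(seed)
  d <- cis_effect + trans_effect
  P2X <- stats::rpois(1, depth * 2^(d / 2))
  P4X <- stats::rpois(1, depth * 2^(-d / 2))
  htot <- stats::rpois(1, depth * (1 + k) / 3)
  p_dip <- 1 / (1 + k * 2^(-cis_effect))
  H2X <- stats::rbinom(1, htot, p_dip)
  c(P2X = P2X, P4X = P4X, H2X = H2X, H4X = htot - H2X)
}

#' Simulate allele counts for one chromosome under a dosage scenario
#'
#' Generates an [allele_count_table()] for a single chromosome of a single
#' triploid individual whose tetraploid parent carries `c4` copies (of the
#' euploid 4) and who inherited `k` of them (plus one diploid-parent copy).
#' Relative to a library-normalized genome baseline, the tetraploid parent's
#' per-gene expression scales by `c4/4`, the hybrid total by `(1+k)/3`, and
#' the hybrid's diploid-allele fraction is `1/(1+k)`. No cis or trans
#' regulatory effects are planted.
#'
#' @param c4 tetraploid-parent copy number, 1..4.
#' @param k copies inherited by the hybrid, 1..min(3, c4).
#' @param n_genes number of genes on the chromosome.
#' @param depth expected allele-informative reads per gene per parent library.
#' @param dispersion NB dispersion phi (0 gives Poisson totals).
#' @param seed integer seed.
#' @param chromosome,individual labels used in the returned table.
#' @param expr_sdlog spread of the log-normal per-gene baseline.
#' @return An [allele_count_table()] with `n_genes` rows.
#' @examples
#' tab <- simulate_dosage_scenario(4, 2, n_genes = 100, depth = 200,
#'                                 dispersion = 0.05, seed = 1)
#' stats::median(with(tab, 100 * H2X / (H2X + H4X)), na.rm = TRUE)  # ~ 33.3
#' @export
simulate_dosage_scenario <- function(c4, k, n_genes, depth, dispersion = 0.05,
                                     seed = 1L, chromosome = "chr01",
                                     individual = "H01", expr_sdlog = 1) {
  if (!c4 %in% 1:4) .stopf("c4 must be in 1..4")
  if (!k %in% 1:3) .stopf("k must be in 1..3")
  if (k > c4)
    .stopf("k = %d > c4 = %d: the hybrid cannot inherit more copies than the tetraploid parent has",
           k, c4)
  if (depth <= 0) .stopf("depth must be positive")
  if (dispersion < 0) .stopf("dispersion must be non-negative")
  set.seed(seed)
  r <- exp(stats::rnorm(n_genes, 0, expr_sdlog))
  r <- r / mean(r)
  P2X <- .rnb(n_genes, depth * r, dispersion)
  P4X <- .rnb(n_genes, depth * r * c4 / 4, dispersion)
  htot <- .rnb(n_genes, depth * r * (1 + k) / 3, dispersion)
  H2X <- stats::rbinom(n_genes, htot, 1 / (1 + k))
  allele_count_table(data.frame(
    gene_id = sprintf("gene%05d", seq_len(n_genes)),
    chromosome = chromosome, individual = individual,
    P2X = P2X, P4X = P4X, H2X = H2X, H4X = htot - H2X,
    stringsAsFactors = FALSE))
}
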