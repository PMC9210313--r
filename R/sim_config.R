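#' Simulation configuration for a synthetic triploid family
#'
#' Bundles every knob of the synthetic-data generator. The defaults describe a
#' family resembling the study system the package targets: a diploid (2x) and
#' a tetraploid (4x) parent crossed to give triploid (3x) progeny, each
#' genotype sequenced with 3 biological replicates of bulk RNA-Seq.
#'
#' Genes are assigned one inheritance label and one regulatory-divergence
#' label. `frac_de` fixes, exactly, the number of genes with a planted
#' expression difference between the parents; those genes receive
#' non-conserved inheritance labels in the proportions of `class_mixture`
#' (restricted to its non-conserved entries) and regulatory labels from the
#' divergence-requiring classes of `reg_mixture`. Genes without parental
#' divergence are conserved or compensatory (offsetting cis and trans
#' effects). Aneuploidy events replace the euploid chromosome state
#' (`c4 = 4` copies in the tetraploid parent, `k = 2` of them inherited) on
#' selected chromosomes.
#'
#' @param n_genes number of genes.
#' @param n_chromosomes number of chromosomes; genes are spread evenly.
#' @param n_progeny number of triploid progeny individuals.
#' @param n_replicates biological replicates per genotype (>= 2).
#' @param mean_depth expected reads per gene in a library (counts).
#' @param dispersion negative-binomial dispersion phi, Var = mu + phi mu^2.
#' @param frac_de proportion of genes differentially expressed between the
#'   parents, in `[0, 1]`.
#' @param class_mixture named proportions over [inheritance_classes()];
#'   must sum to 1.
#' @param reg_mixture named proportions over [regulatory_classes()];
#'   must sum to 1.
#' @param aneuploidy_events list of `list(chromosome =, c4 =, k =)` entries,
#'   applied to every progeny individual. `c4` in 1..4 is the chromosome copy
#'   number of the tetraploid parent; `k` in 1..3 the number of those copies
#'   inherited by the hybrid; `k <= c4` is required.
#' @param causal_set_size number of genes driving the synthetic phenotypes.
#' @param causal_from_de draw the causal genes from the parent-DE set when it
#'   is large enough (default `TRUE`): heterosis is then driven by genes whose
#'   expression diverges between the parents. `FALSE` samples causal genes
#'   from all genes.
#' @param effect_sd standard deviation of causal effect sizes (trait units
#'   per standardized-expression unit).
#' @param noise_sd standard deviation of phenotype noise (trait units).
#' @param trait_baseline mean trait value (trait units) added to every
#'   genotype's phenotype. Keeping it well away from zero makes
#'   midparent-percent heterosis well defined and numerically stable, as for
#'   positive traits like biomass or height.
#' @param de_effect magnitude (log2 units) of the planted parental expression
#'   difference for differentially expressed genes.
#' @param transgressive_effect extra log2 shift of the hybrid beyond the more
#'   extreme parent for over/underdominant genes.
#' @param ase_fraction fraction of a gene's reads overlapping
#'   parent-diagnostic sites, i.e. usable for allele-specific counts.
#' @param expr_sdlog standard deviation of the log-normal distribution of
#'   per-gene baseline relative expression.
#' @param indiv_sdlog standard deviation (natural-log scale) of the per-gene,
#'   per-progeny biological deviation from the family mean, shared by an
#'   individual's replicates. Without it progeny would be
#'   expression-identical and phenotypic variation among them pure noise.
#' @param segregation_sd standard deviation of a per-progeny parental-balance
#'   factor: each sib `i` draws `b_i ~ N(0, segregation_sd)` and every
#'   parent-DE gene's expression shifts by `b_i * d_g / 2` log2 units toward
#'   the diploid (`b_i > 0`) or tetraploid parent. This models the shared
#'   segregation of divergent regulatory backgrounds that makes parent-DE
#'   genes co-vary across sibs; set 0 for archetypal class expression.
#' @param n_traits number of synthetic phenotypes.
#' @param seed integer seed; identical configurations reproduce identical
#'   families byte for byte.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_family()]
#' @export
sim_config <- function(n_genes = 2000L,
                       n_chromosomes = 19L,
                       n_progeny = 10L,
                       n_replicates = 3L,
                       mean_depth = 200,
                       dispersion = 0.05,
                       frac_de = 0.2,
                       class_mixture = c(conserved = 0.80, additive = 0.10,
                                         P1_dominant = 0.04, P2_dominant = 0.04,
                                         overdominant = 0.01, underdominant = 0.01),
                       reg_mixture = c(conserved = 0.70, cis = 0.10, trans = 0.10,
                                       cis_plus_trans = 0.04, cis_times_trans = 0.03,
                                       compensatory = 0.03),
                       aneuploidy_events = list(),
                       causal_set_size = 50L,
                       causal_from_de = TRUE,
                       effect_sd = 1,
                       noise_sd = 0.5,
                       trait_baseline = 100,
                       de_effect = 3,
                       transgressive_effect = 2,
                       ase_fraction = 0.3,
                       expr_sdlog = 1,
                       indiv_sdlog = 0.25,
                       segregation_sd = 0.3,
                       n_traits = 3L,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_chromosomes = as.integer(n_chromosomes),
              n_progeny = as.integer(n_progeny),
              n_replicates = as.integer(n_replicates),
              mean_depth = mean_depth,
              dispersion = dispersion,
              frac_de = frac_de,
              class_mixture = class_mixture,
              reg_mixture = reg_mixture,
              aneuploidy_events = aneuploidy_events,
              causal_set_size = as.integer(causal_set_size),
              causal_from_de = isTRUE(causal_from_de),
              effect_sd = effect_sd,
              noise_sd = noise_sd,
              trait_baseline = trait_baseline,
              de_effect = de_effect,
              transgressive_effect = transgressive_effect,
              ase_fraction = ase_fraction,
              expr_sdlog = expr_sdlog,
              indiv_sdlog = indiv_sdlog,
              segregation_sd = segregation_sd,
              n_traits = as.integer(n_traits),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks ranges, mixture normalization and aneuploidy-event feasibility.
#' Called by [sim_config()]; exported so hand-built configurations can be
#' checked too.
#'
#' @param cfg a `sim_config` object.
#' @return `cfg`, invisibly, if valid; otherwise an error.
#' @export
validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_genes < 1) .stopf("n_genes must be positive")
    if (n_chromosomes < 1) .stopf("n_chromosomes must be positive")
    if (n_progeny < 1) .stopf("n_progeny must be positive")
    if (n_replicates < 2) .stopf("n_replicates must be >= 2")
    if (mean_depth <= 0) .stopf("mean_depth must be positive")
    if (dispersion < 0) .stopf("dispersion must be non-negative")
    if (frac_de < 0 || frac_de > 1) .stopf("frac_de must be in [0, 1]")
    if (causal_set_size < 0 || causal_set_size > n_genes)
      .stopf("causal_set_size must be in [0, n_genes]")
    if (effect_sd < 0 || noise_sd < 0) .stopf("effect_sd/noise_sd must be >= 0")
    if (ase_fraction <= 0 || ase_fraction > 1)
      .stopf("ase_fraction must be in (0, 1]")
  })
  .check_mixture(cfg$class_mixture, .inheritance_classes, "class_mixture")
  .check_mixture(cfg$reg_mixture, .regulatory_classes, "reg_mixture")
  for (ev in cfg$aneuploidy_events) {
    if (!all(c("chromosome", "c4", "k") %in% names(ev)))
      .stopf("aneuploidy event must have fields chromosome, c4, k")
    if (!(ev$c4 %in% 1:4)) .stopf("aneuploidy event: c4 must be in 1..4")
    if (!(ev$k %in% 1:3)) .stopf("aneuploidy event: k must be in 1..3")
    if (ev$k > ev$c4)
      .stopf("aneuploidy event on %s: k = %d > c4 = %d is an impossible inheritance",
             ev$chromosome, ev$k, ev$c4)
  }
  invisible(cfg)
}

.check_mixture <- function(mix, vocab, what) {
  if (is.null(names(mix)) || !all(names(mix) %in% vocab))
    .stopf("%s must be named with labels among: %s", what,
           paste(vocab, collapse = ", "))
  if (any(mix < 0) || any(mix > 1))
    .stopf("%s proportions must lie in [0, 1]", what)
  if (abs(sum(mix) - 1) > 1e-9)
    .stopf("%s proportions must sum to 1 (got %.12f)", what, sum(mix))
  invisible(mix)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic triploid-family configuration\n")
  cat(sprintf("  %d genes on %d chromosomes; %d progeny x %d replicates\n",
              x$n_genes, x$n_chromosomes, x$n_progeny, x$n_replicates))
  cat(sprintf("  mean depth %g, NB dispersion %g, %.0f%% parent-DE genes\n",
              x$mean_depth, x$dispersion, 100 * x$frac_de))
  if (length(x$aneuploidy_events))
    cat(sprintf("  %d aneuploidy event(s)\n", length(x$aneuploidy_events)))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}
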