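make_allele_rows <- function(P2X, P4X, H2X, H4X) {
  allele_count_table(data.frame(
    gene_id = sprintf("g%03d", seq_along(P2X)), chromosome = "chr01",
    individual = "H01", P2X = P2X, P4X = P4X, H2X = H2X, H4X = H4X))
}

test_that("the parental coverage filter is an inclusive boundary at 20", {
  tab <- make_allele_rows(P2X = c(10, 20, 15), P4X = c(9, 0, 5),
                          H2X = c(5, 5, 5), H4X = c(10, 10, 10))
  kept <- filter_ase_sites(tab)
  expect_setequal(kept$gene_id, c("g002", "g003"))  # sums 20 and 20; 19 removed
  # planted sub-threshold rows are removed exactly
  set.seed(31)
  p2 <- c(rep(30L, 900), rep(4L, 100))
  p4 <- c(rep(30L, 900), rep(5L, 100))
  big <- make_allele_rows(p2, p4, rep(10L, 1000), rep(20L, 1000))
  expect_identical(nrow(filter_ase_sites(big)), 900L)
})

test_that("two-sided binomial matches direct enumeration", {
  expect_equal(binomial_two_sided(5, 10, 0.5), 1.0)
  expect_equal(binomial_two_sided(0, 10, 0.5), 2 / 1024, tolerance = 1e-12)
  expect_equal(binomial_two_sided(10, 30, 1 / 3), 1.0)
  expect_equal(binomial_two_sided(0, 0, 0.5), 1)
  expect_error(binomial_two_sided(5, 10, 0), "p0")
  set.seed(33)
  for (i in 1:30) {
    n <- sample(1:60, 1)
    k <- sample(0:n, 1)
    p0 <- runif(1, 0.1, 0.9)
    expect_equal(binomial_two_sided(k, n, p0), oracle_binom_two_sided(k, n, p0),
                 tolerance = 1e-9)
  }
})

test_that("Fisher 2x2 matches hypergeometric enumeration", {
  expect_equal(fisher_2x2(5, 5, 5, 5), 1.0)
  expect_equal(fisher_2x2(10, 0, 0, 10), 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(fisher_2x2(2, 3, 4, 1), oracle_fisher_2x2(2, 3, 4, 1),
               tolerance = 1e-9)
  expect_equal(fisher_2x2(0, 0, 0, 0), 1)
  expect_error(fisher_2x2(-1, 2, 3, 4), "non-negative")
  set.seed(35)
  for (i in 1:30) {
    cells <- sample(0:25, 4, replace = TRUE)
    if (sum(cells) == 0) next
    expect_equal(do.call(fisher_2x2, as.list(cells)),
                 do.call(oracle_fisher_2x2, as.list(cells)), tolerance = 1e-9)
  }
})

test_that("the eight significance patterns map to their regulatory classes", {
  pat <- expand.grid(P = c(TRUE, FALSE), H = c(TRUE, FALSE), F = c(TRUE, FALSE))
  lab <- classify_regulatory(pat$P, pat$H, pat$F,
                             cis = rep(1, 8), trans = rep(0.5, 8))
  byname <- function(P, H, F) lab[pat$P == P & pat$H == H & pat$F == F]
  expect_identical(byname(TRUE, TRUE, FALSE), "cis")
  expect_identical(byname(TRUE, FALSE, TRUE), "trans")
  expect_identical(byname(FALSE, TRUE, TRUE), "compensatory")
  expect_identical(byname(TRUE, TRUE, TRUE), "cis_plus_trans")  # same signs
  expect_identical(byname(FALSE, FALSE, FALSE), "conserved")
  expect_identical(byname(TRUE, FALSE, FALSE), "ambiguous")
  expect_identical(byname(FALSE, TRUE, FALSE), "ambiguous")
  expect_identical(byname(FALSE, FALSE, TRUE), "ambiguous")
  # opposed signs flip the all-significant case to cis x trans
  expect_identical(classify_regulatory(TRUE, TRUE, TRUE, 1, -0.5),
                   "cis_times_trans")
  # a zero magnitude is a tie, broken toward cis + trans
  expect_identical(classify_regulatory(TRUE, TRUE, TRUE, 1, 0),
                   "cis_plus_trans")
})

test_that("all-conserved input yields overwhelmingly conserved calls", {
  # dispersion 0: the binomial/Fisher tests are calibrated for read-sampling
  # noise, which is what an all-null allele table should contain
  tab <- simulate_dosage_scenario(4, 2, n_genes = 800, depth = 300,
                                  dispersion = 0, seed = 37)
  res <- run_regulatory_divergence(tab)
  expect_gte(mean(res$calls$label == "conserved"), 0.99)
})

test_that("planted cis and compensatory genes are recovered at high depth", {
  set.seed(39)
  n_each <- 60
  rows <- list()
  plant <- function(class, cis, trans, i) {
    x <- simulate_allele_counts(class, cis, trans, depth = 500, k = 2,
                                seed = 1000 + i)
    data.frame(gene_id = sprintf("%s_%03d", class, i), chromosome = "chr01",
               individual = "H01", P2X = x["P2X"], P4X = x["P4X"],
               H2X = x["H2X"], H4X = x["H4X"])
  }
  for (i in seq_len(n_each)) {
    rows[[length(rows) + 1]] <- plant("conserved", 0, 0, i)
    rows[[length(rows) + 1]] <- plant("cis", sample(c(-2, 2), 1), 0, i)
    rows[[length(rows) + 1]] <- plant("compensatory", 1.5, -1.5, i)
  }
  tab <- allele_count_table(do.call(rbind, rows))
  res <- run_regulatory_divergence(tab)
  lab <- res$calls$label
  planted <- sub("_[0-9]+$", "", res$calls$gene_id)
  expect_gte(mean(lab[planted == "cis"] == "cis"), 0.9)
  expect_gte(mean(lab[planted == "compensatory"] == "compensatory"), 0.9)
  expect_gte(mean(lab[planted == "conserved"] == "conserved"), 0.95)
})

test_that("classification is invariant to allele relabelling at k = 1", {
  tab <- simulate_dosage_scenario(4, 1, n_genes = 300, depth = 300,
                                  dispersion = 0.05, seed = 41)
  swapped <- tab
  swapped$P2X <- tab$P4X; swapped$P4X <- tab$P2X
  swapped$H2X <- tab$H4X; swapped$H4X <- tab$H2X
  k1 <- c(chr01 = 1)
  a <- run_regulatory_divergence(tab, k_by_chrom = k1)
  b <- run_regulatory_divergence(swapped, k_by_chrom = k1)
  expect_identical(a$calls$label, b$calls$label)
  expect_equal(a$calls$cis, -b$calls$cis, tolerance = 1e-9)
})

test_that("dosage-aware hybrid null controls false positives where the naive null does not", {
  # pure dosage, no regulatory effects: a euploid background (k = 2) plus one
  # replete chromosome (k = 3) whose diploid allele carries only 1/4 of the
  # hybrid reads. The genome-wide library-size proportion sits near 1/3, so
  # the naive fixed null declares the dosage shift "significant" across the
  # replete chromosome; the per-chromosome 1/(1+k) null does not.
  bg <- simulate_dosage_scenario(4, 2, n_genes = 1400, depth = 500,
                                 dispersion = 0.05, seed = 43,
                                 chromosome = "chr02")
  ev <- simulate_dosage_scenario(4, 3, n_genes = 600, depth = 500,
                                 dispersion = 0.05, seed = 44,
                                 chromosome = "chr01")
  ev$gene_id <- paste0("ev_", ev$gene_id)
  tab <- allele_count_table(rbind(as.data.frame(bg), as.data.frame(ev)))
  kmap <- c(chr01 = 3, chr02 = 2)
  aware <- run_regulatory_divergence(tab, null = "dosage", k_by_chrom = kmap)
  naive <- run_regulatory_divergence(tab, null = "fixed")
  on_ev <- aware$calls$chromosome == "chr01"
  expect_lte(mean(aware$calls$H_sig[on_ev]), 0.01)
  # inflation: well above ten times the nominal FDR on the replete chromosome
  expect_gt(mean(naive$calls$H_sig[naive$calls$chromosome == "chr01"]), 0.05)
})
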