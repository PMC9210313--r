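test_that("cpm normalizes every library to one million", {
  m <- matrix(c(1L, 1L, 0L, 0L, 1L, 3L), nrow = 3,
              dimnames = list(c("a", "b", "z"), c("s1", "s2")))
  out <- cpm(m)
  expect_equal(out["a", "s1"], 5e5)
  expect_equal(out["z", "s1"], 0)
  expect_equal(unname(colSums(out)), c(1e6, 1e6), tolerance = 1e-9)
  set.seed(1)
  r <- matrix(rpois(200, 20), 20, 10,
              dimnames = list(sprintf("g%d", 1:20), sprintf("s%d", 1:10)))
  expect_equal(unname(colSums(cpm(r))), rep(1e6, 10), tolerance = 1e-6)
  r[, 1] <- 0L
  expect_error(cpm(r), "zero-depth")
})

test_that("CPM filter keeps genes expressed in all replicates of one group", {
  cm <- matrix(c(0, 0, 0, 0,      # never expressed
                 2, 2, 0, 0,      # expressed in all of group A
                 2, 0, 2, 0,      # never in a full group
                 5, 5, 5, 5),     # everywhere
               nrow = 4, byrow = TRUE,
               dimnames = list(c("g0", "gA", "gM", "gE"),
                               c("a1", "a2", "b1", "b2")))
  kept <- filter_min_cpm(cm, threshold = 1,
                         groups = list(c("a1", "a2"), c("b1", "b2")))
  expect_setequal(kept, c("gA", "gE"))
  # planted always-zero genes are removed exactly
  fam <- simulate_family(sim_config(n_genes = 400, n_progeny = 2, seed = 13))
  mat <- cpm(fam$counts)
  zeros <- matrix(0, 100, ncol(mat),
                  dimnames = list(sprintf("zero%03d", 1:100), colnames(mat)))
  aug <- rbind(mat, zeros)
  kept <- filter_min_cpm(aug, threshold = 1, min_samples = 1)
  expect_identical(sum(!rownames(aug) %in% kept & grepl("^zero", rownames(aug))), 100L)
})

test_that("common dispersion estimation recovers the truth and its limits", {
  # identical replicates within every group: no overdispersion
  counts <- cbind(a = c(10, 50, 100), b = c(10, 50, 100),
                  c = c(20, 40, 90), d = c(20, 40, 90))
  expect_lte(estimate_common_dispersion(counts, c("A", "A", "B", "B")), 1e-4)
  expect_lte(estimate_common_dispersion(matrix(c(10, 10, 10, 10), 1),
                                        c("A", "A", "B", "B")), 1e-6)
  expect_error(estimate_common_dispersion(counts, c("A", "B", "C", "D")),
               "replicates")
  # parameter recovery at phi = 0.2
  set.seed(4)
  mu <- exp(rnorm(2000, log(200), 1))
  y <- cbind(rnbinom(2000, mu = mu, size = 5), rnbinom(2000, mu = mu, size = 5),
             rnbinom(2000, mu = mu, size = 5))
  phi <- estimate_common_dispersion(y, rep("A", 3))
  expect_gt(phi, 0.16)
  expect_lt(phi, 0.24)
})

test_that("common dispersion agrees with the edgeR reference estimator", {
  set.seed(6)
  mu <- exp(rnorm(1000, log(150), 1))
  y <- sapply(1:6, function(i) rnbinom(1000, mu = mu, size = 10))
  grp <- rep(c("A", "B"), each = 3)
  phi <- estimate_common_dispersion(y, grp)
  ref <- edgeR::estimateCommonDisp(edgeR::DGEList(counts = y, group = grp))$common.dispersion
  expect_equal(phi, ref, tolerance = 0.15)
})

test_that("NB exact test: symmetry, degenerate cases, and extreme separation", {
  expect_equal(nb_exact_test(c(5, 5), c(5, 5), phi = 0.1)$p, 1)
  expect_equal(nb_exact_test(c(0, 0), c(0, 0), phi = 0.1),
               list(log2FC = 0, p = 1))
  t1 <- nb_exact_test(c(40, 60), c(10, 15), phi = 0.08)
  t2 <- nb_exact_test(c(10, 15), c(40, 60), phi = 0.08)
  expect_equal(t1$p, t2$p, tolerance = 1e-12)
  expect_equal(t1$log2FC, -t2$log2FC, tolerance = 1e-12)
  expect_lt(nb_exact_test(100, 0, phi = 0.1)$p, 1e-6)
})

test_that("NB exact test at phi = 0 equals the conditional binomial oracle", {
  set.seed(2)
  for (i in 1:40) {
    a <- sample(0:120, 1)
    b <- sample(0:80, 1)
    if (a + b == 0) next
    got <- nb_exact_test(a, b, phi = 0)$p
    expect_equal(got, oracle_poisson_exact(a, b, 1, 1), tolerance = 1e-10)
    # unequal replicate numbers condition on a binomial with p = nA/(nA+nB)
    got2 <- nb_exact_test(c(a, 0, a), b, phi = 0)$p
    expect_equal(got2, oracle_poisson_exact(2 * a, b, 3, 1), tolerance = 1e-10)
  }
})

test_that("NB exact test tracks the edgeR exact test at matched dispersion", {
  set.seed(9)
  n <- 300
  mu <- exp(rnorm(n, log(100), 1))
  fc <- ifelse(seq_len(n) <= 30, 4, 1)
  y <- cbind(rnbinom(n, mu = mu, size = 10), rnbinom(n, mu = mu, size = 10),
             rnbinom(n, mu = mu * fc, size = 10), rnbinom(n, mu = mu * fc, size = 10))
  rownames(y) <- sprintf("g%03d", seq_len(n))
  lib <- colSums(y)
  ours <- sapply(seq_len(n), function(i)
    nb_exact_test(y[i, 1:2], y[i, 3:4], phi = 0.1, lib[1:2], lib[3:4])$p)
  d <- edgeR::DGEList(counts = y, group = c("A", "A", "B", "B"),
                      norm.factors = rep(1, 4))
  d$common.dispersion <- 0.1
  ref <- edgeR::exactTest(d, pair = c("B", "A"),
                          rejection.region = "smallp")$table$PValue
  # same conditional construction; small differences come from pseudo-count
  # rounding, so compare on the log scale with a loose band
  expect_gt(cor(log10(ours + 1e-300), log10(ref + 1e-300)), 0.98)
  expect_equal(mean(ours < 0.005), mean(ref < 0.005), tolerance = 0.03)
})

test_that("BH adjustment reproduces the hand-computed step-up", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.216)
  expect_equal(bh_adjust(p),
               rev(cummin(rev(sort(p) * 10 / (1:10))))[rank(p)],
               tolerance = 1e-12)
  expect_error(bh_adjust(c(0.1, NaN)), "finite")
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("identical groups give zero significant genes", {
  fam <- simulate_family(sim_config(n_genes = 200, n_progeny = 2, frac_de = 0,
                                    seed = 17))
  m <- fam$counts
  # duplicate P1's columns as a fake second genotype
  counts <- cbind(m$counts[, 1:3], m$counts[, 1:3])
  colnames(counts) <- c(paste0("P1_r", 1:3), paste0("P2_r", 1:3))
  m2 <- count_matrix(counts, m$genes,
                     data.frame(sample_id = colnames(counts),
                                genotype = rep(c("P1", "P2"), each = 3),
                                role = rep(c("P1", "P2"), each = 3),
                                family = "F1", replicate = rep(1:3, 2)))
  de <- run_pairwise_de(m2, c("P1", "P2"))
  expect_identical(sum(de$significant), 0L)
  expect_true(all(de$p == 1))
})

test_that("planted strong DE is detected with high power", {
  fam <- simulate_family(sim_config(n_genes = 600, n_progeny = 2,
                                    mean_depth = 500, frac_de = 0.2,
                                    de_effect = 3, seed = 19))
  de <- run_pairwise_de(fam$counts, c("P1", "P2"))
  truth <- fam$truth$genes
  planted <- truth$gene_id[truth$parent_effect != 0]
  found <- de$gene_id[de$significant]
  expect_gte(mean(planted %in% found), 0.95)
})
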