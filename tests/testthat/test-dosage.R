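test_that("diploid percentage follows its defining formula", {
  expect_equal(diploid_percent(10, 20), 33.33333, tolerance = 1e-5)
  expect_equal(diploid_percent(15, 15), 50)
  expect_equal(diploid_percent(0, 7), 0)
  expect_true(is.na(diploid_percent(0, 0)))
  expect_equal(diploid_percent(c(10, 0), c(20, 0)), c(100 / 3, NA))
})

test_that("copy-number inference reproduces the worked dosage signatures", {
  expect_equal(infer_copy_numbers(1.585, 25)[c("c4", "k", "state")],
               list(c4 = 4L, k = 3L, state = "replete"))
  expect_equal(infer_copy_numbers(0.415, 50)[c("c4", "k", "state")],
               list(c4 = 3L, k = 1L, state = "deficient"))
  expect_equal(infer_copy_numbers(0.0, 50)[c("c4", "k", "state")],
               list(c4 = 4L, k = 1L, state = "deficient"))
  expect_equal(infer_copy_numbers(1.0, 100 / 3)$state, "normal")
  expect_error(infer_copy_numbers(NaN, 50), "finite")
  expect_error(infer_copy_numbers(1, 0), "diploid_pct")
})

test_that("noise-free closed forms invert exactly for all 12 valid (c4, k) pairs", {
  for (c4 in 1:4) for (k in 1:min(3, c4)) {
    D <- log2(k) - log2(c4 / 4)
    dp <- 100 / (1 + k)
    got <- infer_copy_numbers(D, dp)
    expect_identical(got$c4, as.integer(c4))
    expect_identical(got$k, as.integer(k))
  }
})

test_that("chromosome profiles match the dosage arithmetic on simulation", {
  cases <- list(list(c4 = 4, k = 2, D = 1.0, dp = 100 / 3),
                list(c4 = 3, k = 2, D = log2(8 / 3), dp = 100 / 3),
                list(c4 = 4, k = 3, D = log2(3), dp = 25))
  for (cs in cases) {
    tab <- simulate_dosage_scenario(cs$c4, cs$k, n_genes = 500, depth = 500,
                                    dispersion = 0.05,
                                    seed = 100 + cs$c4 * 10 + cs$k)
    prof <- chromosome_profile(tab, "chr01", "H01")
    expect_equal(prof$D, cs$D, tolerance = 0.06)
    expect_equal(prof$diploid_pct, cs$dp, tolerance = 0.05)
    expect_identical(prof$c4, as.integer(cs$c4))
    expect_identical(prof$k, as.integer(cs$k))
  }
})

test_that("copy numbers are recovered exactly from moderate-noise simulations", {
  for (c4 in 1:4) for (k in 1:min(3, c4)) {
    tab <- simulate_dosage_scenario(c4, k, n_genes = 500, depth = 200,
                                    dispersion = 0.05, seed = 200 + c4 * 10 + k)
    prof <- chromosome_profile(tab, "chr01", "H01")
    expect_identical(c(prof$c4, prof$k), c(as.integer(c4), as.integer(k)))
  }
})

test_that("profiles flag low-confidence chromosomes and missing data", {
  tab <- simulate_dosage_scenario(4, 2, n_genes = 5, depth = 100, seed = 1)
  expect_true(chromosome_profile(tab, "chr01", "H01")$low_confidence)
  expect_error(chromosome_profile(tab, "chr09", "H01"), "no rows")
})

test_that("balanced triploid dosage centers the ratio cloud at (-1.585, -0.585)", {
  tab <- simulate_dosage_scenario(4, 2, n_genes = 500, depth = 200,
                                  dispersion = 0.05, seed = 47)
  pts <- dosage_ratio_points(tab)
  expect_equal(median(pts$x), log2(1 / 3), tolerance = 0.05)
  expect_equal(median(pts$y), log2(2 / 3), tolerance = 0.05)
})

test_that("the aneuploidy scan separates shifted chromosomes from null ones", {
  set.seed(49)
  null_vals <- rnorm(19 * 60, 0, 0.3)
  null_chr <- rep(sprintf("chr%02d", 1:19), each = 60)
  scan0 <- aneuploidy_scan(null_vals, null_chr)
  expect_gt(min(scan0$p), 1e-6)
  expect_false(any(scan0$significant))
  # one chromosome shifted by +0.4 log2 units, 500 genes
  vals <- c(rnorm(500, 0.4, 0.3), rnorm(1500, 0, 0.3))
  chr <- c(rep("chr01", 500), rep(sprintf("chr%02d", 2:4), each = 500))
  scan1 <- aneuploidy_scan(vals, chr)
  expect_lt(scan1$p[scan1$chromosome == "chr01"], 1e-16)
  expect_true(scan1$significant[scan1$chromosome == "chr01"])
  expect_error(aneuploidy_scan(rnorm(10), rep("chr01", 10)), "2 chromosomes")
})

test_that("the scan's rank-sum p matches exhaustive permutation on tiny vectors", {
  set.seed(51)
  for (i in 1:10) {
    x <- sample(seq(0.1, 10, by = 0.1), 4)
    y <- sample(setdiff(seq(0.1, 10, by = 0.1), x), 4)
    scan <- aneuploidy_scan(c(x, y), rep(c("cA", "cB"), each = 4))
    expect_equal(scan$p[scan$chromosome == "cA"],
                 oracle_ranksum_two_sided(x, y), tolerance = 1e-9)
  }
})

test_that("dosage outliers flag exactly the displaced point in a constructed cloud", {
  set.seed(53)
  pts <- data.frame(gene_id = sprintf("g%03d", 1:101),
                    x = c(rnorm(100, 0, 0.05), 3),
                    y = c(rnorm(100, 0, 0.05), 3))
  out <- dosage_outliers(pts, pr = 1e-5)
  expect_identical(out$gene_id[out$outlier], "g101")
})

test_that("the outlier ellipse is calibrated under bivariate normality", {
  set.seed(55)
  n <- 20000
  pts <- data.frame(x = rnorm(n), y = rnorm(n))
  # pr = 1e-3: expect ~20 flags; accept a wide Poisson band
  out <- dosage_outliers(pts, pr = 1e-3)
  n_flag <- sum(out$outlier)
  expect_gte(n_flag, 6)
  expect_lte(n_flag, 45)
  # pr = 1e-5 on a pure null of modest size: almost surely zero flags
  pts2 <- data.frame(x = rnorm(100), y = rnorm(100))
  expect_identical(sum(dosage_outliers(pts2, pr = 1e-5)$outlier), 0L)
  expect_error(dosage_outliers(data.frame(x = rep(1, 50), y = rep(2, 50))),
               "degenerate")
})

test_that("cumulative dysregulation counts and sums behave monotonically", {
  set.seed(57)
  base <- data.frame(x = rnorm(200, 0, 0.1), y = rnorm(200, 0, 0.1))
  none <- dosage_outliers(base, pr = 1e-5)
  expect_equal(cumulative_dysregulation(none)$value, 0)
  planted <- rbind(base, data.frame(x = rnorm(5, 5, 0.1), y = rnorm(5, 5, 0.1)))
  out <- dosage_outliers(planted, pr = 1e-5)
  expect_equal(cumulative_dysregulation(out, "count")$value, 5)
  s5 <- cumulative_dysregulation(out, "sum")$value
  expect_gt(s5, 0)
  more <- rbind(planted, data.frame(x = 8, y = 8))
  s6 <- cumulative_dysregulation(dosage_outliers(more, pr = 1e-5), "sum")$value
  expect_gt(s6, s5)
  expect_error(cumulative_dysregulation(base), "dosage_outliers")
})
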