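test_that("the Yates shortcut matches the textbook test and clamps near-null tables", {
  # |ad - bc| <= N/2: the continuity correction would overshoot; statistic 0
  z <- yates_chi2(5, 5, 5, 5)
  expect_equal(z$statistic, 0)
  expect_equal(z$p.value, 1)
  expect_gte(z$statistic_unclamped, 0)

  y <- yates_chi2(30, 19, 300, 270)
  ref <- suppressWarnings(
    stats::chisq.test(matrix(c(30, 19, 300, 270), 2, byrow = TRUE), correct = TRUE))
  expect_equal(y$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(y$p.value, ref$p.value, tolerance = 1e-12)
  expect_equal(y$dof, 1L)

  set.seed(99)
  for (k in 1:100) {
    tab <- matrix(sample(1:400, 4, replace = TRUE), 2)
    y <- yates_chi2(tab)
    ref <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
    expect_equal(y$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(y$p.value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("the Yates statistic grows with sample size at fixed proportions", {
  stats_seq <- vapply(1:6, function(f)
    yates_chi2(30 * f, 10 * f, 10 * f, 30 * f)$statistic, numeric(1))
  expect_true(all(diff(stats_seq) > 0))
})

test_that("the Yates statistic is invariant under row and column swaps", {
  tab <- matrix(c(12, 31, 45, 8), 2)
  s0 <- yates_chi2(tab)$statistic
  expect_equal(yates_chi2(tab[2:1, ])$statistic, s0)
  expect_equal(yates_chi2(tab[, 2:1])$statistic, s0)
  expect_equal(yates_chi2(tab[2:1, 2:1])$statistic, s0)
  expect_error(yates_chi2(0, 0, 3, 4), "zero margin")
})

test_that("the 3x2 omnibus statistic is the Pearson sum with Bonferroni follow-up", {
  tab <- matrix(c(10, 40, 25, 25, 40, 10), 3, 2, byrow = TRUE,
                dimnames = list(c("I", "II", "III"), NULL))
  r <- chi2_3x2_bonferroni(tab)
  ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  expect_equal(r$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r$dof, 2L)
  expect_equal(nrow(r$pairwise), 3L)
  expect_true(all(r$pairwise$p.adjusted >= r$pairwise$p.value))
  expect_true(all(r$pairwise$p.adjusted <= 1))
  expect_equal(r$pairwise$p.adjusted,
               pmin(1, 3 * r$pairwise$p.value))

  flat <- matrix(c(10, 20, 10, 20, 10, 20), 3, 2, byrow = TRUE)
  expect_equal(chi2_3x2_bonferroni(flat)$statistic, 0)
  expect_error(chi2_3x2_bonferroni(matrix(c(0, 0, 1, 2, 3, 4), 3, 2, byrow = TRUE)),
               "zero margin")
})

test_that("Kruskal-Wallis matches the rank formula and handles degenerate input", {
  expect_equal(kruskal_wallis(list(c(1, 1, 1), c(1, 1)))$statistic, 0)
  expect_equal(kruskal_wallis(list(c(1, 1, 1), c(1, 1)))$p.value, 1)

  a <- list(c(1.2, 0.8, 1.5, 0.9, 1.1), c(3.2, 2.8, 3.5, 2.9, 3.1))
  kw <- kruskal_wallis(a)
  expect_equal(kw$statistic, kw_brute(a), tolerance = 1e-12)

  set.seed(10)
  for (k in 1:20) {
    s <- lapply(1:3, function(i) round(rnorm(sample(4:9, 1)), 1))
    kw <- kruskal_wallis(s)
    expect_equal(kw$statistic, kw_brute(s), tolerance = 1e-10)
    perm <- sample(3)
    expect_equal(kruskal_wallis(s[perm])$statistic, kw$statistic)
  }
})

test_that("Spearman correlation handles monotone, anti-monotone and tied data", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(spearman_rank(x, x)$rho, 1)
  expect_equal(spearman_rank(x, -x)$rho, -1)
  set.seed(11)
  for (k in 1:20) {
    a <- round(rnorm(15), 1); b <- round(rnorm(15), 1)
    if (length(unique(a)) == 1 || length(unique(b)) == 1) next
    expect_equal(spearman_rank(a, b)$rho, cor(rank(a), rank(b)),
                 tolerance = 1e-12)
  }
  expect_error(spearman_rank(rep(1, 5), 1:5), "zero variance")
})

test_that("region contingency recipes build consistent margins", {
  tabs <- load_packaged_tables()
  cells <- rbind(tabs$maximum, tabs$minimum)
  sizes <- setNames(tabs$composition$n_pairs, tabs$composition$region)
  m <- range_contingency(tabs$maximum, c("II", "III"), region_sizes = sizes)
  expect_equal(unname(m[, 1]),
               c(aggregate_range_cells(tabs$maximum, regions = "II")$n,
                 aggregate_range_cells(tabs$maximum, regions = "III")$n))
  expect_equal(unname(rowSums(m)), unname(sizes[c("II", "III")]))
  y <- yates_chi2(m)
  expect_gte(y$statistic, 0)
  expect_true(y$p.value > 0 && y$p.value <= 1)

  m2 <- range_contingency(cells, c("I", "III"), margin = "range_counts")
  expect_equal(unname(m2["III", 1]),
               aggregate_range_cells(tabs$maximum, regions = "III")$n)
  expect_equal(unname(m2["III", 2]),
               aggregate_range_cells(tabs$minimum, regions = "III")$n)
})
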