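test_that("Maximum-range branches evaluate the printed inequalities", {
  # wide spread: the tight tenth-cut clears the midpoint
  Pi <- c(1.0, 0.0, 0.5, 0.95)
  mx <- bj_max_range(Pi, P0 = 0.2)
  expect_equal(mx$threshold, 0.9)
  expect_equal(mx$branch, "tenth")
  expect_equal(mx$members, c(1L, 4L))

  # narrow spread above the baseline: fall back to the quarter band
  mx2 <- bj_max_range(c(0.3, 0.0, 0.29), P0 = 0.28)
  expect_equal(mx2$branch, "quarter")
  expect_equal(mx2$threshold, 0.295)
  expect_equal(mx2$members, 1L)

  # no substitution raises the probability: no Maximum range
  expect_equal(bj_max_range(rep(0.4, 5), P0 = 0.4)$members, integer(0))
  expect_equal(bj_max_range(c(0.1, 0.2), P0 = 0.5)$branch, "none")
})

test_that("Minimum-range branches and the closed-state correction evaluate correctly", {
  mn <- bj_min_range(c(1.0, 0.2, 0.5), P0 = 0.6)
  expect_equal(mn$branch, "tenth")
  expect_equal(mn$threshold, 0.28)
  expect_equal(mn$members, 2L)

  # tenth-cut overshoots the half-way-to-baseline bound: quarter band
  mn2 <- bj_min_range(c(1.0, 0.5, 0.6), P0 = 0.55)
  expect_equal(mn2$branch, "quarter")
  expect_equal(mn2$threshold, 0.5 + 0.05 / 4)
  expect_equal(mn2$members, 2L)

  # floor at zero: members are the closed positions, count corrected
  Pi <- c(rep(0, 36), runif(64, 0.1, 1))
  mn3 <- bj_min_range(Pi, P0 = 0.5, ng = 100)
  expect_equal(mn3$branch, "closed")
  expect_equal(mn3$members, 1:36)
  expect_equal(mn3$nmin, 36L)
  expect_equal(mn3$effective_nmin, 36 * (1 - 0.36^2))
  alt <- bj_min_range(Pi, P0 = 0.5, ng = 100, correction = "one_minus_ratio_all_sq")
  expect_equal(alt$effective_nmin, 36 * (1 - 0.36)^2)

  # all positions closed: correction vanishes under both parses
  allz <- bj_min_range(rep(0, 10), P0 = 0.3)
  expect_equal(allz$effective_nmin, 0)
  expect_true(allz$all_closed)
  allz2 <- bj_min_range(rep(0, 10), P0 = 0.3, correction = "one_minus_ratio_all_sq")
  expect_equal(allz2$effective_nmin, 0)

  # flat positive profile: no Minimum range
  expect_equal(bj_min_range(rep(0.4, 5), P0 = 0.4)$members, integer(0))
})

test_that("membership matches an exhaustive per-position scan and is scale-equivariant", {
  set.seed(55)
  for (k in 1:500) {
    n <- sample(3:40, 1)
    Pi <- round(runif(n), 1)
    if (runif(1) < 0.3) Pi[sample(n, sample(n, 1))] <- 0
    P0 <- round(runif(1), 2)
    mx <- bj_max_range(Pi, P0)
    mn <- bj_min_range(Pi, P0)
    expect_identical(mx$members, bj_members_brute(Pi, P0, "max"))
    expect_identical(mn$members, bj_members_brute(Pi, P0, "min"))
    for (cc in c(0.1, 10)) {
      mxs <- bj_max_range(cc * Pi, cc * P0)
      mns <- bj_min_range(cc * Pi, cc * P0)
      expect_identical(mxs$members, mx$members)
      expect_identical(mns$members, mn$members)
      # thresholds scale with the data; when a branch condition sits exactly
      # on its boundary, float rounding may pick the other (equivalent) cut,
      # so the threshold comparison is conditioned on the branch
      if (!is.na(mx$threshold) && identical(mxs$branch, mx$branch))
        expect_equal(mxs$threshold, cc * mx$threshold, tolerance = 1e-12)
      if (!is.na(mn$threshold) && identical(mns$branch, mn$branch))
        expect_equal(mns$threshold, cc * mn$threshold, tolerance = 1e-12)
    }
  }
})

test_that("the closed-state census counts zeros per region", {
  part <- region_partition(c(1, 5, 9), c(4, 8, 12), c("I", "II", "III"))
  mkprof <- function(P) data.frame(energy = "0.250", group = "OS",
                                   position = c(0L, 1:12), P = c(0.3, P))
  set.seed(77)
  for (k in 1:20) {
    P <- round(runif(12), 1)
    cen <- closed_state_census(mkprof(P), "0.250", "OS", part)
    expect_equal(unname(cen$per_region),
                 c(sum(P[1:4] == 0), sum(P[5:8] == 0), sum(P[9:12] == 0)))
    expect_equal(cen$total, sum(cen$per_region))
  }
  cen0 <- closed_state_census(mkprof(rep(0, 12)), "0.250", "OS", part)
  expect_true(cen0$all_closed)
  expect_equal(unname(cen0$per_region), c(4L, 4L, 4L))
})

test_that("range summaries count members and A-T pairs per region", {
  d <- gene_duplex("ATATGCGCATGC")       # positions 1-4 AT, 5-8 GC, 9-10 AT, 11-12 GC
  part <- region_partition(c(1, 7), c(6, 12), c("I", "II"))
  prof <- data.frame(
    energy = "0.250", group = "OS", position = 0:12,
    P = c(0.5, 0.9, 0.95, rep(0.5, 8), 0.05, 0.1))
  res <- bj_classify(prof[prof$group == "OS", ])
  s <- summarize_ranges(res, d, part)
  mx <- s$cells[s$cells$table == "Maximum", ]
  expect_equal(mx$n[mx$region == "I"], 2L)   # positions 1, 2 (A-T pairs)
  expect_equal(mx$at[mx$region == "I"], 2L)
  expect_equal(mx$n[mx$region == "II"], 0L)
  mn <- s$cells[s$cells$table == "Minimum", ]
  expect_equal(mn$n[mn$region == "II"], 2L)  # positions 11, 12 (G-C pairs)
  expect_equal(mn$at[mn$region == "II"], 0L)

  # flat profile: both ranges empty everywhere
  flat <- data.frame(energy = "0.250", group = "OS", position = 0:12, P = 0.4)
  sflat <- summarize_ranges(bj_classify(flat), d, part)
  expect_true(all(sflat$cells$n == 0))
})

test_that("cell aggregation filters, sums, and rounds as the summary tables do", {
  cells <- data.frame(
    table = "Minimum",
    energy = c("0.250", "0.250", "0.300"),
    region = c("II", "III", "II"),
    group = c("g1", "g1", "g1"),
    n = c(10L, NA, 4L), at = c(3L, NA, 2L),
    all_closed = c(FALSE, TRUE, FALSE))
  agg <- aggregate_range_cells(cells, regions = "II")
  expect_equal(agg$n, 14)
  expect_equal(agg$at, 5)
  expect_equal(agg$at_pct, round_half_up(100 * 5 / 14, 1))
  expect_equal(aggregate_range_cells(cells, regions = "III")$n, 0)
})
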