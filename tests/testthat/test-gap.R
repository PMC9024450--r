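test_that("yield gap is the plain difference and antisymmetric", {
  expect_equal(yield_gap(13.53, 4.96), 8.57)
  expect_equal(yield_gap(11.90, 6.06), 5.84)
  expect_equal(yield_gap(7.3, 7.3), 0)
  expect_equal(yield_gap(4, 6), -(yield_gap(6, 4)))
  expect_true(is.na(yield_gap(NA, 5)))
  expect_error(yield_gap(-1, 5), "non-negative")
})

test_that("relative yield gap follows the formula and guards zero potential", {
  expect_equal(relative_yield_gap(0, 9), 0)
  expect_equal(round(relative_yield_gap(5.84, 11.90), 2), 49.08)
  expect_equal(round(relative_yield_gap(8.57, 13.53), 2), 63.34)
  expect_warning(out <- relative_yield_gap(2, 0), "zero potential")
  expect_true(is.na(out))
})

test_that("county binning follows the half-open [lo, hi) convention", {
  b <- bin_counties(c(2.9, 3.0, 5.99, 6.0, 12.0))
  expect_identical(b$n, c(1L, 2L, 1L, 0L, 1L))
  expect_identical(b$bin, c("<3", "3-6", "6-9", "9-12", ">=12"))
  expect_equal(sum(b$n), 5L)

  all_one <- bin_counties(rep(4.5, 7))
  expect_equal(all_one$ratio[all_one$bin == "3-6"], 100)
  expect_error(bin_counties(1:3, edges = c(3, 3, 6)), "strictly increasing")
})

test_that("bin counts sum to the non-missing county total", {
  set.seed(1)
  v <- c(runif(50, 0, 15), NA, NA)
  b <- bin_counties(v)
  expect_identical(sum(b$n), 50L)
  expect_equal(sum(b$ratio), 100, tolerance = 0.05)
})

test_that("county yield table derives gaps, bins and negative-gap flags", {
  potential <- data.frame(county_id = c("A", "B", "C"), epoch = "E1",
                          ys_mean = c(12, 10, 5))
  panel <- data.frame(county_id = c("A", "B", "C"), epoch = "E1",
                      actual_farm_yield = c(4, 9, 6))
  yt <- county_yield_table(potential, panel)
  expect_equal(yt$ygap, c(8, 1, -1))
  expect_equal(yt$rygap, c(8 / 12, 1 / 10, -1 / 5) * 100)
  expect_identical(yt$gap_bin, c("6-9", "<3", "<3"))
  expect_identical(yt$negative_gap, c(FALSE, FALSE, TRUE))
})

test_that("gap change telescopes exactly across sub-periods", {
  set.seed(21)
  counties <- sprintf("C%02d", 1:12)
  tab <- expand.grid(county_id = counties, epoch = c("E1", "E2", "E3", "E4"),
                     stringsAsFactors = FALSE)
  tab$ys_mean <- runif(nrow(tab), 9, 14)
  tab$actual_farm_yield <- tab$ys_mean * runif(nrow(tab), 0.3, 0.7)
  yt <- county_yield_table(tab[, c("county_id", "epoch", "ys_mean")], tab)
  gc <- yield_gap_change(yt)
  subs <- gc[!gc$is_full_period, ]
  full <- gc[gc$is_full_period, ]
  agg <- tapply(subs$ygc, subs$county_id, sum)
  expect_equal(as.numeric(agg[full$county_id]), full$ygc, tolerance = 1e-12)
})

test_that("gap change values and classes match the reported-style legend", {
  tab <- data.frame(county_id = "X", epoch = c("E1", "E2"),
                    ys_mean = c(13.53, 11.90),
                    actual_farm_yield = c(13.53 - 8.57, 11.90 - 5.84))
  yt <- county_yield_table(tab[, c("county_id", "epoch", "ys_mean")], tab)
  gc <- yield_gap_change(yt)
  expect_equal(gc$ygc, rep(-2.73, 2), tolerance = 1e-9)
  # equal gaps give a zero change in class L5 (0 <= ygc < 1)
  tab0 <- data.frame(county_id = "X", epoch = c("E1", "E2"),
                     ys_mean = c(10, 10), actual_farm_yield = c(4, 4))
  gc0 <- yield_gap_change(county_yield_table(
    tab0[, c("county_id", "epoch", "ys_mean")], tab0))
  expect_equal(gc0$ygc, c(0, 0))
  expect_identical(unique(gc0$change_class[!gc0$is_full_period]), "L5")
})

test_that("counties missing an epoch are omitted, absent epochs error", {
  tab <- data.frame(county_id = c("A", "B", "A"),
                    epoch = c("E1", "E1", "E2"),
                    ys_mean = c(10, 11, 10),
                    actual_farm_yield = c(4, 5, 6))
  yt <- county_yield_table(tab[, c("county_id", "epoch", "ys_mean")], tab)
  gc <- yield_gap_change(yt)
  expect_identical(unique(gc$county_id), "A")
  expect_error(yield_gap_change(yt, epochs = c("E1", "E9")), "E9")
})

test_that("epoch summaries match brute-force recomputation", {
  set.seed(31)
  tab <- expand.grid(county_id = sprintf("C%02d", 1:20),
                     epoch = c("E1", "E2"), stringsAsFactors = FALSE)
  tab$ys_mean <- runif(40, 8, 15)
  tab$actual_farm_yield <- runif(40, 2, 9)
  yt <- county_yield_table(tab[, c("county_id", "epoch", "ys_mean")], tab)
  sm <- gap_summary(yt)
  for (e in c("E1", "E2")) {
    g <- yt$ygap[yt$epoch == e]
    block <- sm[sm$epoch == e, ]
    expect_equal(unique(block$min), min(g))
    expect_equal(unique(block$max), max(g))
    expect_equal(unique(block$mean), mean(g))
    expect_identical(sum(block$n), length(g))
  }
})
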