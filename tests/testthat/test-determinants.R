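# Shared small fixture: synthetic region with the default retention
# structure (25 districts, 2 counties with missing CLPL).
region_fixture <- local({
  r <- NULL
  function() {
    if (is.null(r)) r <<- simulate_region(sim_config(seed = 17))
    r
  }
})

gapchange_fixture <- local({
  g <- NULL
  function() {
    if (is.null(g)) {
      r <- region_fixture()
      g <<- yield_gap_change(county_yield_table(r$ys_table, r$panel))
    }
    g
  }
})

test_that("factor matrix retention mirrors the district and missing rules", {
  r <- region_fixture()
  gc <- gapchange_fixture()
  fm <- assemble_factor_matrix(r$panel, gc, "E1990_E2018", r$counties)
  expect_identical(length(fm$y), 94L)  # 121 - 25 districts - 2 missing
  expect_identical(fm$n_dropped_district, 25L)
  expect_identical(fm$n_dropped_missing, 2L)
  expect_false(anyNA(fm$x))
  expect_identical(fm$county_id, sort(fm$county_id))

  keep_all <- assemble_factor_matrix(r$panel, gc, "E1990_E2018", r$counties,
                                     exclude_municipal_districts = FALSE)
  expect_identical(length(keep_all$y), 119L)  # only the 2 missing drop out
})

test_that("factor matrix assembly validates period and sample size", {
  r <- region_fixture()
  gc <- gapchange_fixture()
  expect_error(assemble_factor_matrix(r$panel, gc, "bogus", r$counties),
               "absent")
  expect_error(assemble_factor_matrix(r$panel, gc, "E1990_E2018", r$counties,
                                      min_counties = 500),
               "unreliable")
  slim <- r$panel[, setdiff(names(r$panel), "GDPPC")]
  expect_error(assemble_factor_matrix(slim, gc, "E1990_E2018", r$counties),
               "GDPPC")
})

test_that("score normalization floors negatives and fixes the maximum at 1", {
  expect_equal(unname(normalize_scores(c(2, 1, 0))), c(1, 0.5, 0))
  expect_equal(unname(normalize_scores(c(4, -2, 1))), c(1, 0, 0.25))
  raw <- c(a = 3, b = 1.2, c = 0.4)
  expect_equal(normalize_scores(raw * 17), normalize_scores(raw))
  expect_error(normalize_scores(c(0, -1)), "zero or negative")
})

test_that("importance fits are reproducible and recover a planted signal", {
  fm <- simulate_factor_response(seed = 31)
  a <- fit_importance(fm, ntree = 300, seed = 5)
  b <- fit_importance(fm, ntree = 300, seed = 5)
  expect_identical(a$score, b$score)
  expect_identical(a$factor[a$rank == 1], "GDPPC")
  expect_equal(max(a$score), 1)
  expect_identical(sum(a$top10), 10L)
})

test_that("constant responses are rejected", {
  fm <- simulate_factor_response(seed = 1)
  fm$y <- rep(2, length(fm$y))
  expect_error(fit_importance(fm, ntree = 50), "constant response")
})

test_that("pure-noise responses have no reproducibly dominant factor", {
  winners <- vapply(1:5, function(i) {
    fm <- simulate_factor_response(beta = c(GDPPC = 0), noise_sd = 1,
                                   seed = 40 + i)
    res <- fit_importance(fm, ntree = 200, seed = 140 + i)
    res$factor[res$rank == 1]
  }, character(1))
  expect_gt(length(unique(winners)), 1L)
})

test_that("a duplicated collinear noise column never displaces the signal", {
  fm <- simulate_factor_response(seed = 53)
  fm$x$DUP <- fm$x$NP  # perfectly collinear copy of a noise covariate
  fm$categories <- c(fm$categories, DUP = "land_use")
  res <- fit_importance(fm, ntree = 500, seed = 6)
  top <- res$factor[res$rank <= 10]
  expect_true(all(c("GDPPC", "SH", "PCAI") %in% top))
  expect_identical(res$factor[res$rank == 1], "GDPPC")
})

test_that("top-k frequencies count periods and conserve k x periods", {
  mock <- lapply(1:4, function(p) {
    fm <- simulate_factor_response(seed = 60 + p)
    fit_importance(fm, ntree = 100, seed = 160 + p)
  })
  freq <- top_k_frequency(mock)
  expect_identical(sum(freq$frequency), 40L)
  expect_identical(freq$frequency[freq$factor == "GDPPC"], 4L)
  expect_true(all(freq$frequency >= 0 & freq$frequency <= 4))
  expect_error(top_k_frequency(mock[1]), "at least 2")
})

test_that("category contributions are percentages of the ten key slots", {
  res <- fit_importance(simulate_factor_response(seed = 71), ntree = 200,
                        seed = 8)
  contrib <- category_contribution(res)
  expect_identical(sum(contrib$n_top), 10L)
  expect_equal(sum(contrib$percent), 100)
  expect_identical(contrib$category,
                   c("climatic", "socioeconomic", "land_use",
                     "human_investment"))
  # hand-built flags: 4/3/2/1 split
  fake <- res
  cats <- rep(c("climatic", "socioeconomic", "land_use", "human_investment"),
              times = c(4, 3, 2, 1))
  fake$category[fake$rank <= 10] <- cats
  expect_equal(category_contribution(fake)$percent, c(40, 30, 20, 10))
})
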