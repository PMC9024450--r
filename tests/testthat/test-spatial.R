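test_that("contiguity rules give the textbook neighbor counts on a 3x3 grid", {
  cf <- lattice_counties(3, 3)
  wq <- build_contiguity_weights(cf, rule = "queen")
  wr <- build_contiguity_weights(cf, rule = "rook")
  center <- which(wq$ids == "C005")
  expect_length(wq$neighbors[[center]], 8L)
  expect_length(wr$neighbors[[center]], 4L)
  for (i in seq_along(wq$ids)) {
    expect_equal(sum(wq$weights[[i]]), 1, tolerance = 1e-12)
  }
})

test_that("neighbor relations are symmetric and isolates abort", {
  cf <- lattice_counties(4, 3)
  w <- build_contiguity_weights(cf, rule = "rook", row_standardize = FALSE)
  A <- dense_adjacency(w)
  expect_identical(A, t(A))
  # a county far away from the lattice is an isolate
  far <- rbind(c(1e6, 1e6), c(1e6 + 1, 1e6), c(1e6 + 1, 1e6 + 1),
               c(1e6, 1e6 + 1), c(1e6, 1e6))
  cf2 <- county_frame(c(cf$county_id, "FAR"), c(cf$geometry, list(far)))
  expect_error(build_contiguity_weights(cf2), "FAR")
  expect_warning(w2 <- build_contiguity_weights(cf2, allow_isolates = TRUE),
                 "FAR")
  expect_length(w2$neighbors[[which(w2$ids == "FAR")]], 0L)
})

test_that("Gi* reproduces the hand-computed 3-node path statistics", {
  cf <- strip_counties(3)
  w <- build_contiguity_weights(cf, rule = "rook", row_standardize = FALSE)
  hs <- getis_ord_gi_star(c(1, 2, 3), w)
  expect_equal(hs$gi_star_z, c(-sqrt(1.5), 0, sqrt(1.5)), tolerance = 1e-12)
  expect_equal(round(hs$gi_star_z, 4), c(-1.2247, 0, 1.2247))
})

test_that("Gi* equals the double-loop oracle on lattice fixtures", {
  for (dims in list(c(3, 3), c(4, 4), c(5, 5))) {
    cf <- lattice_counties(dims[1], dims[2], seed = dims[1])
    w <- build_contiguity_weights(cf)
    set.seed(dims[1] * 10 + dims[2])
    x <- rnorm(nrow(cf))
    got <- getis_ord_gi_star(x, w)
    want <- oracle_gi_star(x, dense_adjacency(w, include_self = TRUE))
    expect_lt(max(abs(got$gi_star_z - want)), 1e-10)
  }
})

test_that("Gi* classes are sign-symmetric and order-invariant", {
  cf <- lattice_counties(4, 4)
  w <- build_contiguity_weights(cf)
  set.seed(9)
  x <- rnorm(16)
  a <- getis_ord_gi_star(x, w)
  b <- getis_ord_gi_star(-x, w)
  expect_equal(a$gi_star_z, -b$gi_star_z, tolerance = 1e-12)
  flip <- c(hot99 = "cold99", hot95 = "cold95", hot90 = "cold90", ns = "ns",
            cold90 = "hot90", cold95 = "hot95", cold99 = "hot99")
  expect_identical(unname(flip[a$class]), b$class)

  # shuffling input row order must not change any county's z
  perm <- sample(nrow(cf))
  cf_shuffled <- cf[perm, ]
  class(cf_shuffled) <- class(cf)
  w2 <- build_contiguity_weights(cf_shuffled)
  x2 <- x[match(w2$ids, w$ids)]
  c2 <- getis_ord_gi_star(x2, w2)
  expect_equal(c2$gi_star_z[match(w$ids, c2$county_id)], a$gi_star_z,
               tolerance = 1e-12)
})

test_that("Gi* rejects degenerate inputs", {
  cf <- lattice_counties(3, 3)
  w <- build_contiguity_weights(cf)
  expect_error(getis_ord_gi_star(rep(1, 9), w), "zero variance")
  expect_error(getis_ord_gi_star(c(1, 2), w), "different lengths")
})

test_that("bivariate Moran's I matches the two-node hand computation", {
  cf <- strip_counties(2)
  w <- build_contiguity_weights(cf, row_standardize = FALSE)
  m_pos <- bivariate_moran_global(c(1, -1), c(-1, 1), w, n_perm = 0)
  expect_equal(m_pos$global_i, 1, tolerance = 1e-12)
  m_neg <- bivariate_moran_global(c(1, -1), c(1, -1), w, n_perm = 0)
  expect_equal(m_neg$global_i, -1, tolerance = 1e-12)
})

test_that("bivariate Moran's I equals the double-loop oracle and ape's Moran.I", {
  for (dims in list(c(3, 3), c(5, 5))) {
    cf <- lattice_counties(dims[1], dims[2], seed = dims[2])
    w <- build_contiguity_weights(cf)
    n <- nrow(cf)
    set.seed(dims[1] + 100)
    x <- rnorm(n)
    y <- 0.4 * x + rnorm(n)
    got <- bivariate_moran_global(x, y, w, n_perm = 0)
    expect_equal(got$global_i, oracle_bivariate_moran(x, y, dense_weights(w)),
                 tolerance = 1e-10)
    # x = y reduces to univariate Moran's I (independent implementation)
    skip_if_not_installed("ape")
    uni <- bivariate_moran_global(x, x, w, n_perm = 0)
    expect_equal(uni$global_i,
                 ape::Moran.I(x, dense_weights(w))$observed,
                 tolerance = 1e-10)
  }
})

test_that("global bivariate I is invariant to affine rescaling", {
  cf <- lattice_counties(4, 4)
  w <- build_contiguity_weights(cf)
  set.seed(3)
  x <- rnorm(16); y <- rnorm(16)
  base <- bivariate_moran_global(x, y, w, n_perm = 0)$global_i
  shifted <- bivariate_moran_global(3 + 2 * x, -5 + 0.1 * y, w,
                                    n_perm = 0)$global_i
  expect_equal(shifted, base, tolerance = 1e-12)
})

test_that("LISA locals match the oracle and aggregate to the global I", {
  cf <- lattice_counties(5, 5, seed = 2)
  w <- build_contiguity_weights(cf)
  set.seed(14)
  x <- rnorm(25); y <- rnorm(25)
  li <- bivariate_lisa(x, y, w, n_perm = 99, seed = 7)
  expect_equal(li$local_i, oracle_bivariate_lisa(x, y, dense_weights(w)),
               tolerance = 1e-10)
  glob <- bivariate_moran_global(x, y, w, n_perm = 0)$global_i
  expect_equal(attr(li, "global_i"), glob, tolerance = 1e-12)
  expect_true(all(li$pseudo_p > 0 & li$pseudo_p <= 1))
  expect_true(all(li$lisa_class[li$pseudo_p > 0.05] == "ns"))
})

test_that("LISA quadrant classes follow the sign of (z_x, spatial lag)", {
  cf <- strip_counties(2)
  w <- build_contiguity_weights(cf)
  li <- bivariate_lisa(c(1, -1), c(-1, 1), w, n_perm = 99, alpha = 1,
                       seed = 5)
  expect_equal(li$local_i, c(1, 1), tolerance = 1e-12)
  # node 1: z_x = +1, lag = z_y(2) = +1 -> HH; node 2: (-1, -1) -> LL
  expect_identical(li$lisa_class, c("HH", "LL"))
})

test_that("zero-variance inputs and tiny permutation counts are rejected", {
  cf <- lattice_counties(3, 3)
  w <- build_contiguity_weights(cf)
  expect_error(bivariate_moran_global(rep(1, 9), rnorm(9), w), "zero variance")
  expect_error(bivariate_moran_global(rnorm(9), rnorm(9), w, n_perm = 50),
               "at least 99")
  expect_error(bivariate_lisa(rnorm(9), rep(2, 9), w), "zero variance")
})

test_that("pseudo p-values follow the (exceed + 1)/(n + 1) convention", {
  null <- seq(-1, 1, length.out = 999)
  expect_equal(permutation_pvalue(5, null), 1 / 1000)
  expect_equal(permutation_pvalue(0, null), mean(abs(null) >= 0) * 999 / 1000 +
                 1 / 1000, tolerance = 1e-12)
  expect_gt(permutation_pvalue(0.02, null), 0.4)
  expect_equal(permutation_pvalue(-5, null, alternative = "less"), 1 / 1000)
})

test_that("permutation inference is reproducible under a seed", {
  cf <- lattice_counties(4, 4)
  w <- build_contiguity_weights(cf)
  set.seed(8)
  x <- rnorm(16); y <- rnorm(16)
  a <- bivariate_moran_global(x, y, w, n_perm = 199, seed = 99)
  b <- bivariate_moran_global(x, y, w, n_perm = 199, seed = 99)
  expect_identical(a$pseudo_p, b$pseudo_p)
  expect_identical(a$null_draws, b$null_draws)
})
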