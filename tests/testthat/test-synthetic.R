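test_that("county lattice tessellation has the expected adjacency", {
  cf <- lattice_counties(2, 2)
  expect_identical(nrow(cf), 4L)
  w_rook <- build_contiguity_weights(cf, rule = "rook")
  expect_true(all(lengths(w_rook$neighbors) == 2L))

  cf11 <- generate_counties(sim_config(seed = 1))
  expect_identical(nrow(cf11), 121L)
  w_queen <- build_contiguity_weights(cf11, rule = "queen")
  interior <- which(!(seq_len(121) %in% c(1:11, 111:121)) &
                      !(seq_len(121) %% 11 %in% c(0, 1)))
  expect_true(all(lengths(w_queen$neighbors[interior]) == 8L))
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 42, n_county_x = 4, n_county_y = 4,
                    cells_per_county_side = 4)
  a <- simulate_region(cfg)
  b <- simulate_region(cfg)
  expect_identical(a$counties$geometry, b$counties$geometry)
  expect_identical(a$ys_table, b$ys_table)
  expect_identical(as.data.frame(a$panel), as.data.frame(b$panel))
  expect_identical(a$climate[[1]]$Q$values, b$climate[[1]]$Q$values)
})

test_that("degenerate climate ranges give constant fields", {
  cfg <- sim_config(seed = 2, n_county_x = 3, n_county_y = 3,
                    Q_range = c(50, 50))
  cl <- generate_climate_fields(cfg, generate_counties(cfg))
  expect_true(all(cl[[1]]$Q$values == 50))
})

test_that("temperature ranges at or below zero are rejected", {
  expect_error(sim_config(T_range = c(-2, 10)), "T <= 0")
})

test_that("soil coefficient field stays in (0, 1] and is centred near 0.42", {
  cfg <- sim_config(seed = 3, n_county_x = 4, n_county_y = 4)
  cl <- generate_climate_fields(cfg, generate_counties(cfg))
  fs <- cl[[1]]$fs$values
  expect_true(all(fs > 0 & fs <= 1))
  expect_lt(abs(mean(fs) - 0.42), 0.05)
  expect_true(all(cl[[1]]$fw$values == 1))
})

test_that("generated climate fields are spatially autocorrelated", {
  cfg <- sim_config(seed = 4, n_county_x = 5, n_county_y = 5,
                    municipal_block = 0)
  counties <- generate_counties(cfg)
  cl <- generate_climate_fields(cfg, counties)
  assignment <- assign_cells_to_counties(cl[[1]]$Q, counties)
  qmean <- tapply(as.vector(t(cl[[1]]$Q$values)), as.vector(t(assignment)),
                  mean)
  w <- build_contiguity_weights(counties)
  m <- bivariate_moran_global(as.numeric(qmean), as.numeric(qmean), w,
                              n_perm = 0)
  expect_gt(m$global_i, 0)
})

test_that("determinant panel has the full shape and static terrain", {
  cfg <- sim_config(seed = 5)
  counties <- generate_counties(cfg)
  panel <- generate_determinant_panel(cfg, counties)
  expect_identical(nrow(panel), 484L)
  expect_identical(setdiff(names(panel), c("county_id", "epoch")),
                   determinant_variables()$abbrev)
  dem <- tapply(panel$DEM, panel$county_id, function(v) length(unique(v)))
  expect_true(all(dem == 1L))
  # the configured number of non-district counties carry a missing CLPL
  holes <- unique(panel$county_id[is.na(panel$CLPL)])
  expect_length(holes, cfg$n_missing_counties)
  expect_false(any(holes %in% counties$county_id[counties$is_municipal_district]))
})

test_that("farm yield is the exact configured fraction of YS when noise-free", {
  cfg <- sim_config(seed = 6, n_county_x = 3, n_county_y = 3,
                    cells_per_county_side = 4,
                    exploitation_base = rep(0.5, 4),
                    effect_vector = numeric(0), noise_sd = 0,
                    municipal_block = 0, n_missing_counties = 0)
  r <- simulate_region(cfg)
  m <- merge(r$panel, r$ys_table, by = c("county_id", "epoch"))
  expect_equal(m$actual_farm_yield, 0.5 * m$ys_mean, tolerance = 1e-12)
})

test_that("a rising exploitation schedule narrows the mean gap monotonically", {
  cfg <- sim_config(seed = 7, n_county_x = 4, n_county_y = 4,
                    exploitation_base = c(0.4, 0.5, 0.6, 0.7),
                    municipal_block = 0, n_missing_counties = 0)
  r <- simulate_region(cfg)
  yt <- county_yield_table(r$ys_table, r$panel)
  mean_gap <- tapply(yt$ygap, yt$epoch, mean)[cfg$epochs]
  expect_true(all(diff(mean_gap) < 0))
})

test_that("planted-effect covariates correlate with farm yield", {
  r <- simulate_region(sim_config(seed = 8))
  last <- r$panel[r$panel$epoch == "E2018", ]
  for (nm in names(r$config$effect_vector)) {
    expect_gt(abs(cor(last[[nm]], last$actual_farm_yield,
                      use = "complete.obs")), 0.2)
  }
})

test_that("fixture sets round trip through disk", {
  cfg <- sim_config(seed = 9, n_county_x = 3, n_county_y = 3,
                    cells_per_county_side = 4)
  r <- simulate_region(cfg)
  dir <- withr::local_tempdir()
  write_fixture_set(r, dir)
  expect_true(file.exists(file.path(dir, "counties.geojson")))
  q <- read_raster(file.path(dir, "Q_E1990.asc"))
  expect_equal(q$values, r$climate$E1990$Q$values, tolerance = 0)
  panel <- read_epoch_table(file.path(dir, "panel.csv"))
  expect_identical(nrow(panel), nrow(r$panel))
  cfg_back <- yaml::read_yaml(file.path(dir, "config.yaml"))
  expect_equal(cfg_back$seed, cfg$seed)
})
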