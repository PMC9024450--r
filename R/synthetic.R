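#' Configuration of the synthetic study region
#'
#' The generator emulates the statistical structure the analysis assumes: a
#' contiguous lattice of counties over a cultivated-land mosaic, spatially
#' autocorrelated growing-season climate fields, a soil correction surface
#' centred near 0.42, four epochs of farm yields realized as a
#' covariate-driven fraction of the soil production potential, and a
#' 27-variable determinant panel with known planted effects.
#'
#' Defaults are the package's study conditions: an 11 x 11 lattice (121
#' counties, close to a province's ~122 units) with a central 5 x 5 block
#' of municipal districts; growing-season radiation 95-120 kcal/cm2 and
#' mean temperature 24-28 degC, which with a soil coefficient near 0.42
#' put the region-mean soil production potential around 11 t/ha (inside
#' the 10-14 t/ha band reported for double-cropping systems in comparable
#' regions); an exploitation schedule (0.37, 0.55, 0.57, 0.51) of the
#' potential realized as farm yield, reproducing strong gap narrowing in
#' the first period and partial widening later.
#'
#' @param seed integer RNG seed; the whole fixture set is byte-identical
#'   under a fixed seed.
#' @param n_county_x,n_county_y lattice dimensions (>= 2 each).
#' @param cells_per_county_side raster cells per county side (default 8).
#' @param cell_size raster cell side in metres (default 1000).
#' @param epochs ordered epoch labels (default four, emulating
#'   1990/2000/2010/2018).
#' @param Q_range growing-season total radiation range, kcal/cm2.
#' @param T_range growing-season mean temperature range, degC (> 0).
#' @param soil_coeff_mean,soil_coeff_spread centre and half-width of the
#'   soil correction field (clipped to (0, 1]).
#' @param cultivated_fraction range of the cultivated-cell probability.
#' @param paddy_share range of the paddy share among cultivated cells.
#' @param exploitation_base per-epoch base fraction of the potential yield
#'   realized as farm yield, each in (0, 1].
#' @param effect_vector named linear coefficients (on population-
#'   standardized covariates) linking determinants to the exploitation
#'   fraction; names must be determinant abbreviations.
#' @param noise_sd sd of the exploitation noise.
#' @param municipal_block side of the central block of counties flagged as
#'   municipal districts (default 5, i.e. 25 districts).
#' @param n_missing_counties number of non-district counties given a
#'   missing determinant (CLPL) in every epoch, to exercise the
#'   missing-data retention rule (default 2).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_county_x = 11L, n_county_y = 11L,
                       cells_per_county_side = 8L,
                       cell_size = 1000,
                       epochs = c("E1990", "E2000", "E2010", "E2018"),
                       Q_range = c(95, 120),
                       T_range = c(24, 28),
                       soil_coeff_mean = 0.42,
                       soil_coeff_spread = 0.08,
                       cultivated_fraction = c(0.45, 0.75),
                       paddy_share = c(0.55, 0.80),
                       exploitation_base = c(0.37, 0.55, 0.57, 0.51),
                       effect_vector = c(GDPPC = 0.08, SH = 0.04, PCAI = 0.02),
                       noise_sd = 0.02,
                       municipal_block = 5L,
                       n_missing_counties = 2L) {
  if (n_county_x < 2 || n_county_y < 2) stop("county lattice must be >= 2 x 2")
  stopifnot(cells_per_county_side >= 1, cell_size > 0)
  check_range <- function(r, nm, lo_ok = -Inf) {
    if (length(r) != 2 || r[1] > r[2] || r[1] < lo_ok) {
      stop(sprintf("`%s` must be a well-ordered range", nm))
    }
  }
  check_range(Q_range, "Q_range", 0)
  check_range(T_range, "T_range")
  if (T_range[1] <= 0) stop("temperature range producing T <= 0 is rejected")
  check_range(cultivated_fraction, "cultivated_fraction", 0)
  check_range(paddy_share, "paddy_share", 0)
  if (length(exploitation_base) != length(epochs)) {
    stop("`exploitation_base` needs one value per epoch")
  }
  if (any(exploitation_base <= 0 | exploitation_base > 1)) {
    stop("`exploitation_base` values must lie in (0, 1]")
  }
  bad <- setdiff(names(effect_vector), determinant_variables()$abbrev)
  if (length(bad)) {
    stop(sprintf("unknown effect covariate(s): %s", paste(bad, collapse = ", ")))
  }
  structure(
    list(seed = as.integer(seed), n_county_x = as.integer(n_county_x),
         n_county_y = as.integer(n_county_y),
         cells_per_county_side = as.integer(cells_per_county_side),
         cell_size = cell_size, epochs = epochs,
         Q_range = Q_range, T_range = T_range,
         soil_coeff_mean = soil_coeff_mean,
         soil_coeff_spread = soil_coeff_spread,
         cultivated_fraction = cultivated_fraction,
         paddy_share = paddy_share,
         exploitation_base = exploitation_base,
         effect_vector = effect_vector, noise_sd = noise_sd,
         municipal_block = as.integer(municipal_block),
         n_missing_counties = as.integer(n_missing_counties)),
    class = "sim_config"
  )
}

# Gaussian kernel smoothing of a matrix by separable band-matrix products;
# kernels are row-normalized so edges are not darkened.
smooth_matrix <- function(m, sigma) {
  band <- function(n) {
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    k <- exp(-0.5 * (d / sigma)^2)
    k / rowSums(k)
  }
  band(nrow(m)) %*% m %*% t(band(ncol(m)))
}

rescale_range <- function(m, lo, hi) {
  if (lo == hi) return(matrix(lo, nrow(m), ncol(m)))
  rng <- range(m)
  if (rng[1] == rng[2]) return(matrix((lo + hi) / 2, nrow(m), ncol(m)))
  lo + (m - rng[1]) / (rng[2] - rng[1]) * (hi - lo)
}

random_field <- function(nr, nc, sigma, lo, hi) {
  rescale_range(smooth_matrix(matrix(stats::rnorm(nr * nc), nr, nc), sigma),
                lo, hi)
}

#' Generate the county lattice
#'
#' Contiguous rectangular tessellation of `n_county_x` by `n_county_y`
#' square counties; a central `municipal_block` x `municipal_block` block
#' is flagged as municipal districts. Ids are row-major from the
#' north-west corner. Deterministic given the config (no RNG involved).
#'
#' @param config a [sim_config()].
#' @return a [county_frame()].
#' @export
generate_counties <- function(config) {
  nx <- config$n_county_x
  ny <- config$n_county_y
  side <- config$cells_per_county_side * config$cell_size
  total_h <- ny * side
  n <- nx * ny
  ids <- sprintf("C%03d", seq_len(n))
  geoms <- vector("list", n)
  district <- logical(n)
  b <- config$municipal_block
  r0 <- floor((ny - b) / 2)
  c0 <- floor((nx - b) / 2)
  k <- 0L
  for (ry in seq_len(ny)) {       # row 1 = north
    for (cx in seq_len(nx)) {
      k <- k + 1L
      x0 <- (cx - 1) * side
      y1 <- total_h - (ry - 1) * side
      y0 <- y1 - side
      geoms[[k]] <- rbind(c(x0, y0), c(x0 + side, y0),
                          c(x0 + side, y1), c(x0, y1), c(x0, y0))
      district[k] <- b > 0 && ry > r0 && ry <= r0 + b && cx > c0 && cx <= c0 + b
    }
  }
  county_frame(
    county_id = ids, geometry = geoms, name = paste("County", ids),
    is_municipal_district = district,
    area_ha = side^2 / 1e4, crs = "synthetic-projected"
  )
}

#' Generate spatially autocorrelated climate fields per epoch
#'
#' Q and T are Gaussian-smoothed white noise rescaled into the configured
#' ranges (fresh noise per epoch); f(w) is 1 everywhere (rainfall-
#' sufficient region); f(s) is a static smoothed field centred on
#' `soil_coeff_mean` and clipped to (0, 1]; the land-use grid (0 = other,
#' 1 = paddy, 2 = dryland) is a static cultivated mosaic driven by smoothed
#' probability fields.
#'
#' @param config a [sim_config()].
#' @param counties the matching [generate_counties()] frame (fixes the
#'   raster extent).
#' @return named list per epoch, each with [raster_grid()] layers
#'   `Q`, `T`, `fw`, `fs`, `landuse`.
#' @export
generate_climate_fields <- function(config, counties) {
  cps <- config$cells_per_county_side
  nr <- config$n_county_y * cps
  nc <- config$n_county_x * cps
  cs <- config$cell_size
  crs <- attr(counties, "crs")
  mk <- function(values, units) {
    raster_grid(values, xll = 0, yll = 0, cellsize = cs, crs = crs,
                units = units)
  }
  # static soil and land-use layers
  set.seed(derive_seed(config$seed, 90L))
  fs_raw <- random_field(nr, nc, cps, 0, 1)
  fs <- clip(config$soil_coeff_mean +
               config$soil_coeff_spread * (2 * fs_raw - 1), 1e-6, 1)
  set.seed(derive_seed(config$seed, 91L))
  p_cult <- random_field(nr, nc, cps, config$cultivated_fraction[1],
                         config$cultivated_fraction[2])
  p_paddy <- random_field(nr, nc, cps, config$paddy_share[1],
                          config$paddy_share[2])
  u1 <- matrix(stats::runif(nr * nc), nr, nc)
  u2 <- matrix(stats::runif(nr * nc), nr, nc)
  landuse <- matrix(0, nr, nc)
  landuse[u1 < p_cult] <- 2
  landuse[u1 < p_cult & u2 < p_paddy] <- 1
  fs_g <- mk(fs, "dimensionless")
  fw_g <- mk(matrix(1, nr, nc), "dimensionless")
  lu_g <- mk(landuse, "class")
  out <- list()
  for (e in seq_along(config$epochs)) {
    set.seed(derive_seed(config$seed, 100L + e))
    Q <- random_field(nr, nc, cps, config$Q_range[1], config$Q_range[2])
    T_mean <- random_field(nr, nc, cps, config$T_range[1], config$T_range[2])
    out[[config$epochs[e]]] <- list(
      Q = mk(Q, "kcal/cm2"), T = mk(T_mean, "degC"),
      fw = fw_g, fs = fs_g, landuse = lu_g
    )
  }
  out
}

# Marginal registry for the determinant panel: plausible county-scale
# means/sds and epoch trends (anchored at four epochs, interpolated for
# other epoch counts). Pragmatic choices - the panel emulates structure
# (trends, cross-correlation, static terrain), not real marginals.
determinant_marginals <- function() {
  list(
    SH    = list(mean = 1500, sd = 150, trend = c(1, 1, 1, 1)),
    SMI   = list(mean = 120, sd = 15, trend = c(1, 1, 1, 1)),
    Temp  = list(mean = 17.5, sd = 0.8, trend = c(1, 1.01, 1.02, 1.03)),
    Prec  = list(mean = 1400, sd = 150, trend = c(1, 1, 1, 1)),
    RSP   = list(mean = 60, sd = 15, trend = c(1, 0.97, 0.9, 0.82)),
    LDD   = list(mean = 18, sd = 4, trend = c(1, 1.1, 1.25, 1.4)),
    UR    = list(mean = 18, sd = 5, trend = c(1, 1.5, 2.2, 2.9)),
    FL    = list(mean = 30, sd = 8, trend = c(1, 0.95, 0.8, 0.65)),
    GDPPC = list(mean = 2000, sd = 600, trend = c(1, 4, 12, 25)),
    RAGDP = list(mean = 35, sd = 8, trend = c(1, 0.7, 0.45, 0.3)),
    PCAI  = list(mean = 900, sd = 250, trend = c(1, 3.5, 9, 16)),
    RPF   = list(mean = 55, sd = 12, trend = c(1, 1, 0.98, 0.97)),
    NP    = list(mean = 800, sd = 200, trend = c(1, 1.05, 1.1, 1.15)),
    PD    = list(mean = 0.5, sd = 0.15, trend = c(1, 1.05, 1.1, 1.12)),
    LPI   = list(mean = 12, sd = 4, trend = c(1, 0.97, 0.95, 0.93)),
    CLPL  = list(mean = 6, sd = 1.5, trend = c(1, 1, 1, 1)),
    PSAGC = list(mean = 65, sd = 10, trend = c(1, 0.95, 0.88, 0.85)),
    MCI   = list(mean = 180, sd = 30, trend = c(1, 0.95, 0.88, 0.8)),
    APPA  = list(mean = 1.2, sd = 0.3, trend = c(1, 0.9, 0.75, 0.6)),
    REC   = list(mean = 3000, sd = 900, trend = c(1, 2, 4.5, 7)),
    FPA   = list(mean = 0.4, sd = 0.1, trend = c(1, 1.3, 1.5, 1.45)),
    TPA   = list(mean = 30000, sd = 9000, trend = c(1, 1.2, 1.4, 1.5)),
    IA    = list(mean = 40000, sd = 12000, trend = c(1, 1.05, 1.1, 1.12)),
    PAMPA = list(mean = 2.5, sd = 0.7, trend = c(1, 1.6, 2.4, 3.1)),
    ASFF  = list(mean = 20000, sd = 8000, trend = c(1, 1.1, 1.8, 2.6))
  )
}

#' Generate the 27-variable determinant panel
#'
#' Static terrain (DEM, Slope) comes from a smoothed county-level random
#' field and is identical across epochs; socioeconomic and investment
#' variables get county-level baselines with a shared latent factor (mild
#' cross-correlation), multiplicative epoch trends (economic growth,
#' declining farm labor, ...) and small epoch noise. `n_missing_counties`
#' non-district counties carry a missing CLPL value in every epoch.
#'
#' @param config a [sim_config()].
#' @param counties the matching [generate_counties()] frame.
#' @return data.frame: `county_id`, `epoch`, and the 27 determinant columns.
#' @export
generate_determinant_panel <- function(config, counties) {
  set.seed(derive_seed(config$seed, 200L))
  n <- nrow(counties)
  ne <- length(config$epochs)
  nx <- config$n_county_x
  ny <- config$n_county_y
  # static terrain from a county-resolution smoothed field
  dem_f <- random_field(ny, nx, 2, 50, 800)
  slope_f <- rescale_range(0.7 * rescale_range(dem_f, 0, 1) +
                             0.3 * smooth_matrix(matrix(stats::rnorm(ny * nx),
                                                        ny, nx), 2),
                           2, 15)
  dem <- as.vector(t(dem_f))      # row-major, matches county id order
  slope <- as.vector(t(slope_f))
  marg <- determinant_marginals()
  latent <- stats::rnorm(n)       # shared county factor -> cross-correlation
  base <- lapply(marg, function(v) {
    z <- 0.5 * latent + sqrt(0.75) * stats::rnorm(n)
    pmax(v$mean + v$sd * z, 0.05 * v$mean)
  })
  anchor <- seq(0, 1, length.out = 4)
  at <- if (ne == 1) 0 else seq(0, 1, length.out = ne)
  rows <- vector("list", ne)
  for (e in seq_len(ne)) {
    df <- data.frame(county_id = counties$county_id,
                     epoch = config$epochs[e],
                     stringsAsFactors = FALSE)
    for (nm in names(marg)) {
      tr <- stats::approx(anchor, marg[[nm]]$trend, xout = at[e])$y
      noise <- stats::rnorm(n, 0, marg[[nm]]$sd * 0.05)
      df[[nm]] <- pmax(base[[nm]] * tr + noise, 0)
    }
    df$CLPL <- clip(df$CLPL, 1, 10)
    df$DEM <- dem
    df$Slope <- slope
    rows[[e]] <- df
  }
  panel <- do.call(rbind, rows)
  panel <- panel[, c("county_id", "epoch", determinant_variables()$abbrev)]
  if (config$n_missing_counties > 0) {
    eligible <- sort(counties$county_id[!counties$is_municipal_district])
    holes <- utils::head(eligible, config$n_missing_counties)
    panel$CLPL[panel$county_id %in% holes] <- NA_real_
  }
  rownames(panel) <- NULL
  panel
}

#' Generate farm yields as a covariate-driven fraction of the potential
#'
#' Per epoch, the exploitation fraction is
#' `base(epoch) + sum(effect * standardized covariate) + noise`, clipped to
#' \[0.05, 0.95\]; the actual farm yield is that fraction of the county
#' mean soil production potential. The sown grain area is a seeded fraction
#' of the county area with a mild decline over epochs.
#'
#' @param config a [sim_config()].
#' @param ys_table data.frame `county_id`, `epoch`, `ys_mean` (t/ha).
#' @param panel output of [generate_determinant_panel()].
#' @param counties the [generate_counties()] frame (for areas).
#' @return `panel` with `actual_farm_yield` (t/ha) and `sown_area_grain`
#'   (ha) appended; attribute `ground_truth` records the planted effect
#'   vector, exploitation schedule, per-epoch mean YS/YGAP and the true
#'   importance ranking.
#' @export
generate_farm_yields <- function(config, ys_table, panel, counties) {
  set.seed(derive_seed(config$seed, 300L))
  eff <- config$effect_vector
  out <- merge(panel, ys_table[, c("county_id", "epoch", "ys_mean")],
               by = c("county_id", "epoch"), sort = FALSE)
  out <- out[order(match(out$epoch, config$epochs), out$county_id), ]
  area <- counties$area_ha[match(out$county_id, counties$county_id)]
  sown_lat <- stats::rnorm(nrow(counties))
  out$actual_farm_yield <- NA_real_
  out$sown_area_grain <- NA_real_
  for (e in seq_along(config$epochs)) {
    sel <- out$epoch == config$epochs[e]
    n <- sum(sel)
    shift <- rep(0, n)
    for (nm in names(eff)) {
      v <- out[[nm]][sel]
      if (pop_sd(v) > 0) shift <- shift + eff[[nm]] * (v - mean(v)) / pop_sd(v)
    }
    expl <- clip(config$exploitation_base[e] + shift +
                   stats::rnorm(n, 0, config$noise_sd), 0.05, 0.95)
    out$actual_farm_yield[sel] <- out$ys_mean[sel] * expl
    frac <- clip(0.35 + 0.04 * sown_lat[match(out$county_id[sel],
                                              counties$county_id)] -
                   0.01 * (e - 1) + stats::rnorm(n, 0, 0.01), 0.15, 0.6)
    out$sown_area_grain[sel] <- area[sel] * frac
  }
  gap <- out$ys_mean - out$actual_farm_yield
  gt <- list(
    effect_vector = eff,
    exploitation_base = stats::setNames(config$exploitation_base,
                                        config$epochs),
    mean_ys = tapply(out$ys_mean, out$epoch, mean, na.rm = TRUE)[config$epochs],
    mean_ygap = tapply(gap, out$epoch, mean, na.rm = TRUE)[config$epochs],
    true_ranking = names(sort(abs(eff), decreasing = TRUE))
  )
  out$ys_mean <- NULL
  rownames(out) <- NULL
  attr(out, "ground_truth") <- gt
  out
}

#' Simulate a factor matrix with planted linear effects
#'
#' Parameter-recovery design for the importance model: 27 determinant
#' covariates drawn independently standard-normal (population-standardized),
#' a response `y = sum(beta * x) + noise` with the planted coefficients on
#' named covariates, and everything else pure noise. Returns a ready
#' `factor_matrix` so [fit_importance()] can be benchmarked against the
#' known ranking.
#'
#' @param n number of counties (default 95).
#' @param beta named coefficients on determinant abbreviations
#'   (default `c(GDPPC = 1, SH = 0.5, PCAI = 0.25)`).
#' @param noise_sd response noise sd (default 0.5).
#' @param seed RNG seed.
#' @return a `factor_matrix` (see [assemble_factor_matrix()]) with
#'   attribute `true_ranking`.
#' @export
simulate_factor_response <- function(n = 95,
                                     beta = c(GDPPC = 1, SH = 0.5,
                                              PCAI = 0.25),
                                     noise_sd = 0.5, seed = 1L) {
  vars <- determinant_variables()
  bad <- setdiff(names(beta), vars$abbrev)
  if (length(bad)) {
    stop(sprintf("unknown covariate(s) in beta: %s", paste(bad, collapse = ", ")))
  }
  set.seed(as.integer(seed))
  x <- as.data.frame(matrix(stats::rnorm(n * nrow(vars)), nrow = n,
                            dimnames = list(NULL, vars$abbrev)))
  x[] <- lapply(x, function(v) (v - mean(v)) / pop_sd(v))
  y <- as.vector(as.matrix(x[, names(beta), drop = FALSE]) %*% beta) +
    stats::rnorm(n, 0, noise_sd)
  fm <- structure(
    list(x = x, y = y,
         county_id = sprintf("S%03d", seq_len(n)),
         period = "simulated",
         categories = stats::setNames(vars$category, vars$abbrev),
         n_dropped_district = 0L, n_dropped_missing = 0L),
    class = "factor_matrix"
  )
  attr(fm, "true_ranking") <- names(sort(abs(beta), decreasing = TRUE))
  fm
}

#' Generate the full synthetic study region
#'
#' Runs counties -> climate fields -> potential-yield model -> county means
#' -> determinant panel -> farm yields under one seed and returns the whole
#' bundle. Deterministic: the same config yields byte-identical fixtures.
#'
#' @param config a [sim_config()].
#' @param params [step_model_params()] used to realize the potential (the
#'   analysis side re-estimates it from the rasters independently).
#' @return list of class `synthetic_region`: `config`, `counties`,
#'   `climate` (per-epoch field sets), `assignment` (cell-county matrix),
#'   `potential` (per-epoch [potential_yield_grid()]s), `ys_table`,
#'   `panel` (with farm yields; carries the ground-truth attribute),
#'   `ground_truth`.
#' @export
simulate_region <- function(config = sim_config(),
                            params = step_model_params()) {
  counties <- generate_counties(config)
  climate <- generate_climate_fields(config, counties)
  assignment <- assign_cells_to_counties(climate[[1]]$Q, counties)
  potential <- lapply(climate, potential_yield_grid, params = params)
  ys_table <- do.call(rbind, lapply(names(potential), function(e) {
    cm <- county_mean_potential(potential[[e]], climate[[e]]$landuse,
                                counties, assignment = assignment)
    cm$epoch <- e
    cm
  }))
  panel <- generate_determinant_panel(config, counties)
  panel <- generate_farm_yields(config, ys_table, panel, counties)
  structure(
    list(config = config, counties = counties, climate = climate,
         assignment = assignment, potential = potential,
         ys_table = ys_table[, c("county_id", "epoch", "ys_mean",
                                 "n_cultivated_cells")],
         panel = panel, ground_truth = attr(panel, "ground_truth")),
    class = "synthetic_region"
  )
}

#' @export
print.synthetic_region <- function(x, ...) {
  cat(sprintf("<synthetic_region> %d counties, %d epochs, seed %d\n",
              nrow(x$counties), length(x$config$epochs), x$config$seed))
  cat(sprintf("  mean YS by epoch (t/ha): %s\n",
              paste(sprintf("%.2f", x$ground_truth$mean_ys), collapse = ", ")))
  invisible(x)
}

#' Write a synthetic fixture set to disk
#'
#' Emits counties (GeoJSON), all raster layers per epoch (ASCII grid),
#' the panel with farm yields (CSV), the ground truth (CSV) and a config
#' snapshot (YAML).
#'
#' @param region a [simulate_region()] bundle.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_fixture_set <- function(region, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_counties(region$counties, file.path(dir, "counties.geojson"))
  for (e in names(region$climate)) {
    for (layer in c("Q", "T", "fw", "fs", "landuse")) {
      write_raster(region$climate[[e]][[layer]],
                   file.path(dir, sprintf("%s_%s.asc", layer, e)))
    }
  }
  utils::write.csv(region$panel, file.path(dir, "panel.csv"),
                   row.names = FALSE)
  gt <- region$ground_truth
  utils::write.csv(
    data.frame(name = c(paste0("effect_", names(gt$effect_vector)),
                        paste0("exploitation_", names(gt$exploitation_base)),
                        paste0("mean_ys_", names(gt$mean_ys)),
                        paste0("mean_ygap_", names(gt$mean_ygap))),
               value = c(gt$effect_vector, gt$exploitation_base,
                         gt$mean_ys, gt$mean_ygap)),
    file.path(dir, "ground_truth.csv"), row.names = FALSE
  )
  cfg <- region$config
  class(cfg) <- NULL
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
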