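#' Parameters of the step-wise potential-yield revision model
#'
#' The agro-ecological step model revises the photosynthetic production
#' potential successively by temperature, water and soil restrictions:
#' \deqn{YQ = 10^5 \, Q / C \times F \times E}
#' \deqn{YT = (T / 30) \times YQ}
#' \deqn{YW = f(w) \times YT}
#' \deqn{YS = f(s) \times YW}
#' with Q the growing-season total solar radiation (kcal/cm2) and T the
#' growing-season mean temperature (degC). All potentials are in kg/ha.
#'
#' @param C calorific value of dry matter, kcal/g (default 4.25).
#' @param F_light light-energy utilization rate, dimensionless (default 0.03).
#' @param E crop economic coefficient, harvestable fraction of dry matter
#'   (default 0.4, appropriate for rice/corn systems).
#' @param T_ref temperature scaling denominator, degC (30).
#' @param clamp_temperature_ratio clamp T/T_ref into \[0, 1\] (default TRUE)
#'   so the revision chain stays monotone; set FALSE for sensitivity runs.
#' @return list of class `step_model_params`.
#' @examples
#' p <- step_model_params()
#' photosynthetic_potential(100, p)  # 28235.29 kg/ha
#' @export
step_model_params <- function(C = 4.25, F_light = 0.03, E = 0.4, T_ref = 30,
                              clamp_temperature_ratio = TRUE) {
  assert_scalar_number(C, "C")
  assert_scalar_number(F_light, "F_light")
  assert_scalar_number(E, "E")
  if (C <= 0) stop("`C` must be positive")
  if (F_light <= 0 || F_light >= 1) stop("`F_light` must be in (0, 1)")
  if (E <= 0 || E > 0.5) stop("`E` must be in (0, 0.5]")
  structure(
    list(C = C, F_light = F_light, E = E, T_ref = T_ref,
         clamp_temperature_ratio = isTRUE(clamp_temperature_ratio)),
    class = "step_model_params"
  )
}

as_values <- function(x) if (inherits(x, "raster_grid")) x$values else x

rewrap <- function(values, template) {
  if (inherits(template, "raster_grid")) {
    g <- template
    g$values <- values
    g$units <- "kg/ha"
    g
  } else {
    values
  }
}

#' Photosynthetic production potential YQ
#'
#' `YQ = 1e5 * Q / C * F * E` (kg/ha): radiation divided by the calorific
#' value of dry matter gives produced dry matter per cm2, the factor 1e5
#' converts g/cm2 to kg/ha, and F and E scale by light-use efficiency and
#' harvestable fraction.
#'
#' @param Q growing-season total solar radiation, kcal/cm2 (numeric or
#'   [raster_grid()]); `NA` (nodata) propagates.
#' @param params a [step_model_params()].
#' @return YQ in kg/ha, same container as `Q`.
#' @export
photosynthetic_potential <- function(Q, params = step_model_params()) {
  q <- as_values(Q)
  if (any(stats::na.omit(as.vector(q)) < 0)) {
    stop("negative radiation Q is physically impossible")
  }
  rewrap(1e5 * q / params$C * params$F_light * params$E, Q)
}

#' Light-temperature production potential YT
#'
#' `YT = (T / T_ref) * YQ`; with clamping on, the ratio is limited to
#' \[0, 1\] so temperatures outside (0, T_ref) cannot inflate the potential
#' and the monotone chain YQ >= YT holds everywhere.
#'
#' @param T_mean growing-season mean temperature, degC.
#' @param YQ output of [photosynthetic_potential()].
#' @param params a [step_model_params()].
#' @return YT in kg/ha.
#' @export
light_temperature_potential <- function(T_mean, YQ,
                                        params = step_model_params()) {
  tm <- as_values(T_mean)
  yq <- as_values(YQ)
  r <- tm / params$T_ref
  if (params$clamp_temperature_ratio) r <- clip(r, 0, 1)
  rewrap(r * yq, YQ)
}

#' Climatic production potential YW
#'
#' `YW = f(w) * YT` with the water correction coefficient f(w) in \[0, 1\].
#' In rainfall-sufficient regions (rainfall exceeding evapotranspiration,
#' as in the double-cropping rice belt the model targets) f(w) = 1.
#'
#' @param fw water correction coefficient in \[0, 1\].
#' @param YT output of [light_temperature_potential()].
#' @return YW in kg/ha.
#' @export
climatic_potential <- function(fw, YT) {
  f <- as_values(fw)
  fin <- stats::na.omit(as.vector(f))
  if (any(fin < 0 | fin > 1)) stop("`fw` must lie in [0, 1]")
  rewrap(f * as_values(YT), YT)
}

#' Soil production potential YS
#'
#' `YS = f(s) * YW` with the soil correction coefficient f(s) in (0, 1],
#' summarizing elevation, pH, fertility, slope and texture restrictions
#' (supplied as a raster layer; its construction is outside the model).
#'
#' @param fs soil correction coefficient in (0, 1].
#' @param YW output of [climatic_potential()].
#' @return YS in kg/ha.
#' @export
soil_potential <- function(fs, YW) {
  f <- as_values(fs)
  fin <- stats::na.omit(as.vector(f))
  if (any(fin <= 0 | fin > 1)) stop("`fs` must lie in (0, 1]")
  rewrap(f * as_values(YW), YW)
}

#' Run the full step-wise revision chain on one epoch's climate fields
#'
#' @param fields list with co-registered [raster_grid()] layers `Q`, `T`,
#'   `fw`, `fs` (as produced by [generate_climate_fields()]).
#' @param params a [step_model_params()].
#' @return list of class `potential_yield_grid` with raster layers
#'   `YQ`, `YT`, `YW`, `YS` (kg/ha).
#' @export
potential_yield_grid <- function(fields, params = step_model_params()) {
  for (nm in c("T", "fw", "fs")) {
    assert_coregistered(fields$Q, fields[[nm]],
                        sprintf("climate layers Q and %s", nm))
  }
  YQ <- photosynthetic_potential(fields$Q, params)
  YT <- light_temperature_potential(fields$T, YQ, params)
  YW <- climatic_potential(fields$fw, YT)
  YS <- soil_potential(fields$fs, YW)
  structure(list(YQ = YQ, YT = YT, YW = YW, YS = YS, params = params),
            class = "potential_yield_grid")
}

#' @export
print.potential_yield_grid <- function(x, ...) {
  means <- vapply(x[c("YQ", "YT", "YW", "YS")],
                  function(g) mean(g$values, na.rm = TRUE), numeric(1))
  cat("<potential_yield_grid> mean kg/ha: ",
      paste(sprintf("%s=%.0f", names(means), means), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' County mean soil production potential over cultivated land
#'
#' Zonal mean of the YS surface over cultivated cells (paddy or dryland)
#' whose centers fall inside each county polygon, converted to t/ha.
#' Counties with no cultivated cell (or lying outside the raster) are
#' returned as `NA`, never as zero.
#'
#' @param pgrid a [potential_yield_grid()] (or a single YS [raster_grid()]).
#' @param landuse land-use class [raster_grid()]; codes in
#'   `cultivated_codes` count as cultivated.
#' @param counties a [county_frame()].
#' @param cultivated_codes land-use codes treated as cultivated
#'   (default `c(1, 2)` = paddy, dryland).
#' @param assignment optional precomputed [assign_cells_to_counties()]
#'   matrix (saves recomputation across epochs).
#' @return data.frame `county_id`, `ys_mean` (t/ha), `n_cultivated_cells`.
#' @export
county_mean_potential <- function(pgrid, landuse, counties,
                                  cultivated_codes = c(1, 2),
                                  assignment = NULL) {
  ys <- if (inherits(pgrid, "potential_yield_grid")) pgrid$YS else pgrid
  assert_coregistered(ys, landuse, "YS and land-use layers")
  if (is.null(assignment)) {
    assignment <- assign_cells_to_counties(ys, counties)
  }
  cult <- !is.na(landuse$values) & landuse$values %in% cultivated_codes
  ok <- cult & !is.na(ys$values) & !is.na(assignment)
  idx <- assignment[ok]
  vals <- ys$values[ok]
  n <- nrow(counties)
  sums <- vapply(seq_len(n), function(i) sum(vals[idx == i]), numeric(1))
  cnts <- tabulate(idx, nbins = n)
  ys_mean <- ifelse(cnts > 0, (sums / cnts) / 1000, NA_real_)
  data.frame(county_id = counties$county_id,
             ys_mean = ys_mean,
             n_cultivated_cells = cnts,
             stringsAsFactors = FALSE)
}
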