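#' Registry of the 27 candidate determinants of yield-gap change
#'
#' The candidate factors fall in four categories: climatic (4), socioeconomic
#' (7), land-use conditions (7) and human investment (9). Abbreviations are
#' the ones used throughout the package's panel tables. `static` marks
#' terrain variables that do not change across epochs.
#'
#' @return data.frame with columns `abbrev`, `category`, `static`,
#'   `description`.
#' @examples
#' table(determinant_variables()$category)
#' @export
determinant_variables <- function() {
  df <- data.frame(
    abbrev = c(
      "SH", "SMI", "Temp", "Prec",
      "RSP", "LDD", "UR", "FL", "GDPPC", "RAGDP", "PCAI",
      "DEM", "Slope", "RPF", "NP", "PD", "LPI", "CLPL",
      "PSAGC", "MCI", "APPA", "REC", "FPA", "TPA", "IA", "PAMPA", "ASFF"
    ),
    category = rep(
      c("climatic", "socioeconomic", "land_use", "human_investment"),
      times = c(4L, 7L, 7L, 9L)
    ),
    static = FALSE,
    description = c(
      "sunshine hours (h)",
      "solar radiation intensity (W/km)",
      "mean temperature (degC)",
      "precipitation (mm)",
      "rural household population (10k people)",
      "land development degree (%)",
      "population urbanization rate (%)",
      "farm labor (10k people)",
      "GDP per capita (CNY)",
      "ratio of agricultural GDP (%)",
      "per capita annual net income of farmers (CNY)",
      "elevation of cultivated land (m)",
      "slope of cultivated land (deg)",
      "area ratio of paddy fields (%)",
      "number of patches",
      "patch density (1/ha)",
      "largest patch index",
      "cultivated land quality level",
      "proportion of sown area of grain crops (%)",
      "multiple cropping index of grain crops (%)",
      "agricultural practitioners per area (person/ha)",
      "rural electricity consumption (10k W)",
      "fertilizer per area (t/ha)",
      "tractor-plowed area (ha)",
      "irrigated area (ha)",
      "power of agricultural machinery per area (kW/ha)",
      "area of soil testing and formula fertilization (ha)"
    ),
    stringsAsFactors = FALSE
  )
  df$static[df$abbrev %in% c("DEM", "Slope")] <- TRUE
  df
}

#' Read a county-by-epoch panel table from CSV
#'
#' The panel holds, per (county, epoch): the actual farm yield (t/ha), the
#' grain sown area (ha) and the candidate determinant columns keyed by the
#' abbreviations of [determinant_variables()]. Blank cells become `NA`;
#' missingness is preserved, never coerced to zero.
#'
#' @param path CSV path with a header row.
#' @param schema optional named character vector mapping the canonical
#'   column names (names) to the names used in the file (values).
#' @return data.frame with attributes `extra_columns` (columns outside the
#'   known schema, retained) and `missing_determinants` (registry
#'   abbreviations absent from the file).
#' @export
read_epoch_table <- function(path, schema = NULL) {
  if (!file.exists(path)) stop(sprintf("panel file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      j <- match(schema[[canon]], names(df))
      if (!is.na(j)) names(df)[j] <- canon
    }
  }
  mandatory <- c("county_id", "epoch", "actual_farm_yield")
  miss <- setdiff(mandatory, names(df))
  if (length(miss)) {
    stop(sprintf("missing mandatory column(s): %s", paste(miss, collapse = ", ")))
  }
  df$county_id <- as.character(df$county_id)
  df$epoch <- as.character(df$epoch)
  if (!is.numeric(df$actual_farm_yield)) {
    stop("`actual_farm_yield` must be numeric (t/ha)")
  }
  if (any(stats::na.omit(df$actual_farm_yield) < 0)) {
    stop("negative actual_farm_yield encountered")
  }
  key <- paste(df$county_id, df$epoch, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (county_id, epoch) rows in panel")
  }
  vars <- determinant_variables()$abbrev
  known <- c(mandatory, "sown_area_grain", vars)
  for (v in intersect(c("sown_area_grain", vars), names(df))) {
    if (!is.numeric(df[[v]])) df[[v]] <- suppressWarnings(as.numeric(df[[v]]))
  }
  attr(df, "extra_columns") <- setdiff(names(df), known)
  attr(df, "missing_determinants") <- setdiff(vars, names(df))
  df
}
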