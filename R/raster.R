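#' Georeferenced raster grid
#'
#' Minimal single-band raster container used for all gridded inputs of the
#' potential-yield model (growing-season radiation Q, mean temperature T,
#' water and soil correction coefficients, land-use classes).
#'
#' Conventions: row-major storage with row 1 the northernmost row; origin at
#' the lower-left corner (`xll`, `yll`); square cells of side `cellsize` in
#' projected map units; a cell belongs to whatever polygon contains its
#' center. Nodata cells are held as `NA` internally and are excluded from
#' every aggregation; `nodata` is only the on-disk sentinel.
#'
#' @param values numeric matrix (row 1 = north). `NA` marks nodata.
#' @param xll,yll coordinates of the lower-left corner of the grid.
#' @param cellsize cell side length in map units; strictly positive.
#' @param nodata sentinel value used on disk for missing cells.
#' @param crs free-text identifier of the (single, projected) CRS of the run.
#' @param units free-text units of the layer values, recorded not guessed.
#' @return An object of class `raster_grid`.
#' @examples
#' g <- raster_grid(matrix(1:6, nrow = 2), cellsize = 100, units = "kcal/cm2")
#' dim(g$values)
#' @export
raster_grid <- function(values, xll = 0, yll = 0, cellsize = 1,
                        nodata = -9999, crs = "local", units = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("raster values must be numeric")
  assert_scalar_number(cellsize, "cellsize")
  if (cellsize <= 0) stop("`cellsize` must be strictly positive")
  assert_scalar_number(xll, "xll")
  assert_scalar_number(yll, "yll")
  structure(
    list(values = values, xll = xll, yll = yll, cellsize = cellsize,
         nodata = nodata, crs = crs, units = units),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<raster_grid> %d x %d cells, cellsize %g, origin (%g, %g), crs %s\n",
              nrow(v), ncol(v), x$cellsize, x$xll, x$yll, x$crs))
  cat(sprintf("  values: [%g, %g], %d nodata cell(s)%s\n",
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)),
              sum(is.na(v)),
              if (is.null(x$units)) "" else paste0(", units ", x$units)))
  invisible(x)
}

#' Coordinates of all cell centers
#'
#' @param grid a [raster_grid()].
#' @return data.frame with columns `row`, `col`, `x`, `y` in raster order
#'   (row-major, row 1 = north).
#' @export
cell_centers <- function(grid) {
  nr <- nrow(grid$values)
  nc <- ncol(grid$values)
  row <- rep(seq_len(nr), each = nc)
  col <- rep(seq_len(nc), times = nr)
  data.frame(
    row = row, col = col,
    x = grid$xll + (col - 0.5) * grid$cellsize,
    y = grid$yll + (nr - row + 0.5) * grid$cellsize
  )
}

#' Read a single-band raster from an ESRI ASCII grid file
#'
#' The on-disk raster format of the package is the plain-text ESRI ASCII
#' grid (`ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value` header
#' followed by north-to-south rows). An optional `<path>.prj` sidecar holds
#' the CRS identifier. Cells equal to the nodata sentinel become `NA`.
#'
#' @param path path to an `.asc` file.
#' @param units optional units string to attach (units come from run
#'   configuration, they are never guessed from the file).
#' @return a [raster_grid()].
#' @export
read_raster <- function(path, units = NULL) {
  if (!file.exists(path)) stop(sprintf("raster file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6) {
    stop(sprintf("not a georeferenced ASCII grid (truncated header): %s", path))
  }
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2) {
      stop(sprintf("not a georeferenced ASCII grid (bad header line %d): %s",
                   i, path))
    }
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% names(hdr))) {
    stop(sprintf("missing georeference fields (%s) in %s",
                 paste(setdiff(need, names(hdr)), collapse = ", "), path))
  }
  nc <- as.integer(hdr$ncols)
  nr <- as.integer(hdr$nrows)
  body <- scan(text = paste(lines[-(1:6)], collapse = "\n"),
               what = numeric(), quiet = TRUE)
  if (length(body) != nr * nc) {
    stop(sprintf(
      "expected a single band of %d values, found %d in %s (multi-band input is not supported; supply one band per file)",
      nr * nc, length(body), path))
  }
  vals <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  vals[vals == hdr$nodata_value] <- NA_real_
  prj <- paste0(path, ".prj")
  crs <- if (file.exists(prj)) readLines(prj, warn = FALSE)[1] else "local"
  raster_grid(vals, xll = hdr$xllcorner, yll = hdr$yllcorner,
              cellsize = hdr$cellsize, nodata = hdr$nodata_value,
              crs = crs, units = units)
}

#' Write a raster grid to an ESRI ASCII grid file
#'
#' `NA` cells are written as the grid's nodata sentinel. Values are printed
#' with 17 significant digits so a write/read round trip reproduces doubles
#' exactly. A `<path>.prj` sidecar records the CRS.
#'
#' @param grid a [raster_grid()].
#' @param path output path (conventionally `.asc`).
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path) {
  stopifnot(inherits(grid, "raster_grid"))
  v <- grid$values
  v[is.na(v)] <- grid$nodata
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.17g", grid$xll),
    sprintf("yllcorner %.17g", grid$yll),
    sprintf("cellsize %.17g", grid$cellsize),
    sprintf("NODATA_value %.17g", grid$nodata)
  )
  rows <- apply(v, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  if (!is.null(grid$crs)) writeLines(as.character(grid$crs), paste0(path, ".prj"))
  invisible(path)
}

# Check that two grids are co-registered (same shape, transform and CRS).
# All layers of one climate field set must satisfy this.
assert_coregistered <- function(a, b, what = "layers") {
  same <- identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(c(a$xll, a$yll, a$cellsize),
                     c(b$xll, b$yll, b$cellsize))) &&
    identical(a$crs, b$crs)
  if (!same) {
    stop(sprintf("%s are not co-registered (shape, transform and crs must match)",
                 what))
  }
  invisible(TRUE)
}
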