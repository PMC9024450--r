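#' County polygon frame
#'
#' A data.frame of county attributes plus a `geometry` list-column of
#' polygon rings (closed two-column matrices of x/y vertices in the run's
#' projected CRS). This is the vector-side counterpart of [raster_grid()].
#'
#' @param county_id character, unique.
#' @param name display names (defaults to the ids).
#' @param geometry list of numeric matrices with 2 columns; first and last
#'   vertex may coincide (rings are closed on write).
#' @param is_municipal_district logical; urban districts are excluded from
#'   the determinant analysis and the improvement screening.
#' @param area_ha county area in hectares.
#' @param crs CRS identifier shared by the whole frame.
#' @return object of class `county_frame` (also a data.frame).
#' @export
county_frame <- function(county_id, geometry, name = county_id,
                         is_municipal_district = FALSE, area_ha = NA_real_,
                         crs = "local") {
  county_id <- as.character(county_id)
  dup <- county_id[duplicated(county_id)]
  if (length(dup)) {
    stop(sprintf("duplicate county_id: %s", paste(unique(dup), collapse = ", ")))
  }
  if (!is.list(geometry) || length(geometry) != length(county_id)) {
    stop("`geometry` must be a list of polygon rings, one per county")
  }
  for (g in geometry) {
    if (!is.matrix(g) || ncol(g) != 2 || nrow(g) < 3 || !is.numeric(g)) {
      stop("each geometry must be a numeric matrix of >= 3 x/y vertices")
    }
  }
  df <- data.frame(
    county_id = county_id,
    name = rep_len(as.character(name), length(county_id)),
    is_municipal_district = rep_len(as.logical(is_municipal_district),
                                    length(county_id)),
    area_ha = rep_len(as.numeric(area_ha), length(county_id)),
    stringsAsFactors = FALSE
  )
  df$geometry <- geometry
  attr(df, "crs") <- crs
  class(df) <- c("county_frame", "data.frame")
  df
}

#' @export
print.county_frame <- function(x, ...) {
  cat(sprintf("<county_frame> %d counties (%d municipal districts), crs %s\n",
              nrow(x), sum(x$is_municipal_district), attr(x, "crs")))
  print(utils::head(as.data.frame(x)[, c("county_id", "name",
                                         "is_municipal_district", "area_ha")]))
  invisible(x)
}

close_ring <- function(ring) {
  if (!all(ring[1, ] == ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
  ring
}

#' Read county polygons from GeoJSON
#'
#' Expects a FeatureCollection of Polygon features carrying a `county_id`
#' property (plus optional `name`, `is_municipal_district`, `area_ha`).
#' Only the outer ring of each polygon is used; duplicate ids are an error.
#'
#' @param path GeoJSON file path.
#' @param crs CRS identifier to record for the frame (inputs are assumed to
#'   already be in the run's projected CRS; no reprojection is performed).
#' @return a [county_frame()].
#' @export
read_counties <- function(path, crs = "local") {
  if (!file.exists(path)) stop(sprintf("county file not found: %s", path))
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection")) {
    stop("expected a GeoJSON FeatureCollection")
  }
  feats <- gj$features
  get_prop <- function(f, key, default) {
    v <- f$properties[[key]]
    if (is.null(v)) default else v
  }
  ids <- vapply(feats, function(f) {
    v <- f$properties$county_id
    if (is.null(v)) stop("feature without a county_id property")
    as.character(v)
  }, character(1))
  geometry <- lapply(feats, function(f) {
    if (!identical(f$geometry$type, "Polygon")) {
      stop("only Polygon geometries are supported")
    }
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    close_ring(m)
  })
  county_frame(
    county_id = ids,
    geometry = geometry,
    name = vapply(feats, get_prop, character(1), key = "name", default = ""),
    is_municipal_district = vapply(feats, function(f) {
      isTRUE(get_prop(f, "is_municipal_district", FALSE))
    }, logical(1)),
    area_ha = vapply(feats, function(f) {
      as.numeric(get_prop(f, "area_ha", NA_real_))
    }, numeric(1)),
    crs = crs
  )
}

#' Write county polygons to GeoJSON
#'
#' @param counties a [county_frame()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counties <- function(counties, path) {
  stopifnot(inherits(counties, "county_frame"))
  feats <- lapply(seq_len(nrow(counties)), function(i) {
    ring <- close_ring(counties$geometry[[i]])
    list(
      type = "Feature",
      properties = list(
        county_id = counties$county_id[i],
        name = counties$name[i],
        is_municipal_district = counties$is_municipal_district[i],
        area_ha = counties$area_ha[i]
      ),
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(ring)),
                                  function(k) as.list(ring[k, ])))
      )
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = feats),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

# Ray-casting point-in-polygon, vectorized over points.
points_in_ring <- function(px, py, ring) {
  ring <- close_ring(ring)
  n <- nrow(ring) - 1L
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Assign raster cells to counties by cell center
#'
#' Center-point zonal assignment: a cell belongs to the county whose polygon
#' contains its center. Cells outside every county get `NA`.
#'
#' @param grid a [raster_grid()] defining the cell layout.
#' @param counties a [county_frame()].
#' @return integer matrix of county row indices, same shape as `grid$values`.
#' @export
assign_cells_to_counties <- function(grid, counties) {
  cc <- cell_centers(grid)
  idx <- rep(NA_integer_, nrow(cc))
  for (i in seq_len(nrow(counties))) {
    ring <- counties$geometry[[i]]
    bb <- c(range(ring[, 1]), range(ring[, 2]))
    cand <- which(is.na(idx) &
                    cc$x >= bb[1] & cc$x <= bb[2] &
                    cc$y >= bb[3] & cc$y <= bb[4])
    if (!length(cand)) next
    hit <- points_in_ring(cc$x[cand], cc$y[cand], ring)
    idx[cand[hit]] <- i
  }
  matrix(idx, nrow = nrow(grid$values), ncol = ncol(grid$values), byrow = TRUE)
}
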