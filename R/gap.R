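#' Yield gap
#'
#' `YGAP = mean potential yield - mean actual farm yield` (t/ha) per county.
#' A negative gap (farm yield exceeding the modeled potential) is kept and
#' flagged downstream, never clipped: it signals a model/data inconsistency
#' worth seeing. `NA` inputs propagate.
#'
#' @param ys_mean county mean soil production potential, t/ha.
#' @param yfarm_mean county mean actual farm yield, t/ha.
#' @return numeric vector of gaps, t/ha.
#' @examples
#' yield_gap(13.53, 4.96)  # 8.57
#' @export
yield_gap <- function(ys_mean, yfarm_mean) {
  if (any(stats::na.omit(ys_mean) < 0) || any(stats::na.omit(yfarm_mean) < 0)) {
    stop("yields must be non-negative")
  }
  ys_mean - yfarm_mean
}

#' Relative yield gap
#'
#' `RYGAP = 100 * YGAP / ys_mean` (percent of the potential yield).
#'
#' @param ygap yield gap, t/ha.
#' @param ys_mean county mean potential yield, t/ha; zero potentials give
#'   `NA` with a warning.
#' @return percent values.
#' @export
relative_yield_gap <- function(ygap, ys_mean) {
  out <- 100 * ygap / ys_mean
  zero <- !is.na(ys_mean) & ys_mean == 0
  if (any(zero)) {
    warning(sprintf("%d county(ies) with zero potential yield; RYGAP set to NA",
                    sum(zero)))
    out[zero] <- NA_real_
  }
  out
}

#' Default yield-gap bin edges (t/ha)
#'
#' Bins `<3, 3-6, 6-9, 9-12, >=12` t/ha; intervals are half-open
#' `[lo, hi)` with the lower edge included.
#' @return numeric vector of interior edges.
#' @export
gap_bin_edges <- function() c(3, 6, 9, 12)

bin_labels_from_edges <- function(edges) {
  c(sprintf("<%g", edges[1]),
    sprintf("%g-%g", edges[-length(edges)], edges[-1]),
    sprintf(">=%g", edges[length(edges)]))
}

#' Bin county yield gaps and tabulate counts and ratios
#'
#' @param values yield gaps (t/ha); `NA` values are excluded (counts sum to
#'   the number of non-missing counties).
#' @param edges strictly increasing interior edges; intervals are
#'   `(-Inf, e1), [e1, e2), ..., [ek, Inf)`.
#' @return data.frame `bin`, `n`, `ratio` (percent of the non-missing
#'   total, rounded to 2 decimals as in report tables).
#' @examples
#' bin_counties(c(2.9, 3.0, 5.99, 6.0, 12.0))
#' @export
bin_counties <- function(values, edges = gap_bin_edges()) {
  if (is.unsorted(edges, strictly = TRUE)) {
    stop("bin edges must be strictly increasing (overlapping bins rejected)")
  }
  v <- values[!is.na(values)]
  cuts <- cut(v, breaks = c(-Inf, edges, Inf), right = FALSE,
              labels = bin_labels_from_edges(edges))
  n <- as.vector(table(cuts))
  total <- length(v)
  data.frame(bin = levels(cuts), n = n,
             ratio = if (total > 0) round(100 * n / total, 2) else rep(NA_real_, length(n)),
             stringsAsFactors = FALSE)
}

#' Build the county yield table for all epochs
#'
#' Joins the per-county mean potential with the farm-yield panel and derives
#' YGAP, RYGAP and the gap bin per (county, epoch).
#'
#' @param potential data.frame `county_id`, `epoch`, `ys_mean` (t/ha) as
#'   stacked [county_mean_potential()] outputs.
#' @param panel epoch table with `county_id`, `epoch`, `actual_farm_yield`
#'   (t/ha) and optionally `sown_area_grain` (ha).
#' @return data.frame of class `county_yield_table` with columns
#'   `county_id`, `epoch`, `ys_mean`, `yfarm_mean`, `ygap`, `rygap`,
#'   `gap_bin`, `negative_gap` flag (and `sown_area_grain` if supplied).
#' @export
county_yield_table <- function(potential, panel) {
  need <- c("county_id", "epoch", "ys_mean")
  stopifnot(all(need %in% names(potential)))
  keep <- intersect(c("county_id", "epoch", "actual_farm_yield",
                      "sown_area_grain"), names(panel))
  out <- merge(potential[, need], panel[, keep],
               by = c("county_id", "epoch"), all.x = TRUE)
  names(out)[names(out) == "actual_farm_yield"] <- "yfarm_mean"
  out$ygap <- yield_gap(out$ys_mean, out$yfarm_mean)
  out$rygap <- relative_yield_gap(out$ygap, out$ys_mean)
  out$gap_bin <- as.character(cut(out$ygap,
                                  breaks = c(-Inf, gap_bin_edges(), Inf),
                                  right = FALSE,
                                  labels = bin_labels_from_edges(gap_bin_edges())))
  out$negative_gap <- !is.na(out$ygap) & out$ygap < 0
  if (any(out$negative_gap)) {
    yg_log("%d county-epoch rows with farm yield above modeled potential",
           sum(out$negative_gap))
  }
  out <- out[order(out$epoch, out$county_id), ]
  rownames(out) <- NULL
  class(out) <- c("county_yield_table", "data.frame")
  out
}

#' Yield-gap change between epochs
#'
#' `YGC = YGAP(end) - YGAP(start)` per county; negative values mean the gap
#' is closing. Computes every consecutive epoch pair plus the full period,
#' with change classes following the conventional map legend: sub-periods
#' are cut at (-3, -2, -1, 0, 1) and the full period at (-6, -4, -2, 0, 2)
#' t/ha. The sub-period changes telescope exactly to the full-period change.
#'
#' @param table a [county_yield_table()].
#' @param epochs ordered epoch labels (default: sorted unique epochs).
#' @return data.frame of class `gap_change_table`: `county_id`,
#'   `period`, `epoch_start`, `epoch_end`, `ygc`, `change_class`,
#'   `is_full_period`. Counties missing either epoch are omitted (logged).
#' @export
yield_gap_change <- function(table, epochs = sort(unique(table$epoch))) {
  if (length(epochs) < 2) stop("need at least two epochs")
  wide <- stats::reshape(
    as.data.frame(table)[, c("county_id", "epoch", "ygap")],
    idvar = "county_id", timevar = "epoch", direction = "wide"
  )
  names(wide) <- sub("^ygap\\.", "", names(wide))
  missing_epochs <- setdiff(epochs, names(wide))
  if (length(missing_epochs)) {
    stop(sprintf("epoch(s) absent from table: %s",
                 paste(missing_epochs, collapse = ", ")))
  }
  pairs <- cbind(epochs[-length(epochs)], epochs[-1])
  pairs <- rbind(pairs, c(epochs[1], epochs[length(epochs)]))
  full <- c(rep(FALSE, nrow(pairs) - 1), TRUE)
  sub_edges <- c(-3, -2, -1, 0, 1)
  full_edges <- c(-6, -4, -2, 0, 2)
  res <- lapply(seq_len(nrow(pairs)), function(k) {
    a <- wide[[pairs[k, 1]]]
    b <- wide[[pairs[k, 2]]]
    ok <- !is.na(a) & !is.na(b)
    if (any(!ok)) {
      yg_log("period %s-%s: %d county(ies) omitted for missing YGAP",
             pairs[k, 1], pairs[k, 2], sum(!ok))
    }
    edges <- if (full[k]) full_edges else sub_edges
    ygc <- (b - a)[ok]
    data.frame(
      county_id = wide$county_id[ok],
      period = paste(pairs[k, 1], pairs[k, 2], sep = "_"),
      epoch_start = pairs[k, 1],
      epoch_end = pairs[k, 2],
      ygc = ygc,
      change_class = as.character(
        cut(ygc, breaks = c(-Inf, edges, Inf), right = FALSE,
            labels = paste0("L", seq_len(length(edges) + 1)))),
      is_full_period = full[k],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("gap_change_table", "data.frame")
  out
}

#' Summary statistics of yield gaps per epoch
#'
#' Min / max / mean YGAP plus bin counts and ratios per epoch, mirroring the
#' structure of a provincial report table (2-decimal rounding in `ratio`
#' only; `min`, `max`, `mean` stay full precision).
#'
#' @param table a [county_yield_table()].
#' @return data.frame, one row per epoch x bin, with epoch-level min, max,
#'   mean repeated across the epoch's rows.
#' @export
gap_summary <- function(table) {
  out <- do.call(rbind, lapply(split(as.data.frame(table), table$epoch),
                               function(d) {
    b <- bin_counties(d$ygap)
    data.frame(epoch = d$epoch[1],
               min = min(d$ygap, na.rm = TRUE),
               max = max(d$ygap, na.rm = TRUE),
               mean = mean(d$ygap, na.rm = TRUE),
               b, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
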