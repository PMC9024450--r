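#' Screen counties with high yield-improvement capacity
#'
#' Selects counties whose relative yield gap at the final epoch is strictly
#' greater than the threshold (default 30%, above the 25% of the gap that
#' is typically considered unexploitable), then removes municipal
#' districts, where agriculture is not the main industry. Counties at
#' exactly the threshold are excluded (and logged). Result is ordered by
#' RYGAP descending.
#'
#' @param table a [county_yield_table()] restricted to (or filtered for)
#'   the screening epoch, with `rygap` computed.
#' @param counties a [county_frame()] with `is_municipal_district`.
#' @param threshold RYGAP threshold in percent, in (0, 100]; strictly
#'   greater-than (default 30).
#' @param exclude_municipal_districts default TRUE.
#' @return data.frame `county_id`, `rygap`, `ygap`, ordered by `rygap`
#'   descending; attributes `n_above_threshold` (before the district
#'   exclusion) and `n_districts_excluded`.
#' @export
screen_high_gap_counties <- function(table, counties, threshold = 30,
                                     exclude_municipal_districts = TRUE) {
  assert_scalar_number(threshold, "threshold")
  if (threshold <= 0 || threshold > 100) {
    stop("`threshold` must lie in (0, 100] percent")
  }
  d <- as.data.frame(table)
  at_bar <- !is.na(d$rygap) & d$rygap == threshold
  if (any(at_bar)) {
    yg_log("%d county(ies) exactly at the %g%% threshold excluded (strict >)",
           sum(at_bar), threshold)
  }
  sel <- !is.na(d$rygap) & d$rygap > threshold
  n_above <- sum(sel)
  if (exclude_municipal_districts) {
    distr <- counties$county_id[counties$is_municipal_district]
    sel <- sel & !(d$county_id %in% distr)
  }
  out <- d[sel, intersect(c("county_id", "rygap", "ygap"), names(d))]
  out <- out[order(-out$rygap, out$county_id), ]
  rownames(out) <- NULL
  attr(out, "n_above_threshold") <- n_above
  attr(out, "n_districts_excluded") <- n_above - nrow(out)
  out
}

#' Incremental grain production under a yield uplift scenario
#'
#' Total extra production (tonnes) if the actual farm yields of the
#' selected counties rise by `uplift`:
#' `sum(sown_area * actual_yield * uplift)`. Linear in the uplift and
#' additive over counties; counties without a sown area are skipped with a
#' warning.
#'
#' @param sown_area_ha grain sown area per selected county, ha.
#' @param actual_yield_t_ha actual farm yield per selected county, t/ha.
#' @param uplift fractional yield increase in (0, 1) (default 0.05).
#' @return total additional production in tonnes.
#' @examples
#' incremental_production(1e5, 6, 0.05)  # 30000 t
#' @export
incremental_production <- function(sown_area_ha, actual_yield_t_ha,
                                   uplift = 0.05) {
  assert_scalar_number(uplift, "uplift")
  if (uplift < 0 || uplift >= 1) stop("`uplift` must lie in [0, 1)")
  if (length(sown_area_ha) != length(actual_yield_t_ha)) {
    stop("area and yield vectors must align")
  }
  if (any(stats::na.omit(sown_area_ha) < 0) ||
      any(stats::na.omit(actual_yield_t_ha) < 0)) {
    stop("areas and yields must be non-negative")
  }
  skip <- is.na(sown_area_ha)
  if (any(skip)) {
    warning(sprintf("%d county(ies) without sown area skipped", sum(skip)))
  }
  sum(sown_area_ha[!skip] * actual_yield_t_ha[!skip] * uplift, na.rm = TRUE)
}

write_stage_csv <- function(df, outdir, name) {
  utils::write.csv(as.data.frame(df), file.path(outdir, name),
                   row.names = FALSE)
}

#' Run the full yield-gap analysis pipeline on a synthetic region
#'
#' Executes simulate -> potential -> gap -> cluster -> determinants ->
#' identify in order, writing every stage's outputs and a config snapshot
#' to `outdir`. Idempotent under a fixed seed: two runs with the same
#' config produce byte-identical files. Any stage failure aborts with a
#' stage-named error; outputs of earlier stages are preserved.
#'
#' @param config a [sim_config()]; its `seed` drives every random draw.
#' @param outdir output directory (created).
#' @param params [step_model_params()].
#' @param n_perm permutations for Moran/LISA inference (default 999).
#' @param ntree random-forest size (default 1000).
#' @param threshold RYGAP screening threshold, percent (default 30).
#' @param uplift yield-uplift scenario fraction (default 0.05).
#' @param alpha significance level for LISA classes and hot-spot maps.
#' @return invisible list with all stage results: `region`, `yield_table`,
#'   `gap_change`, `summary`, `hotspots`, `bimoran`, `lisa`, `importance`,
#'   `top10`, `contribution`, `selected`, `incremental_tonnes`.
#' @export
run_pipeline <- function(config = sim_config(), outdir,
                         params = step_model_params(),
                         n_perm = 999, ntree = 1000,
                         threshold = 30, uplift = 0.05, alpha = 0.05) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  region <- stop_stage("simulate", {
    r <- simulate_region(config, params)
    write_counties(r$counties, file.path(outdir, "counties.geojson"))
    cfg <- r$config; class(cfg) <- NULL
    yaml::write_yaml(cfg, file.path(outdir, "config.yaml"))
    write_stage_csv(r$panel, outdir, "panel.csv")
    r
  })

  ys_table <- stop_stage("potential", {
    write_stage_csv(region$ys_table, outdir, "county_potential.csv")
    region$ys_table
  })

  gap <- stop_stage("gap", {
    yt <- county_yield_table(ys_table, region$panel)
    gc <- yield_gap_change(yt, epochs = config$epochs)
    sm <- gap_summary(yt)
    write_stage_csv(yt, outdir, "county_yield_table.csv")
    write_stage_csv(gc, outdir, "gap_change_table.csv")
    write_stage_csv(sm, outdir, "gap_bin_summary.csv")
    list(yield_table = yt, gap_change = gc, summary = sm)
  })

  cluster <- stop_stage("cluster", {
    w <- build_contiguity_weights(region$counties)
    yt <- gap$yield_table
    hotspots <- list()
    for (e in config$epochs) {
      d <- yt[yt$epoch == e, ]
      x <- d$ygap[match(w$ids, d$county_id)]
      hs <- getis_ord_gi_star(x, w)
      hotspots[[e]] <- hs
      write_stage_csv(hs, outdir, sprintf("hotspot_%s.csv", e))
    }
    gc <- gap$gap_change
    sub_periods <- unique(gc$period[!gc$is_full_period])
    bim <- list()
    lisa <- list()
    if (length(sub_periods) >= 2) {
      for (k in seq_len(length(sub_periods) - 1)) {
        pa <- sub_periods[k]; pb <- sub_periods[k + 1]
        da <- gc[gc$period == pa, ]; db <- gc[gc$period == pb, ]
        common <- intersect(w$ids, intersect(da$county_id, db$county_id))
        x <- da$ygc[match(w$ids, da$county_id)]
        y <- db$ygc[match(w$ids, db$county_id)]
        if (!setequal(common, w$ids)) {
          stop(sprintf("periods %s/%s do not cover all counties", pa, pb))
        }
        tag <- sprintf("%s_vs_%s", pa, pb)
        gi <- bivariate_moran_global(x, y, w, n_perm = n_perm,
                                     seed = derive_seed(config$seed, 400L + k))
        li <- bivariate_lisa(x, y, w, n_perm = n_perm, alpha = alpha,
                             seed = derive_seed(config$seed, 500L + k))
        bim[[tag]] <- gi
        lisa[[tag]] <- li
        write_stage_csv(
          data.frame(pair = tag, global_i = gi$global_i,
                     pseudo_p = gi$pseudo_p, n_perm = gi$n_perm),
          outdir, sprintf("bimoran_%s.csv", tag))
        write_stage_csv(li, outdir, sprintf("lisa_%s.csv", tag))
      }
    }
    list(weights = w, hotspots = hotspots, bimoran = bim, lisa = lisa)
  })

  det <- stop_stage("determinants", {
    panel_path <- file.path(outdir, "panel.csv")
    if (!file.exists(panel_path)) stop("panel.csv not found in run directory")
    panel <- read_epoch_table(panel_path)
    periods <- unique(gap$gap_change$period)
    importance <- list()
    for (p in periods) {
      fm <- assemble_factor_matrix(panel, gap$gap_change, p, region$counties)
      res <- fit_importance(fm, ntree = ntree,
                            seed = derive_seed(config$seed,
                                               600L + match(p, periods)))
      importance[[p]] <- res
      write_stage_csv(res, outdir, sprintf("importance_%s.csv", p))
    }
    top10 <- top_k_frequency(importance)
    contrib <- do.call(rbind, lapply(names(importance), function(p) {
      cbind(period = p, category_contribution(importance[[p]]))
    }))
    write_stage_csv(top10, outdir, "top10_frequency.csv")
    write_stage_csv(contrib, outdir, "category_contribution.csv")
    list(importance = importance, top10 = top10, contribution = contrib)
  })

  ident <- stop_stage("identify", {
    yt <- gap$yield_table
    final <- yt[yt$epoch == config$epochs[length(config$epochs)], ]
    sel <- screen_high_gap_counties(final, region$counties,
                                    threshold = threshold)
    idx <- match(sel$county_id, final$county_id)
    extra <- incremental_production(final$sown_area_grain[idx],
                                    final$yfarm_mean[idx], uplift)
    write_stage_csv(sel, outdir, "selected_counties.csv")
    write_stage_csv(
      data.frame(threshold_pct = threshold, uplift = uplift,
                 n_selected = nrow(sel),
                 incremental_tonnes = extra),
      outdir, "incremental_production.csv")
    list(selected = sel, incremental_tonnes = extra)
  })

  invisible(list(
    region = region, yield_table = gap$yield_table,
    gap_change = gap$gap_change, summary = gap$summary,
    weights = cluster$weights, hotspots = cluster$hotspots,
    bimoran = cluster$bimoran, lisa = cluster$lisa,
    importance = det$importance, top10 = det$top10,
    contribution = det$contribution,
    selected = ident$selected,
    incremental_tonnes = ident$incremental_tonnes
  ))
}
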