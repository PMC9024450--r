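#' Assemble the factor matrix for one period's determinant analysis
#'
#' Joins the determinant panel (at the period's start epoch) with the
#' yield-gap change of the period, then applies the retention rules:
#' municipal districts are dropped (agriculture is not their main
#' industry), as is any county with a missing determinant value. Row order
#' is deterministic (by county id).
#'
#' @param panel county-by-epoch determinant table (see
#'   [read_epoch_table()] / [generate_determinant_panel()]).
#' @param ygc a [yield_gap_change()] table.
#' @param period period label present in `ygc$period`.
#' @param counties a [county_frame()] carrying `is_municipal_district`.
#' @param exclude_municipal_districts drop flagged districts (default TRUE).
#' @param min_counties abort below this many retained rows (default 20;
#'   an importance model on fewer counties is unreliable).
#' @return list of class `factor_matrix`: `x` (data.frame of the 27
#'   determinants), `y` (YGC response), `county_id`, `period`,
#'   `categories`, `n_dropped_district`, `n_dropped_missing`.
#' @export
assemble_factor_matrix <- function(panel, ygc, period, counties,
                                   exclude_municipal_districts = TRUE,
                                   min_counties = 20) {
  vars <- determinant_variables()
  missing_vars <- setdiff(vars$abbrev, names(panel))
  if (length(missing_vars)) {
    stop(sprintf("panel lacks determinant column(s): %s",
                 paste(missing_vars, collapse = ", ")))
  }
  yg <- ygc[ygc$period == period, c("county_id", "ygc", "epoch_start")]
  if (!nrow(yg)) stop(sprintf("period '%s' absent from gap-change table", period))
  start_epoch <- yg$epoch_start[1]
  pan <- panel[panel$epoch == start_epoch,
               c("county_id", vars$abbrev), drop = FALSE]
  m <- merge(yg[, c("county_id", "ygc")], pan, by = "county_id")
  m <- m[order(m$county_id), ]
  n0 <- nrow(m)
  if (exclude_municipal_districts) {
    distr <- counties$county_id[counties$is_municipal_district]
    m <- m[!(m$county_id %in% distr), ]
  }
  n_dropped_district <- n0 - nrow(m)
  complete <- stats::complete.cases(m[, vars$abbrev])
  n_dropped_missing <- sum(!complete)
  m <- m[complete, ]
  if (nrow(m) < min_counties) {
    stop(sprintf("only %d counties retained for period '%s' (< %d): importance model would be unreliable",
                 nrow(m), period, min_counties))
  }
  structure(
    list(x = m[, vars$abbrev], y = m$ygc, county_id = m$county_id,
         period = period,
         categories = stats::setNames(vars$category, vars$abbrev),
         n_dropped_district = n_dropped_district,
         n_dropped_missing = n_dropped_missing),
    class = "factor_matrix"
  )
}

#' Normalize raw importances to [0, 1]
#'
#' Negative raw importances (possible for permutation importance of pure
#' noise) are floored at zero, then everything is divided by the maximum so
#' the top factor always scores exactly 1. Invariant to positive rescaling
#' of the raw vector.
#'
#' @param raw named numeric vector of raw importances.
#' @return named numeric scores in \[0, 1\].
#' @export
normalize_scores <- function(raw) {
  if (!length(raw) || all(is.na(raw))) stop("empty importance vector")
  floored <- pmax(raw, 0)
  mx <- max(floored, na.rm = TRUE)
  if (mx == 0) stop("all raw importances are zero or negative; nothing to rank")
  floored / mx
}

#' Random-forest importance ranking of the determinants
#'
#' Fits a regression forest of the period's yield-gap change on the 27
#' determinants and ranks factors by permutation (out-of-bag) importance,
#' normalized to \[0, 1\]. Permutation importance is the default because
#' impurity importance is biased toward high-cardinality variables;
#' `importance_type = "impurity"` is kept for comparison. All counties'
#' features are considered at each split (`mtry = p`), which sharpens the
#' separation between planted signals and noise at these sample sizes.
#' Ties at any rank break deterministically by factor name.
#'
#' @param fm a [assemble_factor_matrix()] result.
#' @param ntree number of trees (default 1000).
#' @param mtry candidate variables per split (default: all).
#' @param importance_type `"permutation"` (OOB mean decrease in MSE,
#'   unscaled) or `"impurity"` (residual-sum-of-squares decrease).
#' @param seed RNG seed; identical seeds give identical scores.
#' @param k number of factors flagged as key factors (default 10).
#' @return data.frame of class `importance_result`: `factor`, `category`,
#'   `raw`, `score`, `rank`, `top10`; attributes `period`, `n`, `ntree`.
#' @export
fit_importance <- function(fm, ntree = 1000, mtry = NULL,
                           importance_type = c("permutation", "impurity"),
                           seed = NULL, k = 10) {
  stopifnot(inherits(fm, "factor_matrix"))
  importance_type <- match.arg(importance_type)
  if (pop_sd(fm$y) == 0) stop("constant response: importance is undefined")
  if (is.null(mtry)) mtry <- ncol(fm$x)
  if (!is.null(seed)) set.seed(seed)
  rf <- randomForest::randomForest(
    x = fm$x, y = fm$y, ntree = ntree, mtry = mtry,
    importance = (importance_type == "permutation")
  )
  imp <- randomForest::importance(
    rf, type = if (importance_type == "permutation") 1 else 2, scale = FALSE
  )
  raw <- stats::setNames(imp[, 1], rownames(imp))[colnames(fm$x)]
  score <- normalize_scores(raw)
  ord <- order(-score, names(score))
  rank <- integer(length(score))
  rank[ord] <- seq_along(score)
  ties_at_k <- sum(score == sort(score, decreasing = TRUE)[k]) > 1
  if (ties_at_k) yg_log("tie at rank %d broken by factor name order", k)
  out <- data.frame(
    factor = names(score),
    category = unname(fm$categories[names(score)]),
    raw = unname(raw),
    score = unname(score),
    rank = rank,
    top10 = rank <= k,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$rank), ]
  rownames(out) <- NULL
  attr(out, "period") <- fm$period
  attr(out, "n") <- length(fm$y)
  attr(out, "ntree") <- ntree
  attr(out, "importance_type") <- importance_type
  class(out) <- c("importance_result", "data.frame")
  out
}

#' @export
print.importance_result <- function(x, ...) {
  cat(sprintf("<importance_result> period %s, n = %d, %d trees (%s importance)\n",
              attr(x, "period") %||% "?", attr(x, "n") %||% NA,
              attr(x, "ntree") %||% NA, attr(x, "importance_type") %||% "?"))
  print(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Count how often each factor enters the top k across periods
#'
#' @param results list of [fit_importance()] results (>= 2 periods).
#' @param k top-rank cutoff (default 10).
#' @return data.frame `factor`, `frequency`, sorted by frequency then name.
#' @export
top_k_frequency <- function(results, k = 10) {
  if (length(results) < 2) stop("need importance results for at least 2 periods")
  factors <- results[[1]]$factor
  counts <- stats::setNames(integer(length(factors)), sort(factors))
  for (res in results) {
    top <- res$factor[res$rank <= k]
    counts[top] <- counts[top] + 1L
  }
  out <- data.frame(factor = names(counts), frequency = as.integer(counts),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$frequency, out$factor), ]
  rownames(out) <- NULL
  out
}

#' Category contribution of the key factors
#'
#' Percentage of the top-k slots held by each factor category; with k slots
#' each worth 100/k percent, the four categories always sum to exactly 100.
#'
#' @param result a [fit_importance()] result with top10 flags.
#' @param k top-rank cutoff used for the flags (default 10).
#' @return data.frame `category`, `n_top`, `percent`.
#' @export
category_contribution <- function(result, k = 10) {
  cats <- c("climatic", "socioeconomic", "land_use", "human_investment")
  top <- result[result$rank <= k, ]
  n_top <- vapply(cats, function(cc) sum(top$category == cc), integer(1))
  data.frame(category = cats, n_top = as.integer(n_top),
             percent = 100 * n_top / k,
             stringsAsFactors = FALSE)
}
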