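#' Contiguity-based spatial weights for county polygons
#'
#' Builds queen (shared vertex) or rook (shared edge) neighbor lists from
#' polygon geometry by matching ring vertices on a snap grid: two counties
#' are queen neighbors if they share at least one vertex and rook neighbors
#' if they share at least two (an edge). This is exact for tessellations
#' whose boundaries share vertices, which covers the synthetic lattice and
#' typical administrative cadastres. Counties are ordered by `county_id`
#' so results never depend on input order.
#'
#' @param counties a [county_frame()].
#' @param rule `"queen"` (default) or `"rook"`.
#' @param row_standardize divide each row of weights by its sum (default
#'   TRUE; the convention for Moran-type statistics).
#' @param snap coordinate tolerance for vertex matching.
#' @param allow_isolates keep counties without neighbors (weight row of
#'   zeros) instead of aborting.
#' @return object of class `spatial_weights`: `ids`, `neighbors` (list of
#'   integer indices), `weights` (list of numeric), `row_standardized`,
#'   `rule`.
#' @export
build_contiguity_weights <- function(counties, rule = c("queen", "rook"),
                                     row_standardize = TRUE, snap = 1e-6,
                                     allow_isolates = FALSE) {
  rule <- match.arg(rule)
  ord <- order(counties$county_id)
  ids <- counties$county_id[ord]
  geoms <- counties$geometry[ord]
  n <- length(ids)
  # vertex -> polygons hash
  vert_map <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(n)) {
    ring <- geoms[[i]]
    ring <- ring[!duplicated(round(ring / snap)), , drop = FALSE]
    keys <- unique(paste(round(ring[, 1] / snap), round(ring[, 2] / snap)))
    for (k in keys) {
      vert_map[[k]] <- c(vert_map[[k]], i)
    }
  }
  shared <- new.env(hash = TRUE, parent = emptyenv())
  for (k in ls(vert_map)) {
    polys <- vert_map[[k]]
    if (length(polys) < 2) next
    for (a in seq_along(polys)) {
      for (b in seq_along(polys)) {
        if (polys[a] < polys[b]) {
          pk <- paste(polys[a], polys[b])
          shared[[pk]] <- (shared[[pk]] %||% 0L) + 1L
        }
      }
    }
  }
  neighbors <- rep(list(integer(0)), n)
  need <- if (rule == "queen") 1L else 2L
  for (pk in ls(shared)) {
    if (shared[[pk]] >= need) {
      ab <- as.integer(strsplit(pk, " ")[[1]])
      neighbors[[ab[1]]] <- c(neighbors[[ab[1]]], ab[2])
      neighbors[[ab[2]]] <- c(neighbors[[ab[2]]], ab[1])
    }
  }
  neighbors <- lapply(neighbors, sort)
  iso <- which(lengths(neighbors) == 0L)
  if (length(iso)) {
    msg <- sprintf("isolate county(ies) without neighbors: %s",
                   paste(ids[iso], collapse = ", "))
    if (!allow_isolates) stop(msg) else warning(msg)
  }
  weights <- lapply(neighbors, function(nb) {
    if (!length(nb)) return(numeric(0))
    w <- rep(1, length(nb))
    if (row_standardize) w / sum(w) else w
  })
  structure(list(ids = ids, neighbors = neighbors, weights = weights,
                 row_standardized = isTRUE(row_standardize), rule = rule),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("<spatial_weights> %d units, %s contiguity, %s, avg %.2f neighbors\n",
              length(x$ids), x$rule,
              if (x$row_standardized) "row-standardized" else "binary",
              mean(lengths(x$neighbors))))
  invisible(x)
}

# Sparse triplet view (i, j, w) of a weights object; no self links.
weights_triplets <- function(w) {
  i <- rep(seq_along(w$ids), lengths(w$neighbors))
  data.frame(i = i, j = unlist(w$neighbors) %||% integer(0),
             w = unlist(w$weights) %||% numeric(0))
}

standardize_pop <- function(x, what) {
  s <- pop_sd(x)
  if (s == 0) stop(sprintf("zero variance in %s", what))
  (x - mean(x)) / s
}

#' Getis-Ord Gi* hot-spot statistic
#'
#' Self-inclusive local sum statistic on binary contiguity weights:
#' for each county, `Gi* = (sum_j w_ij x_j - xbar W_i) /
#' (S sqrt((n S1_i - W_i^2) / (n - 1)))` with `w_ij` binary over the
#' neighborhood including the county itself, `S` the population standard
#' deviation of `x`. Values are standard-normal under the null, so hot/cold
#' classes follow |z| thresholds 1.65 / 1.96 / 2.58 (90/95/99%).
#'
#' @param x per-county values, aligned with `w$ids`; no NAs.
#' @param w a [build_contiguity_weights()] object (its binary adjacency is
#'   used; row standardization is ignored here).
#' @param include_self include the county in its own neighborhood (TRUE,
#'   the Gi* form; FALSE gives the plain Gi statistic).
#' @return data.frame of class `hotspot_result`: `county_id`, `gi_star_z`,
#'   `p_value` (two-sided normal), `class` in hot99/hot95/hot90/ns/
#'   cold90/cold95/cold99.
#' @export
getis_ord_gi_star <- function(x, w, include_self = TRUE) {
  n <- length(x)
  if (n != length(w$ids)) stop("x and weights have different lengths")
  if (n < 3) stop("need at least 3 counties")
  if (anyNA(x)) stop("NA values in x")
  xbar <- mean(x)
  S <- pop_sd(x)
  if (S == 0) stop("zero variance in x")
  z <- vapply(seq_len(n), function(i) {
    nb <- w$neighbors[[i]]
    if (include_self) nb <- c(i, nb)
    Wi <- length(nb)           # binary weights
    S1 <- Wi                   # sum of squared binary weights
    num <- sum(x[nb]) - xbar * Wi
    den <- S * sqrt((n * S1 - Wi^2) / (n - 1))
    # a neighborhood spanning the whole map has num = 0 exactly and a zero
    # denominator; the statistic is defined as 0 there (no local deviation)
    if (den == 0) 0 else num / den
  }, numeric(1))
  p <- 2 * stats::pnorm(-abs(z))
  cls <- cut(z, breaks = c(-Inf, -2.58, -1.96, -1.65, 1.65, 1.96, 2.58, Inf),
             labels = c("cold99", "cold95", "cold90", "ns",
                        "hot90", "hot95", "hot99"))
  out <- data.frame(county_id = w$ids, gi_star_z = z, p_value = p,
                    class = as.character(cls), stringsAsFactors = FALSE)
  class(out) <- c("hotspot_result", "data.frame")
  out
}

#' Pseudo p-value from a permutation null
#'
#' Conventional conditional-permutation p-value
#' `(count(|null| >= |observed|) + 1) / (n_perm + 1)` (two-sided; one-sided
#' variants drop the absolute values).
#'
#' @param observed observed statistic.
#' @param null_draws vector of statistics under permutation.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return pseudo p-value in (0, 1].
#' @export
permutation_pvalue <- function(observed, null_draws,
                               alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  exceed <- switch(alternative,
    two.sided = sum(abs(null_draws) >= abs(observed)),
    greater = sum(null_draws >= observed),
    less = sum(null_draws <= observed)
  )
  (exceed + 1) / (length(null_draws) + 1)
}

#' Bivariate global Moran's I with permutation inference
#'
#' `I_xy = sum_ij w_ij z_x[i] z_y[j] / S0`, the correlation between `x` and
#' the spatial lag of `y`; `z` values are population-standardized and `S0`
#' is the total weight. With `x = y` this reduces to univariate Moran's I.
#' Inference conditions on `x`: `y` is permuted across locations `n_perm`
#' times and a two-sided pseudo p-value is reported.
#'
#' @param x,y per-county values aligned with `w$ids`; no NAs, non-constant.
#' @param w a [build_contiguity_weights()] object.
#' @param n_perm number of permutations (>= 99; 0 skips inference).
#' @param seed RNG seed for the permutations.
#' @return list of class `bivariate_moran`: `global_i`, `pseudo_p`,
#'   `n_perm`, `null_draws`.
#' @export
bivariate_moran_global <- function(x, y, w, n_perm = 999, seed = NULL) {
  n <- length(x)
  if (n != length(y) || n != length(w$ids)) stop("length mismatch")
  if (anyNA(x) || anyNA(y)) stop("NA values in inputs")
  zx <- standardize_pop(x, "x")
  zy <- standardize_pop(y, "y")
  tr <- weights_triplets(w)
  S0 <- sum(tr$w)
  if (S0 <= 0) stop("weights sum to zero")
  zx_i <- zx[tr$i]
  I_obs <- sum(tr$w * zx_i * zy[tr$j]) / S0
  null_draws <- numeric(0)
  pseudo_p <- NA_real_
  if (n_perm > 0) {
    if (n_perm < 99) stop("n_perm must be at least 99 (or 0 to skip)")
    if (!is.null(seed)) set.seed(seed)
    null_draws <- vapply(seq_len(n_perm), function(k) {
      zyp <- zy[sample.int(n)]
      sum(tr$w * zx_i * zyp[tr$j]) / S0
    }, numeric(1))
    pseudo_p <- permutation_pvalue(I_obs, null_draws)
  }
  structure(list(global_i = I_obs, pseudo_p = pseudo_p, n_perm = n_perm,
                 null_draws = null_draws),
            class = "bivariate_moran")
}

#' @export
print.bivariate_moran <- function(x, ...) {
  cat(sprintf("<bivariate_moran> I = %.4f, pseudo-p = %s (%d permutations)\n",
              x$global_i,
              if (is.na(x$pseudo_p)) "n/a" else format(x$pseudo_p),
              x$n_perm))
  invisible(x)
}

#' Bivariate local Moran (LISA) with conditional permutation
#'
#' Local statistic `I_i = z_x[i] * sum_j w_ij z_y[j]`. Cluster classes come
#' from the sign quadrant of `(z_x[i], lag_i)` - HH, LL, HL, LH - gated by
#' a conditional-permutation pseudo p-value: for each county the `y` values
#' of the rest of the map are permuted into its neighborhood while
#' `z_x[i]` stays fixed. Counties with `p > alpha` are `ns`. With
#' row-standardized weights `sum_i I_i / S0` equals the global statistic.
#'
#' @inheritParams bivariate_moran_global
#' @param alpha significance level gating the cluster classes (0.05).
#' @return data.frame of class `bivariate_lisa`: `county_id`, `local_i`,
#'   `pseudo_p`, `lisa_class`; attribute `global_i`.
#' @export
bivariate_lisa <- function(x, y, w, n_perm = 999, alpha = 0.05, seed = NULL) {
  n <- length(x)
  if (n != length(y) || n != length(w$ids)) stop("length mismatch")
  if (anyNA(x) || anyNA(y)) stop("NA values in inputs")
  if (n_perm < 99) stop("n_perm must be at least 99")
  zx <- standardize_pop(x, "x")
  zy <- standardize_pop(y, "y")
  if (!is.null(seed)) set.seed(seed)
  lag <- vapply(seq_len(n), function(i) {
    sum(w$weights[[i]] * zy[w$neighbors[[i]]])
  }, numeric(1))
  local_i <- zx * lag
  pseudo_p <- vapply(seq_len(n), function(i) {
    k <- length(w$neighbors[[i]])
    if (k == 0L) return(NA_real_)
    zy_rest <- zy[-i]
    wi <- w$weights[[i]]
    null_i <- vapply(seq_len(n_perm), function(r) {
      zx[i] * sum(wi * zy_rest[sample.int(n - 1L, k)])
    }, numeric(1))
    permutation_pvalue(local_i[i], null_i)
  }, numeric(1))
  quad <- ifelse(zx >= 0 & lag >= 0, "HH",
          ifelse(zx < 0 & lag < 0, "LL",
          ifelse(zx >= 0, "HL", "LH")))
  cls <- ifelse(!is.na(pseudo_p) & pseudo_p <= alpha, quad, "ns")
  tr <- weights_triplets(w)
  out <- data.frame(county_id = w$ids, local_i = local_i,
                    pseudo_p = pseudo_p, lisa_class = cls,
                    stringsAsFactors = FALSE)
  attr(out, "global_i") <- sum(local_i) / sum(tr$w)
  attr(out, "alpha") <- alpha
  class(out) <- c("bivariate_lisa", "data.frame")
  out
}
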