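# Brute-force oracles and small fixtures shared across tests.
# The oracles are deliberately independent double-loop implementations of
# the statistics; they never call the package's vectorized paths.

# Dense binary adjacency matrix from a spatial_weights object.
dense_adjacency <- function(w, include_self = FALSE) {
  n <- length(w$ids)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) A[i, w$neighbors[[i]]] <- 1
  if (include_self) diag(A) <- 1
  A
}

# Dense (possibly row-standardized) weight matrix.
dense_weights <- function(w) {
  n <- length(w$ids)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) W[i, w$neighbors[[i]]] <- w$weights[[i]]
  W
}

# Gi* by explicit double loops on a binary self-inclusive adjacency.
oracle_gi_star <- function(x, A_self) {
  n <- length(x)
  xbar <- mean(x)
  S <- sqrt(sum((x - xbar)^2) / n)
  z <- numeric(n)
  for (i in seq_len(n)) {
    num <- 0; Wi <- 0; S1 <- 0
    for (j in seq_len(n)) {
      num <- num + A_self[i, j] * x[j]
      Wi <- Wi + A_self[i, j]
      S1 <- S1 + A_self[i, j]^2
    }
    den <- S * sqrt((n * S1 - Wi^2) / (n - 1))
    # same convention as the package: a whole-map neighborhood has num = 0
    z[i] <- if (den == 0) 0 else (num - xbar * Wi) / den
  }
  z
}

# Bivariate global Moran's I by explicit double loops.
oracle_bivariate_moran <- function(x, y, W) {
  n <- length(x)
  zx <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  zy <- (y - mean(y)) / sqrt(mean((y - mean(y))^2))
  acc <- 0; S0 <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      acc <- acc + W[i, j] * zx[i] * zy[j]
      S0 <- S0 + W[i, j]
    }
  }
  acc / S0
}

# Bivariate local Moran values by explicit loops.
oracle_bivariate_lisa <- function(x, y, W) {
  n <- length(x)
  zx <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  zy <- (y - mean(y)) / sqrt(mean((y - mean(y))^2))
  out <- numeric(n)
  for (i in seq_len(n)) {
    lag <- 0
    for (j in seq_len(n)) lag <- lag + W[i, j] * zy[j]
    out[i] <- zx[i] * lag
  }
  out
}

# Rectangular county lattice via the generator (no districts by default).
lattice_counties <- function(nx, ny, seed = 1, municipal_block = 0, ...) {
  generate_counties(sim_config(seed = seed, n_county_x = nx, n_county_y = ny,
                               municipal_block = municipal_block, ...))
}

# Hand-built strip of n unit squares in a row (for path-graph fixtures that
# the lattice generator's >= 2x2 constraint excludes).
strip_counties <- function(n) {
  geoms <- lapply(seq_len(n) - 1, function(i) {
    rbind(c(i, 0), c(i + 1, 0), c(i + 1, 1), c(i, 1), c(i, 0))
  })
  county_frame(county_id = sprintf("S%d", seq_len(n)), geometry = geoms)
}

# Single-county fixture around a small raster, for zonal tests.
one_county <- function(xmax, ymax) {
  county_frame(county_id = "only",
               geometry = list(rbind(c(0, 0), c(xmax, 0), c(xmax, ymax),
                                     c(0, ymax), c(0, 0))))
}
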