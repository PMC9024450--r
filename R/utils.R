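# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Population (n-denominator) standard deviation
#'
#' The classical Moran / Gi* derivations standardize with the population
#' standard deviation, not the sample one; this helper keeps that choice in
#' one place.
#'
#' @param x numeric vector, no NAs.
#' @return length-1 numeric.
#' @keywords internal
pop_sd <- function(x) {
  sqrt(mean((x - mean(x))^2))
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Verbosity is a package option so pipeline stages can log without
# threading a flag through every call.
yg_log <- function(...) {
  if (isTRUE(getOption("yieldgapr.verbose", FALSE))) {
    message(sprintf(...))
  }
  invisible(NULL)
}

stop_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

# Deterministic sub-seed derivation: keeps every stage independently
# reproducible while staying inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 31L + offset) %% 2147483647)
}

assert_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    stop(sprintf("`%s` must be a single number in [%s, %s]", name, lo, hi),
         call. = FALSE)
  }
  invisible(x)
}
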