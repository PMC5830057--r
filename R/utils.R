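#' @keywords internal
"_PACKAGE"

## Angle helpers -------------------------------------------------------------

#' Wrap angles to (-pi, pi]
#'
#' @param x numeric vector of angles in radians.
#' @return angles wrapped to the half-open interval (-pi, pi].
#' @export
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  # the modulo puts -pi and pi both at -pi; convention here is (-pi, pi]
  y[y <= -pi] <- pi
  y
}

#' Convert radians to degrees / degrees to radians
#'
#' @param x numeric vector of angles.
#' @return converted angles.
#' @export
rad2deg <- function(x) x * 180 / pi

#' @rdname rad2deg
#' @export
deg2rad <- function(x) x * pi / 180

#' Absolute circular difference between two angles
#'
#' Smallest unsigned angle between two headings, in [0, pi].
#'
#' @param a,b angles in radians.
#' @return unsigned circular difference in radians.
#' @export
circ_dist <- function(a, b) {
  abs(wrap_angle(a - b))
}

## Seed management ------------------------------------------------------------

#' Derive a child seed from a base seed and integer coordinates
#'
#' Deterministic polynomial hash so every (experiment, cell, run) gets an
#' independent, individually re-runnable stream. Result is a valid 32-bit
#' R seed.
#'
#' @param base_seed integer base seed.
#' @param ... further integer coordinates (cell index, run index, ...).
#' @return a single integer in [0, 2^31 - 2].
#' @export
derive_seed <- function(base_seed, ...) {
  parts <- c(as.numeric(base_seed), vapply(list(...), as.numeric, numeric(1)))
  m <- 2147483629 # large prime < 2^31
  h <- 0
  for (p in parts) {
    # multiplier kept small so h * mult stays exact in double precision
    h <- (h * 69069 + (p %% m) + 12345) %% m
  }
  as.integer(h)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  expr
}

stop_invalid <- function(...) {
  stop(..., call. = FALSE)
}
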