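## Kinematics: synthetic 2D random-pursuit direction series.
##
## The decoders only ever see movement *direction* sampled at the 50-ms bin
## rate, so the generator produces unit direction vectors directly at that
## rate. Heading evolves as a smooth random walk: angular velocity follows a
## mean-reverting AR(1) (Ornstein-Uhlenbeck discretization) so consecutive
## headings are strongly correlated (like a hand pursuing a target) while the
## heading itself wanders over the full circle many times in a 300-s session.

#' Construct a direction series
#'
#' @param theta numeric vector of headings in radians; wrapped to (-pi, pi].
#' @param bin_s bin width in seconds (default 0.05).
#' @return an object of class \code{direction_series} with fields
#'   \code{n_bins}, \code{bin_s}, \code{theta} and \code{dxy}
#'   (an \code{n_bins x 2} matrix of unit vectors \code{(cos theta, sin theta)}).
#' @export
direction_series <- function(theta, bin_s = 0.05) {
  if (!is.numeric(theta) || length(theta) < 1) {
    stop_invalid("'theta' must be a non-empty numeric vector")
  }
  if (bin_s <= 0) stop_invalid("'bin_s' must be positive")
  theta <- wrap_angle(as.numeric(theta))
  structure(
    list(
      n_bins = length(theta),
      bin_s = bin_s,
      theta = theta,
      dxy = cbind(dx = cos(theta), dy = sin(theta))
    ),
    class = "direction_series"
  )
}

#' @export
print.direction_series <- function(x, ...) {
  cat(sprintf(
    "<direction_series> %d bins x %.0f ms (%.1f s)\n",
    x$n_bins, x$bin_s * 1000, x$n_bins * x$bin_s
  ))
  invisible(x)
}

#' Generate a random-pursuit direction time series
#'
#' Emulates free 2D pursuit movement covering headings as diverse as
#' possible. Angular velocity omega_t is a stationary AR(1) process
#' (autocorrelation time \code{smoothness} seconds, stationary sd
#' \code{omega_sd} rad/s) and the heading is its wrapped cumulative sum with
#' a uniform random start.
#'
#' @param duration_s session duration in seconds (default 300).
#' @param bin_s bin width in seconds (default 0.05, i.e. 20 Hz).
#' @param smoothness autocorrelation time of angular velocity in seconds;
#'   larger values give straighter, smoother paths.
#' @param omega_sd stationary standard deviation of angular velocity (rad/s).
#' @param seed integer seed for reproducibility.
#' @return a \code{\link{direction_series}} with
#'   \code{round(duration_s / bin_s)} bins.
#' @export
generate_random_pursuit <- function(duration_s = 300, bin_s = 0.05,
                                    smoothness = 1, omega_sd = 2,
                                    seed = NULL) {
  if (duration_s <= 0 || bin_s <= 0 || smoothness <= 0 || omega_sd <= 0) {
    stop_invalid("'duration_s', 'bin_s', 'smoothness' and 'omega_sd' must be positive")
  }
  n <- as.integer(round(duration_s / bin_s))
  if (n < 1) stop_invalid("duration too short for the requested bin width")
  with_seed(seed, {
    rho <- exp(-bin_s / smoothness)
    sd_bin <- omega_sd * bin_s # per-bin heading increment scale
    innov <- stats::rnorm(n, 0, sd_bin * sqrt(1 - rho^2))
    omega <- as.numeric(stats::filter(innov, rho, method = "recursive",
                                      init = stats::rnorm(1, 0, sd_bin)))
    theta0 <- stats::runif(1, -pi, pi)
    direction_series(theta0 + cumsum(omega), bin_s = bin_s)
  })
}

#' Split a direction series into training and test halves
#'
#' First half of the bins is the training period, second half the test
#' period; concatenating the halves reconstructs the input.
#'
#' @param series a \code{\link{direction_series}}.
#' @return list with elements \code{train} and \code{test}.
#' @export
split_train_test <- function(series) {
  stopifnot(inherits(series, "direction_series"))
  n <- series$n_bins
  if (n %% 2L != 0L) stop_invalid("series must have an even number of bins")
  half <- n %/% 2L
  list(
    train = direction_series(series$theta[seq_len(half)], series$bin_s),
    test = direction_series(series$theta[half + seq_len(half)], series$bin_s)
  )
}

#' Read / write a direction series as CSV
#'
#' Columns: \code{bin_index}, \code{theta_rad}, \code{dx}, \code{dy}.
#'
#' @param series a \code{\link{direction_series}}.
#' @param path file path.
#' @param bin_s bin width to attach on read (CSV stores angles only).
#' @return \code{write_direction_series} returns \code{path} invisibly;
#'   \code{read_direction_series} returns a \code{\link{direction_series}}.
#' @export
write_direction_series <- function(series, path) {
  stopifnot(inherits(series, "direction_series"))
  utils::write.csv(
    data.frame(
      bin_index = seq_len(series$n_bins),
      theta_rad = series$theta,
      dx = series$dxy[, 1],
      dy = series$dxy[, 2]
    ),
    path,
    row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_direction_series
#' @export
read_direction_series <- function(path, bin_s = 0.05) {
  df <- utils::read.csv(path)
  direction_series(df$theta_rad, bin_s = bin_s)
}
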