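## Ensemble construction: preferred-direction geometry, well-/poorly-tuned
## mixtures, empirical calibration between the intrinsic (generative) SNR and
## the data-driven (regression-estimated) SNR, and sigmoid PD drift.
##
## SNR conventions. A neuron's firing rate is
##   z_t = b0 + gain * cos(theta_t - pd) + eps_t,  eps_t ~ N(0, sigma2),
## i.e. tuning coefficients (b1, b2) = gain * (cos pd, sin pd). The intrinsic
## SNR is the ratio of the mean-square tuning output (including the DC
## baseline) to the AWGN variance:
##   SNR_int = 10 log10(SP / sigma2),  SP = mean (b0 + b1 Dx + b2 Dy)^2.
## The data-driven SNR refits the cosine model to binned spike counts and
## replaces sigma2 by the residual power, which also absorbs Poisson counting
## noise; the empirical polynomial map between the two is estimated by
## calibrate_snr_map() and inverted to hit data-driven targets.

DEFAULT_B0 <- 45 # baseline rate, spikes/s
DEFAULT_GAIN <- 30 # modulation amplitude, spikes/s

#' Analytic signal power of a cosine tuning curve under uniform headings
#'
#' SP = b0^2 + gain^2 / 2 (mean square of b0 + gain*cos over a uniform angle).
#'
#' @param b0 baseline rate (spikes/s).
#' @param gain modulation amplitude (spikes/s).
#' @return signal power in (spikes/s)^2.
#' @export
analytic_signal_power <- function(b0, gain) b0^2 + gain^2 / 2

#' Assign preferred directions over an angular arc
#'
#' Spreads \code{n} PDs evenly over an arc covering
#' \code{uniformity_pct}\% of the circle, centered at \code{bias_rad}. At
#' 100\% the arc is the full circle with no duplicated endpoint.
#'
#' @param n number of neurons.
#' @param uniformity_pct percentage (0, 100] of the angular space covered.
#' @param bias_rad central angle of the arc (radians).
#' @return numeric vector of \code{n} PD angles in (-pi, pi].
#' @export
assign_pds <- function(n, uniformity_pct, bias_rad = 0) {
  if (n < 1) stop_invalid("'n' must be >= 1")
  if (uniformity_pct <= 0 || uniformity_pct > 100) {
    stop_invalid("'uniformity_pct' must be in (0, 100]")
  }
  span <- 2 * pi * uniformity_pct / 100
  if (uniformity_pct == 100) {
    pds <- bias_rad + span * (seq_len(n) - 1) / n
  } else if (n == 1) {
    pds <- bias_rad
  } else {
    pds <- bias_rad - span / 2 + span * (seq_len(n) - 1) / (n - 1)
  }
  wrap_angle(pds)
}

#' Empirical signal power of a fitted tuning curve
#'
#' Mean square of the tuning-curve output over the observed directions.
#'
#' @param b0,b1,b2 tuning coefficients (rate units).
#' @param series a \code{\link{direction_series}}.
#' @return signal power in (spikes/s)^2.
#' @export
signal_power <- function(b0, b1, b2, series) {
  stopifnot(inherits(series, "direction_series"))
  if (series$n_bins < 1) stop_invalid("empty direction series")
  mean((b0 + b1 * series$dxy[, 1] + b2 * series$dxy[, 2])^2)
}

#' Data-driven SNR of one neuron from binned counts
#'
#' Converts counts to rates (counts / bin width), fits the cosine tuning
#' model by ordinary least squares, and returns
#' \code{10*log10(SP/NP)} where SP is the mean-square fitted tuning output
#' and NP the mean-square residual.
#'
#' @param counts integer vector of per-bin spike counts for one neuron.
#' @param series the \code{\link{direction_series}} aligned with the counts.
#' @return SNR in dB. \code{+Inf} with attribute \code{saturated = TRUE} if
#'   the residual power is zero.
#' @export
snr_dd_from_fit <- function(counts, series) {
  stopifnot(inherits(series, "direction_series"))
  if (length(counts) != series$n_bins) {
    stop_invalid("counts and direction series are not aligned")
  }
  if (length(counts) < 10) stop_invalid("need at least 10 bins")
  if (all(counts == 0)) stop_invalid("degenerate fit: all counts are zero")
  rates <- counts / series$bin_s
  X <- cbind(1, series$dxy)
  beta <- solve(crossprod(X), crossprod(X, rates))
  fitted <- drop(X %*% beta)
  sp <- mean(fitted^2)
  np <- mean((rates - fitted)^2)
  if (np <= 1e-20 * sp) {
    out <- Inf
    attr(out, "saturated") <- TRUE
    return(out)
  }
  10 * log10(sp / np)
}

#' Calibrate the intrinsic-to-data-driven SNR map
#'
#' For each intrinsic SNR on the grid, generates spikes through the full
#' tuning + AWGN + Poisson chain, estimates the data-driven SNR per neuron,
#' averages, and fits a 6th-order polynomial to the (intrinsic, data-driven)
#' pairs by least squares.
#'
#' @param grid_db intrinsic SNR grid in dB; must span at least [-10, 10] and
#'   contain >= 8 points. The default extends to -14 dB because rectification
#'   of the noisy rate at zero bounds the data-driven SNR from below, and the
#'   poorly tuned target (-2.31 dB) sits just under the value attained at an
#'   intrinsic SNR of -10 dB.
#' @param n_neurons neurons simulated per grid point.
#' @param n_reps independent repetitions (fresh trajectory each) per point.
#' @param duration_s,bin_s session geometry for the preliminary simulation.
#' @param b0,gain tuning-curve scale (spikes/s).
#' @param seed integer seed.
#' @return an object of class \code{snr_calibration}: list with
#'   \code{coeffs} (a0..a6), \code{grid} (data.frame of snr_int_db,
#'   snr_dd_db), \code{fit_mse} (dB^2), \code{range_dd_db}, and the
#'   generation parameters.
#' @export
calibrate_snr_map <- function(grid_db = seq(-14, 10, length.out = 97),
                              n_neurons = 12, n_reps = 2,
                              duration_s = 300, bin_s = 0.05,
                              b0 = DEFAULT_B0, gain = DEFAULT_GAIN,
                              seed = 1) {
  if (length(grid_db) < 8) stop_invalid("underdetermined fit: need >= 8 grid points")
  if (min(grid_db) > -10 || max(grid_db) < 10) {
    stop_invalid("grid must span at least [-10, 10] dB")
  }
  if (n_reps < 1) stop_invalid("'n_reps' must be >= 1")
  sp <- analytic_signal_power(b0, gain)
  pds <- assign_pds(n_neurons, 100, 0)
  mean_dd <- vapply(seq_along(grid_db), function(k) {
    sigma2 <- sp / 10^(grid_db[k] / 10)
    dd <- numeric(0)
    for (r in seq_len(n_reps)) {
      s <- derive_seed(seed, 9001L, k, r)
      series <- generate_random_pursuit(duration_s, bin_s, seed = s)
      ens <- ensemble_spec(
        pd = pds, well_tuned = TRUE, b0 = b0, gain = gain,
        sigma2 = sigma2, target_snr_dd = NA_real_
      )
      spikes <- generate_spike_counts(ens, series, seed = derive_seed(s, 7L))
      dd <- c(dd, vapply(
        seq_len(n_neurons),
        function(i) snr_dd_from_fit(spikes$counts[i, ], series),
        numeric(1)
      ))
    }
    mean(dd)
  }, numeric(1))
  grid <- data.frame(snr_int_db = grid_db, snr_dd_db = mean_dd)
  fit <- stats::lm(snr_dd_db ~ poly(snr_int_db, 6, raw = TRUE), data = grid)
  structure(
    list(
      coeffs = unname(stats::coef(fit)),
      grid = grid,
      fit_mse = mean(stats::residuals(fit)^2),
      range_int_db = range(grid_db),
      range_dd_db = range(eval_calibration(unname(stats::coef(fit)), grid_db)),
      b0 = b0, gain = gain, bin_s = bin_s
    ),
    class = "snr_calibration"
  )
}

eval_calibration <- function(coeffs, x) {
  drop(outer(x, 0:6, `^`) %*% coeffs)
}

#' Evaluate a fitted SNR calibration polynomial
#'
#' @param calib an \code{snr_calibration}.
#' @param snr_int_db intrinsic SNR values in dB.
#' @return predicted data-driven SNR in dB.
#' @export
predict_snr_dd <- function(calib, snr_int_db) {
  stopifnot(inherits(calib, "snr_calibration"))
  eval_calibration(calib$coeffs, snr_int_db)
}

#' @export
print.snr_calibration <- function(x, ...) {
  cat(sprintf(
    "<snr_calibration> order-6 polynomial on [%g, %g] dB, fit RMSE %.3g dB\n",
    x$range_int_db[1], x$range_int_db[2], sqrt(x$fit_mse)
  ))
  invisible(x)
}

#' Invert the SNR calibration
#'
#' Finds the intrinsic SNR whose polynomial image equals a target
#' data-driven SNR, by root-finding on the calibrated (monotone) range.
#'
#' @param calib an \code{snr_calibration}.
#' @param target_dd_db target data-driven SNR (dB).
#' @return intrinsic SNR in dB.
#' @export
invert_calibration <- function(calib, target_dd_db) {
  stopifnot(inherits(calib, "snr_calibration"))
  lo <- calib$range_int_db[1]
  hi <- calib$range_int_db[2]
  flo <- predict_snr_dd(calib, lo)
  fhi <- predict_snr_dd(calib, hi)
  if (target_dd_db < min(flo, fhi) || target_dd_db > max(flo, fhi)) {
    stop_invalid(sprintf(
      "target SNR^DD %.3g dB outside calibrated range [%.3g, %.3g] dB",
      target_dd_db, min(flo, fhi), max(flo, fhi)
    ))
  }
  stats::uniroot(
    function(x) predict_snr_dd(calib, x) - target_dd_db,
    lower = lo, upper = hi, tol = 1e-12
  )$root
}

#' Build an ensemble specification
#'
#' Low-level constructor: recycles per-neuron fields to a common length.
#'
#' @param pd preferred directions (radians).
#' @param well_tuned logical flags.
#' @param b0,gain,sigma2 tuning-curve parameters per neuron.
#' @param target_snr_dd data-driven SNR targets (dB), for bookkeeping.
#' @param uniformity_pct,bias_rad,pwtn_pct,uwtn_pct ensemble-level geometry,
#'   recorded as attributes.
#' @return an object of class \code{ensemble_spec}; field \code{neurons} is a
#'   data.frame with one row per neuron.
#' @export
ensemble_spec <- function(pd, well_tuned, b0, gain, sigma2, target_snr_dd,
                          uniformity_pct = NA_real_, bias_rad = NA_real_,
                          pwtn_pct = NA_real_, uwtn_pct = NA_real_) {
  neurons <- data.frame(
    pd = wrap_angle(pd), well_tuned = well_tuned, b0 = b0, gain = gain,
    sigma2 = sigma2, target_snr_dd = target_snr_dd
  )
  if (any(neurons$gain <= 0)) stop_invalid("'gain' must be positive")
  if (any(neurons$sigma2 < 0)) stop_invalid("'sigma2' must be >= 0")
  if (any(neurons$b0 < neurons$gain)) {
    stop_invalid("'b0' must be >= 'gain' so noiseless rates are non-negative")
  }
  structure(
    list(
      neurons = neurons, n = nrow(neurons),
      uniformity_pct = uniformity_pct, bias_rad = bias_rad,
      pwtn_pct = pwtn_pct, uwtn_pct = uwtn_pct
    ),
    class = "ensemble_spec"
  )
}

#' @export
print.ensemble_spec <- function(x, ...) {
  cat(sprintf(
    "<ensemble_spec> %d neurons (%d well-tuned), bias %.1f deg\n",
    x$n, sum(x$neurons$well_tuned), rad2deg(x$bias_rad)
  ))
  invisible(x)
}

#' Compose a mixed well-/poorly-tuned ensemble
#'
#' \code{round(n * pwtn_pct/100)} well-tuned neurons get PDs evenly spread
#' over \code{uwtn_pct}\% of the circle centered at \code{bias_rad} and an
#' AWGN variance calibrated (via \code{\link{invert_calibration}}) to hit
#' \code{snr_well_db}; the remaining poorly tuned neurons get full-circle
#' PDs and a variance targeting \code{snr_poor_db}.
#'
#' @param n ensemble size (default 60).
#' @param pwtn_pct percentage of well-tuned neurons.
#' @param uwtn_pct PD uniformity of the well-tuned neurons (percent of the
#'   circle).
#' @param bias_rad central angle of the well-tuned PD arc.
#' @param snr_well_db,snr_poor_db target data-driven SNRs (dB).
#' @param calib an \code{\link{calibrate_snr_map}} result.
#' @param b0,gain tuning-curve scale (spikes/s).
#' @return an \code{\link{ensemble_spec}}.
#' @export
compose_ensemble <- function(n = 60, pwtn_pct = 100, uwtn_pct = 100,
                             bias_rad = 0, snr_well_db = 2.45,
                             snr_poor_db = -2.31, calib,
                             b0 = DEFAULT_B0, gain = DEFAULT_GAIN) {
  if (pwtn_pct < 0 || pwtn_pct > 100 || uwtn_pct < 0 || uwtn_pct > 100) {
    stop_invalid("'pwtn_pct' and 'uwtn_pct' must be in [0, 100]")
  }
  stopifnot(inherits(calib, "snr_calibration"))
  sp <- analytic_signal_power(b0, gain)
  sigma2_for <- function(target_dd) {
    sp / 10^(invert_calibration(calib, target_dd) / 10)
  }
  n_well <- round(n * pwtn_pct / 100)
  n_poor <- n - n_well
  pd <- numeric(0)
  well <- logical(0)
  sigma2 <- numeric(0)
  target <- numeric(0)
  if (n_well > 0) {
    pd <- c(pd, assign_pds(n_well, uwtn_pct, bias_rad))
    well <- c(well, rep(TRUE, n_well))
    sigma2 <- c(sigma2, rep(sigma2_for(snr_well_db), n_well))
    target <- c(target, rep(snr_well_db, n_well))
  }
  if (n_poor > 0) {
    pd <- c(pd, assign_pds(n_poor, 100, 0))
    well <- c(well, rep(FALSE, n_poor))
    sigma2 <- c(sigma2, rep(sigma2_for(snr_poor_db), n_poor))
    target <- c(target, rep(snr_poor_db, n_poor))
  }
  ensemble_spec(
    pd = pd, well_tuned = well, b0 = b0, gain = gain, sigma2 = sigma2,
    target_snr_dd = target, uniformity_pct = uwtn_pct, bias_rad = bias_rad,
    pwtn_pct = pwtn_pct, uwtn_pct = uwtn_pct
  )
}

## Gompertz PD drift ----------------------------------------------------------

#' Per-bin preferred-direction offsets following a Gompertz sigmoid
#'
#' Offsets are ~0 (at most 1\% of |alpha|) throughout the training half,
#' then rise sigmoidally toward the asymptotic shift \code{alpha_rad} during
#' the test half:
#' \code{y(t) = alpha * exp(-lambda * exp(-c * t))} with \code{t} counted in
#' bins from test onset (negative during training). \code{lambda = ln(100)}
#' pins the shift at test onset to exactly 1\% of \code{alpha}.
#'
#' @param alpha_rad asymptotic PD shift (radians).
#' @param c_rate Gompertz rate parameter (1/bin), in (0, 1).
#' @param n_train_bins,n_test_bins session geometry.
#' @param lambda displacement parameter; default \code{log(100)}.
#' @return numeric vector of length \code{n_train_bins + n_test_bins} of PD
#'   offsets in radians.
#' @export
gompertz_pd_trajectory <- function(alpha_rad, c_rate, n_train_bins,
                                   n_test_bins, lambda = log(100)) {
  if (n_train_bins <= 0 || n_test_bins <= 0) {
    stop_invalid("'n_train_bins' and 'n_test_bins' must be positive")
  }
  if (c_rate <= 0 || c_rate >= 1) stop_invalid("'c_rate' must be in (0, 1)")
  t_test <- seq_len(n_train_bins + n_test_bins) - n_train_bins - 1L
  alpha_rad * exp(-lambda * exp(-c_rate * t_test))
}

#' Sample per-neuron Gompertz drift parameters
#'
#' Asymptotic shifts are uniform on [-45, 45] degrees and rate parameters
#' uniform on [0.001, 0.004] per bin, independently per neuron.
#'
#' @param n number of neurons.
#' @param seed integer seed.
#' @return data.frame with columns \code{alpha_rad} and \code{c_rate}.
#' @export
sample_gompertz_params <- function(n, seed = NULL) {
  with_seed(seed, data.frame(
    alpha_rad = stats::runif(n, -pi / 4, pi / 4),
    c_rate = stats::runif(n, 0.001, 0.004)
  ))
}

#' Build a neurons-by-bins PD drift matrix
#'
#' @param params data.frame from \code{\link{sample_gompertz_params}}.
#' @param n_train_bins,n_test_bins session geometry.
#' @return matrix of PD offsets (radians), one row per neuron.
#' @export
drift_matrix <- function(params, n_train_bins, n_test_bins) {
  t(vapply(
    seq_len(nrow(params)),
    function(i) {
      if (params$alpha_rad[i] == 0) {
        rep(0, n_train_bins + n_test_bins)
      } else {
        gompertz_pd_trajectory(
          params$alpha_rad[i], params$c_rate[i], n_train_bins, n_test_bins
        )
      }
    },
    numeric(n_train_bins + n_test_bins)
  ))
}

## Serialization --------------------------------------------------------------

#' Write / read an ensemble spec as JSON (angles in degrees)
#'
#' @param ensemble an \code{\link{ensemble_spec}}.
#' @param path file path.
#' @return the path (write) or an \code{ensemble_spec} (read).
#' @export
write_ensemble_spec <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "ensemble_spec"))
  neurons <- ensemble$neurons
  neurons$pd_deg <- rad2deg(neurons$pd)
  neurons$pd <- NULL
  jsonlite::write_json(
    list(
      neurons = neurons,
      uniformity_pct = ensemble$uniformity_pct,
      bias_deg = rad2deg(ensemble$bias_rad),
      pwtn_pct = ensemble$pwtn_pct,
      uwtn_pct = ensemble$uwtn_pct
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_ensemble_spec
#' @export
read_ensemble_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ensemble_spec(
    pd = deg2rad(x$neurons$pd_deg),
    well_tuned = x$neurons$well_tuned,
    b0 = x$neurons$b0, gain = x$neurons$gain, sigma2 = x$neurons$sigma2,
    target_snr_dd = x$neurons$target_snr_dd,
    uniformity_pct = x$uniformity_pct, bias_rad = deg2rad(x$bias_deg),
    pwtn_pct = x$pwtn_pct, uwtn_pct = x$uwtn_pct
  )
}
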