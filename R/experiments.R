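## Experiments: seeded Monte-Carlo sweeps over ensemble properties.
##
## Every sweep is a pure function of (config, base seed): each (cell, run)
## derives its own seed, regenerates a fresh pursuit trajectory, composes an
## ensemble, simulates spikes, trains all three decoders on the first half of
## the session and evaluates per-bin angle differences on the second half.

#' Sweep configuration
#'
#' Bundles the session geometry, ensemble defaults and replicate counts used
#' by the experiment drivers.
#'
#' @param base_seed integer base seed; all per-run seeds derive from it.
#' @param n_neurons ensemble size (default 60).
#' @param snr_well_db,snr_poor_db data-driven SNR targets for well-/poorly
#'   tuned neurons (dB).
#' @param duration_s,bin_s session geometry (300 s at 50-ms bins; 50/50
#'   train/test split).
#' @param n_bias_runs repeated runs per condition cell, each at a different
#'   PD bias evenly spaced over the circle (default 100).
#' @param n_drift_runs repeats of the non-stationarity experiment
#'   (default 1000).
#' @param levels percentage menu for uniformity / PWTN / UWTN factors.
#' @param snr_grid SNR levels for the SNR-by-uniformity sweep (dB).
#' @param b0,gain tuning-curve scale (spikes/s).
#' @return object of class \code{sweep_config}.
#' @export
sweep_config <- function(base_seed = 1, n_neurons = 60,
                         snr_well_db = 2.45, snr_poor_db = -2.31,
                         duration_s = 300, bin_s = 0.05,
                         n_bias_runs = 100, n_drift_runs = 1000,
                         levels = c(20, 40, 60, 80, 100),
                         snr_grid = seq(-2.31, 2.45, length.out = 20),
                         b0 = DEFAULT_B0, gain = DEFAULT_GAIN) {
  structure(
    list(
      base_seed = base_seed, n_neurons = n_neurons,
      snr_well_db = snr_well_db, snr_poor_db = snr_poor_db,
      duration_s = duration_s, bin_s = bin_s,
      n_bias_runs = n_bias_runs, n_drift_runs = n_drift_runs,
      levels = levels, snr_grid = snr_grid, b0 = b0, gain = gain
    ),
    class = "sweep_config"
  )
}

#' Read / write a sweep configuration (JSON or YAML by extension)
#'
#' @param config a \code{\link{sweep_config}}.
#' @param path file path ending in .json, .yml or .yaml.
#' @return the path (write) or a \code{sweep_config} (read).
#' @export
write_sweep_config <- function(config, path) {
  stopifnot(inherits(config, "sweep_config"))
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_invalid("the 'yaml' package is required for YAML configs")
    }
    yaml::write_yaml(unclass(config), path)
  } else {
    jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_sweep_config
#' @export
read_sweep_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_invalid("the 'yaml' package is required for YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(sweep_config, x)
}

#' Simulate one session and decode it with all three decoders
#'
#' Generates a fresh pursuit trajectory, simulates spikes for the given
#' ensemble (optionally with PD drift), trains PVA/OLE/KF on the first half
#' and returns the mean test-period angle difference per decoder.
#'
#' @param ensemble an \code{\link{ensemble_spec}}.
#' @param seed integer seed for this session.
#' @param duration_s,bin_s session geometry.
#' @param drift optional neurons x bins PD-offset matrix.
#' @return named numeric vector (radians): \code{KF}, \code{OLE}, \code{PVA};
#'   attribute \code{n_undefined} counts excluded zero-vector bins.
#' @export
run_decode_session <- function(ensemble, seed, duration_s = 300,
                               bin_s = 0.05, drift = NULL) {
  series <- generate_random_pursuit(duration_s, bin_s, seed = seed)
  spikes <- generate_spike_counts(ensemble, series, drift = drift,
                                  seed = derive_seed(seed, 2L))
  half <- series$n_bins %/% 2L
  halves <- split_train_test(series)
  rates <- spike_rates(spikes)
  r_train <- rates[, seq_len(half), drop = FALSE]
  r_test <- rates[, half + seq_len(half), drop = FALSE]
  fit <- fit_tuning(r_train, halves$train)
  kf <- fit_kf(r_train, halves$train)
  res <- list(
    KF = decode_kf(kf, r_test),
    OLE = decode_ole(fit, r_test),
    PVA = decode_pva(fit, r_test)
  )
  out <- vapply(res, function(r) mean(decode_ad(r, halves$test)), numeric(1))
  attr(out, "n_undefined") <- vapply(res, function(r) sum(!r$defined), 0L)
  out
}

decoder_names <- c("KF", "OLE", "PVA")

session_rows <- function(ads, extra) {
  cbind(extra, data.frame(decoder = decoder_names,
                          mean_ad_rad = as.numeric(ads[decoder_names]),
                          row.names = NULL))
}

bias_values <- function(n_runs) 2 * pi * (seq_len(n_runs) - 1) / n_runs

#' SNR-by-uniformity sweep
#'
#' All neurons well tuned (PWTN = 100\%) at each SNR level, with the PD
#' uniformity as the second factor; each cell is repeated over
#' \code{n_bias_runs} PD biases evenly spaced over the circle.
#'
#' @param calib an \code{\link{calibrate_snr_map}} result.
#' @param config a \code{\link{sweep_config}}.
#' @return long data.frame with columns \code{snr_db}, \code{uniformity},
#'   \code{run}, \code{bias_deg}, \code{seed}, \code{decoder},
#'   \code{mean_ad_rad}.
#' @export
run_snr_uniformity_sweep <- function(calib, config = sweep_config()) {
  stopifnot(inherits(config, "sweep_config"))
  biases <- bias_values(config$n_bias_runs)
  rows <- list()
  for (i in seq_along(config$snr_grid)) {
    for (j in seq_along(config$levels)) {
      for (r in seq_len(config$n_bias_runs)) {
        seed <- derive_seed(config$base_seed, 1L, i, j, r)
        ens <- compose_ensemble(
          n = config$n_neurons, pwtn_pct = 100,
          uwtn_pct = config$levels[j], bias_rad = biases[r],
          snr_well_db = config$snr_grid[i],
          snr_poor_db = config$snr_poor_db, calib = calib,
          b0 = config$b0, gain = config$gain
        )
        ads <- run_decode_session(ens, seed, config$duration_s, config$bin_s)
        rows[[length(rows) + 1L]] <- session_rows(ads, data.frame(
          snr_db = config$snr_grid[i], uniformity = config$levels[j],
          run = r, bias_deg = rad2deg(biases[r]), seed = seed
        ))
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "config") <- config
  out
}

#' PWTN-by-UWTN grid
#'
#' 5 x 5 grid over the proportion and uniformity of well-tuned neurons at
#' fixed well/poor SNR targets; \code{n_bias_runs} bias repeats per cell.
#'
#' @inheritParams run_snr_uniformity_sweep
#' @return long data.frame with columns \code{pwtn}, \code{uwtn}, \code{run},
#'   \code{bias_deg}, \code{seed}, \code{decoder}, \code{mean_ad_rad}.
#' @export
run_pwtn_uwtn_grid <- function(calib, config = sweep_config()) {
  stopifnot(inherits(config, "sweep_config"))
  biases <- bias_values(config$n_bias_runs)
  rows <- list()
  for (i in seq_along(config$levels)) {
    for (j in seq_along(config$levels)) {
      for (r in seq_len(config$n_bias_runs)) {
        seed <- derive_seed(config$base_seed, 2L, i, j, r)
        ens <- compose_ensemble(
          n = config$n_neurons, pwtn_pct = config$levels[i],
          uwtn_pct = config$levels[j], bias_rad = biases[r],
          snr_well_db = config$snr_well_db,
          snr_poor_db = config$snr_poor_db, calib = calib,
          b0 = config$b0, gain = config$gain
        )
        ads <- run_decode_session(ens, seed, config$duration_s, config$bin_s)
        rows[[length(rows) + 1L]] <- session_rows(ads, data.frame(
          pwtn = config$levels[i], uwtn = config$levels[j],
          run = r, bias_deg = rad2deg(biases[r]), seed = seed
        ))
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "config") <- config
  out
}

#' Circular-mean AD (degrees) per condition cell and decoder
#'
#' @param results long results from a sweep/grid driver.
#' @param by names of the condition columns to group by.
#' @return data.frame of per-cell circular-mean ADs in degrees
#'   (column \code{ad_deg}).
#' @export
summarize_ad <- function(results, by) {
  agg <- stats::aggregate(
    results$mean_ad_rad,
    by = c(results[by], list(decoder = results$decoder)),
    FUN = function(a) circular_mean(a)$theta_bar
  )
  names(agg)[ncol(agg)] <- "ad_rad"
  agg$ad_deg <- rad2deg(agg$ad_rad)
  agg
}

#' Average decoder AD gaps across UWTN levels, per PWTN level
#'
#' Per-cell circular-mean ADs are differenced between decoder pairs and
#' averaged across UWTN levels \code{>= uwtn_min}.
#'
#' @param grid_results results from \code{\link{run_pwtn_uwtn_grid}}.
#' @param uwtn_min smallest UWTN level included in the average (default 40).
#' @return data.frame with one row per PWTN level and columns
#'   \code{pva_minus_kf_deg}, \code{pva_minus_ole_deg},
#'   \code{kf_minus_ole_deg}.
#' @export
decoder_gaps <- function(grid_results, uwtn_min = 40) {
  cells <- summarize_ad(grid_results, by = c("pwtn", "uwtn"))
  cells <- cells[cells$uwtn >= uwtn_min, ]
  wide <- stats::reshape(
    cells[, c("pwtn", "uwtn", "decoder", "ad_deg")],
    idvar = c("pwtn", "uwtn"), timevar = "decoder", direction = "wide"
  )
  names(wide) <- sub("^ad_deg\\.", "", names(wide))
  out <- stats::aggregate(
    cbind(
      pva_minus_kf_deg = wide$PVA - wide$KF,
      pva_minus_ole_deg = wide$PVA - wide$OLE,
      kf_minus_ole_deg = wide$KF - wide$OLE
    ),
    by = list(pwtn = wide$pwtn), FUN = mean
  )
  out[order(out$pwtn), ]
}

#' Mirrored-cell (triangle) asymmetry of the PWTN-by-UWTN grid
#'
#' For every unordered level pair (a > b), compares the upper-triangle cell
#' (PWTN = a, UWTN = b) with its mirror (PWTN = b, UWTN = a) per decoder:
#' counts pairs where the upper cell has the smaller circular-mean AD and
#' runs a pooled Watson U2 on the concatenated per-run ADs.
#'
#' @param grid_results results from \code{\link{run_pwtn_uwtn_grid}}.
#' @param n_perm permutations for the pooled Watson U2.
#' @param seed seed for the permutation null.
#' @return list per decoder: \code{pairs} (data.frame with per-pair ADs),
#'   \code{n_upper_wins}, \code{n_pairs}, \code{pooled_u2},
#'   \code{pooled_p}.
#' @export
triangle_asymmetry <- function(grid_results, n_perm = 999, seed = 1) {
  levels <- sort(unique(grid_results$pwtn))
  combos <- utils::combn(levels, 2) # columns: (b, a) with b < a
  out <- list()
  for (dec in decoder_names) {
    sub <- grid_results[grid_results$decoder == dec, ]
    upper_all <- numeric(0)
    lower_all <- numeric(0)
    pairs <- data.frame()
    for (k in seq_len(ncol(combos))) {
      b <- combos[1, k]
      a <- combos[2, k]
      up <- sub$mean_ad_rad[sub$pwtn == a & sub$uwtn == b]
      lo <- sub$mean_ad_rad[sub$pwtn == b & sub$uwtn == a]
      upper_all <- c(upper_all, up)
      lower_all <- c(lower_all, lo)
      pairs <- rbind(pairs, data.frame(
        pwtn_hi = a, pwtn_lo = b,
        ad_upper_deg = rad2deg(circular_mean(up)$theta_bar),
        ad_lower_deg = rad2deg(circular_mean(lo)$theta_bar)
      ))
    }
    wu <- watson_u2(upper_all, lower_all, n_perm = n_perm,
                    seed = derive_seed(seed, 3L, match(dec, decoder_names)))
    out[[dec]] <- list(
      pairs = pairs,
      n_upper_wins = sum(pairs$ad_upper_deg < pairs$ad_lower_deg),
      n_pairs = nrow(pairs),
      pooled_u2 = wu$u2, pooled_p = wu$p_value
    )
  }
  out
}

#' Stability (variation-of-AD) analysis of the PWTN-by-UWTN grid
#'
#' For each decoder and bias run, the variation of AD is computed across
#' successive UWTN drops (one replicate per PWTN condition) and across
#' successive PWTN drops (one per UWTN condition); each direction is tested
#' with a two-way ANOVA (decoder x condition) with Bonferroni post hoc
#' comparisons.
#'
#' @param grid_results results from \code{\link{run_pwtn_uwtn_grid}}.
#' @return list with elements \code{uwtn} and \code{pwtn}, each containing
#'   \code{data} (decoder, condition, run, value in deg/\%), \code{anova}
#'   (from \code{\link{anova_two_way}}) and \code{decoder_means}; plus
#'   \code{pooled_decoder_means} across both directions.
#' @export
run_stability_analysis <- function(grid_results) {
  levels <- sort(unique(grid_results$pwtn), decreasing = TRUE)
  variation_table <- function(drop_var, cond_var) {
    rows <- list()
    runs <- sort(unique(grid_results$run))
    conds <- sort(unique(grid_results[[cond_var]]))
    for (dec in decoder_names) {
      sub <- grid_results[grid_results$decoder == dec, ]
      for (cond in conds) {
        sc <- sub[sub[[cond_var]] == cond, ]
        for (r in runs) {
          sr <- sc[sc$run == r, ]
          ad <- rad2deg(sr$mean_ad_rad)
          names(ad) <- as.character(sr[[drop_var]])
          rows[[length(rows) + 1L]] <- data.frame(
            decoder = dec, condition = cond, run = r,
            value = stability_variation(ad, levels)
          )
        }
      }
    }
    do.call(rbind, rows)
  }
  analyze <- function(tab) {
    list(
      data = tab,
      anova = anova_two_way(tab, value = "value", factor_a = "decoder",
                            factor_b = "condition"),
      decoder_means = tapply(tab$value, tab$decoder, mean)
    )
  }
  uwtn <- analyze(variation_table("uwtn", "pwtn"))
  pwtn <- analyze(variation_table("pwtn", "uwtn"))
  pooled <- rbind(uwtn$data, pwtn$data)
  list(
    uwtn = uwtn, pwtn = pwtn,
    pooled_decoder_means = tapply(pooled$value, pooled$decoder, mean),
    pooled_anova = anova_two_way(
      transform(pooled, condition = interaction(condition, rep(
        c("uwtn", "pwtn"), c(nrow(uwtn$data), nrow(pwtn$data))
      ))),
      value = "value", factor_a = "decoder", factor_b = "condition"
    )
  )
}

#' Non-stationarity experiment (Gompertz PD drift)
#'
#' PWTN = UWTN = 100\%. Each repeat samples per-neuron drift parameters
#' (asymptotic shift uniform on [-45, 45] degrees, rate uniform on
#' [0.001, 0.004] per bin), keeps the training half stationary and lets PDs
#' drift during the test half; a stationary control with identical seeds is
#' run alongside.
#'
#' @inheritParams run_snr_uniformity_sweep
#' @return long data.frame with columns \code{run}, \code{condition}
#'   (\code{"stationary"} or \code{"drift"}), \code{seed}, \code{decoder},
#'   \code{mean_ad_rad}.
#' @export
run_nonstationarity <- function(calib, config = sweep_config()) {
  stopifnot(inherits(config, "sweep_config"))
  n_runs <- config$n_drift_runs
  biases <- bias_values(n_runs)
  rows <- list()
  for (r in seq_len(n_runs)) {
    seed <- derive_seed(config$base_seed, 4L, r)
    ens <- compose_ensemble(
      n = config$n_neurons, pwtn_pct = 100, uwtn_pct = 100,
      bias_rad = biases[r], snr_well_db = config$snr_well_db,
      snr_poor_db = config$snr_poor_db, calib = calib,
      b0 = config$b0, gain = config$gain
    )
    n_bins <- as.integer(round(config$duration_s / config$bin_s))
    half <- n_bins %/% 2L
    params <- sample_gompertz_params(config$n_neurons,
                                     seed = derive_seed(seed, 5L))
    drift <- drift_matrix(params, half, n_bins - half)
    for (cond in c("stationary", "drift")) {
      ads <- run_decode_session(
        ens, seed, config$duration_s, config$bin_s,
        drift = if (cond == "drift") drift else NULL
      )
      rows[[length(rows) + 1L]] <- session_rows(ads, data.frame(
        run = r, condition = cond, seed = seed
      ))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "config") <- config
  out
}

#' Summarize the non-stationarity experiment
#'
#' @param results from \code{\link{run_nonstationarity}}.
#' @param n_perm,seed permutation settings for the between-decoder Watson U2
#'   tests on the drift-condition ADs.
#' @return list with \code{ad_deg} (circular-mean AD per decoder and
#'   condition), \code{increase_deg} (drift minus stationary), and
#'   \code{watson} (pairwise p-values between decoders under drift).
#' @export
summarize_nonstationarity <- function(results, n_perm = 999, seed = 1) {
  cm <- function(cond, dec) {
    circular_mean(results$mean_ad_rad[
      results$condition == cond & results$decoder == dec
    ])$theta_bar
  }
  ad <- sapply(c("stationary", "drift"), function(cond) {
    sapply(decoder_names, function(dec) rad2deg(cm(cond, dec)))
  })
  drift_ads <- function(dec) {
    results$mean_ad_rad[results$condition == "drift" & results$decoder == dec]
  }
  pairs <- utils::combn(decoder_names, 2)
  watson <- apply(pairs, 2, function(p) {
    a <- drift_ads(p[1])
    b <- drift_ads(p[2])
    if (length(a) < 8 || length(b) < 8) return(NA_real_) # too few repeats
    watson_u2(a, b, n_perm = n_perm, seed = seed)$p_value
  })
  names(watson) <- apply(pairs, 2, paste, collapse = "_vs_")
  list(
    ad_deg = ad,
    increase_deg = ad[, "drift"] - ad[, "stationary"],
    watson = watson
  )
}

#' Spearman correlation of AD against SNR per decoder and uniformity
#'
#' @param sweep_results from \code{\link{run_snr_uniformity_sweep}}.
#' @return data.frame with columns \code{decoder}, \code{uniformity},
#'   \code{rho}.
#' @export
snr_monotonicity <- function(sweep_results) {
  cells <- summarize_ad(sweep_results, by = c("snr_db", "uniformity"))
  out <- expand.grid(
    decoder = decoder_names,
    uniformity = sort(unique(cells$uniformity)),
    stringsAsFactors = FALSE
  )
  out$rho <- mapply(function(dec, u) {
    sub <- cells[cells$decoder == dec & cells$uniformity == u, ]
    stats::cor(sub$snr_db, sub$ad_deg, method = "spearman")
  }, out$decoder, out$uniformity)
  out
}
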