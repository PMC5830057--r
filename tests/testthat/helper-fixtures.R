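# Shared fixtures. The SNR calibration is expensive (a preliminary
# simulation), so it is computed once per test run and reused.

cached_calib <- local({
  calib <- NULL
  function() {
    if (is.null(calib)) calib <<- calibrate_snr_map(seed = 11)
    calib
  }
})

# Direction series with evenly spaced headings (exact angular moments).
even_series <- function(n, bin_s = 0.05) {
  direction_series(2 * pi * (seq_len(n) - 1) / n, bin_s = bin_s)
}

# Noiseless rate matrix for an ensemble over a series (no AWGN, no Poisson).
noiseless_rates <- function(pd, b0, gain, series) {
  B <- cbind(b0, gain * cos(pd), gain * sin(pd))
  B %*% rbind(1, t(series$dxy))
}
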