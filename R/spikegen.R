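## Spike generation: cosine tuning + additive white Gaussian rate noise +
## Poisson counts at 50-ms bins.
##
## Rates are held constant within a bin, so drawing one Poisson count per bin
## with mean rate * bin_s is distribution-identical to summing 50 independent
## 1-ms Poisson draws (Poisson additivity); an explicit 1-ms event-list
## exporter is provided for spike-train output. One AWGN draw is taken per
## bin — the noise lives on the firing-rate scale at which the tuning model
## is estimated — and rates are rectified at zero before the Poisson draw.

#' Noiseless cosine-tuning rate of one neuron
#'
#' \code{b0 + gain * cos(theta - (pd + pd_offset))}, evaluated through the
#' tuning-coefficient expansion \code{b0 + b1*dx + b2*dy}.
#'
#' @param neuron one-row data.frame (or list) with fields \code{b0},
#'   \code{gain}, \code{pd}.
#' @param dxy unit 2-vector (or n x 2 matrix) of movement direction.
#' @param pd_offset additive PD offset in radians (drift), scalar or
#'   per-row vector.
#' @return firing rate(s) in spikes/s.
#' @export
tuning_rate <- function(neuron, dxy, pd_offset = 0) {
  dxy <- if (is.null(dim(dxy))) matrix(dxy, nrow = 1) else as.matrix(dxy)
  nrm <- sqrt(rowSums(dxy^2))
  if (any(abs(nrm - 1) > 1e-8)) stop_invalid("'dxy' must be unit vectors")
  pd <- neuron$pd + pd_offset
  drop(neuron$b0 + neuron$gain * (cos(pd) * dxy[, 1] + sin(pd) * dxy[, 2]))
}

#' Add white Gaussian noise to a firing rate and rectify at zero
#'
#' @param signal_rate noiseless rate(s), spikes/s.
#' @param sigma2 noise variance ((spikes/s)^2).
#' @return noisy non-negative rate(s).
#' @export
noisy_rate <- function(signal_rate, sigma2) {
  if (any(sigma2 < 0)) stop_invalid("'sigma2' must be >= 0")
  pmax(0, signal_rate + stats::rnorm(length(signal_rate), 0, sqrt(sigma2)))
}

#' Generate binned spike counts for an ensemble
#'
#' Per neuron and bin: noiseless cosine rate (with optional per-bin PD drift),
#' one AWGN draw, rectification at zero, then a Poisson count with mean
#' \code{rate * bin_s}.
#'
#' @param ensemble an \code{\link{ensemble_spec}}.
#' @param series a \code{\link{direction_series}}.
#' @param drift optional neurons x bins matrix of PD offsets (radians), e.g.
#'   from \code{\link{drift_matrix}}.
#' @param seed integer seed.
#' @return an object of class \code{spike_data}: list with \code{counts}
#'   (neurons x bins integer matrix), \code{rates_true} (noiseless rates),
#'   \code{bin_s} and \code{seed}.
#' @export
generate_spike_counts <- function(ensemble, series, drift = NULL, seed = NULL) {
  stopifnot(inherits(ensemble, "ensemble_spec"),
            inherits(series, "direction_series"))
  nn <- ensemble$n
  nb <- series$n_bins
  neu <- ensemble$neurons
  if (!is.null(drift)) {
    drift <- as.matrix(drift)
    if (!all(dim(drift) == c(nn, nb))) {
      stop_invalid("'drift' must be a neurons x bins matrix")
    }
    pd <- drift + neu$pd # row-wise recycling: drift[i,] + pd[i]
    rates_true <- neu$b0 +
      neu$gain * (cos(pd) * rep(series$dxy[, 1], each = nn) +
                  sin(pd) * rep(series$dxy[, 2], each = nn))
  } else {
    # b1,b2 expansion: rate = b0 + gain*cos(pd)*dx + gain*sin(pd)*dy
    B <- cbind(neu$b0, neu$gain * cos(neu$pd), neu$gain * sin(neu$pd))
    rates_true <- B %*% rbind(1, t(series$dxy))
  }
  with_seed(seed, {
    noise <- matrix(stats::rnorm(nn * nb, 0, sqrt(neu$sigma2)), nn, nb)
    lambda <- pmax(0, rates_true + noise) * series$bin_s
    counts <- matrix(stats::rpois(nn * nb, lambda), nn, nb)
    structure(
      list(counts = counts, rates_true = rates_true, bin_s = series$bin_s,
           seed = seed),
      class = "spike_data"
    )
  })
}

#' @export
print.spike_data <- function(x, ...) {
  cat(sprintf(
    "<spike_data> %d neurons x %d bins (%.0f ms), mean rate %.1f sp/s\n",
    nrow(x$counts), ncol(x$counts), x$bin_s * 1000,
    mean(x$counts) / x$bin_s
  ))
  invisible(x)
}

#' Convert spike counts to firing rates
#'
#' @param x a \code{spike_data} or a counts matrix.
#' @param bin_s bin width in seconds (taken from \code{x} when available).
#' @return neurons x bins matrix of rates (spikes/s).
#' @export
spike_rates <- function(x, bin_s = 0.05) {
  if (inherits(x, "spike_data")) x$counts / x$bin_s else as.matrix(x) / bin_s
}

#' Export spike counts as a 1-ms event list
#'
#' Given a bin count k, spike times are placed uniformly at random within the
#' bin (the order statistics of a homogeneous Poisson process conditioned on
#' its count).
#'
#' @param spikes a \code{spike_data}.
#' @param seed integer seed for within-bin placement.
#' @return data.frame with columns \code{neuron_id}, \code{spike_time_s}.
#' @export
spike_events <- function(spikes, seed = NULL) {
  stopifnot(inherits(spikes, "spike_data"))
  cnt <- spikes$counts
  with_seed(seed, {
    idx <- which(cnt > 0, arr.ind = TRUE)
    k <- cnt[cnt > 0]
    neuron <- rep(idx[, 1], k)
    bin <- rep(idx[, 2], k)
    t_s <- (bin - 1) * spikes$bin_s + stats::runif(length(bin)) * spikes$bin_s
    ord <- order(neuron, t_s)
    data.frame(neuron_id = neuron[ord], spike_time_s = t_s[ord])
  })
}

#' Write / read spike counts as CSV plus JSON metadata
#'
#' @param spikes a \code{spike_data}.
#' @param path CSV path for the neurons x bins count matrix; metadata goes to
#'   \code{paste0(path, ".json")}.
#' @return the path (write) or a \code{spike_data} (read).
#' @export
write_spike_data <- function(spikes, path) {
  stopifnot(inherits(spikes, "spike_data"))
  utils::write.table(spikes$counts, path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(bin_s = spikes$bin_s, seed = spikes$seed,
         n_neurons = nrow(spikes$counts), n_bins = ncol(spikes$counts)),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_spike_data
#' @export
read_spike_data <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  counts <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(counts) <- NULL
  structure(
    list(counts = counts, rates_true = NULL, bin_s = meta$bin_s,
         seed = meta$seed),
    class = "spike_data"
  )
}
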