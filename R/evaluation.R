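## Evaluation: angle-difference metric, circular means, Rayleigh uniformity
## test, Watson's two-sample U2 (permutation p-values), variation-of-AD
## stability metric, and two-way ANOVA with Bonferroni post hoc comparisons.

#' Angle difference between true and estimated direction
#'
#' \code{|acos(d_true . d_est)|} with the dot product clamped to [-1, 1];
#' result lies in [0, pi].
#'
#' @param d_true,d_est unit 2-vectors, or matrices with one row per bin.
#' @return angle difference(s) in radians.
#' @export
angle_difference <- function(d_true, d_est) {
  a <- if (is.null(dim(d_true))) matrix(d_true, nrow = 1) else as.matrix(d_true)
  b <- if (is.null(dim(d_est))) matrix(d_est, nrow = 1) else as.matrix(d_est)
  if (any(abs(sqrt(rowSums(a^2)) - 1) > 1e-8, na.rm = TRUE) ||
      any(abs(sqrt(rowSums(b^2)) - 1) > 1e-8, na.rm = TRUE)) {
    stop_invalid("inputs must be unit vectors")
  }
  dot <- pmin(1, pmax(-1, rowSums(a * b)))
  abs(acos(dot))
}

#' Per-bin angle differences of a decode result
#'
#' Undefined bins (zero-magnitude raw estimate) are dropped.
#'
#' @param result a \code{decode_result}.
#' @param series the matching test \code{\link{direction_series}}.
#' @return numeric vector of ADs in radians, one per defined bin.
#' @export
decode_ad <- function(result, series) {
  stopifnot(inherits(result, "decode_result"),
            inherits(series, "direction_series"))
  ok <- result$defined
  angle_difference(series$dxy[ok, , drop = FALSE],
                   result$d_unit[ok, , drop = FALSE])
}

#' Circular mean of a sample of angles
#'
#' \code{X = mean(cos a)}, \code{Y = mean(sin a)},
#' \code{theta_bar = atan2(Y, X)} (quadrant-correct).
#'
#' @param angles numeric vector of angles in radians.
#' @return list with \code{X}, \code{Y}, \code{theta_bar}, resultant length
#'   \code{R} and \code{n}. \code{theta_bar} is \code{NA} (undefined mean)
#'   when \code{R < 1e-12}.
#' @export
circular_mean <- function(angles) {
  if (length(angles) < 1) stop_invalid("empty angle sample")
  X <- mean(cos(angles))
  Y <- mean(sin(angles))
  R <- sqrt(X^2 + Y^2)
  list(
    X = X, Y = Y, R = R,
    theta_bar = if (R < 1e-12) NA_real_ else atan2(Y, X),
    n = length(angles)
  )
}

#' Rayleigh test of circular uniformity
#'
#' z = n R^2 with R the resultant length; the p-value uses the standard
#' series approximation
#' \code{p = exp(-z) [1 + (2z - z^2)/(4n) - (24z - 132z^2 + 76z^3 - 9z^4)/(288 n^2)]}.
#'
#' @param angles numeric vector of angles in radians (n >= 5).
#' @return list with \code{z}, \code{p_value}, \code{R}, \code{n}.
#' @export
rayleigh_test <- function(angles) {
  n <- length(angles)
  if (n < 5) stop_invalid("Rayleigh test needs at least 5 angles")
  R <- circular_mean(angles)$R
  z <- n * R^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
                    (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  list(z = z, p_value = min(max(p, 0), 1), R = R, n = n)
}

## Watson's two-sample U2 ------------------------------------------------------

# U2 statistic from a sorted-pooled membership vector. d is the running
# difference of the two empirical CDFs; ties are handled mid-rank style by
# evaluating d only at the end of each tied group, weighted by its size
# (weights w sum to N).
watson_u2_stat <- function(is_a_sorted, w, n, m) {
  d <- cumsum(ifelse(is_a_sorted, 1 / n, -1 / m))
  N <- n + m
  n * m / N^2 * (sum(w * d^2) - sum(w * d)^2 / N)
}

tie_weights <- function(pooled_sorted) {
  # weight vector: size of the tied group at its last member, 0 elsewhere
  grp <- cumsum(!duplicated(pooled_sorted))
  w <- numeric(length(grp))
  last <- !duplicated(grp, fromLast = TRUE)
  w[last] <- tabulate(grp)[grp[last]]
  w
}

#' Watson's two-sample U2 test for circular data
#'
#' Statistic from the pooled circular ranks; the p-value is obtained by a
#' seeded label-permutation null (the statistic is recomputed for
#' \code{n_perm} random reassignments of the pooled angles to the two
#' samples).
#'
#' @param sample_a,sample_b numeric vectors of angles in radians
#'   (each n >= 8).
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed for the permutation null.
#' @return list with \code{u2}, \code{p_value}, \code{n_perm}, \code{ties}.
#' @export
watson_u2 <- function(sample_a, sample_b, n_perm = 999, seed = 1) {
  n <- length(sample_a)
  m <- length(sample_b)
  if (n < 8 || m < 8) stop_invalid("both samples need at least 8 angles")
  pooled <- wrap_angle(c(sample_a, sample_b))
  lab <- c(rep(TRUE, n), rep(FALSE, m))
  ord <- order(pooled)
  pooled <- pooled[ord]
  lab <- lab[ord]
  has_ties <- anyDuplicated(pooled) > 0
  w <- if (has_ties) tie_weights(pooled) else rep(1, n + m)
  u2 <- watson_u2_stat(lab, w, n, m)
  N <- n + m
  with_seed(seed, {
    # vectorized label permutations: one column per permutation
    L <- matrix(FALSE, N, n_perm)
    idx <- vapply(seq_len(n_perm), function(b) sample.int(N, n), integer(n))
    L[idx + rep((seq_len(n_perm) - 1L) * N, each = n)] <- TRUE
    D <- apply(ifelse(L, 1 / n, -1 / m), 2, cumsum)
    stats <- n * m / N^2 *
      (colSums(w * D^2) - colSums(w * D)^2 / N)
    list(
      u2 = u2, p_value = (sum(stats >= u2 - 1e-15) + 1) / (n_perm + 1),
      n_perm = n_perm, ties = has_ties
    )
  })
}

#' Summarize per-run mean angle differences across repeated runs
#'
#' Per-run summaries (arithmetic mean of the per-bin ADs within a run) are
#' combined across runs by the circular mean; the arithmetic
#' mean across runs is kept as a diagnostic (the two coincide for small ADs).
#'
#' @param run_means numeric vector of per-run mean ADs in radians.
#' @return object of class \code{ad_summary}: list with \code{run_means},
#'   \code{X}, \code{Y}, \code{theta_bar} (circular mean, radians),
#'   \code{mean_arith}, \code{n_runs}.
#' @export
ad_summary <- function(run_means) {
  cm <- circular_mean(run_means)
  structure(
    list(
      run_means = run_means, X = cm$X, Y = cm$Y, R = cm$R,
      theta_bar = cm$theta_bar, mean_arith = mean(run_means),
      n_runs = length(run_means)
    ),
    class = "ad_summary"
  )
}

#' @export
print.ad_summary <- function(x, ...) {
  cat(sprintf(
    "<ad_summary> %d runs: circular mean AD %.2f deg (arithmetic %.2f deg)\n",
    x$n_runs, rad2deg(x$theta_bar), rad2deg(x$mean_arith)
  ))
  invisible(x)
}

#' Variation of AD across successive condition-level drops
#'
#' For descending levels (e.g. 100, 80, 60, 40, 20 percent) computes, for
#' each successive drop hi -> lo, \code{(AD_lo - AD_hi) / hi} and returns the
#' mean. Units: AD units per percent.
#'
#' @param ad_by_level named numeric vector of ADs; names are the levels.
#' @param levels numeric vector of levels in strictly descending order.
#' @return mean variation of AD.
#' @export
stability_variation <- function(ad_by_level, levels = c(100, 80, 60, 40, 20)) {
  if (length(levels) < 2 || any(diff(levels) >= 0)) {
    stop_invalid("'levels' must be >= 2 values in strictly descending order")
  }
  key <- as.character(levels)
  if (!all(key %in% names(ad_by_level))) stop_invalid("missing AD level")
  ad <- ad_by_level[key]
  hi <- seq_len(length(levels) - 1)
  mean((ad[hi + 1] - ad[hi]) / levels[hi])
}

#' Two-way ANOVA with Bonferroni-corrected pairwise comparisons
#'
#' Fits \code{value ~ factor_a * factor_b} with \code{stats::aov}; returns F
#' and p for both main effects and the interaction, plus Bonferroni-adjusted
#' pairwise t comparisons within each factor.
#'
#' @param data data.frame with the response and two factor columns.
#' @param value,factor_a,factor_b column names.
#' @return list with \code{table} (effect, df, F, p), \code{pairwise_a},
#'   \code{pairwise_b} (Bonferroni-adjusted p-value matrices).
#' @export
anova_two_way <- function(data, value = "value", factor_a = "decoder",
                          factor_b = "condition") {
  df <- data.frame(
    y = data[[value]],
    a = factor(data[[factor_a]]),
    b = factor(data[[factor_b]])
  )
  cells <- table(df$a, df$b)
  if (any(cells == 0)) stop_invalid("unbalanced design: empty factor cells")
  if (any(cells < 2)) stop_invalid("need >= 2 replicates per cell")
  fit <- stats::aov(y ~ a * b, data = df)
  tab <- summary(fit)[[1]]
  eff <- data.frame(
    effect = c(factor_a, factor_b, "interaction"),
    df = tab[1:3, "Df"],
    F = tab[1:3, "F value"],
    p = tab[1:3, "Pr(>F)"]
  )
  # a constant response has no effects: report F = 0 rather than 0/0 noise
  zero <- if (stats::var(df$y) == 0) rep(TRUE, 3) else {
    !is.finite(eff$F) & tab[1:3, "Sum Sq"] < 1e-24
  }
  eff$F[zero] <- 0
  eff$p[zero] <- 1
  pw <- function(g) {
    if (stats::sd(df$y) == 0) {
      k <- nlevels(g)
      m <- matrix(1, k - 1, k - 1)
      return(m)
    }
    stats::pairwise.t.test(df$y, g, p.adjust.method = "bonferroni")$p.value
  }
  list(table = eff, pairwise_a = pw(df$a), pairwise_b = pw(df$b))
}
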