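## Direction decoders: population vector algorithm (PVA), optimal linear
## estimator (OLE) and Kalman filter (KF), all trained on binned firing rates
## (counts / bin width) and the training direction series.

#' Fit per-neuron cosine tuning models and the residual covariance
#'
#' Ordinary least squares of each neuron's rate on (1, dx, dy); the ensemble
#' residual covariance Sigma is estimated from the stacked residuals and
#' ridge-conditioned (\code{eps = 1e-8 * mean(diag(Sigma))}, with a 1e-10
#' floor) so degenerate noiseless inputs remain invertible.
#'
#' @param x a \code{\link{spike_data}} or a neurons x bins matrix of firing
#'   rates (spikes/s).
#' @param train the training \code{\link{direction_series}}.
#' @return object of class \code{tuning_fit}: per-neuron \code{b0_hat},
#'   \code{b1_hat}, \code{b2_hat}, \code{pd_hat}, \code{resid_var}; matrices
#'   \code{B} (N x 2), \code{Sigma} and \code{Sigma_cond} (N x N).
#' @export
fit_tuning <- function(x, train) {
  stopifnot(inherits(train, "direction_series"))
  rates <- if (inherits(x, "spike_data")) spike_rates(x) else as.matrix(x)
  nb <- ncol(rates)
  if (nb != train$n_bins) stop_invalid("rates and training series are not aligned")
  if (nb < 3) stop_invalid("need at least 3 training bins")
  X <- cbind(1, train$dxy)
  XtX <- crossprod(X)
  if (qr(XtX)$rank < 3) stop_invalid("degenerate design: training directions are collinear")
  coefs <- solve(XtX, crossprod(X, t(rates))) # 3 x N
  resid <- t(rates) - X %*% coefs # bins x N
  Sigma <- crossprod(resid) / max(1, nb - 3)
  eps <- max(1e-8 * mean(diag(Sigma)), 1e-10)
  structure(
    list(
      b0_hat = coefs[1, ], b1_hat = coefs[2, ], b2_hat = coefs[3, ],
      pd_hat = atan2(coefs[3, ], coefs[2, ]),
      resid_var = diag(Sigma),
      B = t(coefs[2:3, , drop = FALSE]),
      Sigma = Sigma,
      Sigma_cond = Sigma + diag(eps, nrow(Sigma)),
      n_train = nb
    ),
    class = "tuning_fit"
  )
}

#' @export
print.tuning_fit <- function(x, ...) {
  cat(sprintf(
    "<tuning_fit> %d neurons, %d training bins\n",
    length(x$b0_hat), x$n_train
  ))
  invisible(x)
}

as_rate_matrix <- function(z, n_neurons) {
  z <- if (is.null(dim(z))) matrix(z, ncol = 1) else as.matrix(z)
  if (nrow(z) != n_neurons) stop_invalid("rate vector does not match the fitted ensemble")
  z
}

finish_decode <- function(d, decoder) {
  # d: bins x 2 raw estimates
  mag <- sqrt(rowSums(d^2))
  defined <- mag > 1e-12
  theta <- ifelse(defined, atan2(d[, 2], d[, 1]), NA_real_)
  u <- d / ifelse(defined, mag, 1)
  u[!defined, ] <- NA_real_
  structure(
    list(d_hat = d, d_unit = u, theta_hat = theta, defined = defined,
         decoder = decoder),
    class = "decode_result"
  )
}

#' @export
print.decode_result <- function(x, ...) {
  cat(sprintf(
    "<decode_result> %s: %d bins (%d undefined)\n",
    x$decoder, length(x$theta_hat), sum(!x$defined)
  ))
  invisible(x)
}

#' Population vector decoding
#'
#' Sums baseline-centered rates times unit PD vectors:
#' \code{d_hat = sum_i (z_i - b0_i) c_i}.
#'
#' @param fit a \code{\link{fit_tuning}} result.
#' @param z rates for one bin (N-vector) or N x bins matrix.
#' @return a \code{decode_result}; bins whose population vector has zero
#'   magnitude are flagged undefined.
#' @export
decode_pva <- function(fit, z) {
  stopifnot(inherits(fit, "tuning_fit"))
  z <- as_rate_matrix(z, length(fit$b0_hat))
  C <- cbind(cos(fit$pd_hat), sin(fit$pd_hat)) # N x 2
  d <- crossprod(z - fit$b0_hat, C) # bins x 2
  finish_decode(d, "PVA")
}

#' Optimal linear estimation decoding
#'
#' Generalized least squares through the fitted tuning matrix and residual
#' covariance: \code{d_hat = (B' Sigma^-1 B)^-1 B' Sigma^-1 (z - b0)}.
#'
#' @inheritParams decode_pva
#' @param center subtract the fitted per-neuron baseline before decoding
#'   (default TRUE).
#' @return a \code{decode_result}.
#' @export
decode_ole <- function(fit, z, center = TRUE) {
  stopifnot(inherits(fit, "tuning_fit"))
  z <- as_rate_matrix(z, length(fit$b0_hat))
  SiB <- solve(fit$Sigma_cond, fit$B) # N x 2
  W <- solve(crossprod(fit$B, SiB), t(SiB)) # 2 x N
  zc <- if (center) z - fit$b0_hat else z
  d <- t(W %*% zc)
  finish_decode(d, "OLE")
}

#' Fit the Kalman-filter observation and state models
#'
#' Observation model z = b0 + H d + eps (H and Q time invariant, fitted by
#' least squares with an intercept, Q from its residual covariance); state
#' model d_t = A d_{t-1} + v (A and V by least squares on successive training
#' directions).
#'
#' @inheritParams fit_tuning
#' @return object of class \code{kf_model}: \code{H} (N x 2), \code{b0},
#'   \code{Q} (conditioned), \code{A}, \code{V} (2 x 2), \code{init_state},
#'   \code{init_cov}.
#' @export
fit_kf <- function(x, train) {
  fit <- fit_tuning(x, train)
  D <- train$dxy
  nb <- nrow(D)
  D0 <- D[-nb, , drop = FALSE]
  D1 <- D[-1, , drop = FALSE]
  A <- t(solve(crossprod(D0), crossprod(D0, D1))) # 2 x 2
  resid <- D1 - D0 %*% t(A)
  V <- crossprod(resid) / max(1, nb - 1 - 2)
  structure(
    list(
      H = fit$B, b0 = fit$b0_hat, Q = fit$Sigma_cond,
      A = A, V = V,
      init_state = c(1, 0), init_cov = diag(10, 2),
      tuning = fit
    ),
    class = "kf_model"
  )
}

#' @export
print.kf_model <- function(x, ...) {
  cat(sprintf("<kf_model> %d neurons, 2-D direction state\n", nrow(x$H)))
  invisible(x)
}

#' Generic linear Kalman filter recursion
#'
#' Textbook predict/update recursion with time-invariant models, implemented
#' in information form for the update (posterior precision
#' \code{P^-1 + H' Q^-1 H}), which is algebraically identical to the
#' gain form but keeps all per-bin solves at state dimension.
#'
#' @param Z observations, one column per time step (p x T).
#' @param H observation matrix (p x k).
#' @param Q observation noise covariance (p x p).
#' @param A state transition (k x k).
#' @param V state noise covariance (k x k).
#' @param x0 initial state mean (k-vector).
#' @param P0 initial state covariance (k x k).
#' @return list with \code{states} (T x k posterior means) and \code{P_trace}
#'   (posterior covariance trace per step).
#' @export
kalman_filter <- function(Z, H, Q, A, V, x0, P0) {
  Z <- as.matrix(Z)
  k <- length(x0)
  nt <- ncol(Z)
  QiH <- solve(Q, H) # p x k
  HtQiH <- crossprod(H, QiH) # k x k
  HtQiZ <- crossprod(QiH, Z) # k x T
  x <- x0
  P <- P0
  states <- matrix(NA_real_, nt, k)
  p_trace <- numeric(nt)
  for (t in seq_len(nt)) {
    xp <- A %*% x
    Pp <- A %*% P %*% t(A) + V
    Ppi <- solve(Pp)
    prec <- Ppi + HtQiH
    P <- solve(prec)
    P <- (P + t(P)) / 2
    x <- P %*% (Ppi %*% xp + HtQiZ[, t])
    states[t, ] <- x
    p_trace[t] <- sum(diag(P))
  }
  list(states = states, P_trace = p_trace)
}

#' Kalman-filter decoding of test-period directions
#'
#' @param model a \code{\link{fit_kf}} result.
#' @param x a \code{\link{spike_data}} or neurons x bins rate matrix for the
#'   test period.
#' @return a \code{decode_result}; raw (un-normalized) state estimates are
#'   kept in \code{d_hat}, unit-normalized copies in \code{d_unit}.
#' @export
decode_kf <- function(model, x) {
  stopifnot(inherits(model, "kf_model"))
  rates <- if (inherits(x, "spike_data")) spike_rates(x) else as.matrix(x)
  rates <- as_rate_matrix(rates, nrow(model$H))
  run <- kalman_filter(
    rates - model$b0, model$H, model$Q, model$A, model$V,
    model$init_state, model$init_cov
  )
  out <- finish_decode(run$states, "KF")
  out$P_trace <- run$P_trace
  out
}

#' Serialize a fitted decoder model to JSON
#'
#' Matrices are written row-major with explicit dimensions.
#'
#' @param model a \code{tuning_fit} or \code{kf_model}.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_decoder_model <- function(model, path) {
  mat <- function(m) list(dim = dim(m), data = as.numeric(t(m)))
  payload <- if (inherits(model, "kf_model")) {
    list(
      type = "kf", H = mat(model$H), b0 = model$b0, Q = mat(model$Q),
      A = mat(model$A), V = mat(model$V),
      init_state = model$init_state, init_cov = mat(model$init_cov)
    )
  } else if (inherits(model, "tuning_fit")) {
    list(
      type = "tuning", b0_hat = model$b0_hat, b1_hat = model$b1_hat,
      b2_hat = model$b2_hat, pd_hat = model$pd_hat,
      Sigma = mat(model$Sigma)
    )
  } else {
    stop_invalid("unsupported model type")
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write decoded directions as CSV
#'
#' Columns: \code{bin_index}, \code{dx_hat}, \code{dy_hat},
#' \code{theta_hat_rad}, \code{defined_flag}.
#'
#' @param result a \code{decode_result}.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_decode_result <- function(result, path) {
  stopifnot(inherits(result, "decode_result"))
  utils::write.csv(
    data.frame(
      bin_index = seq_along(result$theta_hat),
      dx_hat = result$d_hat[, 1], dy_hat = result$d_hat[, 2],
      theta_hat_rad = result$theta_hat, defined_flag = result$defined
    ),
    path,
    row.names = FALSE
  )
  invisible(path)
}
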