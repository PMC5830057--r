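test_that("tuning fits recover exact coefficients from noiseless rates", {
  series <- even_series(40)
  pd <- c(0.3, -1.2, 2.5)
  rates <- noiseless_rates(pd, b0 = 45, gain = 30, series)
  fit <- fit_tuning(rates, series)
  expect_equal(fit$b0_hat, rep(45, 3), tolerance = 1e-9)
  expect_equal(fit$pd_hat, pd, tolerance = 1e-9)
  expect_equal(unname(fit$B),
               unname(cbind(30 * cos(pd), 30 * sin(pd))), tolerance = 1e-9)
})

test_that("tuning fit matches a hand-computed normal-equation solution", {
  # 2 neurons x 4 bins toy
  theta <- c(0.1, 1.3, -2.0, 2.8)
  series <- direction_series(theta)
  rates <- matrix(c(3, 7, 2, 5,
                    1, 4, 6, 2), 2, 4, byrow = TRUE)
  fit <- fit_tuning(rates, series)
  X <- cbind(1, cos(theta), sin(theta))
  beta_oracle <- solve(t(X) %*% X) %*% t(X) %*% t(rates)
  expect_equal(c(fit$b0_hat, fit$b1_hat, fit$b2_hat),
               c(beta_oracle[1, ], beta_oracle[2, ], beta_oracle[3, ]),
               tolerance = 1e-10)
  resid <- t(rates) - X %*% beta_oracle
  expect_equal(unname(fit$Sigma), unname(t(resid) %*% resid / 1),
               tolerance = 1e-10)

  collinear <- direction_series(rep(0.5, 4))
  expect_error(fit_tuning(rates, collinear), "degenerate design")
  expect_error(fit_tuning(rates[, 1:2], direction_series(theta[1:2])),
               "3 training bins")
})

test_that("residual covariance of independent neurons is near-diagonal", {
  series <- generate_random_pursuit(150, 0.05, seed = 71)
  set.seed(72)
  rates <- noiseless_rates(c(0, pi / 2), 45, 30, series) +
    matrix(rnorm(2 * 3000, 0, 10), 2)
  fit <- fit_tuning(rates, series)
  rho <- fit$Sigma[1, 2] / sqrt(fit$Sigma[1, 1] * fit$Sigma[2, 2])
  expect_lt(abs(rho), 0.05)
})

test_that("PVA decodes exactly with symmetric PDs and noiseless rates", {
  pd <- c(0, pi / 2, pi, -pi / 2)
  train <- even_series(16)
  fit <- fit_tuning(noiseless_rates(pd, 45, 30, train), train)
  thetas <- seq(-3, 3, by = 0.25)
  z <- noiseless_rates(pd, 45, 30, direction_series(thetas))
  res <- decode_pva(fit, z)
  expect_true(all(res$defined))
  expect_equal(res$theta_hat, wrap_angle(thetas), tolerance = 1e-9)

  # all rates at baseline -> zero population vector, flagged undefined
  res0 <- decode_pva(fit, matrix(45, 4, 1))
  expect_false(res0$defined[1])
  expect_true(is.na(res0$theta_hat[1]))

  # single neuron above baseline points at its PD
  fit1 <- fit_tuning(noiseless_rates(0.8, 45, 30, train), train)
  res1 <- decode_pva(fit1, matrix(50, 1, 1))
  expect_equal(res1$theta_hat[1], 0.8, tolerance = 1e-9)
})

test_that("OLE equals the explicit GLS oracle and the pseudoinverse at Sigma = I", {
  # 3-neuron toy with a hand-built covariance
  B <- cbind(c(1, 0, 0.5), c(0, 1, 0.5))
  Sigma <- matrix(c(2, 0.3, 0.1,
                    0.3, 1.5, 0.2,
                    0.1, 0.2, 1.0), 3, 3)
  fit <- structure(
    list(b0_hat = c(1, 2, 3), b1_hat = B[, 1], b2_hat = B[, 2],
         pd_hat = atan2(B[, 2], B[, 1]), B = B,
         Sigma = Sigma, Sigma_cond = Sigma),
    class = "tuning_fit"
  )
  z <- c(2.5, 1.0, 4.2)
  d_oracle <- solve(t(B) %*% solve(Sigma) %*% B) %*%
    t(B) %*% solve(Sigma) %*% (z - c(1, 2, 3))
  expect_equal(drop(decode_ole(fit, z)$d_hat), drop(d_oracle),
               tolerance = 1e-12)

  fit$Sigma_cond <- diag(3)
  d_pinv <- solve(t(B) %*% B) %*% t(B) %*% (z - c(1, 2, 3))
  expect_equal(drop(decode_ole(fit, z)$d_hat), drop(d_pinv), tolerance = 1e-12)

  # uncentered mode
  d_unc <- solve(t(B) %*% B) %*% t(B) %*% z
  expect_equal(drop(decode_ole(fit, z, center = FALSE)$d_hat), drop(d_unc),
               tolerance = 1e-12)
})

test_that("OLE recovers direction exactly from noiseless rates", {
  pd <- c(0.2, 1.1, -2.3, 0.5, 2.9)
  train <- even_series(20)
  fit <- fit_tuning(noiseless_rates(pd, 45, 30, train), train)
  thetas <- seq(-3, 3, by = 0.5)
  res <- decode_ole(fit, noiseless_rates(pd, 45, 30, direction_series(thetas)))
  expect_equal(res$theta_hat, wrap_angle(thetas), tolerance = 1e-8)
})

test_that("KF state model recovers an exact rotation and toy least squares", {
  delta <- 0.21
  series <- direction_series(0.3 + delta * (0:999))
  rates <- noiseless_rates(c(0, 2), 45, 30, series)
  model <- fit_kf(rates, series)
  # counter-clockwise rotation by delta: d_t = R d_{t-1}
  R <- matrix(c(cos(delta), sin(delta), -sin(delta), cos(delta)), 2, 2)
  expect_equal(unname(model$A), R, tolerance = 1e-9)
  expect_lt(max(abs(model$V)), 1e-15)

  # 4-bin toy: A and V from explicit normal equations
  th <- c(0.0, 0.9, -1.4, 2.2)
  s4 <- direction_series(th)
  m4 <- fit_kf(matrix(rpois(8, 5) + 1, 2, 4), s4)
  D <- cbind(cos(th), sin(th))
  D0 <- D[1:3, ]; D1 <- D[2:4, ]
  A_oracle <- t(solve(t(D0) %*% D0) %*% t(D0) %*% D1)
  expect_equal(unname(m4$A), unname(A_oracle), tolerance = 1e-10)
  V_oracle <- crossprod(D1 - D0 %*% t(A_oracle)) / 1
  expect_equal(unname(m4$V), unname(V_oracle), tolerance = 1e-10)
})

test_that("KF observation noise covariance matches injected noise", {
  series <- generate_random_pursuit(150, 0.05, seed = 81)
  set.seed(82)
  rates <- noiseless_rates(c(0, pi / 2, pi), 45, 30, series) +
    matrix(rnorm(3 * 3000, 0, 1), 3)
  model <- fit_kf(rates, series)
  expect_true(all(abs(diag(model$Q) - 1) < 0.1))
})

test_that("kalman_filter reproduces a hand-worked scalar recursion", {
  # 1 neuron, 1-D state, 3 steps, gain-form oracle
  a <- 0.9; v <- 0.2; h <- 1.5; q <- 0.7
  x <- 0.4; p <- 2.0
  z <- c(1.1, -0.3, 0.8)
  oracle <- numeric(3)
  for (t in 1:3) {
    xp <- a * x; pp <- a^2 * p + v
    K <- pp * h / (h^2 * pp + q)
    x <- xp + K * (z[t] - h * xp)
    p <- (1 - K * h) * pp
    oracle[t] <- x
  }
  run <- kalman_filter(matrix(z, 1), matrix(h, 1, 1), matrix(q, 1, 1),
                       matrix(a, 1, 1), matrix(v, 1, 1), 0.4,
                       matrix(2, 1, 1))
  expect_equal(drop(run$states), oracle, tolerance = 1e-12)
})

test_that("KF limits behave as expected", {
  pd <- c(0.1, 1.7, -2.5, 2.0)
  train <- even_series(40)
  rates_train <- noiseless_rates(pd, 45, 30, train)
  model <- fit_kf(rates_train, train)

  # Q -> 0 at fixed state noise: posterior follows the observations
  # (pseudoinverse of H)
  thetas <- seq(-3, 3, by = 0.5)
  z <- noiseless_rates(pd, 45, 30, direction_series(thetas))
  model0 <- model
  model0$Q <- diag(1e-12, 4)
  model0$V <- diag(0.1, 2)
  res <- decode_kf(model0, z)
  expect_equal(res$theta_hat, wrap_angle(thetas), tolerance = 1e-6)

  # V -> 0, A = I: the state freezes
  modelf <- model
  modelf$A <- diag(2)
  modelf$V <- matrix(0, 2, 2)
  set.seed(83)
  zr <- matrix(rnorm(4 * 200, 45, 2), 4, 200)
  resf <- decode_kf(modelf, zr)
  late_step <- sqrt(sum((resf$d_hat[200, ] - resf$d_hat[199, ])^2))
  early_step <- sqrt(sum((resf$d_hat[3, ] - resf$d_hat[2, ])^2))
  expect_lt(late_step, 1e-3)
  expect_lt(late_step, early_step)
})

test_that("posterior covariance trace is non-increasing toward steady state", {
  series <- generate_random_pursuit(60, 0.05, seed = 91)
  halves <- split_train_test(series)
  ens <- ensemble_spec(pd = assign_pds(6, 100, 0), well_tuned = TRUE,
                       b0 = 45, gain = 30, sigma2 = 100, target_snr_dd = NA)
  spikes <- generate_spike_counts(ens, series, seed = 92)
  rates <- spike_rates(spikes)
  model <- fit_kf(rates[, 1:600], halves$train)
  res <- decode_kf(model, rates[, 601:1200])
  expect_true(all(diff(res$P_trace) <= 1e-10))
})

test_that("all decoders achieve sub-degree error on noiseless uniform ensembles", {
  pd <- assign_pds(12, 100, 0.4)
  series <- generate_random_pursuit(300, 0.05, seed = 93)
  halves <- split_train_test(series)
  rates <- noiseless_rates(pd, 45, 30, series)
  r_train <- rates[, 1:3000]; r_test <- rates[, 3001:6000]
  fit <- fit_tuning(r_train, halves$train)
  kf <- fit_kf(r_train, halves$train)
  for (res in list(decode_pva(fit, r_test), decode_ole(fit, r_test),
                   decode_kf(kf, r_test))) {
    expect_lt(rad2deg(mean(decode_ad(res, halves$test))), 1)
  }
})

test_that("decoder models serialize to JSON with explicit shapes", {
  train <- even_series(20)
  rates <- noiseless_rates(c(0.2, 1.4), 45, 30, train)
  fit <- fit_tuning(rates, train)
  kf <- fit_kf(rates, train)
  p1 <- tempfile(fileext = ".json"); p2 <- tempfile(fileext = ".json")
  write_decoder_model(fit, p1)
  write_decoder_model(kf, p2)
  j <- jsonlite::read_json(p1, simplifyVector = TRUE)
  expect_equal(j$type, "tuning")
  expect_equal(j$Sigma$dim, c(2, 2))
  j2 <- jsonlite::read_json(p2, simplifyVector = TRUE)
  expect_equal(j2$A$dim, c(2, 2))
  expect_equal(matrix(j2$H$data, 2, 2, byrow = TRUE), unname(kf$H),
               tolerance = 1e-12)
  unlink(c(p1, p2))

  res <- decode_pva(fit, rates)
  p3 <- tempfile(fileext = ".csv")
  write_decode_result(res, p3)
  df <- read.csv(p3)
  expect_equal(nrow(df), 20)
  expect_true(all(c("dx_hat", "dy_hat", "theta_hat_rad", "defined_flag") %in%
                    names(df)))
  unlink(p3)
})
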