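# State-space builders, filter/smoother correctness, fitting and imputation.

test_that("BSM state-space matrices match the printed s = 4 form", {
  ssm <- bsm_state_space(bsm_spec(4, 0.1, 0.2, 0.3, 0.4))
  expect_identical(ssm$T_mat,
                   rbind(c(1, 1, 0, 0, 0),
                         c(0, 1, 0, 0, 0),
                         c(0, 0, -1, -1, -1),
                         c(0, 0, 1, 0, 0),
                         c(0, 0, 0, 1, 0)))
  expect_identical(ssm$Z, c(1, 0, 1, 0, 0))
  expect_identical(ssm$R_mat,
                   rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                         c(0, 0, 0), c(0, 0, 0)))
  expect_identical(diag(ssm$Q), c(0.1, 0.2, 0.3))
  expect_identical(ssm$H, 0.4)
})

test_that("BSM builder generalizes to other seasonal periods", {
  s2 <- bsm_state_space(bsm_spec(2, 1, 1, 1, 1))
  expect_equal(dim(s2$T_mat), c(3, 3))
  expect_identical(s2$T_mat[3, ], c(0, 0, -1))   # 1x1 seasonal block

  s48 <- bsm_state_space(bsm_spec(48, 1, 1, 1, 1))
  expect_equal(dim(s48$T_mat), c(49, 49))
  expect_identical(s48$T_mat[3, 3:49], rep(-1, 47))
  # seasonal shift block: gamma_{t-j} moves down one row each step
  expect_true(all(s48$T_mat[cbind(4:49, 3:48)] == 1))
  expect_equal(sum(s48$T_mat != 0), 3 + 47 + 46)
  expect_identical(s48$Z, c(1, 0, 1, rep(0, 46)))
  expect_error(bsm_spec(1), "s >= 2")

  # all variances zero: simulation is deterministic
  ssm0 <- bsm_state_space(bsm_spec(4, 0, 0, 0, 0))
  a_init <- c(1, 0.1, 0.5, -0.2, -0.3)
  y1 <- simulate_ssm(ssm0, 20, a_init = a_init, seed = 1)$y
  y2 <- simulate_ssm(ssm0, 20, a_init = a_init, seed = 2)$y
  expect_identical(y1, y2)
})

test_that("ARMA state-space simulation equals the difference recursion", {
  cases <- list(list(ar = 0.7, ma = numeric(0)),
                list(ar = c(0.5, -0.3), ma = 0.4),
                list(ar = numeric(0), ma = 0.6))
  withr::with_seed(31, shocks <- rnorm(500))
  for (cs in cases) {
    sp <- arima_spec(length(cs$ar), 0, length(cs$ma), ar = cs$ar,
                     ma = cs$ma, sigma2 = 1)
    ssm <- arima_state_space(sp)
    sim <- simulate_ssm(ssm, 500, eta = matrix(shocks, 1),
                        eps = numeric(500), a_init = rep(0, ssm$k))
    expect_lt(max(abs(sim$y - arma_recursion(cs$ar, cs$ma, shocks))), 1e-10)
  }
  expect_error(arima_state_space(arima_spec(1, 0, 0, ar = 1.2, sigma2 = 1)),
               "not stationary")
})

test_that("random-walk filter tracks observations exactly when noiseless", {
  rw <- state_space_model(matrix(1), 1, matrix(1), matrix(1), 0,
                          a0 = 0, P0 = matrix(1e7))
  y <- cumsum(rnorm(30))
  kf <- kalman_filter(rw, y)
  expect_equal(as.numeric(kf$a_filt), y, tolerance = 1e-6)
  # ARIMA(0,1,0) with H = 0: smoothing returns the observations (the exactly
  # singular one-step covariance is ridge-stabilized, hence the tolerance)
  sp <- arima_spec(0, 1, 0, sigma2 = 1)
  sm <- suppressWarnings(rts_smooth(arima_state_space(sp), y))
  expect_equal(sm$yhat, y, tolerance = 1e-4)
})

test_that("missing observations skip the update step", {
  withr::with_seed(41, {
    ssm <- random_ssm(3, 2)
    y <- simulate_ssm(ssm, 15, seed = 2)$y
  })
  y[7] <- NA
  kf <- kalman_filter(ssm, y, want_cov = TRUE)
  expect_identical(kf$a_filt[, 7], kf$a_pred[, 7])
  expect_identical(kf$P_filt[, , 7], kf$P_pred[, , 7])
  # setting a value missing and restoring it leaves the loglik unchanged
  y2 <- y; y2[7] <- 5; y3 <- y2; y3[7] <- NA; y3[7] <- y2[7]
  expect_identical(kalman_filter(ssm, y2)$loglik, kalman_filter(ssm, y3)$loglik)
})

test_that("filter loglik and smoothed moments match the joint-Gaussian oracle", {
  withr::with_seed(52, {
    for (rep in 1:8) {
      ssm <- random_ssm()
      n <- sample(8:20, 1)
      y <- simulate_ssm(ssm, n, seed = rep)$y
      y[rbinom(n, 1, 0.3) == 1] <- NA
      if (all(is.na(y))) y[1] <- 0
      or <- joint_gaussian_oracle(ssm, y)
      sm <- rts_smooth(ssm, y, want_cov = TRUE)
      expect_lt(max(abs(sm$a_smooth - or$a_smooth)), 1e-8)
      expect_lt(abs(sm$loglik - or$loglik), 1e-8)
      # smoothing cannot increase variance; boundary identity at t = n
      kf <- kalman_filter(ssm, y, want_cov = TRUE)
      for (t in seq_len(n)) {
        expect_true(all(diag(sm$P_smooth[, , t]) <=
                          diag(kf$P_filt[, , t]) + 1e-10))
      }
      expect_equal(sm$a_smooth[, n], kf$a_filt[, n], tolerance = 1e-12)
    }
  })
})

test_that("ML fitting recovers local-level variances and is deterministic", {
  spec_true <- bsm_spec(2, var_level = 0.5, var_slope = 0,
                        var_seasonal = 0, var_obs = 1)
  ssm <- bsm_state_space(spec_true)
  y <- simulate_ssm(ssm, 3000, a_init = c(10, 0, 0), seed = 77)$y
  fit <- suppressWarnings(
    fit_ssm(y, bsm_spec(2, var_slope = 0, var_seasonal = 0)))
  expect_lt(abs(fit$spec$var_level - 0.5), 0.2 * 0.5)
  expect_lt(abs(fit$spec$var_obs - 1), 0.2)
  # the fitted likelihood is at least the truth's
  expect_gte(fit$loglik + 1e-6, gapfillr:::ssm_loglik(spec_true, y))
  refit <- suppressWarnings(
    fit_ssm(y, bsm_spec(2, var_slope = 0, var_seasonal = 0)))
  expect_identical(tidy(fit), tidy(refit))
})

test_that("imputation preserves observations, beats mean fill, forecasts at the end", {
  cfg <- weather_config(n_days = 14, annual_amplitude = 0, ar1_sd = 0.3,
                        obs_noise_sd = 0.1, seed = 13)
  y <- simulate_temperature(cfg)$machine
  s <- regular_series(y)

  # no missing values: output equals input
  imp0 <- impute_kalman(s, bsm_spec(48, 1e-3, 1e-6, 1e-4, 0.01))
  expect_identical(imp0$imputed, s$value)

  # 2-day interior gap: smoother beats filling with the training mean
  y2 <- y
  gap_idx <- (3 * 48 + 1):(5 * 48)
  y2[gap_idx] <- NA
  imp <- impute_kalman(regular_series(y2), bsm_spec(48))
  expect_identical(imp$imputed[-gap_idx], y[-gap_idx])
  rmse_kalman <- sqrt(mean((imp$imputed[gap_idx] - y[gap_idx])^2))
  rmse_mean <- sqrt(mean((mean(y2, na.rm = TRUE) - y[gap_idx])^2))
  expect_lt(rmse_kalman, rmse_mean)

  # gap at the series end: smoothed values equal the filter forecasts
  y3 <- y[1:(13 * 48)]
  y3[(12 * 48 + 1):length(y3)] <- NA
  fit <- suppressWarnings(fit_ssm(y3, bsm_spec(48)))
  sm <- rts_smooth(fit$ssm, y3)
  kf <- kalman_filter(fit$ssm, y3)
  tail_idx <- (12 * 48 + 1):length(y3)
  expect_equal(sm$yhat[tail_idx], kf$yhat_filt[tail_idx], tolerance = 1e-8)
})

test_that("short gaps are prefilled locally; long gaps and observations untouched", {
  cfg <- weather_config(n_days = 30, annual_amplitude = 0, ar1_sd = 0.2,
                        obs_noise_sd = 0.05, seed = 23)
  sim <- simulate_temperature(cfg)
  y <- sim$machine
  y[300] <- NA                              # single missing slot
  y[(20 * 48 + 1):(23 * 48)] <- NA          # 3-day gap > max_gap
  s <- regular_series(y)
  out <- prefill_short_gaps(s, max_gap = 48)
  expect_false(is.na(out$value[300]))
  expect_true(all(is.na(out$value[(20 * 48 + 1):(23 * 48)])))
  obs_idx <- which(!is.na(y))
  expect_identical(out$value[obs_idx], y[obs_idx])
  # the filled slot lies between its neighbours (smooth local signal)
  lo <- min(out$value[c(299, 301)]) - 0.25
  hi <- max(out$value[c(299, 301)]) + 0.25
  expect_gte(out$value[300], lo)
  expect_lte(out$value[300], hi)
  # no-op when nothing is missing
  s_full <- regular_series(sim$machine)
  expect_identical(prefill_short_gaps(s_full)$value, sim$machine)
})

test_that("AIC order selection returns a usable ARIMA fit", {
  withr::with_seed(61, y <- as.numeric(arima.sim(list(ar = c(0.6, 0.2)), 600)))
  best <- select_arima(y, p_max = 2, d_max = 0, q_max = 1)
  expect_s3_class(best, "ssm_fit")
  tab <- attr(best, "aic_table")
  expect_equal(nrow(tab), 3 * 1 * 2)
  expect_equal(min(tab$aic, na.rm = TRUE), best$aic)
  expect_gte(best$spec$p + best$spec$q, 1)
})
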