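# Linear-Gaussian state-space models: basic structural (level + slope +
# seasonal) and ARIMA forms, Kalman filtering and RTS smoothing with missing
# observations, maximum-likelihood fitting by prediction-error decomposition,
# and smoothing-based imputation.

DIFFUSE_KAPPA <- 1e7

#' Construct a time-invariant linear-Gaussian state-space model
#'
#' State evolution `a_t = T a_{t-1} + R eta_t`, `eta ~ N(0, Q)`; observation
#' `y_t = Z a_t + eps_t`, `eps ~ N(0, H)`. `a0`/`P0` are the prior mean and
#' covariance of the state at the first time point (diffuse `kappa * I` by
#' default).
#'
#' @param T_mat k x k state-transition matrix.
#' @param Z Length-k observation vector.
#' @param R_mat k x q noise-driving matrix.
#' @param Q q x q state-noise covariance.
#' @param H Observation-noise variance (scalar, >= 0).
#' @param a0,P0 Initial state mean / covariance (defaults: 0, `1e7 * I`).
#' @return An object of class `state_space_model`.
#' @export
state_space_model <- function(T_mat, Z, R_mat, Q, H, a0 = NULL, P0 = NULL) {
  T_mat <- as.matrix(T_mat)
  k <- nrow(T_mat)
  Z <- as.numeric(Z)
  R_mat <- as.matrix(R_mat)
  Q <- as.matrix(Q)
  stopifnot(ncol(T_mat) == k, length(Z) == k, nrow(R_mat) == k,
            ncol(R_mat) == nrow(Q), nrow(Q) == ncol(Q), H >= 0)
  if (any(!is.finite(T_mat)) || any(!is.finite(Q)) || !is.finite(H)) {
    abort("state-space matrices must be finite")
  }
  if (is.null(a0)) a0 <- numeric(k)
  if (is.null(P0)) P0 <- diag(DIFFUSE_KAPPA, k)
  structure(list(T_mat = T_mat, Z = Z, R_mat = R_mat, Q = Q, H = H,
                 a0 = as.numeric(a0), P0 = as.matrix(P0), k = k),
            class = "state_space_model")
}

#' @export
print.state_space_model <- function(x, ...) {
  cat(sprintf("<state_space_model> state dim %d, %d shock(s), H = %.4g\n",
              x$k, ncol(x$R_mat), x$H))
  invisible(x)
}

#' Basic structural model specification
#'
#' Local linear trend (level + slope) plus a dummy-seasonal component with
#' period `s`: the seasonal effects over any `s` consecutive steps sum to a
#' zero-mean disturbance. `NA` variances are treated as free parameters by
#' [fit_ssm()].
#'
#' @param s Seasonal period (>= 2); 48 is the daily cycle of a half-hourly
#'   series.
#' @param var_level,var_slope,var_seasonal,var_obs Disturbance variances of
#'   the level, slope, seasonal and observation equations.
#' @return An object of class `bsm_spec`.
#' @export
bsm_spec <- function(s = 48L, var_level = NA, var_slope = NA,
                     var_seasonal = NA, var_obs = NA) {
  stopifnot(s >= 2)
  vars <- c(var_level, var_slope, var_seasonal, var_obs)
  if (any(!is.na(vars) & vars < 0)) abort("variances must be nonnegative")
  structure(list(s = as.integer(s), var_level = var_level,
                 var_slope = var_slope, var_seasonal = var_seasonal,
                 var_obs = var_obs),
            class = "bsm_spec")
}

#' @export
print.bsm_spec <- function(x, ...) {
  cat(sprintf(
    "<bsm_spec> period %d; variances level %s, slope %s, seasonal %s, obs %s\n",
    x$s, format(x$var_level), format(x$var_slope), format(x$var_seasonal),
    format(x$var_obs)))
  invisible(x)
}

#' Build the state-space form of a basic structural model
#'
#' State is `(mu, beta, gamma_1, ..., gamma_{s-1})`, dimension `2 + (s - 1)`.
#' The level/slope block is `[[1, 1], [0, 1]]`; the seasonal block has -1
#' across its first row and a shifted identity below; `Z = (1, 0, 1, 0, ...)`
#' and `R` selects the level, slope and seasonal shocks.
#'
#' @param spec A [bsm_spec()] with all variances set (non-`NA`).
#' @return A `state_space_model`.
#' @export
bsm_state_space <- function(spec) {
  stopifnot(inherits(spec, "bsm_spec"))
  vars <- c(spec$var_level, spec$var_slope, spec$var_seasonal, spec$var_obs)
  if (anyNA(vars)) abort("all variances must be set; use fit_ssm() to estimate")
  s <- spec$s
  k <- 2L + (s - 1L)
  T_mat <- matrix(0, k, k)
  T_mat[1, 1] <- 1; T_mat[1, 2] <- 1; T_mat[2, 2] <- 1
  T_mat[3, 2 + seq_len(s - 1L)] <- -1
  if (s > 2) {
    for (j in seq_len(s - 2L)) T_mat[3 + j, 2 + j] <- 1
  }
  Z <- numeric(k); Z[1] <- 1; Z[3] <- 1
  R_mat <- matrix(0, k, 3)
  R_mat[1, 1] <- 1; R_mat[2, 2] <- 1; R_mat[3, 3] <- 1
  Q <- diag(c(spec$var_level, spec$var_slope, spec$var_seasonal), 3)
  state_space_model(T_mat, Z, R_mat, Q, spec$var_obs)
}

#' ARIMA model specification
#'
#' @param p,d,q Autoregressive, differencing and moving-average orders.
#' @param ar,ma Coefficient vectors (`NULL` = free, estimated by
#'   [fit_ssm()]).
#' @param sigma2 Innovation variance (`NA` = free).
#' @param mu Series mean subtracted before modelling when `d = 0`
#'   (`NA` = use the observed mean).
#' @return An object of class `arima_spec`.
#' @export
arima_spec <- function(p = 1L, d = 0L, q = 0L, ar = NULL, ma = NULL,
                       sigma2 = NA, mu = NA) {
  stopifnot(p >= 0, d >= 0, q >= 0)
  if (!is.null(ar)) stopifnot(length(ar) == p)
  if (!is.null(ma)) stopifnot(length(ma) == q)
  structure(list(p = as.integer(p), d = as.integer(d), q = as.integer(q),
                 ar = ar, ma = ma, sigma2 = sigma2, mu = mu),
            class = "arima_spec")
}

#' @export
print.arima_spec <- function(x, ...) {
  cat(sprintf("<arima_spec> ARIMA(%d,%d,%d), sigma2 = %s\n",
              x$p, x$d, x$q, format(x$sigma2)))
  invisible(x)
}

ar_stationary <- function(ar) {
  length(ar) == 0 || all(Mod(polyroot(c(1, -ar))) > 1 + 1e-8)
}

#' Build the state-space (Harvey companion) form of an ARIMA model
#'
#' The ARMA(p, q) core uses the companion form with state dimension
#' `max(p, q + 1)`; each order of differencing adds one integration state on
#' top. Stationary initialization is used for the ARMA block (`d = 0`);
#' integration states get a diffuse prior.
#'
#' @param spec An [arima_spec()] with coefficients and `sigma2` set.
#' @return A `state_space_model`.
#' @export
arima_state_space <- function(spec) {
  stopifnot(inherits(spec, "arima_spec"))
  ar <- spec$ar %||% numeric(0)
  ma <- spec$ma %||% numeric(0)
  if (length(ar) != spec$p || length(ma) != spec$q || is.na(spec$sigma2)) {
    abort("coefficients and sigma2 must be set; use fit_ssm() to estimate")
  }
  if (!ar_stationary(ar)) abort("AR polynomial is not stationary")
  r <- max(spec$p, spec$q + 1L)
  phi <- c(ar, numeric(r - spec$p))
  theta <- c(ma, numeric(r - 1L - spec$q))
  T_a <- matrix(0, r, r)
  T_a[, 1] <- phi
  if (r > 1) T_a[seq_len(r - 1L), 1L + seq_len(r - 1L)] <- diag(r - 1L)
  R_a <- matrix(c(1, theta), ncol = 1)
  Z_a <- c(1, numeric(r - 1L))
  Q <- matrix(spec$sigma2, 1, 1)
  # stationary prior for the ARMA block
  RQR <- R_a %*% Q %*% t(R_a)
  P_a <- matrix(solve(diag(r * r) - kronecker(T_a, T_a), as.numeric(RQR)), r, r)
  T_mat <- T_a; R_mat <- R_a; Z <- Z_a; P0 <- P_a
  for (i in seq_len(spec$d)) {       # add one integration level per d
    k <- nrow(T_mat)
    T_new <- rbind(c(1, as.numeric(Z %*% T_mat)),
                   cbind(0, T_mat))
    R_new <- rbind(as.numeric(Z %*% R_mat), R_mat)
    Z <- c(1, numeric(k))
    P0 <- rbind(0, cbind(0, P0))
    P0[1, 1] <- DIFFUSE_KAPPA
    T_mat <- T_new; R_mat <- R_new
  }
  state_space_model(T_mat, Z, R_mat, Q, 0, a0 = numeric(nrow(T_mat)),
                    P0 = P0)
}

as_y_vector <- function(y) {
  if (is.data.frame(y)) y <- y$value
  y <- as.numeric(y)
  bad <- !is.na(y) & !is.finite(y)
  if (any(bad)) abort("observations must be finite or NA")
  y
}

#' Kalman filter with missing observations
#'
#' Standard predict/update recursion; at a missing time point the update is
#' skipped (filtered = predicted) and no likelihood is accumulated.
#'
#' @param ssm A `state_space_model`.
#' @param y Numeric vector or series tibble; `NA` = missing.
#' @param want_cov Keep the full filtered/predicted covariance cubes
#'   (memory-heavy; intended for short series).
#' @return A list of class `kalman_filter_result`: `loglik`, filtered and
#'   predicted state means (columns = time), one-step observation mean and
#'   variance, innovations, and the input `y`.
#' @export
kalman_filter <- function(ssm, y, want_cov = FALSE) {
  stopifnot(inherits(ssm, "state_space_model"))
  yv <- as_y_vector(y)
  out <- cpp_kalman_filter(ssm$T_mat, matrix(ssm$Z, 1), ssm$R_mat, ssm$Q,
                           ssm$H, ssm$a0, ssm$P0, yv, want_cov)
  for (nm in c("yhat_filt", "yvar_filt", "innov", "innov_var")) {
    out[[nm]] <- as.numeric(out[[nm]])
  }
  out$y <- yv
  out$ssm <- ssm
  class(out) <- "kalman_filter_result"
  out
}

#' Rauch-Tung-Striebel smoother
#'
#' Backward recursion conditioning every state on the full observation set.
#' Accepts either the raw observations or a [kalman_filter()] result (whose
#' stored observations are reused; the forward pass is recomputed
#' internally).
#'
#' @param ssm A `state_space_model`.
#' @param y Observations (vector / series tibble) or a
#'   `kalman_filter_result`.
#' @param want_cov Keep the full smoothed covariance cube (short series
#'   only).
#' @return A list of class `kalman_smooth_result`: `loglik`, smoothed state
#'   means `a_smooth`, smoothed observation mean `yhat` and variance `yvar`
#'   (`Z P Z' + H`), filtered/predicted means.
#' @export
rts_smooth <- function(ssm, y, want_cov = FALSE) {
  stopifnot(inherits(ssm, "state_space_model"))
  if (inherits(y, "kalman_filter_result")) y <- y$y
  yv <- as_y_vector(y)
  out <- cpp_kalman_smooth(ssm$T_mat, matrix(ssm$Z, 1), ssm$R_mat, ssm$Q,
                           ssm$H, ssm$a0, ssm$P0, yv, want_cov)
  out$yhat <- as.numeric(out$yhat)
  out$yvar <- as.numeric(out$yvar)
  out$y <- yv
  out$ssm <- ssm
  class(out) <- "kalman_smooth_result"
  out
}

#' @rdname rts_smooth
#' @export
kalman_smooth <- rts_smooth

#' Simulate from a state-space model
#'
#' Deterministic given the shock matrix: `a_t = T a_{t-1} + R eta_t` from
#' `a_init`, `y_t = Z a_t + eps_t`.
#'
#' @param ssm A `state_space_model`.
#' @param n Series length (ignored when `eta` is given).
#' @param eta Optional q x n shock matrix (drawn from `Q` if `NULL`).
#' @param eps Optional observation-noise vector (drawn from `H` if `NULL`).
#' @param a_init Initial state (default `a0`).
#' @param seed RNG seed used when shocks are drawn.
#' @return A list with `y` and the state path `alpha`.
#' @export
simulate_ssm <- function(ssm, n, eta = NULL, eps = NULL, a_init = NULL,
                         seed = 1L) {
  stopifnot(inherits(ssm, "state_space_model"))
  q <- ncol(ssm$R_mat)
  if (is.null(eta) || is.null(eps)) {
    withr::with_seed(seed, {
      if (is.null(eta)) {
        # eigen square root: exact zeros for zero-variance components
        eg <- eigen(ssm$Q, symmetric = TRUE)
        rt <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), q) %*%
          t(eg$vectors)
        eta <- rt %*% matrix(rnorm(q * n), q, n)
      }
      if (is.null(eps)) eps <- rnorm(n, 0, sqrt(ssm$H))
    })
  }
  n <- length(eps)
  stopifnot(ncol(eta) == n)
  cpp_simulate_ssm(ssm$T_mat, matrix(ssm$Z, 1), ssm$R_mat, as.matrix(eta),
                   as.numeric(eps), a_init %||% ssm$a0)
}

# ---------------------------------------------------------------- fitting

has_free_params <- function(spec) {
  if (inherits(spec, "bsm_spec")) {
    anyNA(c(spec$var_level, spec$var_slope, spec$var_seasonal, spec$var_obs))
  } else if (inherits(spec, "arima_spec")) {
    (is.null(spec$ar) && spec$p > 0) || (is.null(spec$ma) && spec$q > 0) ||
      is.na(spec$sigma2)
  } else {
    FALSE
  }
}

build_ssm <- function(spec) {
  if (inherits(spec, "bsm_spec")) bsm_state_space(spec)
  else if (inherits(spec, "arima_spec")) arima_state_space(spec)
  else if (inherits(spec, "state_space_model")) spec
  else abort("spec must be a bsm_spec, arima_spec or state_space_model")
}

# Monahan transform: unconstrained reals -> stationary AR (or invertible MA)
# coefficients, via partial autocorrelations in (-1, 1).
pacf_to_coef <- function(u) {
  r <- tanh(u)
  p <- length(r)
  if (p == 0) return(numeric(0))
  phi <- r[1]
  if (p > 1) {
    for (k in 2:p) {
      phi <- c(phi - r[k] * rev(phi), r[k])
    }
  }
  phi
}

ssm_loglik <- function(spec, yv) {
  ssm <- build_ssm(spec)
  out <- cpp_kalman_filter(ssm$T_mat, matrix(ssm$Z, 1), ssm$R_mat, ssm$Q,
                           ssm$H, ssm$a0, ssm$P0, yv, FALSE)
  out$loglik
}

fit_ssm_bsm <- function(yv, spec) {
  free <- c(level = is.na(spec$var_level), slope = is.na(spec$var_slope),
            seasonal = is.na(spec$var_seasonal), obs = is.na(spec$var_obs))
  vy <- var(yv, na.rm = TRUE)
  if (!is.finite(vy) || vy <= 0) vy <- 1
  # fixed starting values, as fractions of the sample variance
  start_frac <- c(level = 1e-2, slope = 1e-7, seasonal = 1e-5, obs = 0.25)
  fill <- function(theta) {
    v <- c(spec$var_level, spec$var_slope, spec$var_seasonal, spec$var_obs)
    v[free] <- vy * exp(theta)
    bsm_spec(spec$s, v[1], v[2], v[3], v[4])
  }
  nll <- function(theta) {
    sp <- fill(theta)
    -ssm_loglik(sp, yv)
  }
  theta0 <- log(start_frac[free])
  opt <- optim(theta0, nll, method = "L-BFGS-B", lower = -25, upper = 8,
               control = list(maxit = 200))
  sp <- fill(opt$par)
  list(spec = sp, loglik = -opt$value, npar = sum(free),
       convergence = opt$convergence, message = opt$message)
}

fit_ssm_arima <- function(yv, spec) {
  p <- spec$p; d <- spec$d; q <- spec$q
  mu <- spec$mu
  if (d == 0) {
    if (is.na(mu)) mu <- mean(yv, na.rm = TRUE)
  } else mu <- 0
  yc <- yv - mu
  dy <- diff(yv, differences = max(1, d))
  s2_0 <- var(dy, na.rm = TRUE)
  if (!is.finite(s2_0) || s2_0 <= 0) s2_0 <- var(yv, na.rm = TRUE)
  if (!is.finite(s2_0) || s2_0 <= 0) s2_0 <- 1
  free_ar <- is.null(spec$ar) & p > 0
  free_ma <- is.null(spec$ma) & q > 0
  free_s2 <- is.na(spec$sigma2)
  fill <- function(theta) {
    i <- 0
    ar <- spec$ar
    if (free_ar) { ar <- pacf_to_coef(theta[i + seq_len(p)]); i <- i + p }
    ma <- spec$ma
    # invertibility region is the sign-reflection of the AR stationary region
    if (free_ma) { ma <- -pacf_to_coef(theta[i + seq_len(q)]); i <- i + q }
    s2 <- if (free_s2) s2_0 * exp(theta[i + 1]) else spec$sigma2
    arima_spec(p, d, q, ar = ar %||% numeric(0), ma = ma %||% numeric(0),
               sigma2 = s2, mu = mu)
  }
  nll <- function(theta) {
    sp <- fill(theta)
    ll <- tryCatch(ssm_loglik(sp, yc), error = function(e) -Inf)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  nfree <- p * free_ar + q * free_ma + free_s2
  if (nfree == 0) {
    sp <- fill(numeric(0))
    return(list(spec = sp, loglik = ssm_loglik(sp, yc), npar = 0,
                convergence = 0, message = NULL, mu = mu))
  }
  theta0 <- numeric(nfree)
  opt <- optim(theta0, nll, method = "BFGS", control = list(maxit = 300))
  sp <- fill(opt$par)
  list(spec = sp, loglik = -opt$value,
       npar = nfree + (d == 0 && is.na(spec$mu)),
       convergence = opt$convergence, message = opt$message, mu = mu)
}

#' Fit a state-space model by maximum likelihood
#'
#' Gaussian likelihood via the prediction-error decomposition of the Kalman
#' filter; free parameters (`NA` variances of a [bsm_spec()], `NULL`/`NA`
#' coefficients of an [arima_spec()]) are optimized by quasi-Newton on
#' transformed scales (log variances; partial-autocorrelation transform for
#' AR/MA stationarity and invertibility). Deterministic given the data:
#' starting values are fixed.
#'
#' @param y Observations (vector or series tibble), `NA` = missing.
#' @param spec A [bsm_spec()] or [arima_spec()] with free parameters.
#' @return An object of class `ssm_fit`: filled `spec`, the built `ssm`,
#'   `loglik`, `aic`, optimizer `convergence` (0 = converged), and for ARIMA
#'   the centring mean `mu`.
#' @export
fit_ssm <- function(y, spec) {
  yv <- as_y_vector(y)
  n_obs <- sum(!is.na(yv))
  k_dim <- if (inherits(spec, "bsm_spec")) 2 + spec$s - 1 else
    max(spec$p, spec$q + 1) + spec$d
  if (n_obs <= 10 * k_dim) {
    abort(sprintf("need more than %d observed points to fit (got %d)",
                  10 * k_dim, n_obs))
  }
  res <- if (inherits(spec, "bsm_spec")) fit_ssm_bsm(yv, spec)
         else if (inherits(spec, "arima_spec")) fit_ssm_arima(yv, spec)
         else abort("spec must be a bsm_spec or arima_spec")
  if (res$convergence != 0) {
    warn(sprintf("optimizer did not fully converge (code %d%s)",
                 res$convergence,
                 if (!is.null(res$message) && nzchar(res$message %||% ""))
                   paste0(": ", res$message) else ""))
  }
  structure(
    list(spec = res$spec, ssm = build_ssm(res$spec), loglik = res$loglik,
         aic = -2 * res$loglik + 2 * res$npar, npar = res$npar,
         convergence = res$convergence, mu = res$mu %||% 0,
         n_obs = n_obs),
    class = "ssm_fit")
}

#' @export
print.ssm_fit <- function(x, ...) {
  cat(sprintf("<ssm_fit> loglik %.2f, AIC %.2f, %d free parameter(s)%s\n",
              x$loglik, x$aic, x$npar,
              if (x$convergence == 0) "" else " [not converged]"))
  print(x$spec)
  invisible(x)
}

#' @rdname fit_ssm
#' @param x An `ssm_fit`.
#' @param ... Unused.
#' @method tidy ssm_fit
#' @export
tidy.ssm_fit <- function(x, ...) {
  sp <- x$spec
  if (inherits(sp, "bsm_spec")) {
    tibble(term = c("var_level", "var_slope", "var_seasonal", "var_obs"),
           estimate = c(sp$var_level, sp$var_slope, sp$var_seasonal,
                        sp$var_obs))
  } else {
    tibble(term = c(sprintf("ar%d", seq_len(sp$p)),
                    sprintf("ma%d", seq_len(sp$q)), "sigma2", "mu"),
           estimate = c(sp$ar, sp$ma, sp$sigma2, x$mu))
  }
}

#' @rdname fit_ssm
#' @method glance ssm_fit
#' @export
glance.ssm_fit <- function(x, ...) {
  tibble(loglik = x$loglik, aic = x$aic, npar = x$npar,
         converged = x$convergence == 0, n_obs = x$n_obs)
}

#' Select an ARIMA order by AIC over a small grid
#'
#' Fits every `(p, d, q)` with `p <= p_max`, `d <= d_max`, `q <= q_max` by
#' [fit_ssm()] and keeps the lowest-AIC fit. Failed fits are skipped.
#'
#' @param y Observations.
#' @param p_max,d_max,q_max Grid bounds (defaults 3, 1, 3).
#' @return The best `ssm_fit`, with the AIC table in attribute
#'   `"aic_table"`.
#' @export
select_arima <- function(y, p_max = 3L, d_max = 1L, q_max = 3L) {
  yv <- as_y_vector(y)
  grid <- expand.grid(p = 0:p_max, d = 0:d_max, q = 0:q_max)
  fits <- purrr::pmap(grid, function(p, d, q) {
    tryCatch(suppressWarnings(fit_ssm(yv, arima_spec(p, d, q))),
             error = function(e) NULL)
  })
  aics <- purrr::map_dbl(fits, ~ if (is.null(.x)) NA_real_ else .x$aic)
  tab <- tibble(p = grid$p, d = grid$d, q = grid$q, aic = aics)
  if (all(is.na(aics))) abort("no ARIMA model could be fitted")
  best <- fits[[which.min(aics)]]
  attr(best, "aic_table") <- tab
  best
}

#' Impute missing values by Kalman smoothing
#'
#' Fits the requested state-space family to the observed values (unless a
#' ready `ssm_fit` is supplied), runs the RTS smoother, and fills every
#' missing position with the smoothed observation estimate `Z a_{t|n}`;
#' observed positions are returned bit-identical. The per-position standard
#' deviation `sqrt(Z P_{t|n} Z' + H)` is reported.
#'
#' @param series Series tibble (or numeric vector) with `NA` gaps.
#' @param spec A [bsm_spec()] (default: daily-seasonal BSM with free
#'   variances), an [arima_spec()], the string `"arima-auto"` for AIC order
#'   selection, or an already fitted `ssm_fit`.
#' @return A tibble `timestamp`, `value` (original), `imputed` (filled),
#'   `sd`, `provenance` (`"observed"`/`"imputed"`), with the `ssm_fit` in
#'   attribute `"fit"`. Class `gf_imputation`.
#' @export
impute_kalman <- function(series, spec = bsm_spec(48)) {
  if (is.numeric(series)) series <- regular_series(series)
  yv <- as_y_vector(series)
  fit <- if (inherits(spec, "ssm_fit")) {
    spec
  } else if (identical(spec, "arima-auto")) {
    select_arima(yv)
  } else if (!has_free_params(spec)) {
    # fully specified model: smooth directly, no ML step
    mu0 <- if (inherits(spec, "arima_spec") && !is.na(spec$mu)) spec$mu else 0
    list(spec = spec, ssm = build_ssm(spec), loglik = NA_real_, mu = mu0)
  } else {
    fit_ssm(yv, spec)
  }
  mu <- fit$mu %||% 0
  sm <- rts_smooth(fit$ssm, yv - mu)
  filled <- ifelse(is.na(yv), sm$yhat + mu, yv)
  out <- tibble(
    timestamp = series$timestamp %||%
      regular_series(yv)$timestamp,
    value = yv,
    imputed = filled,
    sd = sqrt(pmax(sm$yvar, 0)),
    provenance = ifelse(is.na(yv), "imputed", "observed"))
  structure(out, class = c("gf_imputation", class(out)), fit = fit)
}

#' Prefill short gaps by local Kalman smoothing
#'
#' Runs of missing values no longer than `max_gap` slots are replaced by
#' smoothed estimates computed on a local window around each run (`pad_days`
#' days each side); longer gaps are left untouched and observed values are
#' never altered. Model variances are fitted once on the longest observed
#' stretch (capped at `fit_days` days) and reused for every gap.
#'
#' @param series Series tibble with `NA` gaps.
#' @param max_gap Longest run (in slots) that is filled (default 48 = one
#'   day).
#' @param spec State-space family used for smoothing (default daily-seasonal
#'   BSM).
#' @param pad_days Context on each side of a run used for smoothing.
#' @param fit_days Maximum days of data used for variance fitting.
#' @return The series with short gaps filled and a `mask` column reflecting
#'   the *original* observation pattern.
#' @export
prefill_short_gaps <- function(series, max_gap = 48L, spec = bsm_spec(48),
                               pad_days = 3L, fit_days = 30L) {
  series <- build_mask(series)
  yv <- series$value
  na_runs <- rle(is.na(yv))
  if (!any(na_runs$values)) return(series)
  ends <- cumsum(na_runs$lengths)
  starts <- ends - na_runs$lengths + 1L
  short <- which(na_runs$values & na_runs$lengths <= max_gap)
  if (length(short) == 0) return(series)

  spd <- series_slots_per_day(series)
  # fit once on the longest observed stretch
  obs_runs <- which(!na_runs$values)
  longest <- obs_runs[which.max(na_runs$lengths[obs_runs])]
  fs <- starts[longest]
  fe <- min(ends[longest], fs + fit_days * spd - 1L)
  fit <- suppressWarnings(fit_ssm(yv[fs:fe], spec))

  pad <- pad_days * spd
  for (r in short) {
    lo <- max(1L, starts[r] - pad)
    hi <- min(length(yv), ends[r] + pad)
    mu <- fit$mu %||% 0
    sm <- rts_smooth(fit$ssm, yv[lo:hi] - mu)
    idx <- starts[r]:ends[r]
    series$value[idx] <- sm$yhat[idx - lo + 1L] + mu
  }
  series
}
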