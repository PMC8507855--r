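# Independent oracles used across tests.

# Brute-force joint-Gaussian oracle for a time-invariant linear-Gaussian
# state-space model: builds the full covariance of the stacked states and
# observations, then conditions on the observed entries directly. Independent
# of the package's filter/smoother code path.
joint_gaussian_oracle <- function(ssm, y) {
  k <- ssm$k
  n <- length(y)
  A <- ssm$T_mat
  RQR <- ssm$R_mat %*% ssm$Q %*% t(ssm$R_mat)
  mu_a <- matrix(0, k, n)
  mu_a[, 1] <- ssm$a0
  Pt <- array(0, c(k, k, n))
  Pt[, , 1] <- ssm$P0
  for (t in seq_len(n)[-1]) {
    mu_a[, t] <- A %*% mu_a[, t - 1]
    Pt[, , t] <- A %*% Pt[, , t - 1] %*% t(A) + RQR
  }
  bigC <- matrix(0, k * n, k * n)
  for (t in seq_len(n)) {
    blk <- Pt[, , t]
    bigC[(t - 1) * k + 1:k, (t - 1) * k + 1:k] <- blk
    if (t < n) {
      for (u in (t + 1):n) {
        blk <- blk %*% t(A)
        bigC[(t - 1) * k + 1:k, (u - 1) * k + 1:k] <- blk
        bigC[(u - 1) * k + 1:k, (t - 1) * k + 1:k] <- t(blk)
      }
    }
  }
  Zbig <- matrix(0, n, k * n)
  for (t in seq_len(n)) Zbig[t, (t - 1) * k + 1:k] <- ssm$Z
  mu_y <- as.numeric(Zbig %*% as.numeric(mu_a))
  Sy <- Zbig %*% bigC %*% t(Zbig) + diag(ssm$H, n)
  obs <- which(!is.na(y))
  Cay <- bigC %*% t(Zbig)
  resid <- y[obs] - mu_y[obs]
  Syo <- Sy[obs, obs, drop = FALSE]
  cond_mean_states <- as.numeric(mu_a) +
    as.numeric(Cay[, obs, drop = FALSE] %*% solve(Syo, resid))
  loglik <- -0.5 * (length(obs) * log(2 * pi) +
                      as.numeric(determinant(Syo)$modulus) +
                      as.numeric(crossprod(resid, solve(Syo, resid))))
  list(a_smooth = matrix(cond_mean_states, k, n), loglik = loglik)
}

# random stable time-invariant state-space model (state dim <= 5)
random_ssm <- function(k = sample(1:5, 1), q = sample(1:2, 1)) {
  A <- matrix(rnorm(k * k), k)
  A <- A / (max(Mod(eigen(A, only.values = TRUE)$values)) + 0.4)
  Z <- rnorm(k)
  R <- matrix(rnorm(k * q), k, q)
  Q <- crossprod(matrix(rnorm(q * q), q)) + diag(0.1, q)
  H <- runif(1, 0.05, 1)
  P0 <- crossprod(matrix(rnorm(k * k), k)) + diag(0.3, k)
  a0 <- rnorm(k)
  state_space_model(A, Z, R, Q, H, a0, P0)
}

# ARMA difference-equation recursion with explicit shocks (zero presample)
arma_recursion <- function(ar, ma, shocks) {
  n <- length(shocks)
  p <- length(ar); q <- length(ma)
  x <- numeric(n)
  for (t in seq_len(n)) {
    v <- shocks[t]
    if (p > 0) for (i in seq_len(p)) if (t - i >= 1) v <- v + ar[i] * x[t - i]
    if (q > 0) for (j in seq_len(q)) if (t - j >= 1) v <- v + ma[j] * shocks[t - j]
    x[t] <- v
  }
  x
}

# a small random training window for network tests
random_window <- function(w = 4, nf = 5, obs_frac = 0.6, score_frac = 0.5,
                          mu = 10, sd_ = 3) {
  tgt <- matrix(rnorm(w * nf, mu, sd_), w, nf)
  im <- matrix(rbinom(w * nf, 1, obs_frac), w, nf)
  lm_ <- matrix(rbinom(w * nf, 1, score_frac), w, nf) * (1 - im)
  if (sum(lm_) == 0) lm_[which(im == 0)[1]] <- 1
  inp <- tgt
  inp[im == 0] <- NA
  gapfillr:::new_window_sample(inp, im, tgt, lm_)
}

# central finite-difference gradient of a scalar function of a parameter list
fd_grads <- function(fun, params, eps = 1e-5) {
  out <- params
  for (nm in names(params)) {
    p <- params[[nm]]
    g <- p * 0
    for (i in seq_along(p)) {
      pp <- params
      pp[[nm]][i] <- p[i] + eps
      fp <- fun(pp)
      pp[[nm]][i] <- p[i] - eps
      fm <- fun(pp)
      g[i] <- (fp - fm) / (2 * eps)
    }
    out[[nm]] <- g
  }
  out
}

# one fully observed synthetic day (48 slots) as a segment tibble
full_day_segment <- function(seed = 1) {
  withr::with_seed(seed, {
    tibble::tibble(day = 1L, slot = 0:47,
                   value = 20 + 4 * sin(2 * pi * (0:47 - 16) / 48) +
                     rnorm(48, 0, 0.2),
                   mask = 1L)
  })
}
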