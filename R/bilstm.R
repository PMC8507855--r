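# BiLSTM-I: bidirectional LSTM-I encoder + LSTM/affine decoder, trained by
# Adam on a three-part masked absolute-error loss. The batched forward and
# backward (BPTT) passes live in src/lstm.cpp; this file provides the
# plain-R reference implementations of the individual operations (used for
# exposition and as an independent check of the C++ kernel), parameter
# initialization, the training loop, and inference.

sigmoid <- function(x) 1 / (1 + exp(-x))

# one LSTM step on row-vectors; W is (p + h) x 4h with gate blocks [i|f|g|o]
lstm_cell_step <- function(inp, h_prev, c_prev, W, b) {
  h <- length(h_prev)
  z <- c(inp, h_prev) %*% W + b
  i <- sigmoid(z[, seq_len(h)])
  f <- sigmoid(z[, h + seq_len(h)])
  g <- tanh(z[, 2 * h + seq_len(h)])
  o <- sigmoid(z[, 3 * h + seq_len(h)])
  c_new <- f * c_prev + i * g
  list(h = as.numeric(o * tanh(c_new)), c = as.numeric(c_new))
}

#' One LSTM-I step: estimate, substitute, update
#'
#' Computes the estimate of the current input from the previous hidden state
#' (`x_tilde = Wx' h_prev + bx`), substitutes it at missing positions
#' (`x_c = m * x + (1 - m) * x_tilde`), advances the LSTM, and accumulates
#' the absolute estimation error at loss-scored positions.
#'
#' @param x_t Input vector (length = slots; `NA` allowed at masked
#'   positions).
#' @param m_t 0/1 observation mask for `x_t`.
#' @param h_prev,c_prev Previous hidden / cell state (zeros at t = 1).
#' @param params List with `Wx` (h x slots), `bx`, `W` ((slots + h) x 4h),
#'   `b`.
#' @param truth_t Optional true values (required wherever
#'   `loss_mask_t = 1`).
#' @param loss_mask_t Optional 0/1 vector of scored positions.
#' @return List `h`, `c`, `x_tilde`, `loss_contrib` (sum of absolute errors
#'   at scored positions, 0 when no truth is given).
#' @export
lstm_i_step <- function(x_t, m_t, h_prev, c_prev, params, truth_t = NULL,
                        loss_mask_t = NULL) {
  x_tilde <- as.numeric(h_prev %*% params$Wx + params$bx)
  x0 <- ifelse(is.na(x_t), 0, x_t)
  x_c <- m_t * x0 + (1 - m_t) * x_tilde
  st <- lstm_cell_step(x_c, h_prev, c_prev, params$W, params$b)
  loss <- 0
  if (!is.null(loss_mask_t) && any(loss_mask_t == 1)) {
    if (is.null(truth_t) || anyNA(truth_t[loss_mask_t == 1])) {
      abort("truth required at every loss-scored position")
    }
    loss <- sum(loss_mask_t * abs(ifelse(is.na(truth_t), 0, truth_t) -
                                    x_tilde))
  }
  list(h = st$h, c = st$c, x_tilde = x_tilde, loss_contrib = loss)
}

#' Bidirectional LSTM-I encoding of a window (reference implementation)
#'
#' Runs the forward reader over days `1..w` and the backward reader over the
#' reversed window; hidden states are concatenated aligned to the original
#' day order. The per-direction losses are mean absolute estimation errors
#' over loss-scored positions.
#'
#' @param sample A `window_sample`.
#' @param params Full BiLSTM-I parameter list (see
#'   [init_bilstm_params()]).
#' @return List `h` (w x 2h matrix), `l_f`, `l_b`, `xtil_f`, `xtil_b`.
#' @export
encode_bidirectional <- function(sample, params) {
  w <- nrow(sample$input)
  nf <- ncol(sample$input)
  h_dim <- nrow(params$Wx_f)
  # Wx stored h x slots; R step uses h_prev %*% Wx
  run <- function(ord, Wx, bx, W, b) {
    h_prev <- numeric(h_dim); c_prev <- numeric(h_dim)
    H <- matrix(0, w, h_dim)
    X <- matrix(0, w, nf)
    loss <- 0
    for (t in ord) {
      st <- lstm_i_step(sample$input[t, ], sample$input_mask[t, ], h_prev,
                        c_prev, list(Wx = Wx, bx = bx, W = W, b = b),
                        truth_t = sample$target[t, ],
                        loss_mask_t = sample$loss_mask[t, ])
      H[t, ] <- st$h
      X[t, ] <- st$x_tilde
      loss <- loss + st$loss_contrib
      h_prev <- st$h; c_prev <- st$c
    }
    list(H = H, X = X, loss = loss)
  }
  fw <- run(seq_len(w), params$Wx_f, params$bx_f, params$W_f, params$b_f)
  bw <- run(rev(seq_len(w)), params$Wx_b, params$bx_b, params$W_b,
            params$b_b)
  N <- sum(sample$loss_mask)
  list(h = cbind(fw$H, bw$H),
       l_f = if (N > 0) fw$loss / N else 0,
       l_b = if (N > 0) bw$loss / N else 0,
       xtil_f = fw$X, xtil_b = bw$X)
}

#' Decode an encoded hidden sequence into slot values (reference
#' implementation)
#'
#' `s_t = LSTM(h_t, s_{t-1})`, `y_t = Wy' s_t + by`, with `s_0 = 0`.
#'
#' @param h w x 2h matrix of encoder outputs.
#' @param params Parameter list with `W_d`, `b_d`, `Wy`, `by`.
#' @return A w x slots matrix of decoded values.
#' @export
decode <- function(h, params) {
  hd <- nrow(params$Wy)
  w <- nrow(h)
  s_prev <- numeric(hd); c_prev <- numeric(hd)
  Y <- matrix(0, w, ncol(params$Wy))
  for (t in seq_len(w)) {
    st <- lstm_cell_step(h[t, ], s_prev, c_prev, params$W_d, params$b_d)
    Y[t, ] <- st$h %*% params$Wy + params$by
    s_prev <- st$h; c_prev <- st$c
  }
  Y
}

#' Three-part training loss of a window
#'
#' `l_f` and `l_b` are the mean absolute estimation errors of the forward
#' and backward encoder readers at loss-scored positions; `l_y` is the mean
#' absolute error of the decoder output at the same positions;
#' `total = l_f + l_b + l_y`.
#'
#' @param sample A `window_sample` with target values at every scored
#'   position.
#' @param xtil_f,xtil_b w x slots encoder estimates (see
#'   [encode_bidirectional()]).
#' @param y w x slots decoder output.
#' @return A one-row tibble `l_f`, `l_b`, `l_y`, `total`.
#' @export
loss_total <- function(sample, xtil_f, xtil_b, y) {
  lm_ <- sample$loss_mask
  N <- sum(lm_)
  if (N == 0) abort("empty loss mask: nothing to train on")
  tr <- sample$target
  if (anyNA(tr[lm_ == 1])) abort("truth required at every loss-scored position")
  tr0 <- ifelse(is.na(tr), 0, tr)
  l_f <- sum(lm_ * abs(tr0 - xtil_f)) / N
  l_b <- sum(lm_ * abs(tr0 - xtil_b)) / N
  l_y <- sum(lm_ * abs(tr0 - y)) / N
  tibble(l_f = l_f, l_b = l_b, l_y = l_y, total = l_f + l_b + l_y)
}

# ------------------------------------------------------------ parameters

unif_mat <- function(nr, nc, bound) {
  matrix(runif(nr * nc, -bound, bound), nr, nc)
}

# LSTM weights U(-1/sqrt(h), 1/sqrt(h)); forget-gate bias raised to +1
init_lstm_block <- function(p, h) {
  bound <- 1 / sqrt(h)
  W <- unif_mat(p + h, 4 * h, bound)
  b <- runif(4 * h, -bound, bound)
  b[h + seq_len(h)] <- b[h + seq_len(h)] + 1
  list(W = W, b = b)
}

#' Initialize BiLSTM-I parameters
#'
#' @param n_features Slots per day (48).
#' @param hidden Encoder hidden size per direction.
#' @param hidden_dec Decoder hidden size.
#' @param seed RNG seed.
#' @return Named list of parameter matrices/vectors.
#' @export
init_bilstm_params <- function(n_features = 48L, hidden = 64L,
                               hidden_dec = 64L, seed = 1L) {
  withr::with_seed(seed, {
    be <- 1 / sqrt(hidden)
    f <- init_lstm_block(n_features, hidden)
    b <- init_lstm_block(n_features, hidden)
    d <- init_lstm_block(2L * hidden, hidden_dec)
    list(
      Wx_f = unif_mat(hidden, n_features, be), bx_f = runif(n_features, -be, be),
      W_f = f$W, b_f = f$b,
      Wx_b = unif_mat(hidden, n_features, be), bx_b = runif(n_features, -be, be),
      W_b = b$W, b_b = b$b,
      W_d = d$W, b_d = d$b,
      Wy = unif_mat(hidden_dec, n_features, 1 / sqrt(hidden_dec)),
      by = runif(n_features, -1 / sqrt(hidden_dec), 1 / sqrt(hidden_dec)))
  })
}

# ------------------------------------------------------- cube conversion

# stack a list of window samples into (B, slots, w) arrays, z-scored
samples_to_cubes <- function(samples, mu, sd_) {
  B <- length(samples)
  w <- nrow(samples[[1]]$input)
  nf <- ncol(samples[[1]]$input)
  x <- array(0, c(B, nf, w)); m <- array(0, c(B, nf, w))
  tr <- array(0, c(B, nf, w)); lm_ <- array(0, c(B, nf, w))
  for (i in seq_len(B)) {
    s <- samples[[i]]
    xi <- (s$input - mu) / sd_
    xi[is.na(xi)] <- 0
    ti <- (s$target - mu) / sd_
    ti[is.na(ti)] <- 0
    x[i, , ] <- t(xi); m[i, , ] <- t(s$input_mask)
    tr[i, , ] <- t(ti); lm_[i, , ] <- t(s$loss_mask)
  }
  list(x = x, m = m, tr = tr, lm = lm_, w = w, nf = nf)
}

sub_cube <- function(cu, idx) {
  list(x = cu$x[idx, , , drop = FALSE], m = cu$m[idx, , , drop = FALSE],
       tr = cu$tr[idx, , , drop = FALSE], lm = cu$lm[idx, , , drop = FALSE])
}

# Adam step on a list of parameter arrays
adam_update <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (!is.matrix(params[[nm]])) g <- as.numeric(g)  # rowvec comes back 1 x n
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / corr1) / (sqrt(state$v[[nm]] / corr2) + eps)
  }
  list(params = params, state = state)
}

init_adam <- function(params) {
  list(t = 0, m = purrr::map(params, ~ .x * 0),
       v = purrr::map(params, ~ .x * 0))
}

norm_constants <- function(samples) {
  vals <- unlist(purrr::map(samples, ~ .x$target))
  vals <- vals[!is.na(vals)]
  mu <- mean(vals)
  sd_ <- sd(vals)
  if (!is.finite(sd_) || sd_ <= 0) abort("degenerate training data: sd <= 0")
  c(mu = mu, sd = sd_)
}

# shared training loop over a batched pass function
run_training <- function(arch, samples, val_samples, pass_fun, params,
                         lr, batch_size, max_epochs, patience, seed,
                         verbose) {
  nc <- norm_constants(samples)
  cu <- samples_to_cubes(samples, nc["mu"], nc["sd"])
  cu_val <- if (length(val_samples) > 0) {
    samples_to_cubes(val_samples, nc["mu"], nc["sd"])
  } else NULL

  state <- init_adam(params)
  best <- list(val = Inf, params = params, epoch = 0L)
  hist <- vector("list", max_epochs)
  B <- length(samples)
  withr::with_seed(seed + 1L, {
    for (ep in seq_len(max_epochs)) {
      idx <- sample.int(B)
      batches <- split(idx, ceiling(seq_along(idx) / batch_size))
      tl <- c(0, 0, 0)
      for (bi in batches) {
        sc <- sub_cube(cu, bi)
        attr(sc, "idx") <- bi           # lets pass_fun fetch per-sample extras
        out <- pass_fun(sc, params, want_grad = TRUE)
        if (!is.finite(out$total)) {
          abort(sprintf("training diverged (non-finite loss at epoch %d)", ep))
        }
        upd <- adam_update(params, out$grads, state, lr)
        params <- upd$params; state <- upd$state
        tl <- tl + c(out$l_f %||% 0, out$l_b %||% 0,
                     out[[3]] %||% 0) * length(bi)
      }
      train_terms <- tl / B
      val_total <- NA_real_
      if (!is.null(cu_val)) {
        scv <- cu_val
        attr(scv, "val") <- TRUE
        vo <- pass_fun(scv, params, want_grad = FALSE)
        val_total <- vo$total
      }
      monitor <- if (is.na(val_total)) sum(train_terms) else val_total
      hist[[ep]] <- tibble(epoch = ep, l_f = train_terms[1],
                           l_b = train_terms[2], l_third = train_terms[3],
                           total = sum(train_terms), val = val_total)
      if (verbose) {
        message(sprintf("epoch %3d  train %.4f  val %s", ep,
                        sum(train_terms),
                        ifelse(is.na(val_total), "-",
                               sprintf("%.4f", val_total))))
      }
      if (monitor < best$val - 1e-6) {
        best <- list(val = monitor, params = params, epoch = ep)
      } else if (ep - best$epoch >= patience) break
    }
  })
  list(params = best$params, best_epoch = best$epoch, best_val = best$val,
       mu = unname(nc["mu"]), sd = unname(nc["sd"]),
       history = dplyr::bind_rows(hist[!purrr::map_lgl(hist, is.null)]))
}

split_val <- function(samples, val_samples, val_frac, seed) {
  if (!is.null(val_samples)) return(list(train = samples, val = val_samples))
  n <- length(samples)
  n_val <- floor(n * val_frac)
  if (n_val < 1 || n < 5) return(list(train = samples, val = list()))
  withr::with_seed(seed + 2L, idx <- sample.int(n, n_val))
  list(train = samples[-idx], val = samples[idx])
}

bilstm_pass_cubes <- function(sc, params, want_grad) {
  cpp_bilstm_pass(sc$x, sc$m, sc$tr, sc$lm, params, want_grad)
}

#' Train the BiLSTM-I imputer
#'
#' Minimizes the three-part masked absolute-error objective (forward and
#' backward encoder estimation errors plus decoder imputation error) by Adam
#' over mini-batches, with early stopping on a validation set. Inputs are
#' z-scored by the training mean/sd; the constants are stored in the model.
#' Fully reproducible under `seed`.
#'
#' @param samples List of `window_sample` training windows (identical
#'   shapes).
#' @param val_samples Optional validation windows; when `NULL`, a fraction
#'   `val_frac` of `samples` is held out (seeded split).
#' @param hidden Encoder hidden size per direction (default 64).
#' @param hidden_dec Decoder hidden size (default 64).
#' @param lr Adam learning rate.
#' @param batch_size Mini-batch size.
#' @param max_epochs Epoch cap.
#' @param patience Early-stopping patience (epochs without improvement).
#' @param val_frac Held-out fraction when `val_samples` is `NULL`.
#' @param seed Seed covering parameter init, the validation split and batch
#'   shuffling.
#' @param verbose Print per-epoch losses.
#' @return An object of class `trained_imputer` (architecture tag
#'   `"bilstm_i"`): best parameters, normalization constants, config echo,
#'   training history.
#' @export
train_bilstm_i <- function(samples, val_samples = NULL, hidden = 64L,
                           hidden_dec = 64L, lr = 1e-3, batch_size = 16L,
                           max_epochs = 200L, patience = 20L,
                           val_frac = 0.1, seed = 1L, verbose = FALSE) {
  stopifnot(length(samples) >= 1)
  check_same_shape(samples)
  nf <- ncol(samples[[1]]$input)
  sp <- split_val(samples, val_samples, val_frac, seed)
  params <- init_bilstm_params(nf, hidden, hidden_dec, seed)
  res <- run_training("bilstm_i", sp$train, sp$val, bilstm_pass_cubes,
                      params, lr, batch_size, max_epochs, patience, seed,
                      verbose)
  new_trained_imputer("bilstm_i", res, nf,
                      list(hidden = hidden, hidden_dec = hidden_dec,
                           lr = lr, batch_size = batch_size,
                           max_epochs = max_epochs, patience = patience),
                      seed)
}

check_same_shape <- function(samples) {
  dims <- unique(purrr::map(samples, ~ dim(.x$input)))
  if (length(dims) != 1) abort("all samples must share the same (w, slots) shape")
  invisible(TRUE)
}

new_trained_imputer <- function(arch, res, n_features, config, seed) {
  structure(
    list(arch = arch, params = res$params, mu = res$mu, sd = res$sd,
         n_features = n_features, config = config, seed = seed,
         history = res$history, best_epoch = res$best_epoch,
         best_val = res$best_val),
    class = "trained_imputer")
}

#' @export
print.trained_imputer <- function(x, ...) {
  cat(sprintf(
    "<trained_imputer> %s; %d epochs run, best epoch %d (monitor %.4f); norm mu %.2f sd %.2f\n",
    x$arch, nrow(x$history), x$best_epoch, x$best_val, x$mu, x$sd))
  invisible(x)
}

#' @rdname train_bilstm_i
#' @param x A `trained_imputer`.
#' @param ... Unused.
#' @method tidy trained_imputer
#' @export
tidy.trained_imputer <- function(x, ...) x$history

#' @rdname train_bilstm_i
#' @method glance trained_imputer
#' @export
glance.trained_imputer <- function(x, ...) {
  tibble(arch = x$arch, epochs_run = nrow(x$history),
         best_epoch = x$best_epoch, monitor = x$best_val,
         norm_mu = x$mu, norm_sd = x$sd)
}

#' Fill one window with a trained imputer
#'
#' Observed positions are returned bit-identical to the input; every masked
#' position is filled with the model output (decoder output for BiLSTM-I,
#' mean of the directional estimates for BRITS-I), denormalized to degrees
#' Celsius.
#'
#' @param model A `trained_imputer`.
#' @param window A `window_sample` whose slot dimension matches the model
#'   (any window length is accepted; the recurrence is length-agnostic).
#' @return A list of class `imputed_window`: `values` (w x slots), `raw`
#'   (model output everywhere), `provenance` (`"observed"`/`"imputed"`
#'   matrix), `window`.
#' @export
impute_window <- function(model, window) {
  stopifnot(inherits(model, "trained_imputer"),
            inherits(window, "window_sample"))
  if (ncol(window$input) != model$n_features) {
    abort(sprintf("window has %d slots but the model expects %d",
                  ncol(window$input), model$n_features))
  }
  dummy <- window
  dummy$target <- matrix(0, nrow(window$input), ncol(window$input))
  dummy$loss_mask <- matrix(0, nrow(window$input), ncol(window$input))
  cu <- samples_to_cubes(list(dummy), model$mu, model$sd)
  out <- if (model$arch == "bilstm_i") {
    cpp_bilstm_pass(cu$x, cu$m, cu$tr, cu$lm, model$params, FALSE)
  } else {
    df <- delta_cube(window$input_mask, "forward")
    db <- delta_cube(window$input_mask, "backward")
    cpp_brits_pass(cu$x, cu$m, cu$tr, cu$lm, df, db, model$params, FALSE)
  }
  yhat <- t(out$y[1, , ]) * model$sd + model$mu      # back to w x slots, degC
  vals <- ifelse(window$input_mask == 1, window$input, yhat)
  prov <- ifelse(window$input_mask == 1, "observed", "imputed")
  structure(list(values = vals, raw = yhat, provenance = prov,
                 window = window),
            class = "imputed_window")
}

#' @export
print.imputed_window <- function(x, ...) {
  cat(sprintf("<imputed_window> %d days x %d slots, %d imputed\n",
              nrow(x$values), ncol(x$values), sum(x$provenance == "imputed")))
  invisible(x)
}
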