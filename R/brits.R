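# BRITS-I-style baseline: the unidirectional RITS-I recurrence (temporal
# decay of the hidden state, history-only estimation) run in both directions;
# the final estimate is the mean of the two directional estimates and the
# loss adds a forward/backward consistency penalty.

#' Temporal decay factor
#'
#' `gamma = exp(-max(0, delta %*% W_g + b_g))`, elementwise: the influence of
#' the hidden state decays with the time since the last observation.
#'
#' @param delta Nonnegative lag matrix (rows = time steps, cols = slots) or a
#'   single lag vector.
#' @param W_g Slots x h decay weight matrix.
#' @param b_g Length-h bias.
#' @return Decay factors in `(0, 1]`, same rows as `delta`.
#' @export
temporal_decay <- function(delta, W_g, b_g) {
  if (is.null(dim(delta))) delta <- matrix(delta, nrow = 1)
  if (any(delta < 0)) abort("lags must be nonnegative")
  u <- delta %*% W_g
  u <- sweep(u, 2, b_g, "+")
  exp(-pmax(u, 0))
}

#' Per-slot observation lags of a window
#'
#' `delta[t, j]` is the number of steps since slot `j` was last observed,
#' looking backwards (`"forward"` reading direction) or forwards
#' (`"backward"`); 0 at the sequence boundary.
#'
#' @param mask w x slots 0/1 observation mask.
#' @param direction `"forward"` or `"backward"`.
#' @return A w x slots lag matrix.
#' @export
compute_deltas <- function(mask, direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  w <- nrow(mask)
  d <- matrix(0, w, ncol(mask))
  if (direction == "forward") {
    for (t in seq_len(w)[-1]) {
      d[t, ] <- ifelse(mask[t - 1, ] == 1, 1, d[t - 1, ] + 1)
    }
  } else {
    for (t in rev(seq_len(w - 1))) {
      d[t, ] <- ifelse(mask[t + 1, ] == 1, 1, d[t + 1, ] + 1)
    }
  }
  d
}

# (1, slots, w) lag cube for a single window
delta_cube <- function(mask, direction) {
  d <- compute_deltas(mask, direction)
  arr <- array(0, c(1, ncol(mask), nrow(mask)))
  arr[1, , ] <- t(d)
  arr
}

# (B, slots, w) lag cubes for a batch of identical-mask samples
brits_cubes <- function(samples) {
  B <- length(samples)
  w <- nrow(samples[[1]]$input_mask)
  nf <- ncol(samples[[1]]$input_mask)
  df <- array(0, c(B, nf, w)); db <- array(0, c(B, nf, w))
  for (i in seq_len(B)) {
    df[i, , ] <- t(compute_deltas(samples[[i]]$input_mask, "forward"))
    db[i, , ] <- t(compute_deltas(samples[[i]]$input_mask, "backward"))
  }
  list(df = df, db = db)
}

#' Initialize BRITS-I parameters
#'
#' @inheritParams init_bilstm_params
#' @return Named list of parameter matrices/vectors (per direction: decay
#'   map `Wg`/`bg`, estimate map `Wx`/`bx`, LSTM block `W`/`b`).
#' @export
init_brits_params <- function(n_features = 48L, hidden = 64L, seed = 1L) {
  withr::with_seed(seed, {
    be <- 1 / sqrt(hidden)
    f <- init_lstm_block(n_features, hidden)
    b <- init_lstm_block(n_features, hidden)
    list(
      Wg_f = unif_mat(n_features, hidden, be), bg_f = runif(hidden, 0, be),
      Wx_f = unif_mat(hidden, n_features, be), bx_f = runif(n_features, -be, be),
      W_f = f$W, b_f = f$b,
      Wg_b = unif_mat(n_features, hidden, be), bg_b = runif(hidden, 0, be),
      Wx_b = unif_mat(hidden, n_features, be), bx_b = runif(n_features, -be, be),
      W_b = b$W, b_b = b$b)
  })
}

#' Train the BRITS-I baseline imputer
#'
#' Same training protocol as [train_bilstm_i()]; the objective is the sum of
#' the two directional masked absolute estimation errors plus the mean
#' absolute forward/backward consistency discrepancy over all positions.
#'
#' @inheritParams train_bilstm_i
#' @return A `trained_imputer` with architecture tag `"brits_i"`.
#' @export
train_brits_i <- function(samples, val_samples = NULL, hidden = 64L,
                          lr = 1e-3, batch_size = 16L, max_epochs = 200L,
                          patience = 20L, val_frac = 0.1, seed = 1L,
                          verbose = FALSE) {
  stopifnot(length(samples) >= 1)
  check_same_shape(samples)
  nf <- ncol(samples[[1]]$input)
  sp <- split_val(samples, val_samples, val_frac, seed)
  params <- init_brits_params(nf, hidden, seed)

  dc_train <- brits_cubes(sp$train)
  dc_val <- if (length(sp$val) > 0) brits_cubes(sp$val) else NULL
  # lag cubes are fixed per sample; the shared loop tags batches with their
  # sample indices and the validation pass with a "val" attribute
  pass <- function(sc, params, want_grad) {
    if (isTRUE(attr(sc, "val"))) {
      df <- dc_val$df; db <- dc_val$db
    } else if (!is.null(attr(sc, "idx"))) {
      idx <- attr(sc, "idx")
      df <- dc_train$df[idx, , , drop = FALSE]
      db <- dc_train$db[idx, , , drop = FALSE]
    } else {
      df <- dc_train$df; db <- dc_train$db
    }
    cpp_brits_pass(sc$x, sc$m, sc$tr, sc$lm, df, db, params, want_grad)
  }
  res <- run_training("brits_i", sp$train, sp$val, pass, params, lr,
                      batch_size, max_epochs, patience, seed, verbose)
  new_trained_imputer("brits_i", res, nf,
                      list(hidden = hidden, lr = lr,
                           batch_size = batch_size,
                           max_epochs = max_epochs, patience = patience),
                      seed)
}

#' @rdname impute_window
#' @export
impute_brits_i <- function(model, window) {
  stopifnot(identical(model$arch, "brits_i"))
  impute_window(model, window)
}
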