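# LSTM-I cell, encoder-decoder, loss decomposition, gradients, training.

test_that("masked substitution: observed inputs override the estimate", {
  withr::with_seed(3, {
    nf <- 6; h <- 4
    params <- list(Wx = matrix(rnorm(h * nf), h), bx = rnorm(nf),
                   W = matrix(rnorm((nf + h) * 4 * h, 0, 0.3), nf + h),
                   b = rnorm(4 * h))
    x <- rnorm(nf, 10)
    h0 <- rnorm(h); c0 <- rnorm(h)
    # all-observed: hidden state is unaffected by the estimate map
    params2 <- params; params2$Wx <- params$Wx * 10; params2$bx <- params$bx + 5
    a <- lstm_i_step(x, rep(1, nf), h0, c0, params)
    b <- lstm_i_step(x, rep(1, nf), h0, c0, params2)
    expect_identical(a$h, b$h)
    expect_identical(a$c, b$c)
    expect_false(identical(a$x_tilde, b$x_tilde))
    # all-missing: the substituted input IS the estimate
    xm <- rep(NA_real_, nf)
    st <- lstm_i_step(xm, rep(0, nf), h0, c0, params)
    ref <- lstm_i_step(st$x_tilde, rep(1, nf), h0, c0, params)
    expect_equal(st$h, ref$h, tolerance = 1e-12)

    # random-mask identity over many draws
    for (i in 1:25) {
      m <- rbinom(nf, 1, 0.5)
      xi <- ifelse(m == 1, rnorm(nf, 10), NA)
      s1 <- lstm_i_step(xi, m, h0, c0, params)
      s2 <- lstm_i_step(xi, m, h0, c0, params2)
      xc1 <- m * ifelse(is.na(xi), 0, xi) + (1 - m) * s1$x_tilde
      xc2 <- m * ifelse(is.na(xi), 0, xi) + (1 - m) * s2$x_tilde
      expect_identical(xc1[m == 1], xc2[m == 1])
    }
  })
})

test_that("perfect estimates give zero loss contribution", {
  nf <- 4; h <- 2
  params <- list(Wx = matrix(0, h, nf), bx = c(1, 2, 3, 4),
                 W = matrix(0, nf + h, 4 * h), b = rep(0, 4 * h))
  truth <- c(1, 2, 3, 4)             # equals bx since h_prev = 0
  st <- lstm_i_step(rep(NA_real_, nf), rep(0, nf), rep(0, h), rep(0, h),
                    params, truth_t = truth, loss_mask_t = rep(1, nf))
  expect_equal(st$loss_contrib, 0)
  expect_error(lstm_i_step(rep(NA_real_, nf), rep(0, nf), rep(0, h),
                           rep(0, h), params, truth_t = rep(NA_real_, nf),
                           loss_mask_t = rep(1, nf)),
               "truth required")
})

test_that("encoder output has width 2h and is deterministic; decoder maps lengths", {
  withr::with_seed(5, ws <- random_window(w = 6, nf = 8))
  params <- init_bilstm_params(8, hidden = 5, hidden_dec = 4, seed = 2)
  enc1 <- encode_bidirectional(ws, params)
  enc2 <- encode_bidirectional(ws, params)
  expect_identical(enc1, enc2)
  expect_equal(dim(enc1$h), c(6, 10))
  y <- decode(enc1$h, params)
  expect_equal(dim(y), c(6, 8))
  # zero output map: y is the constant bias row
  p0 <- params; p0$Wy <- p0$Wy * 0
  y0 <- decode(enc1$h, p0)
  expect_equal(y0, matrix(params$by, 6, 8, byrow = TRUE))
})

test_that("the R reference forward pass matches the C++ kernel exactly", {
  withr::with_seed(7, ws <- random_window(w = 5, nf = 7))
  params <- init_bilstm_params(7, hidden = 4, hidden_dec = 3, seed = 4)
  enc <- encode_bidirectional(ws, params)
  y <- decode(enc$h, params)
  lr <- loss_total(ws, enc$xtil_f, enc$xtil_b, y)
  cu <- gapfillr:::samples_to_cubes(list(ws), 0, 1)
  out <- gapfillr:::cpp_bilstm_pass(cu$x, cu$m, cu$tr, cu$lm, params, FALSE)
  expect_equal(lr$l_f, out$l_f, tolerance = 1e-12)
  expect_equal(lr$l_b, out$l_b, tolerance = 1e-12)
  expect_equal(lr$l_y, out$l_y, tolerance = 1e-12)
  expect_equal(y, t(out$y[1, , ]), tolerance = 1e-12)
})

test_that("loss decomposition: total = l_f + l_b + l_y, linear in the errors", {
  withr::with_seed(9, ws <- random_window(w = 4, nf = 5))
  params <- init_bilstm_params(5, 3, 3, seed = 1)
  enc <- encode_bidirectional(ws, params)
  y <- decode(enc$h, params)
  lr <- loss_total(ws, enc$xtil_f, enc$xtil_b, y)
  expect_equal(lr$total, lr$l_f + lr$l_b + lr$l_y)
  # perfect estimates and output -> zero loss
  perfect <- loss_total(ws, ws$target, ws$target, ws$target)
  expect_equal(perfect$total, 0)
  # doubling every scored error doubles the total
  dbl <- loss_total(ws, ws$target + 2 * (enc$xtil_f - ws$target),
                    ws$target + 2 * (enc$xtil_b - ws$target),
                    ws$target + 2 * (y - ws$target))
  expect_equal(dbl$total, 2 * lr$total, tolerance = 1e-12)
  # empty loss mask is rejected
  ws0 <- ws; ws0$loss_mask <- ws$loss_mask * 0
  expect_error(loss_total(ws0, enc$xtil_f, enc$xtil_b, y), "empty loss mask")
})

test_that("analytic gradients match central finite differences (mini network)", {
  withr::with_seed(1, ws <- random_window(w = 4, nf = 5))
  params <- init_bilstm_params(5, hidden = 3, hidden_dec = 3, seed = 3)
  cu <- gapfillr:::samples_to_cubes(list(ws), 0, 1)
  out <- gapfillr:::cpp_bilstm_pass(cu$x, cu$m, cu$tr, cu$lm, params, TRUE)
  fd <- fd_grads(function(p) {
    gapfillr:::cpp_bilstm_pass(cu$x, cu$m, cu$tr, cu$lm, p, FALSE)$total
  }, params)
  for (nm in names(params)) {
    ga <- as.numeric(out$grads[[nm]])
    gf <- as.numeric(fd[[nm]])
    expect_lt(max(abs(ga - gf)) / max(abs(gf)), 1e-4)
  }
})

test_that("training is reproducible and can overfit a single tiny window", {
  # one window: w = 6 days (m = 2 hidden days, s = 2 context), 8 slots
  withr::with_seed(15, {
    tgt <- matrix(10 + 3 * sin(seq_len(6 * 8) / 3), 6, 8) +
      matrix(rnorm(48, 0, 0.3), 6, 8)
  })
  im <- matrix(1, 6, 8)
  im[3:4, ] <- 0; im[3:4, c(2, 5)] <- 1
  lm_ <- (1 - im); lm_[c(1:2, 5:6), ] <- 0
  inp <- tgt; inp[im == 0] <- NA
  ws <- gapfillr:::new_window_sample(inp, im, tgt, lm_)

  m1 <- train_bilstm_i(list(ws), val_samples = list(), hidden = 24,
                       hidden_dec = 24, lr = 5e-3, batch_size = 1,
                       max_epochs = 400, patience = 400, seed = 11)
  m2 <- train_bilstm_i(list(ws), val_samples = list(), hidden = 24,
                       hidden_dec = 24, lr = 5e-3, batch_size = 1,
                       max_epochs = 400, patience = 400, seed = 11)
  expect_identical(m1$history$total, m2$history$total)
  expect_lt(dplyr::last(m1$history$total), m1$history$total[1])

  iw <- impute_window(m1, ws)
  # observed positions bit-identical
  expect_identical(iw$values[im == 1], ws$input[im == 1])
  # scored-position error after overfitting
  err <- (iw$values - tgt)[lm_ == 1]
  expect_lt(mean(abs(err)), 0.1 * sd(tgt))
  expect_lt(sqrt(mean(err^2)), 0.2)

  # all-observed window: output equals input everywhere
  ws_full <- gapfillr:::new_window_sample(tgt, matrix(1, 6, 8), tgt,
                                          matrix(0, 6, 8))
  expect_identical(impute_window(m1, ws_full)$values, tgt)
})

test_that("impute_window rejects slot mismatches and flags provenance", {
  withr::with_seed(19, ws <- random_window(w = 4, nf = 6))
  m <- train_bilstm_i(list(ws), val_samples = list(), hidden = 4,
                      hidden_dec = 4, max_epochs = 2, patience = 5,
                      seed = 2)
  iw <- impute_window(m, ws)
  expect_identical(iw$provenance == "observed", ws$input_mask == 1)
  bad <- random_window(w = 4, nf = 5)
  expect_error(impute_window(m, bad), "slots")
})
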