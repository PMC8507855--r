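# Temporal decay and the BRITS-I baseline.

test_that("temporal decay is 1 at zero lag and nonincreasing in the lag", {
  h <- 3; nf <- 4
  Wg <- matrix(0.2, nf, h)
  bg <- rep(0, h)
  expect_equal(as.numeric(temporal_decay(rep(0, nf), Wg, bg)), rep(1, h))
  lags <- matrix(seq(0, 10, by = 0.5), ncol = 1) %*% matrix(1, 1, nf)
  g <- temporal_decay(lags, Wg, bg)
  expect_true(all(diff(g[, 1]) <= 0))
  expect_true(all(g > 0 & g <= 1))
  # negative pre-activations are clipped: decay never exceeds 1
  g2 <- temporal_decay(lags, -Wg, bg)
  expect_true(all(g2 == 1))
  expect_error(temporal_decay(matrix(-1, 1, nf), Wg, bg), "nonnegative")
})

test_that("observation lags count steps since/until the nearest observation", {
  m <- rbind(c(1, 0), c(0, 0), c(1, 0), c(1, 1))
  df <- compute_deltas(m, "forward")
  expect_identical(df, rbind(c(0, 0), c(1, 1), c(2, 2), c(1, 3)))
  db <- compute_deltas(m, "backward")
  expect_identical(db, rbind(c(2, 3), c(1, 2), c(1, 1), c(0, 0)))
})

test_that("BRITS gradients match finite differences; loss decomposes", {
  withr::with_seed(2, ws <- random_window(w = 4, nf = 5))
  params <- init_brits_params(5, hidden = 3, seed = 6)
  cu <- gapfillr:::samples_to_cubes(list(ws), 0, 1)
  df <- gapfillr:::delta_cube(ws$input_mask, "forward")
  db <- gapfillr:::delta_cube(ws$input_mask, "backward")
  out <- gapfillr:::cpp_brits_pass(cu$x, cu$m, cu$tr, cu$lm, df, db, params,
                                   TRUE)
  expect_equal(out$total, out$l_f + out$l_b + out$l_cons, tolerance = 1e-12)
  # consistency term is the mean absolute directional discrepancy
  expect_equal(out$l_cons, mean(abs(out$xtil_f - out$xtil_b)),
               tolerance = 1e-12)
  # the combined estimate is the directional mean
  expect_equal(out$y, (out$xtil_f + out$xtil_b) / 2, tolerance = 1e-12)
  fd <- fd_grads(function(p) {
    gapfillr:::cpp_brits_pass(cu$x, cu$m, cu$tr, cu$lm, df, db, p,
                              FALSE)$total
  }, params)
  for (nm in names(params)) {
    ga <- as.numeric(out$grads[[nm]])
    gf <- as.numeric(fd[[nm]])
    expect_lt(max(abs(ga - gf)) / max(abs(gf)), 1e-4)
  }
})

test_that("BRITS training is reproducible, learns, and preserves observations", {
  withr::with_seed(25, {
    tgt <- matrix(12 + 2 * cos(seq_len(6 * 8) / 4), 6, 8) +
      matrix(rnorm(48, 0, 0.2), 6, 8)
  })
  im <- matrix(1, 6, 8)
  im[3:4, ] <- 0; im[3:4, c(3, 6)] <- 1
  lm_ <- (1 - im); lm_[c(1:2, 5:6), ] <- 0
  inp <- tgt; inp[im == 0] <- NA
  ws <- gapfillr:::new_window_sample(inp, im, tgt, lm_)

  m1 <- train_brits_i(list(ws), val_samples = list(), hidden = 24, lr = 5e-3,
                      batch_size = 1, max_epochs = 400, patience = 400,
                      seed = 9)
  m2 <- train_brits_i(list(ws), val_samples = list(), hidden = 24, lr = 5e-3,
                      batch_size = 1, max_epochs = 400, patience = 400,
                      seed = 9)
  expect_identical(m1$history$total, m2$history$total)
  expect_lt(dplyr::last(m1$history$total), m1$history$total[1])

  iw <- impute_brits_i(m1, ws)
  expect_identical(iw$values[im == 1], ws$input[im == 1])
  err <- (iw$values - tgt)[lm_ == 1]
  expect_lt(mean(abs(err)), 0.1 * sd(tgt))

  ws_full <- gapfillr:::new_window_sample(tgt, matrix(1, 6, 8), tgt,
                                          matrix(0, 6, 8))
  expect_identical(impute_window(m1, ws_full)$values, tgt)
})
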