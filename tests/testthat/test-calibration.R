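# Manual-to-machine calibration and anchor insertion.

test_that("calibration recovers exact and noisy linear maps", {
  man <- regular_series(seq(10, 25, length.out = 20))
  mac <- man
  mac$value <- 0.5 * man$value + 2
  cal <- fit_manual_calibration(man, mac)
  expect_equal(cal$slope, 0.5, tolerance = 1e-12)
  expect_equal(cal$intercept, 2, tolerance = 1e-12)

  ident <- fit_manual_calibration(man, man)
  expect_equal(ident$slope, 1, tolerance = 1e-12)
  expect_equal(ident$intercept, 0, tolerance = 1e-12)

  # noisy pairs: coefficients equal the closed-form normal-equation solution
  withr::with_seed(21, {
    x <- rnorm(50, 18, 4)
    y <- 0.9 * x + 1.5 + rnorm(50, 0, 0.3)
  })
  man2 <- regular_series(x)
  mac2 <- regular_series(y)
  cal2 <- fit_manual_calibration(man2, mac2)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(cal2$intercept, beta[1], tolerance = 1e-10)
  expect_equal(cal2$slope, beta[2], tolerance = 1e-10)
  expect_equal(tidy(cal2)$estimate, c(beta[1], beta[2]), tolerance = 1e-10)
  expect_equal(glance(cal2)$n_pairs, 50)
})

test_that("degenerate calibration inputs are rejected", {
  one <- regular_series(5)
  expect_error(fit_manual_calibration(one, one), "at least 2")
  const <- regular_series(rep(7, 10))
  expect_error(fit_manual_calibration(const, const), "zero variance")
})

test_that("gap injection removes exactly 48*m values; anchors restore 3/day", {
  cfg <- weather_config(n_days = 60, seed = 2)
  sim <- simulate_temperature(cfg)
  machine <- gapfillr:::sim_channel(sim, "machine")
  truth <- gapfillr:::sim_channel(sim, "truth")

  gap30 <- gap_spec(16, m = 30, s = 14)
  gapped <- inject_gap(machine, gap30)
  expect_equal(sum(is.na(gapped$value)), 1440)
  out <- which(is.na(gapped$value))
  expect_true(all(out > 15 * 48 & out <= 45 * 48))
  untouched <- setdiff(seq_len(nrow(machine)), out)
  expect_identical(gapped$value[untouched], machine$value[untouched])

  cfg90 <- weather_config(n_days = 90, seed = 2)
  mac90 <- gapfillr:::sim_channel(simulate_temperature(cfg90), "machine")
  expect_equal(sum(is.na(inject_gap(mac90, gap_spec(16, 60, 14))$value)),
               2880)
  # gap too close to the series edge (needs s context days)
  expect_error(inject_gap(machine, gap_spec(5, 30, 14)), "do not fit")

  manual <- derive_manual_obs(truth, bias = 0, noise_sd = 0, seed = 3)
  anchored <- insert_anchors(gapped, manual, identity_calibration(), gap30)
  expect_equal(sum(is.na(anchored$value)), 1440 - 30 * 3)
  # identity calibration + exact manual readings -> anchors carry truth
  filled <- which(!is.na(anchored$value) & is.na(gapped$value))
  expect_identical(anchored$value[filled], truth$value[filled])
  # observed machine values never modified
  expect_identical(anchored$value[untouched], machine$value[untouched])
  # mask construction is consistent with the inserted anchors
  expect_identical(anchored$mask, build_mask(anchored)$mask)
})

test_that("a missing manual reading leaves its anchor slot missing, with warning", {
  cfg <- weather_config(n_days = 40, seed = 4)
  sim <- simulate_temperature(cfg)
  machine <- gapfillr:::sim_channel(sim, "machine")
  truth <- gapfillr:::sim_channel(sim, "truth")
  gap <- gap_spec(16, m = 5, s = 14)
  gapped <- inject_gap(machine, gap)
  manual <- derive_manual_obs(truth, seed = 5)
  manual <- manual[-((16 - 1) * 3 + 1), ]      # drop a reading inside the gap
  expect_warning(anchored <- insert_anchors(gapped, manual,
                                            identity_calibration(), gap),
                 "no manual reading")
  expect_equal(sum(anchored$mask == 1) + sum(is.na(anchored$value)),
               nrow(anchored))
  expect_equal(sum(is.na(anchored$value)), 5 * 48 - (5 * 3 - 1))
})
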