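# Accuracy metrics and the comparison harness plumbing.

test_that("metrics match a direct transcription of their formulas", {
  withr::with_seed(33, {
    for (rep in 1:5) {
      x <- rnorm(10, 15, 4)
      y <- x + rnorm(10, 0, 1)
      m <- suppressWarnings(compute_metrics(x, y))
      expect_equal(m$rmse, sqrt(sum((x - y)^2) / 10), tolerance = 1e-12)
      expect_equal(m$mae, sum(abs(x - y)) / 10, tolerance = 1e-12)
      keep <- abs(x) >= 0.5
      expect_equal(m$mre, mean(abs(x[keep] - y[keep]) / abs(x[keep])),
                   tolerance = 1e-12)
      pcc <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
      expect_equal(m$pcc, pcc, tolerance = 1e-12)
    }
  })
})

test_that("trivial cases: perfect and offset imputations", {
  x <- c(10, 12, 14, 18)
  perfect <- compute_metrics(x, x)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$mre, 0)
  expect_equal(perfect$pcc, 1)
  off <- compute_metrics(x, x + 1)
  expect_equal(off$rmse, 1)
  expect_equal(off$mae, 1)
  expect_equal(off$pcc, 1)
})

test_that("metric invariants hold over many random cases", {
  withr::with_seed(44, {
    for (i in 1:1000) {
      n <- sample(2:30, 1)
      x <- rnorm(n, 10, 5)
      y <- rnorm(n, 10, 5)
      m <- suppressWarnings(compute_metrics(x, y))
      expect_gte(m$rmse, m$mae)
      expect_gte(m$pcc, -1)
      expect_lte(m$pcc, 1)
    }
  })
})

test_that("metrics are permutation-invariant and validate their inputs", {
  withr::with_seed(5, {
    x <- rnorm(20, 12, 3)
    y <- x + rnorm(20, 0, 0.5)
    p <- sample(20)
  })
  expect_equal(compute_metrics(x, y), compute_metrics(x[p], y[p]))
  expect_error(compute_metrics(1, 1.2), "at least 2")
  expect_warning(compute_metrics(c(0.1, 5, 8), c(0.2, 5, 8)),
                 "excluded from MRE")
  # eval_mask selects the scored subset
  mask <- c(rep(1, 10), rep(0, 10))
  expect_equal(compute_metrics(x, y, mask), compute_metrics(x[1:10], y[1:10]))
})

test_that("baseline fills behave as defined", {
  cfg <- weather_config(n_days = 20, annual_amplitude = 0, seed = 8)
  sim <- simulate_temperature(cfg)
  machine <- gapfillr:::sim_channel(sim, "machine")
  gap <- gap_spec(9, m = 3, s = 5)
  gapped <- inject_gap(machine, gap)

  cl <- climatology_fill(gapped)
  slot <- rep(0:47, 20)
  for (sl in c(0, 17, 40)) {
    obs <- !is.na(gapped$value) & slot == sl
    expect_equal(unique(cl$imputed[is.na(gapped$value) & slot == sl]),
                 mean(gapped$value[obs]))
  }
  expect_identical(cl$imputed[!is.na(gapped$value)],
                   machine$value[!is.na(gapped$value)])

  li <- linear_gap_fill(gapped, gap)
  idx <- gapfillr:::gap_slot_range(gap)
  lo <- machine$value[min(idx) - 1]
  hi <- machine$value[max(idx) + 1]
  expect_equal(li$imputed[idx],
               lo + (hi - lo) * seq_along(idx) / (length(idx) + 1),
               tolerance = 1e-10)
})

test_that("the comparison harness is deterministic and internally consistent", {
  sc <- scenario_config(
    weather = weather_config(n_days = 40, seed = 3),
    gap_days = 4L, gap_start_day = 20L, s = 5L, stride = 4L)
  t1 <- run_comparison(sc, methods = c("climatology", "linear"), seeds = 2L)
  t2 <- run_comparison(sc, methods = c("climatology", "linear"), seeds = 2L)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_equal(nrow(t1), 2)
  expect_true(all(t1$status == "ok"))
  expect_equal(unique(t1$n), 4 * 45)

  # the climatology row reproduces compute_metrics on the mean-filled series
  prep <- gapfillr:::prepare_scenario(sc, 2L)
  pg <- prep$per_gap[["4"]]
  filled <- climatology_fill(pg$anchored)$imputed
  idx <- gapfillr:::gap_slot_range(pg$gap)
  hidden <- idx[is.na(pg$anchored$value[idx])]
  direct <- suppressWarnings(
    compute_metrics(prep$truth$value[hidden], filled[hidden]))
  expect_equal(t1$rmse[t1$method == "climatology"], direct$rmse)
  expect_equal(t1$pcc[t1$method == "climatology"], direct$pcc)
})

test_that("method failures land in a failed row, not a crash", {
  sc <- scenario_config(
    weather = weather_config(n_days = 40, seed = 3),
    gap_days = 4L, gap_start_day = 20L, s = 5L)
  tb <- run_comparison(sc, methods = c("climatology", "not_a_method"),
                       seeds = 1L)
  expect_equal(nrow(tb), 2)
  expect_match(tb$status[tb$method == "not_a_method"], "failed")
  expect_true(is.na(tb$rmse[tb$method == "not_a_method"]))
})
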