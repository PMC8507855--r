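# Synthetic subtropical temperature generator: annual sinusoid + diurnal
# sinusoid + a shared AR(1) weather deviation at the sampling resolution,
# observed by a "machine" channel (iid noise) and a sparse "manual" channel
# (bias + iid noise at a few fixed slots per day).

#' Configuration of the synthetic weather generator
#'
#' Defaults emulate a subtropical forest site: 22 degC mean, 6 degC annual
#' and 4 degC diurnal half-amplitude, slowly mixing AR(1) weather deviations
#' (phi 0.95 per half-hour step, innovation sd 0.6 degC, stationary sd about
#' 1.9 degC), and 0.2 degC machine observation noise. Manual readings carry a
#' 0.5 degC bias and 0.3 degC noise, so calibration is exercised.
#'
#' @param mean_temp Annual mean temperature (degC).
#' @param annual_amplitude Half-amplitude of the annual cycle (degC).
#' @param diurnal_amplitude Half-amplitude of the diurnal cycle (degC).
#' @param diurnal_phase Phase shift of the diurnal sinusoid in slots; the
#'   default 16 puts the daily maximum at slot 28 (14:00).
#' @param ar1_phi AR(1) coefficient of the weather deviation per slot,
#'   `|phi| < 1`.
#' @param ar1_sd AR(1) innovation sd (degC).
#' @param obs_noise_sd Machine observation noise sd (degC).
#' @param manual_bias Additive bias of manual readings (degC).
#' @param manual_noise_sd Manual reading noise sd (degC).
#' @param n_days Number of simulated days.
#' @param start_time Timestamp of slot 0 of day 1.
#' @param slots_per_day Observations per day (48 = half-hourly).
#' @param seed Default RNG seed used by [simulate_temperature()].
#' @return An object of class `weather_config`.
#' @export
weather_config <- function(mean_temp = 22, annual_amplitude = 6,
                           diurnal_amplitude = 4, diurnal_phase = 16,
                           ar1_phi = 0.95, ar1_sd = 0.6, obs_noise_sd = 0.2,
                           manual_bias = 0.5, manual_noise_sd = 0.3,
                           n_days = 730,
                           start_time = as.POSIXct("2019-01-01 00:00:00",
                                                   tz = "UTC"),
                           slots_per_day = 48L, seed = 1L) {
  stopifnot(abs(ar1_phi) < 1, ar1_sd >= 0, obs_noise_sd >= 0,
            manual_noise_sd >= 0, n_days >= 1, slots_per_day >= 1)
  structure(as.list(environment()), class = "weather_config")
}

#' @export
print.weather_config <- function(x, ...) {
  cat(sprintf(
    "<weather_config> %d days x %d slots; mean %.1f, annual +/-%.1f, diurnal +/-%.1f degC; AR(1) phi %.2f sd %.2f; obs noise %.2f\n",
    x$n_days, x$slots_per_day, x$mean_temp, x$annual_amplitude,
    x$diurnal_amplitude, x$ar1_phi, x$ar1_sd, x$obs_noise_sd))
  invisible(x)
}

#' Simulate a half-hourly temperature series
#'
#' Truth is `mean + annual_amplitude * sin(2*pi*day/365.25) +
#' diurnal_amplitude * sin(2*pi*(slot - phase)/slots_per_day) + AR(1)
#' deviation`; the machine channel adds iid Gaussian observation noise.
#' The AR(1) deviation is shared across slots (one process at the sampling
#' resolution) and starts from its stationary distribution. Reproducible
#' under `seed`.
#'
#' @param cfg A [weather_config()].
#' @param seed RNG seed (default: the one in `cfg`).
#' @return A tibble with columns `timestamp`, `truth`, `machine`.
#' @export
simulate_temperature <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "weather_config"))
  spd <- cfg$slots_per_day
  L <- cfg$n_days * spd
  t_idx <- seq_len(L) - 1L
  day <- t_idx %/% spd            # 0-based day
  slot <- t_idx %% spd
  det <- cfg$mean_temp +
    cfg$annual_amplitude * sin(2 * pi * day / 365.25) +
    cfg$diurnal_amplitude * sin(2 * pi * (slot - cfg$diurnal_phase) / spd)
  withr::with_seed(seed, {
    if (cfg$ar1_sd > 0) {
      dev <- as.numeric(stats::filter(
        rnorm(L, 0, cfg$ar1_sd), cfg$ar1_phi, method = "recursive",
        init = rnorm(1, 0, cfg$ar1_sd / sqrt(1 - cfg$ar1_phi^2))))
    } else {
      dev <- numeric(L)
    }
    noise <- if (cfg$obs_noise_sd > 0) rnorm(L, 0, cfg$obs_noise_sd) else 0
    tibble(
      timestamp = cfg$start_time + t_idx * (86400 / spd),
      truth = det + dev,
      machine = det + dev + noise)
  })
}

#' Derive sparse manual observations from the true series
#'
#' One reading per day per anchor slot: truth + bias + iid noise.
#'
#' @param truth Tibble with `timestamp` and a truth column (`truth` or
#'   `value`).
#' @param anchor_slots 0-based slots at which readings are taken.
#' @param bias Additive bias (degC).
#' @param noise_sd Reading noise sd (degC).
#' @param seed RNG seed.
#' @return A tibble `timestamp`, `value`.
#' @export
derive_manual_obs <- function(truth, anchor_slots = c(16L, 27L, 39L),
                              bias = 0, noise_sd = 0, seed = 1L) {
  val <- if ("truth" %in% names(truth)) truth$truth else truth$value
  step <- series_step_secs(truth)
  slots <- slot_of(truth$timestamp, step)
  keep <- slots %in% anchor_slots
  withr::with_seed(seed, {
    noise <- if (noise_sd > 0) rnorm(sum(keep), 0, noise_sd) else 0
    tibble(timestamp = truth$timestamp[keep],
           value = val[keep] + bias + noise)
  })
}

#' Remove all machine observations inside a gap
#'
#' Sets every slot of the gap days to missing (`48 * m` values for
#' half-hourly data); everything else is untouched. The gap must leave `s`
#' context days available on each side.
#'
#' @param series Series tibble (e.g. the `machine` channel).
#' @param gap A [gap_spec()].
#' @return The series with the gap injected and a `mask` column.
#' @export
inject_gap <- function(series, gap) {
  stopifnot(inherits(gap, "gap_spec"))
  spd <- series_slots_per_day(series)
  if (spd != gap$slots_per_day) abort("slots/day mismatch with gap spec")
  nd <- nrow(series) / spd
  if (gap$gap_start_day - gap$s < 1 ||
      gap$gap_start_day + gap$m - 1 + gap$s > nd) {
    abort(sprintf(
      "gap days %d-%d with s = %d context days do not fit in %d days",
      gap$gap_start_day, gap$gap_start_day + gap$m - 1, gap$s, floor(nd)))
  }
  series$value[gap_slot_range(gap)] <- NA_real_
  build_mask(series)
}

# convert the truth/machine sim tibble into plain series tibbles
sim_channel <- function(sim, channel = c("machine", "truth")) {
  channel <- match.arg(channel)
  tibble(timestamp = sim$timestamp, value = sim[[channel]])
}
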