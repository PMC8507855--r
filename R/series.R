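# Regular half-hourly series, observation masks, and daily segmentation.
#
# A "series" throughout the package is a tibble with a `timestamp` column
# (POSIXct, naive local time stored as UTC) and a `value` column (degrees
# Celsius, NA = missing). Days are indexed 1-based; within-day slots are
# 0-based (slot 0 = 00:00-00:30), so the default manual-observation anchors
# at roughly 08:00, 13:30 and 19:30 are slots 16, 27 and 39.

#' Construct a regular half-hourly series tibble
#'
#' @param values Numeric vector of temperatures (deg C); `NA` marks a missing
#'   observation.
#' @param start_time POSIXct timestamp of the first value (should fall on a
#'   slot boundary; midnight for day-aligned operations).
#' @param step_mins Sampling step in minutes. Must divide a day evenly.
#' @return A tibble with columns `timestamp` and `value`.
#' @examples
#' s <- regular_series(c(20, 21, NA, 22))
#' @export
regular_series <- function(values,
                           start_time = as.POSIXct("2019-01-01 00:00:00",
                                                   tz = "UTC"),
                           step_mins = 30) {
  stopifnot(is.numeric(values), length(values) >= 1)
  if ((24 * 60) %% step_mins != 0) {
    abort(sprintf("step of %s min does not divide one day evenly", step_mins))
  }
  if (any(!is.finite(values) & !is.na(values))) {
    abort("values must be finite or NA (NA is the missing marker)")
  }
  tibble(
    timestamp = start_time + (seq_along(values) - 1) * step_mins * 60,
    value = as.double(values)
  )
}

series_step_secs <- function(series) {
  if (nrow(series) < 2) return(1800)
  d <- as.numeric(difftime(series$timestamp[2], series$timestamp[1],
                           units = "secs"))
  if (nrow(series) > 2) {
    dd <- diff(as.numeric(series$timestamp))
    if (any(abs(dd - d) > 1e-6)) abort("series is not regularly sampled")
  }
  d
}

series_slots_per_day <- function(series) {
  step <- series_step_secs(series)
  spd <- 86400 / step
  if (abs(spd - round(spd)) > 1e-8) {
    abort("sampling step does not divide one day evenly")
  }
  as.integer(round(spd))
}

slot_of <- function(timestamp, step_secs) {
  secs <- as.numeric(timestamp) %% 86400
  as.integer(round(secs / step_secs))
}

#' Build the observation mask of a series
#'
#' Adds (or rewrites) an integer `mask` column: 1 where the value is
#' observed, 0 where it is missing.
#'
#' @param series A series tibble (see [regular_series()]).
#' @return The series with a `mask` column.
#' @examples
#' build_mask(regular_series(c(20, NA, 21)))$mask
#' @export
build_mask <- function(series) {
  stopifnot(is.data.frame(series), "value" %in% names(series))
  series$mask <- as.integer(!is.na(series$value))
  as_tibble(series)
}

#' Segment a series into whole days
#'
#' Splits a day-aligned series into daily segments of `slots_per_day` values
#' (48 for half-hourly data). The result is a long tibble with `day` (1-based)
#' and `slot` (0-based) columns; [flatten_segments()] is its exact inverse.
#'
#' @param series A series tibble starting at slot 0 of a day and covering a
#'   whole number of days.
#' @return A tibble with columns `day`, `slot`, `timestamp`, `value`, `mask`,
#'   of class `segmented_series`.
#' @export
segment_days <- function(series) {
  series <- build_mask(series)
  step <- series_step_secs(series)
  spd <- series_slots_per_day(series)
  first_slot <- slot_of(series$timestamp[1], step)
  if (first_slot != 0) {
    abort(sprintf(
      "series must start at slot 0 of a day (00:00); it starts at slot %d",
      first_slot))
  }
  L <- nrow(series)
  if (L %% spd != 0) {
    abort(sprintf(
      "series length %d is not divisible by %d slots/day (remainder %d)",
      L, spd, L %% spd))
  }
  out <- tibble(
    day = rep(seq_len(L / spd), each = spd),
    slot = rep(seq_len(spd) - 1L, times = L / spd),
    timestamp = series$timestamp,
    value = series$value,
    mask = series$mask
  )
  structure(out,
            class = c("segmented_series", class(out)),
            slots_per_day = spd,
            step_secs = step)
}

#' Flatten a segmented series back to a plain series
#'
#' @param seg A `segmented_series` from [segment_days()].
#' @return A series tibble with `timestamp`, `value`, `mask`.
#' @export
flatten_segments <- function(seg) {
  stopifnot(inherits(seg, "segmented_series"))
  seg <- dplyr::arrange(as_tibble(seg), .data$day, .data$slot)
  tibble(timestamp = seg$timestamp, value = seg$value, mask = seg$mask)
}

#' Number of days in a segmented series
#' @param seg A `segmented_series`.
#' @return Integer day count.
#' @export
n_days <- function(seg) {
  stopifnot(inherits(seg, "segmented_series"))
  max(seg$day)
}

# day x slot value matrix of a segmented series (rows = days)
seg_matrix <- function(seg, col = "value") {
  spd <- attr(seg, "slots_per_day")
  matrix(seg[[col]], ncol = spd, byrow = TRUE)
}

#' Reduce a fully observed day segment to sparse anchor observations
#'
#' Keeps the values at the given anchor slots and marks every other slot
#' missing, reproducing the observation pattern of a day inside a long gap
#' where only morning / midday / evening manual readings exist.
#'
#' @param segment A one-day tibble with columns `slot` (0-based) and `value`
#'   (and optionally `mask`), fully observed.
#' @param anchor_slots Integer 0-based slots to retain (default
#'   `c(16, 27, 39)`, i.e. 08:00, 13:30, 19:30).
#' @return The segment with non-anchor values set to `NA` and `mask` updated.
#' @export
apply_anchor_pattern <- function(segment, anchor_slots = c(16L, 27L, 39L)) {
  stopifnot(is.data.frame(segment), all(c("slot", "value") %in% names(segment)))
  spd <- nrow(segment)
  if (anyNA(segment$value)) {
    abort("anchor pattern is applied to fully observed days only")
  }
  if (length(anchor_slots) > 0 &&
      (any(anchor_slots < 0) || any(anchor_slots >= spd))) {
    abort(sprintf("anchor slots must lie in [0, %d]", spd - 1))
  }
  keep <- segment$slot %in% anchor_slots
  segment$value[!keep] <- NA_real_
  segment$mask <- as.integer(keep)
  as_tibble(segment)
}

#' Specification of a long observation gap
#'
#' @param gap_start_day First day of the gap (1-based day index).
#' @param m Gap length in days.
#' @param s Days of fully observed context kept on each side of the gap
#'   when building model windows (default 14). The window length is
#'   `w = m + 2 * s`.
#' @param anchor_slots 0-based within-day slots at which sparse manual
#'   observations exist inside the gap (default `c(16, 27, 39)`).
#' @param slots_per_day Slots per day (default 48 = half-hourly).
#' @return An object of class `gap_spec`.
#' @examples
#' gap_spec(351, m = 30)
#' @export
gap_spec <- function(gap_start_day, m, s = 14L,
                     anchor_slots = c(16L, 27L, 39L), slots_per_day = 48L) {
  stopifnot(m >= 1, s >= 1, gap_start_day >= 1)
  anchor_slots <- sort(unique(as.integer(anchor_slots)))
  if (length(anchor_slots) > 0 &&
      (any(anchor_slots < 0) || any(anchor_slots >= slots_per_day))) {
    abort(sprintf("anchor slots must lie in [0, %d]", slots_per_day - 1))
  }
  structure(
    list(gap_start_day = as.integer(gap_start_day), m = as.integer(m),
         s = as.integer(s), anchor_slots = anchor_slots,
         slots_per_day = as.integer(slots_per_day)),
    class = "gap_spec")
}

#' @export
print.gap_spec <- function(x, ...) {
  cat(sprintf(
    "<gap_spec> days %d-%d (m = %d, s = %d, window w = %d), anchors at slots %s\n",
    x$gap_start_day, x$gap_start_day + x$m - 1L, x$m, x$s, x$m + 2L * x$s,
    paste(x$anchor_slots, collapse = ", ")))
  invisible(x)
}

#' Window length (days) implied by a gap specification
#' @param gap A [gap_spec()].
#' @return Integer `m + 2 * s`.
#' @export
window_length <- function(gap) {
  stopifnot(inherits(gap, "gap_spec"))
  gap$m + 2L * gap$s
}

gap_day_range <- function(gap) {
  seq(gap$gap_start_day, gap$gap_start_day + gap$m - 1L)
}

gap_slot_range <- function(gap) {
  spd <- gap$slots_per_day
  first <- (gap$gap_start_day - 1L) * spd + 1L
  seq(first, first + gap$m * spd - 1L)
}
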