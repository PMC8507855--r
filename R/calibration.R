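# Manual-to-machine calibration: the sparse manual thermometer readings are
# related to the automatic sensor by an approximately linear map, fitted by
# ordinary least squares on a time-matched overlap period.

#' Fit the manual-to-machine calibration line
#'
#' Ordinary least squares of machine readings on time-matched manual
#' readings: `machine = slope * manual + intercept`.
#'
#' @param manual Tibble with `timestamp`, `value` (manual readings).
#' @param machine Tibble with `timestamp`, `value` (machine readings).
#' @return A `calibration_model` with fields `slope`, `intercept`,
#'   `n_pairs`, `residual_sd`.
#' @examples
#' man <- regular_series(c(10, 12, 14, 16))
#' mac <- regular_series(0.5 * c(10, 12, 14, 16) + 2)
#' fit_manual_calibration(man, mac)
#' @export
fit_manual_calibration <- function(manual, machine) {
  pairs <- dplyr::inner_join(
    dplyr::select(manual, "timestamp", manual = "value"),
    dplyr::select(machine, "timestamp", machine = "value"),
    by = "timestamp")
  pairs <- pairs[complete.cases(pairs), ]
  if (nrow(pairs) < 2) {
    abort("need at least 2 time-matched (manual, machine) pairs")
  }
  if (var(pairs$manual) == 0) {
    abort("manual readings have zero variance; slope is unidentified")
  }
  fit <- lm(machine ~ manual, data = pairs)
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         n_pairs = nrow(pairs),
         residual_sd = sqrt(sum(fit$residuals^2) / max(1, nrow(pairs) - 2))),
    class = "calibration_model")
}

#' Identity calibration (manual readings taken at face value)
#' @return A `calibration_model` with slope 1, intercept 0.
#' @export
identity_calibration <- function() {
  structure(list(slope = 1, intercept = 0, n_pairs = 2L, residual_sd = 0),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "<calibration_model> machine = %.4f * manual + %.4f (n = %d, residual sd %.3f degC)\n",
    x$slope, x$intercept, x$n_pairs, x$residual_sd))
  invisible(x)
}

#' @export
predict.calibration_model <- function(object, newdata, ...) {
  object$slope * newdata + object$intercept
}

#' @rdname fit_manual_calibration
#' @param x A `calibration_model`.
#' @param ... Unused.
#' @method tidy calibration_model
#' @export
tidy.calibration_model <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope))
}

#' @rdname fit_manual_calibration
#' @method glance calibration_model
#' @export
glance.calibration_model <- function(x, ...) {
  tibble(n_pairs = x$n_pairs, residual_sd = x$residual_sd)
}

#' Insert calibrated manual anchors into a gap
#'
#' Within the gap days (which must be entirely missing in the machine
#' series), places the calibrated manual reading at each anchor slot; all
#' other gap slots stay missing, and the series outside the gap is returned
#' untouched. A missing manual reading leaves its slot missing with a
#' warning.
#'
#' @param series Series tibble with the gap (all gap-day values `NA`).
#' @param manual Tibble `timestamp`, `value` of sparse manual readings.
#' @param cal A `calibration_model` (default: identity).
#' @param gap A [gap_spec()].
#' @return The series with a `mask` column and anchors filled.
#' @export
insert_anchors <- function(series, manual, cal = identity_calibration(),
                           gap) {
  stopifnot(inherits(gap, "gap_spec"), inherits(cal, "calibration_model"))
  step <- series_step_secs(series)
  idx <- gap_slot_range(gap)
  if (max(idx) > nrow(series)) abort("gap exceeds the series range")
  if (any(!is.na(series$value[idx]))) {
    abort("gap days must be entirely missing before anchors are inserted")
  }
  slots <- slot_of(series$timestamp[idx], step)
  anchor_pos <- idx[slots %in% gap$anchor_slots]
  key <- match(as.numeric(series$timestamp[anchor_pos]),
               as.numeric(manual$timestamp))
  have <- !is.na(key)
  have[have] <- !is.na(manual$value[key[have]])
  if (any(!have)) {
    warn(sprintf("%d anchor slot(s) have no manual reading; left missing",
                 sum(!have)))
  }
  series$value[anchor_pos[have]] <-
    predict(cal, manual$value[key[have]])
  build_mask(series)
}
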