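# Rolling-window training samples: w = m + 2s days, the middle m days masked
# down to the anchor pattern, the s context days on each side fully observed.

#' A single model window
#'
#' Internal constructor; validated container for one training / inference
#' window of `w` days by `slots_per_day` slots.
#'
#' @param input Numeric `w x slots` matrix with `NA` at masked positions.
#' @param input_mask 0/1 matrix of the same shape (1 = observed).
#' @param target Numeric matrix with the full truth (training) or `NA`
#'   (inference).
#' @param loss_mask 0/1 matrix marking positions where error is scored;
#'   disjoint from `input_mask`.
#' @param start_day 1-based index of the first window day in its source
#'   series.
#' @return An object of class `window_sample`.
#' @keywords internal
new_window_sample <- function(input, input_mask, target, loss_mask,
                              start_day = 1L) {
  stopifnot(is.matrix(input),
            identical(dim(input), dim(input_mask)),
            identical(dim(input), dim(loss_mask)))
  if (any(loss_mask * input_mask != 0)) {
    abort("loss_mask and input_mask must be disjoint")
  }
  structure(list(input = input, input_mask = input_mask, target = target,
                 loss_mask = loss_mask, start_day = as.integer(start_day)),
            class = "window_sample")
}

#' @export
print.window_sample <- function(x, ...) {
  cat(sprintf("<window_sample> %d days x %d slots, %d observed, %d scored\n",
              nrow(x$input), ncol(x$input), sum(x$input_mask),
              sum(x$loss_mask)))
  invisible(x)
}

#' Cut rolling training windows from a gap-free stretch
#'
#' Slides a window of `w = m + 2s` days over a fully observed segmented
#' series. In each window the middle `m` days are reduced to the anchor
#' observation pattern (the values at `anchor_slots` are kept, everything
#' else is hidden), the `s` days on each side stay fully observed, and the
#' hidden truth is retained as the training target. The loss mask marks
#' exactly the artificially hidden positions.
#'
#' @param seg A `segmented_series` ([segment_days()]); all days in the range
#'   used must be fully observed.
#' @param gap A [gap_spec()]; only `m`, `s` and `anchor_slots` are used.
#' @param stride Step between consecutive window start days (default 1).
#' @param days Optional integer vector restricting the source day range
#'   (default: all days).
#' @return A list of `window_sample` objects, length
#'   `floor((n_days - w) / stride) + 1`.
#' @export
make_windows <- function(seg, gap, stride = 1L, days = NULL) {
  stopifnot(inherits(seg, "segmented_series"), inherits(gap, "gap_spec"))
  spd <- attr(seg, "slots_per_day")
  V <- seg_matrix(seg, "value")
  if (!is.null(days)) {
    if (any(diff(days) != 1L)) abort("`days` must be a contiguous day range")
    V <- V[days, , drop = FALSE]
  } else {
    days <- seq_len(nrow(V))
  }
  w <- window_length(gap)
  nd <- nrow(V)
  if (nd < w) {
    abort(sprintf("need at least w = %d full days, got %d", w, nd))
  }
  if (anyNA(V)) {
    abort("training windows require fully observed days in the source range")
  }
  day_mask <- matrix(0, w, spd)
  day_mask[seq_len(gap$s), ] <- 1
  day_mask[w - gap$s + seq_len(gap$s), ] <- 1
  mid <- gap$s + seq_len(gap$m)
  day_mask[mid, gap$anchor_slots + 1L] <- 1
  loss_mask <- matrix(0, w, spd)
  loss_mask[mid, ] <- 1
  loss_mask <- loss_mask * (1 - day_mask)

  starts <- seq(1L, nd - w + 1L, by = stride)
  purrr::map(starts, function(st) {
    tgt <- V[st + seq_len(w) - 1L, , drop = FALSE]
    inp <- tgt
    inp[day_mask == 0] <- NA_real_
    new_window_sample(inp, day_mask, tgt, loss_mask,
                      start_day = days[st])
  })
}

#' Build the inference window around a real gap
#'
#' Extracts the `w = m + 2s` days centred on a gap from a series whose gap
#' days carry only anchor observations (see [insert_anchors()]), producing a
#' `window_sample` whose mask is taken from the data. When `truth` is given,
#' the target and loss mask are filled so the window can be scored.
#'
#' @param series A series tibble covering the gap and its context.
#' @param gap A [gap_spec()].
#' @param truth Optional series tibble with the complete true values.
#' @return A `window_sample` spanning days
#'   `gap_start_day - s .. gap_start_day + m + s - 1`.
#' @export
build_gap_window <- function(series, gap, truth = NULL) {
  seg <- segment_days(series)
  spd <- attr(seg, "slots_per_day")
  if (spd != gap$slots_per_day) abort("slots/day mismatch with gap spec")
  w <- window_length(gap)
  d0 <- gap$gap_start_day - gap$s
  if (d0 < 1 || d0 + w - 1 > n_days(seg)) {
    abort("gap window exceeds the series range; need s context days per side")
  }
  days <- d0 + seq_len(w) - 1L
  V <- seg_matrix(seg, "value")[days, , drop = FALSE]
  M <- 1 - is.na(V)
  ctx <- c(seq_len(gap$s), w - gap$s + seq_len(gap$s))
  if (any(is.na(V[ctx, ]))) {
    abort("context days beside the gap must be fully observed (prefill first)")
  }
  lm_ <- matrix(0, w, spd)
  lm_[gap$s + seq_len(gap$m), ] <- 1
  lm_ <- lm_ * (1 - M)
  tgt <- matrix(NA_real_, w, spd)
  if (!is.null(truth)) {
    tseg <- segment_days(truth)
    tgt <- seg_matrix(tseg, "value")[days, , drop = FALSE]
  }
  new_window_sample(V, M, tgt, lm_, start_day = d0)
}
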