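# ggplot2 views of imputation results and method comparisons.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_ribbon labs facet_wrap theme_minimal position_dodge
NULL

#' @export
ggplot2::autoplot

#' Plot a Kalman imputation result
#'
#' Observed values, imputed trajectory and a +/-2 sd band.
#'
#' @param object A `gf_imputation` from [impute_kalman()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gf_imputation
#' @export
autoplot.gf_imputation <- function(object, ...) {
  ggplot(object, aes(x = .data$timestamp)) +
    geom_ribbon(aes(ymin = .data$imputed - 2 * .data$sd,
                    ymax = .data$imputed + 2 * .data$sd),
                fill = "steelblue", alpha = 0.2) +
    geom_line(aes(y = .data$imputed, colour = .data$provenance,
                  group = 1)) +
    labs(x = NULL, y = "temperature (°C)", colour = NULL) +
    theme_minimal()
}

#' Plot a method comparison
#'
#' RMSE per method and gap length.
#'
#' @param object A `gf_comparison` from [run_comparison()].
#' @param metric Metric column to plot (default `"rmse"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gf_comparison
#' @export
autoplot.gf_comparison <- function(object, metric = "rmse", ...) {
  df <- as_tibble(object)
  key <- if ("model" %in% names(df)) "model" else "method"
  ggplot(df, aes(x = stats::reorder(.data[[key]], .data[[metric]]),
                 y = .data[[metric]], fill = factor(.data$gap_days))) +
    geom_col(position = position_dodge(width = 0.8), width = 0.7) +
    labs(x = NULL, y = toupper(metric), fill = "gap (days)") +
    theme_minimal()
}

#' Overlay truth, observations and an imputed window
#'
#' @param window A `window_sample` (with targets, e.g. from
#'   [build_gap_window()] with truth).
#' @param imputed An `imputed_window` from [impute_window()].
#' @param days Which window days to show (default: 3 days around the window
#'   centre).
#' @return A ggplot object.
#' @export
plot_imputed_window <- function(window, imputed, days = NULL) {
  w <- nrow(window$input)
  spd <- ncol(window$input)
  if (is.null(days)) {
    mid <- round(w / 2)
    days <- max(1, mid - 1):min(w, mid + 1)
  }
  df <- tidyr::expand_grid(day = seq_len(w), slot = seq_len(spd) - 1L)
  df$t <- (df$day - 1) * spd + df$slot
  df$truth <- as.numeric(t(window$target))
  df$observed <- as.numeric(t(ifelse(window$input_mask == 1, window$input,
                                     NA)))
  df$imputed <- as.numeric(t(imputed$values))
  df <- df[df$day %in% days, ]
  ggplot(df, aes(x = .data$t / spd)) +
    geom_line(aes(y = .data$truth), colour = "grey40") +
    geom_line(aes(y = .data$imputed), colour = "firebrick",
              linetype = "dashed") +
    geom_point(aes(y = .data$observed), colour = "black", size = 1.4) +
    labs(x = "window day", y = "temperature (°C)") +
    theme_minimal()
}
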