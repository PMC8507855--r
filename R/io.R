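# CSV interchange: `timestamp` (ISO-8601), `value` (degC, empty = missing),
# optional `mask` on output. Manual-observation files use the same layout.

#' Read a half-hourly series from CSV
#'
#' Expects columns `timestamp` (ISO-8601) and `value`; an empty field is the
#' missing marker.
#'
#' @param path File path.
#' @return A series tibble (`timestamp`, `value`).
#' @export
read_series_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("timestamp", "value") %in% names(df))) {
    abort("CSV must have 'timestamp' and 'value' columns")
  }
  tibble(
    timestamp = as.POSIXct(df$timestamp, tz = "UTC",
                           tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                          "%Y-%m-%d %H:%M:%S",
                                          "%Y-%m-%d")),
    value = suppressWarnings(as.numeric(df$value)))
}

#' Write a series to CSV
#'
#' @param series Series tibble (extra columns such as `mask` are kept).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  out <- as.data.frame(series)
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S")
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Serialize a trained imputer to JSON
#'
#' Stores the architecture tag, all parameter blocks, normalization
#' constants, config echo and seed; [read_imputer_json()] restores an
#' equivalent model (round-trip exact to double precision).
#'
#' @param model A `trained_imputer`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_imputer_json <- function(model, path) {
  stopifnot(inherits(model, "trained_imputer"))
  payload <- list(
    arch = model$arch,
    n_features = model$n_features,
    mu = model$mu, sd = model$sd, seed = model$seed,
    config = model$config,
    best_epoch = model$best_epoch, best_val = model$best_val,
    params = purrr::map(model$params, function(p) {
      list(dim = dim(p) %||% length(p), data = as.numeric(p))
    }))
  # 17 significant digits: bit-exact double round trip
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_imputer_json
#' @param path Path to a JSON file written by [write_imputer_json()].
#' @export
read_imputer_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- purrr::map(p$params, function(blk) {
    d <- as.integer(unlist(blk$dim))
    v <- as.numeric(unlist(blk$data))
    if (length(d) == 2) matrix(v, d[1], d[2]) else v
  })
  structure(
    list(arch = p$arch, params = params, mu = p$mu, sd = p$sd,
         n_features = p$n_features, config = p$config, seed = p$seed,
         history = tibble(), best_epoch = p$best_epoch,
         best_val = p$best_val),
    class = "trained_imputer")
}
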