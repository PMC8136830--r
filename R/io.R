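#' Write and read replicated dose-response tables
#'
#' The on-disk exchange format is a flat CSV with one row per well:
#' columns `condition`, `fs`, `dose`, `replicate`, `geomean`, `n_cells`,
#' `seed`. Doses must be positive; the round trip is lossless up to the
#' 17-significant-digit text representation of doubles.
#'
#' @param data A data frame with the columns above (e.g. a
#'   [generate_experiment()] result).
#' @param path File path.
#' @return `write_dose_response_csv()` returns `path` invisibly;
#'   `read_dose_response_csv()` returns a validated tibble.
#' @export
write_dose_response_csv <- function(data, path) {
  cols <- c("condition", "fs", "dose", "replicate", "geomean",
            "n_cells", "seed")
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0L) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  out <- as_tibble(data)[cols]
  # full double precision so read(write(x)) == x
  num <- c("fs", "dose", "geomean")
  out[num] <- lapply(out[num], function(v) sprintf("%.17g", v))
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_dose_response_csv
#' @export
read_dose_response_csv <- function(path) {
  # doubles come in as text and go through strtod for exact round trips
  spec <- readr::cols(
    condition = readr::col_character(),
    fs = readr::col_character(),
    dose = readr::col_character(),
    replicate = readr::col_integer(),
    geomean = readr::col_character(),
    n_cells = readr::col_integer(),
    seed = readr::col_integer()
  )
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  missing_cols <- setdiff(names(spec$cols), header)
  if (length(missing_cols) > 0L) {
    abort(paste0("file ", path, " is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  out <- readr::read_csv(path, col_types = spec, progress = FALSE)
  probs <- readr::problems(out)
  if (nrow(probs) > 0L) {
    abort(sprintf("parse error in %s at row %d, column %s.",
                  path, probs$row[1], probs$col[1]))
  }
  for (col in c("fs", "dose", "geomean")) {
    v <- suppressWarnings(as.numeric(out[[col]]))
    bad <- which(is.na(v) & !is.na(out[[col]]))
    if (length(bad) > 0L) {
      abort(sprintf("parse error in %s: column `%s`, row %d is not numeric.",
                    path, col, bad[1]))
    }
    out[[col]] <- v
  }
  bad <- which(!is.finite(out$dose) | out$dose <= 0)
  if (length(bad) > 0L) {
    abort(sprintf("non-positive dose in column `dose` at row %d.", bad[1]))
  }
  bad <- which(!is.finite(out$geomean) | out$geomean < 0)
  if (length(bad) > 0L) {
    abort(sprintf("invalid value in column `geomean` at row %d.", bad[1]))
  }
  out
}

#' Serialize metrics and sweeps
#'
#' `write_metrics_json()` writes any metrics tibble (e.g. from
#' [circuit_metrics()] or [glance()]) as a JSON object; `write_sweep_csv()`
#' writes an [sweep_fs()] result with columns `fs`, `fca`, `s_max`, `mdl`,
#' `threshold`.
#'
#' @param x The object to serialize.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(x, path) {
  jsonlite::write_json(as.list(as_tibble(x)), path,
                       auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_metrics_json
#' @export
write_sweep_csv <- function(x, path) {
  stopifnot(all(c("fs", "fca", "s_max", "mdl", "threshold") %in% names(x)))
  readr::write_csv(as_tibble(x)[c("fs", "fca", "s_max", "mdl", "threshold")],
                   path)
  invisible(path)
}
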