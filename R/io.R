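#' Load a delimited feature table
#'
#' Reads a CSV (comma) or TSV (tab; extensions `.tsv` / `.txt`) file with a
#' header row, checks every cell is numeric and non-missing, and splits out
#' the requested label / prediction columns from the feature columns.
#'
#' @param path File path; the delimiter is chosen from the extension.
#' @param target Optional name of the label column.
#' @param prediction Optional name of the prediction column.
#' @return A list with `X` (feature matrix, named columns), `y` (label
#'   vector or `NULL`), `yhat` (prediction vector or `NULL`) and
#'   `feature_names`.
#' @export
load_table <- function(path, target = NULL, prediction = NULL) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) < 2L) stop(sprintf("%s has %d data rows; at least 2 required",
                                  path, nrow(df)))
  for (req in c(target, prediction)) {
    if (!req %in% names(df)) {
      stop(sprintf("column \"%s\" not found in %s (columns: %s)", req, path,
                   paste(names(df), collapse = ", ")))
    }
  }
  for (j in seq_along(df)) {
    col <- df[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))))[1L]
      if (is.na(bad)) bad <- 1L
      stop(sprintf("non-numeric cell at row %d, column \"%s\" of %s",
                   bad, names(df)[j], path))
    }
    if (anyNA(col)) {
      stop(sprintf(paste0(
        "missing value at row %d, column \"%s\" of %s; missing values are ",
        "rejected, not imputed"), which(is.na(col))[1L], names(df)[j], path))
    }
  }
  drop <- c(target, prediction)
  feats <- setdiff(names(df), drop)
  if (length(feats) < 1L) stop("no feature columns remain after removing target/prediction")
  X <- as.matrix(df[, feats, drop = FALSE])
  list(X = X,
       y = if (is.null(target)) NULL else df[[target]],
       yhat = if (is.null(prediction)) NULL else df[[prediction]],
       feature_names = feats)
}

#' Write a simulated dataset as a delimited table
#'
#' Columns `x1..xd` then `y`, with a header row; comma- or tab-separated by
#' the path extension. Round-trips losslessly through [load_table()] at full
#' double precision.
#'
#' @param sim A list with `X` and `y`, as returned by the simulators.
#' @param path Output path (`.csv` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_table <- function(sim, path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- as.data.frame(sim$X)
  df$y <- sim$y
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

RESULT_SCHEMA_VERSION <- "1.0"

#' Build a serialisable result record from an attribution
#'
#' @param res A `sunnies_attribution`.
#' @param config Optional named list echoing the run configuration.
#' @return A `sunnies_result` list: schema version, config echo, feature
#'   names, values, full-set payoff, optional bootstrap block, timestamp.
#' @export
result_record <- function(res, config = NULL) {
  stopifnot(inherits(res, "sunnies_attribution"))
  rec <- list(
    schema_version = RESULT_SCHEMA_VERSION,
    config = config,
    target_kind = res$target_kind,
    measure = res$measure,
    n = res$n,
    method = res$method,
    seed = res$seed,
    feature_names = names(res$values),
    values = as.numeric(res$values),
    payoff_full = res$payoff_full,
    n_evaluations = res$n_evaluations,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  if (!is.null(res$bootstrap)) {
    rec$bootstrap <- list(point = res$bootstrap$point,
                          lower = res$bootstrap$lower,
                          upper = res$bootstrap$upper,
                          B = res$bootstrap$B[1L],
                          resample_size = res$bootstrap$resample_size[1L],
                          seed = res$bootstrap$seed[1L])
  }
  class(rec) <- "sunnies_result"
  rec
}

#' Serialise a result record to JSON
#'
#' Numbers are written at full precision so values survive a write/read
#' round trip bit-exactly; a bootstrap-free record simply omits the
#' bootstrap block.
#'
#' @param record A `sunnies_result` (or any list).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
serialize_result <- function(record, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop(sprintf("output directory does not exist: %s", dir))
  # 17 significant digits: the minimum that round-trips IEEE doubles exactly
  jsonlite::write_json(unclass(record), path, auto_unbox = TRUE,
                       digits = I(17), null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a result record back from JSON
#'
#' @param path Path written by [serialize_result()].
#' @return A `sunnies_result` list with numeric vectors restored.
#' @export
read_result <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  rec$values <- as.numeric(rec$values)
  class(rec) <- "sunnies_result"
  rec
}
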