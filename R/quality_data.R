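#' Construct a frozen-storage quality dataset
#'
#' The universal exchange object of the package: replicate measurements of the
#' five quality indicators over a (storage temperature, storage time) grid.
#'
#' @param measurements Data frame with columns \code{temperature_K} (kelvin,
#'   > 0), \code{time_weeks} (>= 0), \code{indicator} (one of
#'   \code{indicator_names()}), \code{replicate} (positive integer) and
#'   \code{value} (>= 0, in the indicator's unit).
#' @param metadata Named list of free-form provenance information (seed,
#'   generator parameters, ...).
#' @return An object of class \code{quality_dataset}: a list with elements
#'   \code{measurements} (validated, sorted data frame) and \code{metadata}.
#' @export
quality_dataset <- function(measurements, metadata = list()) {
  required <- c("temperature_K", "time_weeks", "indicator", "replicate", "value")
  missing_cols <- setdiff(required, names(measurements))
  if (length(missing_cols) > 0) {
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  m <- as.data.frame(measurements)[required]
  m$temperature_K <- as.numeric(m$temperature_K)
  m$time_weeks <- as.numeric(m$time_weeks)
  m$indicator <- as.character(m$indicator)
  m$replicate <- as.integer(m$replicate)
  m$value <- as.numeric(m$value)

  if (nrow(m) > 0) {
    bad_ind <- setdiff(unique(m$indicator), indicator_names())
    if (length(bad_ind) > 0) {
      stop("validation error: unknown indicator(s): ",
           paste(bad_ind, collapse = ", "), call. = FALSE)
    }
    bad <- which(!is.finite(m$value) | m$value < 0 |
                 !is.finite(m$time_weeks) | m$time_weeks < 0 |
                 !is.finite(m$temperature_K) | m$temperature_K <= 0 |
                 is.na(m$replicate) | m$replicate < 1)
    if (length(bad) > 0) {
      stop("validation error: invalid time/temperature/value/replicate at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
    key <- paste(m$temperature_K, m$time_weeks, m$indicator, m$replicate)
    if (anyDuplicated(key)) {
      stop("uniqueness error: duplicated (temperature, time, indicator, replicate) key(s): ",
           paste(utils::head(unique(key[duplicated(key)]), 3), collapse = "; "),
           call. = FALSE)
    }
    m <- m[order(m$temperature_K, m$time_weeks, m$indicator, m$replicate), ,
           drop = FALSE]
    rownames(m) <- NULL
  }
  structure(list(measurements = m, metadata = metadata),
            class = "quality_dataset")
}

#' @export
print.quality_dataset <- function(x, ...) {
  m <- x$measurements
  cat("<quality_dataset> ", nrow(m), " measurements\n", sep = "")
  if (nrow(m) > 0) {
    cat("  temperatures (K): ", paste(sort(unique(m$temperature_K)), collapse = ", "),
        "\n  weeks: ", paste(sort(unique(m$time_weeks)), collapse = ", "),
        "\n  indicators: ", paste(sort(unique(m$indicator)), collapse = ", "), "\n",
        sep = "")
  }
  if (length(x$metadata) > 0) {
    cat("  metadata: ", paste(names(x$metadata), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Read a quality-measurement CSV
#'
#' Expects the package's exchange schema: comma-separated, UTF-8, dot decimal,
#' header \code{temperature_K,time_weeks,indicator,replicate,value}.
#'
#' @param path Path to an existing CSV file.
#' @return A \code{quality_dataset}.
#' @export
read_quality_csv <- function(path) {
  if (!file.exists(path)) {
    stop("I/O error: file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = NA, check.names = TRUE)
  required <- c("temperature_K", "time_weeks", "indicator", "replicate", "value")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  quality_dataset(df, metadata = list(source = path))
}

#' Write a quality dataset to CSV
#'
#' Round-trips at full double precision: \code{read_quality_csv()} of the
#' written file reproduces the dataset's measurements exactly.
#'
#' @param dataset A \code{quality_dataset}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_quality_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "quality_dataset"))
  m <- dataset$measurements
  out <- data.frame(
    temperature_K = format(m$temperature_K, digits = 17, trim = TRUE,
                           scientific = FALSE),
    time_weeks = format(m$time_weeks, digits = 17, trim = TRUE,
                        scientific = FALSE),
    indicator = m$indicator,
    replicate = m$replicate,
    value = vapply(m$value, function(v) sprintf("%.17g", v), character(1)),
    stringsAsFactors = FALSE
  )
  if (nrow(m) == 0) {
    out <- out[0, , drop = FALSE]
  }
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) {
    stop("I/O error: cannot write ", path, ": ", conditionMessage(ok),
         call. = FALSE)
  }
  invisible(path)
}

#' Replicate means of a quality dataset
#'
#' Collapses replicates to their mean per (temperature, time, indicator); the
#' modelling pipeline operates on one mean curve per temperature.
#'
#' @param dataset A \code{quality_dataset}.
#' @return Data frame with columns \code{temperature_K}, \code{time_weeks},
#'   \code{indicator}, \code{value} (the replicate mean), \code{n_replicates}.
#' @export
replicate_means <- function(dataset) {
  stopifnot(inherits(dataset, "quality_dataset"))
  m <- dataset$measurements
  if (nrow(m) == 0) {
    return(data.frame(temperature_K = numeric(0), time_weeks = numeric(0),
                      indicator = character(0), value = numeric(0),
                      n_replicates = integer(0)))
  }
  agg <- stats::aggregate(value ~ temperature_K + time_weeks + indicator,
                          data = m, FUN = mean)
  n <- stats::aggregate(cbind(n_replicates = value) ~
                          temperature_K + time_weeks + indicator,
                        data = m, FUN = length)
  out <- merge(agg, n, by = c("temperature_K", "time_weeks", "indicator"))
  out$n_replicates <- as.integer(out$n_replicates)
  out <- out[order(out$temperature_K, out$time_weeks, out$indicator), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
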