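#' Construct a validated CGM trace
#'
#' A CGM trace is an ordered sequence of timestamped interstitial glucose
#' readings for one patient, sampled nominally every five minutes. The
#' Medtronic Enlite class of sensors reports values in \[40, 400\] mg/dl;
#' readings outside that range are rejected as sensor-impossible rather
#' than clamped. Gaps (consecutive readings further apart than the nominal
#' interval) are allowed and preserved; readings closer together than the
#' nominal interval minus the jitter tolerance (including duplicated
#' timestamps) are rejected.
#'
#' @param timestamp POSIXct (or anything coercible via [as.POSIXct()] with
#'   UTC assumed) reading times. Rows are sorted by timestamp before
#'   validation, so unordered input is accepted as long as the sorted
#'   times are strictly increasing.
#' @param glucose_mgdl numeric glucose readings in mg/dl, each in
#'   \[40, 400\].
#' @param patient_id identifier carried through windowing and
#'   benchmarking.
#' @param nominal_interval nominal seconds between readings (default 300).
#' @param tolerance allowed clock jitter in seconds around the nominal
#'   interval (default 60). Real CGM clocks drift; two readings are
#'   treated as consecutive when their spacing is within
#'   `nominal_interval + tolerance`, and spacings below
#'   `nominal_interval - tolerance` are invalid.
#' @return A tibble of class `cgm_trace` with columns `timestamp` and
#'   `glucose_mgdl`, carrying `patient_id`, `nominal_interval` and
#'   `tolerance` as attributes.
#' @seealso [read_cgm_csv()], [write_cgm_csv()], [split_chronological()],
#'   [build_windows()]
#' @export
cgm_trace <- function(timestamp, glucose_mgdl, patient_id = NA_character_,
                      nominal_interval = 300, tolerance = 60) {
  if (length(timestamp) != length(glucose_mgdl)) {
    stop("`timestamp` and `glucose_mgdl` must have the same length")
  }
  ts <- as.POSIXct(timestamp, tz = "UTC")
  g <- as.numeric(glucose_mgdl)
  ord <- order(ts)
  ts <- ts[ord]
  g <- g[ord]
  x <- tibble::tibble(timestamp = ts, glucose_mgdl = g)
  x <- structure(x,
    patient_id = as.character(patient_id),
    nominal_interval = as.numeric(nominal_interval),
    tolerance = as.numeric(tolerance),
    class = c("cgm_trace", class(tibble::tibble()))
  )
  validate_cgm_trace(x)
}

validate_cgm_trace <- function(x) {
  g <- x$glucose_mgdl
  if (anyNA(g) || anyNA(x$timestamp)) {
    stop("CGM trace contains missing timestamps or glucose values")
  }
  bad <- g < 40 | g > 400
  if (any(bad)) {
    stop(sprintf(
      "glucose readings outside the sensor range [40, 400] mg/dl: %s",
      paste(utils::head(format(g[bad]), 5), collapse = ", ")
    ))
  }
  if (nrow(x) >= 2) {
    dd <- diff(as.numeric(x$timestamp))
    if (any(dd <= 0)) {
      stop("timestamps must be strictly increasing (duplicates rejected)")
    }
    min_gap <- attr(x, "nominal_interval") - attr(x, "tolerance")
    if (any(dd < min_gap)) {
      stop(sprintf(
        "consecutive readings closer than %g s violate the nominal sampling interval",
        min_gap
      ))
    }
  }
  x
}

#' @export
print.cgm_trace <- function(x, ...) {
  cat(sprintf(
    "<cgm_trace> patient %s: %d readings", attr(x, "patient_id"), nrow(x)
  ))
  if (nrow(x) > 0) {
    cat(sprintf(
      ", %s to %s", format(min(x$timestamp)), format(max(x$timestamp))
    ))
  }
  cat("\n")
  NextMethod()
}

#' Read a CGM trace from the canonical CSV format
#'
#' The canonical on-disk format is a CSV with header
#' `timestamp,glucose_mgdl`, ISO-8601 timestamps and glucose in mg/dl.
#' Rows are sorted by timestamp and validated (see [cgm_trace()]):
#' duplicated timestamps and glucose outside \[40, 400\] are errors.
#'
#' @param path path to the CSV file.
#' @param patient_id optional identifier; defaults to the file name.
#' @inheritParams cgm_trace
#' @return A [cgm_trace()].
#' @export
read_cgm_csv <- function(path, patient_id = NULL, nominal_interval = 300,
                         tolerance = 60) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (is.null(patient_id)) {
    patient_id <- sub("\\.csv$", "", basename(path))
  }
  df <- readr::read_csv(path,
    col_types = readr::cols(
      timestamp = readr::col_datetime(),
      glucose_mgdl = readr::col_double()
    ),
    progress = FALSE
  )
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    stop(sprintf(
      "malformed rows in %s (first at line %d)", path, probs$row[1]
    ))
  }
  if (!identical(names(df), c("timestamp", "glucose_mgdl"))) {
    stop("expected CSV header `timestamp,glucose_mgdl`")
  }
  cgm_trace(df$timestamp, df$glucose_mgdl,
    patient_id = patient_id,
    nominal_interval = nominal_interval, tolerance = tolerance
  )
}

#' Write a CGM trace to the canonical CSV format
#'
#' Round-trips exactly: `read_cgm_csv(write_cgm_csv(tr, f))` reproduces
#' `tr`'s timestamps and glucose values, gaps included. An empty trace
#' produces a header-only file.
#'
#' @param trace a [cgm_trace()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cgm_csv <- function(trace, path) {
  stopifnot(inherits(trace, "cgm_trace"))
  df <- tibble::tibble(
    timestamp = trace$timestamp,
    glucose_mgdl = trace$glucose_mgdl
  )
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Pair a training trace with a strictly later test trace
#'
#' @param train,test [cgm_trace()] objects; every test timestamp must be
#'   strictly after the last training timestamp, mirroring the
#'   chronological train/test protocol used for CGM forecasting
#'   benchmarks.
#' @return A list of class `patient_dataset` with elements `train` and
#'   `test`.
#' @export
patient_dataset <- function(train, test) {
  stopifnot(inherits(train, "cgm_trace"), inherits(test, "cgm_trace"))
  if (nrow(train) == 0 || nrow(test) == 0) {
    stop("both train and test traces must be non-empty")
  }
  if (max(train$timestamp) >= min(test$timestamp)) {
    stop("test data must occur strictly after training data")
  }
  structure(
    list(train = train, test = test),
    patient_id = attr(train, "patient_id"),
    class = "patient_dataset"
  )
}

#' @export
print.patient_dataset <- function(x, ...) {
  cat(sprintf(
    "<patient_dataset> %s: %d train / %d test readings\n",
    attr(x, "patient_id"), nrow(x$train), nrow(x$test)
  ))
  invisible(x)
}

#' Split a trace chronologically into train and test parts
#'
#' The split point is the reading with index
#' `floor((1 - test_fraction) * n)`: everything up to and including it is
#' training data, the remainder is test data. The default
#' `test_fraction = 0.25` mirrors the roughly six-week training /
#' two-week testing protocol of eight-week CGM studies.
#'
#' @param trace a [cgm_trace()] with at least 2 readings.
#' @param test_fraction fraction of readings reserved for testing,
#'   in (0, 1).
#' @return A [patient_dataset()].
#' @export
split_chronological <- function(trace, test_fraction = 0.25) {
  stopifnot(inherits(trace, "cgm_trace"))
  n <- nrow(trace)
  if (n < 2) stop("need at least 2 readings to split")
  if (!(test_fraction > 0 && test_fraction < 1)) {
    stop("`test_fraction` must be in (0, 1)")
  }
  k <- floor((1 - test_fraction) * n)
  if (k < 1 || k >= n) stop("split leaves an empty train or test side")
  patient_dataset(
    trace_slice(trace, seq_len(k)),
    trace_slice(trace, (k + 1):n)
  )
}

# rebuild a cgm_trace from a row subset, keeping attributes
trace_slice <- function(trace, idx) {
  cgm_trace(trace$timestamp[idx], trace$glucose_mgdl[idx],
    patient_id = attr(trace, "patient_id"),
    nominal_interval = attr(trace, "nominal_interval"),
    tolerance = attr(trace, "tolerance")
  )
}
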