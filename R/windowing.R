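#' Glycemic range thresholds
#'
#' Level-1 hypoglycemia and hyperglycemia thresholds. Readings strictly
#' below `hypo` are hypoglycemic, strictly above `hyper` hyperglycemic;
#' the boundary values 70 and 180 mg/dl themselves count as normal
#' (hypo means "< 70", hyper means "> 180").
#'
#' @param hypo hypoglycemia threshold in mg/dl (default 70).
#' @param hyper hyperglycemia threshold in mg/dl (default 180).
#' @return A list of class `glycemic_thresholds`.
#' @export
glycemic_thresholds <- function(hypo = 70, hyper = 180) {
  stopifnot(is.numeric(hypo), is.numeric(hyper), length(hypo) == 1,
            length(hyper) == 1)
  if (!(40 < hypo && hypo < hyper && hyper < 400)) {
    stop("thresholds must satisfy 40 < hypo < hyper < 400")
  }
  structure(list(hypo = hypo, hyper = hyper), class = "glycemic_thresholds")
}

pseudolabel_levels <- c("hypo", "normal", "hyper")

#' Discretize a glucose value into a glycemic pseudolabel
#'
#' Pseudolabels turn the regression target into a three-class label
#' (hypo / normal / hyper) so that classification-style oversamplers can
#' be applied; they are discarded again before the regressor is trained.
#'
#' @param bg glucose value(s) in mg/dl, each in \[40, 400\].
#' @param thresholds a [glycemic_thresholds()].
#' @return A factor with levels `hypo`, `normal`, `hyper`.
#' @export
assign_pseudolabel <- function(bg, thresholds = glycemic_thresholds()) {
  stopifnot(inherits(thresholds, "glycemic_thresholds"))
  if (any(!is.finite(bg)) || any(bg < 40 | bg > 400)) {
    stop("glucose values must lie in [40, 400] mg/dl")
  }
  lab <- ifelse(bg < thresholds$hypo, "hypo",
         ifelse(bg > thresholds$hyper, "hyper", "normal"))
  factor(lab, levels = pseudolabel_levels)
}

#' Build supervised windows from a CGM trace
#'
#' Slides a prediction window of `window_len` consecutive readings (120
#' minutes at the nominal 5-minute spacing) along the trace; the target is
#' the reading `horizon_steps` steps (30 minutes) after the window's last
#' reading. A window is emitted only when all `window_len + horizon_steps`
#' readings are consecutive within the trace's spacing tolerance, i.e. no
#' gap may fall inside the window nor between the window end and the
#' target. Incomplete windows are discarded, never imputed.
#'
#' @param trace a [cgm_trace()].
#' @param window_len number of feature readings per window (default 24).
#' @param horizon_steps readings between window end and target
#'   (default 6, i.e. 30 minutes).
#' @param stride window start increment in readings (default 1).
#' @param thresholds a [glycemic_thresholds()] used for the pseudolabels.
#' @return A tibble of class `windowed_dataset` with feature columns
#'   `x1..x<window_len>` (oldest to newest), `target`, `pseudolabel` and
#'   `end_time`. An unproductive trace yields zero rows.
#' @export
build_windows <- function(trace, window_len = 24, horizon_steps = 6,
                          stride = 1, thresholds = glycemic_thresholds()) {
  stopifnot(inherits(trace, "cgm_trace"), window_len >= 1,
            horizon_steps >= 1, stride >= 1)
  n <- nrow(trace)
  span <- window_len + horizon_steps
  g <- trace$glucose_mgdl
  ts <- as.numeric(trace$timestamp)
  nominal <- attr(trace, "nominal_interval")
  tol <- attr(trace, "tolerance")

  starts <- integer(0)
  if (n >= span) {
    contiguous <- abs(diff(ts) - nominal) <= tol
    run_id <- cumsum(c(0L, as.integer(!contiguous)))
    for (r in split(seq_len(n), run_id)) {
      len <- length(r)
      if (len >= span) {
        starts <- c(starts, r[seq(1L, len - span + 1L, by = stride)])
      }
    }
  }

  if (length(starts) == 0) {
    X <- matrix(numeric(0), nrow = 0, ncol = window_len)
    target <- numeric(0)
    end_time <- trace$timestamp[0]
  } else {
    idx <- outer(starts, 0:(window_len - 1), "+")
    X <- matrix(g[idx], nrow = length(starts), ncol = window_len)
    target <- g[starts + span - 1L]
    end_time <- trace$timestamp[starts + window_len - 1L]
  }
  windowed_dataset(X, target,
    end_time = end_time,
    thresholds = thresholds,
    patient_id = attr(trace, "patient_id")
  )
}

#' Construct a windowed dataset from a feature matrix and targets
#'
#' Low-level constructor used by [build_windows()] and by the
#' oversamplers; also convenient for building small datasets directly in
#' examples and tests. The pseudolabel of each row is derived from its
#' target unless supplied.
#'
#' @param features numeric matrix, one window per row, values in
#'   \[40, 400\] mg/dl, columns ordered oldest to newest.
#' @param target numeric vector of 30-minute-ahead glucose values.
#' @param pseudolabel optional factor; defaults to
#'   [assign_pseudolabel()] of `target`.
#' @param end_time optional POSIXct of window end times.
#' @param thresholds a [glycemic_thresholds()].
#' @param patient_id identifier carried along.
#' @return A tibble of class `windowed_dataset`.
#' @export
windowed_dataset <- function(features, target, pseudolabel = NULL,
                             end_time = NULL,
                             thresholds = glycemic_thresholds(),
                             patient_id = NA_character_) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(target))
  if (nrow(features) > 0 &&
      (any(features < 40) || any(features > 400))) {
    stop("window features must lie in [40, 400] mg/dl")
  }
  if (is.null(pseudolabel)) {
    pseudolabel <- assign_pseudolabel(target, thresholds)
  } else {
    pseudolabel <- factor(pseudolabel, levels = pseudolabel_levels)
  }
  if (is.null(end_time)) {
    end_time <- as.POSIXct(rep(NA_real_, length(target)), tz = "UTC")
  }
  colnames(features) <- paste0("x", seq_len(ncol(features)))
  out <- tibble::as_tibble(features)
  out$target <- as.numeric(target)
  out$pseudolabel <- pseudolabel
  out$end_time <- end_time
  structure(out,
    thresholds = thresholds,
    patient_id = as.character(patient_id),
    window_len = ncol(features),
    class = c("windowed_dataset", class(tibble::tibble()))
  )
}

#' Extract the feature matrix of a windowed dataset
#'
#' @param ds a [windowed_dataset()].
#' @return Numeric matrix with one row per window.
#' @export
window_features <- function(ds) {
  stopifnot(inherits(ds, "windowed_dataset"))
  wl <- attr(ds, "window_len")
  as.matrix(ds[, paste0("x", seq_len(wl)), drop = FALSE])
}

# row subset keeping class and attributes
windows_slice <- function(ds, idx) {
  windowed_dataset(window_features(ds)[idx, , drop = FALSE],
    ds$target[idx],
    pseudolabel = ds$pseudolabel[idx],
    end_time = ds$end_time[idx],
    thresholds = attr(ds, "thresholds"),
    patient_id = attr(ds, "patient_id")
  )
}

#' @export
print.windowed_dataset <- function(x, ...) {
  cnt <- table(x$pseudolabel)
  cat(sprintf(
    "<windowed_dataset> patient %s: %d windows (%s)\n",
    attr(x, "patient_id"), nrow(x),
    paste(sprintf("%s %d", names(cnt), cnt), collapse = ", ")
  ))
  invisible(x)
}

#' Degree-2 polynomial feature expansion
#'
#' Expands `d` features into `d + d(d+1)/2` features: the linear terms in
#' index order, then the squares in index order, then the pairwise
#' products `x_i * x_j` for `i < j` in lexicographic order. The intercept
#' is not included; it is handled by the downstream learner. Used for the
#' sparse linear models (Lasso and linear SVR), which need the quadratic
#' terms to capture non-linear glucose dynamics.
#'
#' @param x numeric vector of length `d`, or a matrix whose rows are
#'   expanded independently.
#' @return A vector of length `d + d(d+1)/2`, or a matrix with that many
#'   columns.
#' @examples
#' expand_polynomial(c(2, 3)) # 2 3 4 9 6
#' @export
expand_polynomial <- function(x) {
  if (is.matrix(x)) {
    d <- ncol(x)
    stopifnot(d >= 1)
    out <- cbind(x, x^2)
    if (d >= 2) {
      pairs <- utils::combn(d, 2)
      out <- cbind(out, x[, pairs[1, ], drop = FALSE] *
                        x[, pairs[2, ], drop = FALSE])
    }
    colnames(out) <- NULL
    out
  } else {
    as.vector(expand_polynomial(matrix(x, nrow = 1)))
  }
}

#' Feature-wise standardization fitted on training data
#'
#' Centers and scales each column of `apply_x` with the mean and
#' (population) standard deviation of the corresponding `train_x` column,
#' as is done before every learner in the benchmark pipeline.
#' Zero-variance columns are divided by 1, so constant features are
#' centered but never produce division by zero.
#'
#' @param train_x numeric matrix the statistics are fitted on.
#' @param apply_x numeric matrix to transform (defaults to `train_x`).
#' @return A list with `x` (the standardized `apply_x`), `mean` and `sd`.
#' @export
standardize <- function(train_x, apply_x = train_x) {
  train_x <- as.matrix(train_x)
  apply_x <- as.matrix(apply_x)
  if (nrow(train_x) == 0) stop("`train_x` must be non-empty")
  if (ncol(train_x) != ncol(apply_x)) {
    stop("`train_x` and `apply_x` must have the same columns")
  }
  st <- fit_standardizer(train_x)
  list(x = apply_standardizer(st, apply_x), mean = st$mean, sd = st$sd)
}

fit_standardizer <- function(x) {
  m <- colMeans(x)
  # population sd, matching the usual ML-pipeline scaler
  s <- sqrt(colMeans(sweep(x, 2, m)^2))
  s[!is.finite(s) | s == 0] <- 1
  list(mean = m, sd = s)
}

apply_standardizer <- function(st, x) {
  sweep(sweep(x, 2, st$mean), 2, st$sd, "/")
}
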