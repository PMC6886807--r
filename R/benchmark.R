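# deterministic fan-out of one master seed into per-task sub-seeds,
# kept inside 32-bit integer range
derive_seed <- function(master, ...) {
  idx <- c(...)
  s <- (abs(as.numeric(master)) %% 1000003) * 8191 + 1
  for (i in seq_along(idx)) {
    s <- (s * 48271 + idx[i] * 1009 + i * 97) %% 2147483647
  }
  as.integer(s %% 2147483646) + 1L
}

#' Windowize one patient's train and test traces
#'
#' Produces exactly the windowed datasets a benchmark cell trains and
#' evaluates on: the training trace is windowized and, when it exceeds
#' `control$max_train_windows`, reduced to a seeded subsample (order
#' preserved). Exposed so that analytic reference values — e.g. the
#' constant-mean MARD of the dummy baseline — can be recomputed from the
#' identical inputs.
#'
#' @param data a [patient_dataset()].
#' @param seed integer cell seed.
#' @param control a [benchmark_control()].
#' @param thresholds a [glycemic_thresholds()].
#' @return A list with `train` and `test` [windowed_dataset()]s.
#' @export
experiment_windows <- function(data, seed,
                               control = benchmark_control(),
                               thresholds = glycemic_thresholds()) {
  stopifnot(inherits(data, "patient_dataset"))
  train_w <- build_windows(data$train, thresholds = thresholds)
  test_w <- build_windows(data$test, thresholds = thresholds)
  cap <- control$max_train_windows
  if (is.finite(cap) && nrow(train_w) > cap) {
    keep <- withr::with_seed(derive_seed(seed, 1),
                             sort(sample.int(nrow(train_w), cap)))
    train_w <- windows_slice(train_w, keep)
  }
  list(train = train_w, test = test_w)
}

#' Run one model/oversampler combination on one patient
#'
#' The full evaluation pipeline for a single benchmark cell: windowize
#' the training trace, oversample the training windows only, train the
#' model on features and targets (pseudolabels are discarded), predict
#' on the windowized test trace, and score with range-partitioned MARD
#' and Clarke EGA. All randomness (subsampling, oversampler, learner) is
#' derived deterministically from `seed`.
#'
#' @param data a [patient_dataset()].
#' @param spec a [model_spec()].
#' @param oversampler `"none"`, `"random"`, `"smote"` or `"adasyn"`.
#' @param seed integer cell seed.
#' @param control a [benchmark_control()].
#' @param thresholds a [glycemic_thresholds()].
#' @return A list with `mard` ([mard_by_range()] report), `ega`
#'   ([ega_report()]), `n_train` and `n_test`.
#' @export
run_experiment <- function(data, spec,
                           oversampler = c("none", "random", "smote",
                                           "adasyn"),
                           seed = 1, control = benchmark_control(),
                           thresholds = glycemic_thresholds()) {
  oversampler <- match.arg(oversampler)
  w <- experiment_windows(data, seed, control, thresholds)
  if (nrow(w$train) == 0) stop("no training windows")
  if (nrow(w$test) == 0) stop("no test windows")
  train_ds <- oversample(w$train, method = oversampler,
                         seed = derive_seed(seed, 2))
  spec$seed <- derive_seed(seed, 3)
  model <- glyco_train(spec, window_features(train_ds), train_ds$target,
                       control = control)
  pred <- predict(model, window_features(w$test))
  pred <- pmax(pred, 1) # metric domain: predictions must stay positive
  list(
    mard = mard_by_range(pred, w$test$target, thresholds),
    ega = ega_report(pred, w$test$target),
    n_train = nrow(train_ds),
    n_test = nrow(w$test)
  )
}

oversampler_names <- c("none", "random", "smote", "adasyn")

#' Run the full model x oversampler x patient grid
#'
#' Evaluates every combination of the registered models and oversampling
#' options on every patient (10 models x 4 oversamplers x n patients
#' cells; 240 for the canonical six-patient cohort). Each cell gets its
#' own sub-seed derived from the master seed, so cells are independent
#' of grid iteration order and can be re-run in isolation. Per-cell
#' failures are recorded in the `error` column and the grid continues.
#'
#' @param patients a list of [patient_dataset()]s or a
#'   [simulate_cohort()] result.
#' @param seed master integer seed.
#' @param models named list of [model_spec()]s
#'   (default [model_registry()]).
#' @param oversamplers character subset of
#'   `c("none", "random", "smote", "adasyn")`.
#' @param control a [benchmark_control()].
#' @param thresholds a [glycemic_thresholds()].
#' @return A tibble of class `glyco_result_table` with one row per cell:
#'   identifiers, the four MARD values and counts, the five EGA
#'   percentages, and `error` (`NA` on success). Undefined range metrics
#'   are `NA`.
#' @export
run_grid <- function(patients, seed = 1, models = model_registry(),
                     oversamplers = oversampler_names,
                     control = benchmark_control(),
                     thresholds = glycemic_thresholds()) {
  if (inherits(patients, "sim_cohort")) patients <- patients$patients
  stopifnot(length(patients) >= 1)
  oversamplers <- match.arg(oversamplers, oversampler_names,
                            several.ok = TRUE)
  rows <- list()
  for (pi in seq_along(patients)) {
    pd <- patients[[pi]]
    pid <- attr(pd, "patient_id")
    if (is.null(pid) || is.na(pid)) pid <- sprintf("patient-%02d", pi)
    for (mi in seq_along(models)) {
      for (oi in seq_along(oversamplers)) {
        spec <- models[[mi]]
        cell_seed <- derive_seed(seed, pi, mi, oi)
        res <- tryCatch(
          run_experiment(pd, spec, oversamplers[oi], seed = cell_seed,
                         control = control, thresholds = thresholds),
          error = function(e) e
        )
        if (inherits(res, "error")) {
          row <- tibble::tibble(
            patient_id = pid, model = spec$name,
            oversampler = oversamplers[oi],
            mard_all = NA_real_, mard_hypo = NA_real_,
            mard_norm = NA_real_, mard_hyper = NA_real_,
            n_all = NA_integer_, n_hypo = NA_integer_,
            n_norm = NA_integer_, n_hyper = NA_integer_,
            pct_A = NA_real_, pct_B = NA_real_, pct_C = NA_real_,
            pct_D = NA_real_, pct_E = NA_real_,
            error = conditionMessage(res)
          )
        } else {
          m <- res$mard
          row <- tibble::tibble(
            patient_id = pid, model = spec$name,
            oversampler = oversamplers[oi],
            mard_all = m$mard_all, mard_hypo = m$mard_hypo,
            mard_norm = m$mard_norm, mard_hyper = m$mard_hyper,
            n_all = m$n_all, n_hypo = m$n_hypo, n_norm = m$n_norm,
            n_hyper = m$n_hyper,
            pct_A = res$ega$pct[["A"]], pct_B = res$ega$pct[["B"]],
            pct_C = res$ega$pct[["C"]], pct_D = res$ega$pct[["D"]],
            pct_E = res$ega$pct[["E"]],
            error = NA_character_
          )
        }
        rows[[length(rows) + 1]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("glyco_result_table", class(out))
  out
}

benchmark_metrics <- c("mard_all", "mard_hypo", "mard_norm", "mard_hyper",
                       "pct_A", "pct_B", "pct_C", "pct_D", "pct_E")

# TRUE when larger metric values are better (only EGA zone A)
metric_higher_better <- function(metric) {
  metric <- match.arg(metric, benchmark_metrics)
  identical(metric, "pct_A")
}

combo_label <- function(model, oversampler) {
  paste(model, oversampler, sep = "+")
}

#' Rank model/oversampler combinations on one metric
#'
#' Averages the metric across patients for every combination and sorts
#' best-first (ascending for the MARD variants and EGA zones B-E,
#' descending for EGA zone A). Patients where a combination's metric is
#' undefined are excluded from that combination's mean, with the number
#' of contributing patients reported. Equal means keep a stable order by
#' combination label. EGA zones C and E can be ranked but are poor
#' selection criteria on their own: a constant predictor trivially
#' scores zero in them.
#'
#' @param table a `glyco_result_table` from [run_grid()].
#' @param metric one of `mard_all`, `mard_hypo`, `mard_norm`,
#'   `mard_hyper`, `pct_A` .. `pct_E`.
#' @param top_n rows to return (default 5; `Inf` for all).
#' @return A tibble with `combination`, `model`, `oversampler`, `mean`
#'   and `n_patients`, best combination first.
#' @export
rank_combinations <- function(table, metric, top_n = 5) {
  metric <- match.arg(metric, benchmark_metrics)
  combos <- unique(table[, c("model", "oversampler")])
  vals <- table[[metric]]
  out <- lapply(seq_len(nrow(combos)), function(i) {
    sel <- table$model == combos$model[i] &
      table$oversampler == combos$oversampler[i]
    v <- vals[sel]
    tibble::tibble(
      combination = combo_label(combos$model[i], combos$oversampler[i]),
      model = combos$model[i], oversampler = combos$oversampler[i],
      mean = if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE),
      n_patients = sum(!is.na(v))
    )
  })
  out <- do.call(rbind, out)
  out <- out[!is.na(out$mean), , drop = FALSE]
  if (nrow(out) == 0) stop(sprintf("metric '%s' undefined everywhere", metric))
  ord <- order(if (metric_higher_better(metric)) -out$mean else out$mean,
               out$combination)
  out <- out[ord, , drop = FALSE]
  utils::head(out, top_n)
}

#' Within-patient rank matrix of all combinations
#'
#' Ranks every model/oversampler combination within each patient on one
#' metric (rank 1 = best in that patient, direction-aware, average ranks
#' on ties; undefined values stay `NA`). This is the block design the
#' Friedman and Nemenyi tests operate on: combinations are treatments,
#' patients are blocks.
#'
#' @inheritParams rank_combinations
#' @return A numeric matrix, combinations x patients.
#' @export
rank_matrix <- function(table, metric) {
  metric <- match.arg(metric, benchmark_metrics)
  combos <- unique(combo_label(table$model, table$oversampler))
  patients <- unique(table$patient_id)
  m <- matrix(NA_real_, length(combos), length(patients),
              dimnames = list(combos, patients))
  lab <- combo_label(table$model, table$oversampler)
  for (j in seq_along(patients)) {
    sel <- table$patient_id == patients[j]
    v <- table[[metric]][sel]
    if (metric_higher_better(metric)) v <- -v
    ok <- !is.na(v)
    r <- rep(NA_real_, length(v))
    r[ok] <- rank(v[ok], ties.method = "average")
    m[lab[sel], j] <- r
  }
  m
}

#' Friedman rank test across patients
#'
#' Omnibus test of whether all combinations perform the same across
#' patients, computed from a within-block rank matrix with the
#' chi-square approximation on k − 1 degrees of freedom and the standard
#' tie correction. Columns containing missing ranks are dropped (the
#' test needs complete blocks).
#'
#' @param ranks a combinations x patients rank matrix from
#'   [rank_matrix()].
#' @return A list with `statistic`, `df`, `p.value`, `k` (treatments)
#'   and `n` (blocks used).
#' @export
friedman_rank_test <- function(ranks) {
  ranks <- as.matrix(ranks)
  complete <- colSums(is.na(ranks)) == 0
  ranks <- ranks[, complete, drop = FALSE]
  k <- nrow(ranks); n <- ncol(ranks)
  if (k < 2 || n < 2) stop("need at least 2 treatments and 2 complete blocks")
  R <- rowSums(ranks)
  tie_term <- sum(apply(ranks, 2, function(col) {
    t <- table(col)
    sum(t^3 - t)
  }))
  C <- 1 - tie_term / (n * (k^3 - k))
  num <- 12 * sum((R - n * (k + 1) / 2)^2) / (n * k * (k + 1))
  if (C <= 0) {
    warning("all treatments tied in every block; statistic degenerate")
    stat <- 0
  } else {
    stat <- num / C
  }
  list(
    statistic = stat, df = k - 1,
    p.value = stats::pchisq(stat, df = k - 1, lower.tail = FALSE),
    k = k, n = n
  )
}

#' Nemenyi post-hoc pairwise comparisons
#'
#' All-pairs comparison of mean ranks after a Friedman test, using the
#' studentized-range critical-difference formulation: the p-value for a
#' pair is the upper tail of the studentized range distribution (with
#' infinite degrees of freedom) at the standardized mean-rank
#' difference. With few blocks (patients) this test has little power
#' even when mean differences are large.
#'
#' @inheritParams friedman_rank_test
#' @return A symmetric k x k matrix of p-values with unit diagonal.
#' @export
nemenyi_posthoc <- function(ranks) {
  ranks <- as.matrix(ranks)
  complete <- colSums(is.na(ranks)) == 0
  ranks <- ranks[, complete, drop = FALSE]
  k <- nrow(ranks); n <- ncol(ranks)
  if (k < 2 || n < 2) stop("need at least 2 treatments and 2 complete blocks")
  rbar <- rowMeans(ranks)
  se <- sqrt(k * (k + 1) / (6 * n))
  q <- abs(outer(rbar, rbar, "-")) / se * sqrt(2)
  p <- 1 - stats::ptukey(q, nmeans = k, df = Inf)
  diag(p) <- 1
  dimnames(p) <- list(rownames(ranks), rownames(ranks))
  pmin(pmax(p, 0), 1)
}

#' Paired t-test between two combinations on one metric
#'
#' Two-sided paired t-test of the per-patient metric values of two
#' combinations. Patients where either value is undefined are dropped
#' (the number dropped is reported). A zero-variance difference vector
#' is degenerate and returns p = 1 with a warning.
#'
#' @inheritParams rank_combinations
#' @param combo_a,combo_b combination labels `"model+oversampler"`.
#' @return A list with `p.value`, `mean_a`, `mean_b`, `n_pairs` and
#'   `n_dropped`.
#' @export
paired_t_metric <- function(table, combo_a, combo_b, metric) {
  metric <- match.arg(metric, benchmark_metrics)
  lab <- combo_label(table$model, table$oversampler)
  patients <- unique(table$patient_id)
  get_vals <- function(combo) {
    vapply(patients, function(p) {
      v <- table[[metric]][lab == combo & table$patient_id == p]
      if (length(v) != 1) NA_real_ else v
    }, numeric(1))
  }
  va <- get_vals(combo_a)
  vb <- get_vals(combo_b)
  ok <- !is.na(va) & !is.na(vb)
  if (sum(ok) < 2) stop("fewer than 2 complete pairs")
  d <- va[ok] - vb[ok]
  if (stats::sd(d) < 1e-12) {
    warning("zero-variance paired differences; p-value degenerate")
    p <- 1
  } else {
    p <- stats::t.test(va[ok], vb[ok], paired = TRUE)$p.value
  }
  list(
    p.value = p, mean_a = mean(va[ok]), mean_b = mean(vb[ok]),
    n_pairs = sum(ok), n_dropped = sum(!ok)
  )
}
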