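# Fixture builders shared across the suite. Everything is generated in
# code; no data files.

t0 <- as.POSIXct("2022-03-01 00:00:00", tz = "UTC")

# contiguous 5-min trace with the given glucose values
make_trace <- function(values, start = t0, patient_id = "test") {
  cgm_trace(start + 300 * (seq_along(values) - 1), values,
            patient_id = patient_id)
}

# trace with gaps: `segments` is a list of glucose vectors; consecutive
# segments are separated by `gap_mins` minutes of missing data
make_gappy_trace <- function(segments, gap_mins = 40, start = t0) {
  ts <- list()
  cur <- start
  for (seg in segments) {
    ts[[length(ts) + 1]] <- cur + 300 * (seq_along(seg) - 1)
    cur <- cur + 300 * (length(seg) - 1) + gap_mins * 60
  }
  cgm_trace(do.call(c, ts), unlist(segments), patient_id = "gappy")
}

# random trace with random gap pattern, for property tests
random_gappy_trace <- function(n, gap_prob = 0.05) {
  steps <- rep(300, n - 1)
  gaps <- runif(n - 1) < gap_prob
  steps[gaps] <- 300 * sample(2:30, sum(gaps), replace = TRUE)
  ts <- t0 + c(0, cumsum(steps))
  cgm_trace(ts, runif(n, 40, 400), patient_id = "rand")
}

# brute-force windowing oracle: check every start position directly
oracle_windows <- function(trace, window_len = 24, horizon_steps = 6) {
  n <- nrow(trace)
  span <- window_len + horizon_steps
  ts <- as.numeric(trace$timestamp)
  nominal <- attr(trace, "nominal_interval")
  tol <- attr(trace, "tolerance")
  starts <- integer(0)
  if (n >= span) {
    for (s in 1:(n - span + 1)) {
      dd <- diff(ts[s:(s + span - 1)])
      if (all(abs(dd - nominal) <= tol)) starts <- c(starts, s)
    }
  }
  starts
}

# small imbalanced windowed dataset with controllable class counts
make_imbalanced_windows <- function(n_hypo, n_norm, n_hyper, d = 24) {
  n <- n_hypo + n_norm + n_hyper
  target <- c(runif(n_hypo, 41, 69), runif(n_norm, 75, 175),
              runif(n_hyper, 185, 395))
  # features loosely correlated with the target so classes cluster
  X <- matrix(pmin(400, pmax(40, rep(target, d) + rnorm(n * d, 0, 15))),
              nrow = n, ncol = d)
  windowed_dataset(X, target, patient_id = "imb")
}

# independently coded Clarke-grid oracle: scalar, rule-by-rule, with an
# explicit precedence walk (vs the vectorized production version)
oracle_ega_zone <- function(a, p) {
  in_zone_a <- function(a, p) {
    if (a < 70 && p < 70) return(TRUE)
    abs(p - a) <= 0.2 * a
  }
  in_zone_e <- function(a, p) {
    (a <= 70 && p >= 180) || (a >= 180 && p <= 70)
  }
  in_zone_c <- function(a, p) {
    if (a >= 70 && a <= 290 && p >= a + 110) return(TRUE)
    a >= 130 && a <= 180 && p <= (7 / 5) * a - 182
  }
  in_zone_d <- function(a, p) {
    if (a >= 240 && p >= 70 && p <= 180) return(TRUE)
    if (a <= 175 / 3 && p >= 70 && p <= 180) return(TRUE)
    a >= 175 / 3 && a <= 70 && p >= (6 / 5) * a
  }
  if (in_zone_a(a, p)) "A"
  else if (in_zone_e(a, p)) "E"
  else if (in_zone_c(a, p)) "C"
  else if (in_zone_d(a, p)) "D"
  else "B"
}
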