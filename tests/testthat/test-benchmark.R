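# build a result table directly from a matrix of metric values
# (combinations x patients), for testing the ranking/statistics layer
table_from_values <- function(values, metric = "mard_all") {
  combos <- expand.grid(
    model = paste0("m", seq_len(nrow(values))),
    oversampler = "none", stringsAsFactors = FALSE
  )
  rows <- list()
  for (j in seq_len(ncol(values))) {
    for (i in seq_len(nrow(values))) {
      row <- tibble::tibble(
        patient_id = paste0("p", j), model = combos$model[i],
        oversampler = "none",
        mard_all = NA_real_, mard_hypo = NA_real_, mard_norm = NA_real_,
        mard_hyper = NA_real_, n_all = 10L, n_hypo = 1L, n_norm = 8L,
        n_hyper = 1L, pct_A = NA_real_, pct_B = NA_real_,
        pct_C = NA_real_, pct_D = NA_real_, pct_E = NA_real_,
        error = NA_character_
      )
      row[[metric]] <- values[i, j]
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("glyco_result_table", class(out))
  out
}

test_that("Friedman statistic matches the closed form and friedman.test", {
  # textbook 3-treatment x 4-block example, no ties
  vals <- matrix(c(
    1, 3, 2,
    1, 3, 2,
    2, 3, 1,
    1, 2, 3
  ), nrow = 3) # treatments x blocks (each column already a permutation)
  ranks <- vals
  ft <- friedman_rank_test(ranks)
  k <- 3; n <- 4
  Rj <- rowSums(ranks)
  chi2 <- 12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
  expect_equal(ft$statistic, chi2, tolerance = 1e-12)
  expect_equal(ft$df, 2)
  expect_equal(ft$p.value, pchisq(chi2, 2, lower.tail = FALSE))

  # random value matrices against stats::friedman.test (with ties)
  withr::with_seed(41, {
    for (i in 1:10) {
      k <- sample(3:8, 1); n <- sample(3:8, 1)
      y <- matrix(sample(1:5, k * n, replace = TRUE) + rnorm(k * n, 0, 0.1),
                  nrow = k)
      ranks <- apply(y, 2, rank)
      ours <- friedman_rank_test(ranks)
      ref <- stats::friedman.test(t(y))
      expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-9)
      expect_equal(ours$p.value, unname(ref$p.value), tolerance = 1e-9)
    }
  })
})

test_that("Friedman test is exchangeable over blocks and degenerate on ties", {
  withr::with_seed(42, {
    y <- matrix(rnorm(5 * 6), 5, 6)
    ranks <- apply(y, 2, rank)
    base <- friedman_rank_test(ranks)
    perm <- friedman_rank_test(ranks[, sample(6)])
    expect_equal(base$statistic, perm$statistic)
  })
  # identical performance everywhere: all ranks tied
  tied <- matrix(2, 3, 4)
  expect_warning(ft <- friedman_rank_test(tied), "degenerate")
  expect_equal(ft$statistic, 0)
  expect_equal(ft$p.value, 1)
})

test_that("Nemenyi p-values are symmetric, unit-diagonal and tie-blind", {
  tied <- matrix(2, 3, 4)
  p <- nemenyi_posthoc(tied)
  expect_true(all(abs(p - 1) < 1e-12))

  withr::with_seed(43, {
    ranks <- apply(matrix(rnorm(6 * 5), 6, 5), 2, rank)
    p <- nemenyi_posthoc(ranks)
    expect_equal(p, t(p), tolerance = 1e-12)
    expect_true(all(diag(p) == 1))
    expect_true(all(p >= 0 & p <= 1))
  })
})

test_that("few blocks starve the Nemenyi test of power", {
  # 40 combinations over only 6 patient blocks: the omnibus Friedman
  # test detects graded mean differences, yet the Nemenyi post-hoc
  # cannot isolate a single significant pair
  withr::with_seed(47, {
    means <- seq(0, 0.75, length.out = 40)
    vals <- matrix(rnorm(40 * 6, mean = means, sd = 1), 40, 6)
    ranks <- apply(vals, 2, rank)
    expect_lt(friedman_rank_test(ranks)$p.value, 0.05)
    p <- nemenyi_posthoc(ranks)
    expect_gt(min(p[upper.tri(p)]), 0.05)
  })
})

test_that("paired t-tests match the textbook formula and guard ties", {
  withr::with_seed(45, {
    va <- rnorm(6, 10, 2)
    vb <- rnorm(6, 11, 2)
    tab <- table_from_values(rbind(va, vb))
    res <- paired_t_metric(tab, "m1+none", "m2+none", "mard_all")
    d <- va - vb
    tstat <- mean(d) / (sd(d) / sqrt(length(d)))
    p_ref <- 2 * pt(-abs(tstat), df = length(d) - 1)
    expect_equal(res$p.value, p_ref, tolerance = 1e-9)
    expect_equal(res$n_pairs, 6)
  })

  # constant differences have zero variance: degenerate, p = 1
  tab <- table_from_values(rbind(1:6, 2:7))
  expect_warning(
    res <- paired_t_metric(tab, "m1+none", "m2+none", "mard_all"),
    "zero-variance"
  )
  expect_equal(res$p.value, 1)

  tab1 <- table_from_values(matrix(c(1, 2), 2, 1))
  expect_error(paired_t_metric(tab1, "m1+none", "m2+none", "mard_all"),
               "fewer than 2")
})

test_that("combination ranking averages across patients, direction-aware", {
  withr::with_seed(46, {
    vals <- matrix(runif(8 * 5, 5, 20), 8, 5)
    vals[3, ] <- 1 # dominates every patient on a lower-better metric
    tab <- table_from_values(vals)
    rk <- rank_combinations(tab, "mard_all", top_n = Inf)
    expect_equal(rk$combination[1], "m3+none")
    # means equal brute-force row means
    for (i in seq_len(nrow(rk))) {
      row <- as.integer(sub("^m(\\d+)\\+none$", "\\1", rk$combination[i]))
      expect_equal(rk$mean[i], mean(vals[row, ]))
    }
    # higher-better metric flips the direction
    tabA <- table_from_values(vals, metric = "pct_A")
    rkA <- rank_combinations(tabA, "pct_A", top_n = Inf)
    expect_equal(rkA$combination[1],
                 paste0("m", which.max(rowMeans(vals)), "+none"))
  })

  # exact ties keep a stable order by combination label
  tie <- table_from_values(matrix(c(5, 5, 7), 3, 1))
  rk <- rank_combinations(tie, "mard_all")
  expect_equal(rk$combination, c("m1+none", "m2+none", "m3+none"))

  # undefined values are excluded from means, with counts reported
  vals <- matrix(c(10, NA, 10, 20, NA, 30), 2, 3)
  tab <- table_from_values(vals)
  rk <- rank_combinations(tab, "mard_all", top_n = Inf)
  expect_equal(rk$n_patients[rk$combination == "m1+none"], 2)
  expect_equal(rk$mean[rk$combination == "m1+none"], 10)

  # affine rescaling applied to all combinations leaves the order fixed
  withr::with_seed(47, vals <- matrix(runif(6 * 4), 6, 4))
  o1 <- rank_combinations(table_from_values(vals), "mard_all", Inf)$combination
  o2 <- rank_combinations(table_from_values(3 * vals + 2), "mard_all",
                          Inf)$combination
  expect_equal(o1, o2)
})

test_that("rank matrices rank within patients with average ties", {
  vals <- matrix(c(
    10, 20, 20, 30,
    10, 10, 10, 10
  ), nrow = 4)
  tab <- table_from_values(vals)
  rm <- rank_matrix(tab, "mard_all")
  expect_equal(unname(rm[, 1]), c(1, 2.5, 2.5, 4))
  expect_equal(unname(rm[, 2]), c(2.5, 2.5, 2.5, 2.5))
})

test_that("a single experiment is deterministic and reproduces the dummy analytically", {
  pd <- simulate_patient(sim_config(days = 6), seed = 77)
  ctl <- benchmark_control(max_train_windows = 600)
  res <- run_experiment(pd, model_spec("dummy"), "none", seed = 5,
                        control = ctl)
  w <- experiment_windows(pd, seed = 5, control = ctl)
  analytic <- mard(rep(mean(w$train$target), nrow(w$test)), w$test$target)
  expect_equal(res$mard$mard_all, analytic, tolerance = 1e-12)

  res2 <- run_experiment(pd, model_spec("dummy"), "none", seed = 5,
                         control = ctl)
  expect_identical(res$mard, res2$mard)

  # oversampler "none" leaves training windows bit-identical
  w2 <- experiment_windows(pd, seed = 5, control = ctl)
  expect_identical(w$train, w2$train)
})

test_that("a small grid has one isolated cell per combination", {
  cohort <- simulate_cohort(1, sim_config(days = 6), seed = 88)
  models <- model_registry(seed = 1)[c("dummy", "knn")]
  ctl <- benchmark_control(max_train_windows = 500)
  tab <- run_grid(cohort, seed = 9, models = models,
                  oversamplers = c("none", "random"), control = ctl)
  expect_equal(nrow(tab), 1 * 2 * 2)
  expect_true(all(is.na(tab$error)))

  # cells are independent of grid composition: the dummy+none cell run
  # inside a different grid subset is identical
  tab2 <- run_grid(cohort, seed = 9, models = models["dummy"],
                   oversamplers = "none", control = ctl)
  a <- tab[tab$model == "dummy" & tab$oversampler == "none", ]
  expect_equal(a$mard_all, tab2$mard_all[1])
  expect_equal(a$pct_A, tab2$pct_A[1])
})
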