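test_that("the oversampling plan fills every class up to the majority", {
  withr::with_seed(1, {
    ds <- make_imbalanced_windows(2, 10, 5)
    plan <- make_plan(ds)
    expect_equal(plan$majority_class, "normal")
    expect_equal(plan$deficit,
                 c(hypo = 8L, normal = 0L, hyper = 5L))

    bal <- make_imbalanced_windows(4, 4, 4)
    expect_true(all(make_plan(bal)$deficit == 0))

    none <- make_imbalanced_windows(0, 10, 3)
    expect_warning(plan0 <- make_plan(none), "cannot be oversampled")
    expect_equal(plan0$deficit[["hypo"]], 0L)
    expect_equal(plan0$deficit[["hyper"]], 7L)
  })
})

test_that("random oversampling duplicates own-class rows to balance", {
  withr::with_seed(2, ds <- make_imbalanced_windows(2, 10, 5))
  out <- oversample_random(ds, seed = 7)
  expect_equal(unname(table(out$pseudolabel)["hypo"]), 10,
               ignore_attr = TRUE)
  expect_true(all(table(out$pseudolabel) == 10))

  # each added row is an exact copy of an original row of its class
  X0 <- window_features(ds)
  Xa <- window_features(out)
  prov <- attr(out, "provenance")
  added <- (nrow(ds) + 1):nrow(out)
  for (i in seq_along(added)) {
    src <- prov$parent_i[i]
    expect_identical(Xa[added[i], ], X0[src, ])
    expect_identical(out$target[added[i]], ds$target[src])
    expect_identical(as.character(out$pseudolabel[added[i]]), prov$class[i])
  }

  # determinism contract
  expect_identical(oversample_random(ds, seed = 7), out)
  out2 <- oversample_random(ds, seed = 8)
  expect_false(identical(out$target, out2$target))

  # balanced input passes through unchanged
  withr::with_seed(3, bal <- make_imbalanced_windows(5, 5, 5))
  same <- oversample_random(bal, seed = 1)
  expect_equal(nrow(same), nrow(bal))
  expect_equal(same$target, bal$target)
})

test_that("SMOTE synthesizes features and target with one shared lambda", {
  withr::with_seed(4, ds <- make_imbalanced_windows(4, 12, 6))
  out <- oversample_smote(ds, k = 3, seed = 11)
  expect_true(all(table(out$pseudolabel) == 12))

  X0 <- window_features(ds)
  Xa <- window_features(out)
  prov <- attr(out, "provenance")
  added <- (nrow(ds) + 1):nrow(out)
  expect_equal(length(added), nrow(prov))
  for (i in seq_along(added)) {
    xi <- X0[prov$parent_i[i], ]
    xj <- X0[prov$parent_j[i], ]
    lam <- prov$lambda[i]
    expect_true(lam >= 0 && lam <= 1)
    expect_equal(Xa[added[i], ], xi + lam * (xj - xi), tolerance = 1e-12)
    ti <- ds$target[prov$parent_i[i]]
    tj <- ds$target[prov$parent_j[i]]
    expect_equal(out$target[added[i]], ti + lam * (tj - ti),
                 tolerance = 1e-12)
    # convexity: synthetic pseudolabel equals its parents' class
    expect_equal(as.character(out$pseudolabel[added[i]]), prov$class[i])
    expect_equal(as.character(ds$pseudolabel[prov$parent_i[i]]),
                 prov$class[i])
    # componentwise bounds of the parents
    expect_true(all(Xa[added[i], ] >= pmin(xi, xj) - 1e-12))
    expect_true(all(Xa[added[i], ] <= pmax(xi, xj) + 1e-12))
  }

  expect_identical(oversample_smote(ds, k = 3, seed = 11), out)
})

test_that("SMOTE interpolation endpoints reproduce the parents", {
  # two hypo rows far apart: every synthetic is on their segment
  X <- rbind(matrix(40, 2, 24), matrix(runif(5 * 24, 80, 170), 5, 24))
  X[2, ] <- 42
  ds <- windowed_dataset(X, c(60, 68, runif(5, 80, 170)))
  expect_warning(out <- oversample_smote(ds, seed = 2),
                 "cannot be oversampled") # fixture has no hyper rows
  prov <- attr(out, "provenance")
  hp <- prov[prov$class == "hypo", ]
  added <- which(seq_len(nrow(out)) > nrow(ds) &
                 out$pseudolabel == "hypo")
  # with parents (40..., 60) and (42..., 68): target = 60 + lam * 8
  for (i in seq_along(added)) {
    lam <- hp$lambda[i]
    expect_equal(out$target[added[i]],
                 ds$target[hp$parent_i[i]] +
                   lam * (ds$target[hp$parent_j[i]] -
                          ds$target[hp$parent_i[i]]))
    expect_true(out$target[added[i]] >= 60 - 1e-12 &&
                out$target[added[i]] <= 68 + 1e-12)
  }
})

test_that("single-member classes fall back to duplication with a warning", {
  withr::with_seed(5, ds <- make_imbalanced_windows(1, 8, 3))
  expect_warning(out <- oversample_smote(ds, seed = 1), "single example")
  expect_true(all(table(out$pseudolabel) == 8))
  # all added hypo rows are copies of the lone original
  hypo0 <- which(ds$pseudolabel == "hypo")
  added <- which(seq_len(nrow(out)) > nrow(ds) & out$pseudolabel == "hypo")
  for (i in added) {
    expect_equal(window_features(out)[i, ],
                 window_features(ds)[hypo0, ])
  }
})

test_that("ADASYN allocation is proportional with largest-remainder rounding", {
  expect_equal(adasyn_allocation(c(1, 0), 6), c(6L, 0L))
  expect_equal(adasyn_allocation(c(0, 0), 4), c(2L, 2L))
  expect_equal(adasyn_allocation(c(0.6, 0.4, 0), 5), c(3L, 2L, 0L))
  expect_equal(adasyn_allocation(numeric(0), 0), integer(0))

  # brute-force largest-remainder oracle on random cases
  withr::with_seed(6, {
    for (i in 1:50) {
      n <- sample(1:12, 1)
      r <- round(runif(n) * (runif(n) > 0.3), 3)
      deficit <- sample(0:40, 1)
      alloc <- adasyn_allocation(r, deficit)
      expect_equal(sum(alloc), deficit)
      expect_true(all(alloc >= 0))
      if (sum(r) > 0 && deficit > 0) {
        raw <- deficit * r / sum(r)
        base <- floor(raw)
        rem <- deficit - sum(base)
        expected <- base
        if (rem > 0) {
          ord <- order(-(raw - base), seq_len(n))
          expected[ord[seq_len(rem)]] <- expected[ord[seq_len(rem)]] + 1
        }
        expect_equal(alloc, as.integer(expected))
      } else if (deficit > 0) {
        expect_true(max(alloc) - min(alloc) <= 1)
      }
    }
  })
})

test_that("ADASYN seeds synthesis from difficult examples and balances", {
  withr::with_seed(7, ds <- make_imbalanced_windows(6, 15, 8))
  out <- oversample_adasyn(ds, k = 5, seed = 13)
  expect_true(all(table(out$pseudolabel) == 15))

  # provenance recomputation, as for SMOTE
  X0 <- window_features(ds)
  Xa <- window_features(out)
  prov <- attr(out, "provenance")
  added <- (nrow(ds) + 1):nrow(out)
  for (i in seq_along(added)) {
    xi <- X0[prov$parent_i[i], ]
    xj <- X0[prov$parent_j[i], ]
    lam <- prov$lambda[i]
    expect_equal(Xa[added[i], ], xi + lam * (xj - xi), tolerance = 1e-12)
    expect_equal(as.character(ds$pseudolabel[prov$parent_j[i]]),
                 prov$class[i]) # synthesis neighbor is same-class
  }
  expect_identical(oversample_adasyn(ds, k = 5, seed = 13), out)
})

test_that("oversampling dispatcher covers all four options", {
  withr::with_seed(8, ds <- make_imbalanced_windows(3, 9, 4))
  expect_identical(oversample(ds, "none"), ds)
  for (m in c("random", "smote", "adasyn")) {
    out <- oversample(ds, m, seed = 3)
    expect_true(all(table(out$pseudolabel) == 9))
    # originals always come first, untouched
    expect_equal(out$target[seq_len(nrow(ds))], ds$target)
  }
})
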