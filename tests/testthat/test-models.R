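# small linear-ish regression fixture: windows in the CGM range with a
# target that is a noisy weighted sum of the last readings
make_regression_fixture <- function(n, noise = 2) {
  X <- matrix(runif(n * 24, 60, 300), n, 24)
  y <- pmin(400, pmax(40,
    0.5 * X[, 24] + 0.3 * X[, 23] + 0.2 * X[, 22] + rnorm(n, 0, noise)
  ))
  list(X = X, y = y)
}

test_that("the registry holds the ten benchmark configurations", {
  reg <- model_registry(seed = 3)
  expect_length(reg, 10)
  expect_equal(anyDuplicated(names(reg)), 0)
  expect_setequal(names(reg), c(
    "dummy", "lasso", "linear_svr", "decision_tree", "knn", "rbf_svr",
    "mlp_1", "mlp_2", "random_forest", "gradient_boosting"
  ))
  expect_equal(reg$mlp_2$hyperparameters$hidden, c(5, 5))
  expect_equal(reg$mlp_1$hyperparameters$hidden, 5)
  # polynomial features exactly for the sparse linear models
  poly <- vapply(reg, `[[`, logical(1), "uses_polynomial_features")
  expect_equal(names(poly)[poly], c("lasso", "linear_svr"))
  # ensembles default to 500 trees, optimizers to the 1e5 cap
  expect_equal(reg$random_forest$hyperparameters$n_trees, 500)
  expect_equal(reg$gradient_boosting$hyperparameters$n_trees, 500)
  expect_equal(reg$mlp_1$hyperparameters$maxit, 1e5)
  expect_equal(reg$linear_svr$hyperparameters$maxit, 1e5)
  expect_equal(reg$lasso$hyperparameters$nfolds, 5)
})

test_that("the dummy baseline predicts the training mean everywhere", {
  fit <- glyco_train(model_spec("dummy"), matrix(100, 2, 24), c(100, 200))
  pred <- predict(fit, matrix(runif(5 * 24, 40, 400), 5, 24))
  expect_equal(pred, rep(150, 5))
  expect_equal(fit$fit$mean, 150, tolerance = 1e-9)
})

test_that("training is deterministic under a fixed spec seed", {
  withr::with_seed(31, fx <- make_regression_fixture(80))
  Xnew <- matrix(runif(10 * 24, 60, 300), 10, 24)
  ctl <- benchmark_control(max_iter = 500, n_trees = 10, n_centers = 40)
  for (name in c("lasso", "mlp_1", "random_forest", "rbf_svr", "knn")) {
    p1 <- predict(glyco_train(model_spec(name, seed = 42), fx$X, fx$y,
                              control = ctl), Xnew)
    p2 <- predict(glyco_train(model_spec(name, seed = 42), fx$X, fx$y,
                              control = ctl), Xnew)
    expect_identical(p1, p2)
    expect_true(all(is.finite(p1)))
  }
})

test_that("an unpruned tree memorizes distinct training rows", {
  withr::with_seed(32, fx <- make_regression_fixture(60, noise = 5))
  fit <- glyco_train(model_spec("decision_tree"), fx$X, fx$y)
  expect_equal(predict(fit, fx$X), fx$y, tolerance = 1e-9)
})

test_that("predict encapsulates the model's own preprocessing", {
  withr::with_seed(33, fx <- make_regression_fixture(60))
  Xnew <- matrix(runif(8 * 24, 60, 300), 8, 24)
  fit <- glyco_train(model_spec("lasso", seed = 2), fx$X, fx$y)
  # manual pipeline: expand, standardize with train stats, bare learner
  Etr <- expand_polynomial(fx$X)
  st <- standardize(Etr, expand_polynomial(Xnew))
  manual <- as.numeric(
    predict(fit$fit$cv, newx = st$x, s = "lambda.min")
  )
  expect_equal(predict(fit, Xnew), manual, tolerance = 1e-12)
  expect_error(predict(fit, Xnew[, 1:10]), "feature columns")
})

test_that("linear models beat the dummy baseline on linear ground truth", {
  withr::with_seed(34, {
    fx <- make_regression_fixture(300)
    te <- make_regression_fixture(100)
  })
  ctl <- benchmark_control(max_iter = 4000)
  m_dummy <- mard(predict(glyco_train(model_spec("dummy"), fx$X, fx$y),
                          te$X), te$y)
  for (name in c("lasso", "linear_svr")) {
    fit <- glyco_train(model_spec(name, seed = 5), fx$X, fx$y,
                       control = ctl)
    expect_lt(mard(pmax(predict(fit, te$X), 1), te$y), m_dummy)
  }
})
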