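model_names <- c(
  "dummy", "lasso", "linear_svr", "decision_tree", "knn",
  "rbf_svr", "mlp_1", "mlp_2", "random_forest", "gradient_boosting"
)

default_hyperparameters <- function(name) {
  switch(name,
    dummy = list(),
    lasso = list(nfolds = 5, maxit = 1e5),
    linear_svr = list(epsilon = 0.1, lambda = 1e-4, maxit = 1e5,
                      tol = 1e-7),
    decision_tree = list(max_depth = 50, min_split = 2, min_leaf = 1),
    knn = list(k = 5),
    rbf_svr = list(epsilon = 0.1, lambda = 1e-3, n_centers = 1000,
                   maxit = 1e5, tol = 1e-7),
    mlp_1 = list(hidden = 5, maxit = 1e5, learning_rate = 1e-3,
                 batch_size = 200, tol = 1e-5),
    mlp_2 = list(hidden = c(5, 5), maxit = 1e5, learning_rate = 1e-3,
                 batch_size = 200, tol = 1e-5),
    random_forest = list(n_trees = 500, max_depth = 50, min_split = 2,
                         min_leaf = 1),
    gradient_boosting = list(n_trees = 500, shrinkage = 0.1,
                             max_depth = 3, min_split = 2, min_leaf = 1),
    stop(sprintf("unknown model '%s'", name))
  )
}

#' Construct a model specification
#'
#' @param name one of `dummy`, `lasso`, `linear_svr`, `decision_tree`,
#'   `knn`, `rbf_svr`, `mlp_1`, `mlp_2`, `random_forest`,
#'   `gradient_boosting`.
#' @param seed integer seed fixed into the spec; training is
#'   deterministic given spec and data.
#' @param ... hyperparameter overrides merged over the defaults (see
#'   [model_registry()]).
#' @return A list of class `model_spec` with `name`,
#'   `uses_polynomial_features`, `hyperparameters` and `seed`.
#' @export
model_spec <- function(name, seed = 1, ...) {
  name <- match.arg(name, model_names)
  hp <- utils::modifyList(default_hyperparameters(name), list(...))
  structure(
    list(
      name = name,
      uses_polynomial_features = name %in% c("lasso", "linear_svr"),
      hyperparameters = hp,
      seed = as.integer(seed)
    ),
    class = "model_spec"
  )
}

#' The ten benchmarked regressor configurations
#'
#' Returns the ten model specifications compared in the benchmark, with
#' their conventional hyperparameters: the Lasso selects its L1 penalty
#' by five-fold cross-validation on the training data; the Lasso, SVR
#' and MLP optimizers are capped at 100,000 iterations; the tree
#' ensembles use 500 trees; the MLPs have hidden layers of five tanh
#' units (one layer for `mlp_1`, two for `mlp_2`) trained with ADAM.
#' Only the two sparse linear models (`lasso`, `linear_svr`) receive the
#' degree-2 polynomial feature expansion; the RBF kernel SVR models
#' non-linearity through its kernel instead. The `dummy` baseline
#' predicts the patient's training-mean glucose.
#'
#' @param seed integer seed assigned to every spec.
#' @return A named list of ten [model_spec()] objects.
#' @export
model_registry <- function(seed = 1) {
  stats::setNames(lapply(model_names, model_spec, seed = seed), model_names)
}

#' Computational caps for a benchmark run
#'
#' Optional overrides that scale the learners down for time-boxed runs
#' (iteration caps, ensemble sizes, kernel centers, training-set size).
#' `NULL` entries leave the spec's own hyperparameters untouched.
#' Reducing these trades accuracy for speed but never changes the
#' pipeline structure, so structural results (grid shape, determinism,
#' metric bookkeeping) are unaffected.
#'
#' @param max_iter cap on first-order optimizer steps (SVRs, MLPs); the
#'   Lasso's coordinate descent is already fast and is never capped
#'   below its default.
#' @param n_trees cap on ensemble size (random forest, gradient
#'   boosting).
#' @param n_centers cap on RBF kernel centers.
#' @param max_train_windows cap on training windows per experiment; a
#'   seeded subsample is taken before oversampling when exceeded.
#' @return A list of class `benchmark_control`.
#' @export
benchmark_control <- function(max_iter = NULL, n_trees = NULL,
                              n_centers = NULL, max_train_windows = Inf) {
  structure(
    list(
      max_iter = max_iter, n_trees = n_trees, n_centers = n_centers,
      max_train_windows = max_train_windows
    ),
    class = "benchmark_control"
  )
}

apply_control <- function(spec, control) {
  hp <- spec$hyperparameters
  # glmnet's maxit counts coordinate-descent passes, not gradient steps;
  # capping it like a first-order optimizer only breaks convergence
  if (!is.null(control$max_iter) && !is.null(hp$maxit) &&
      spec$name != "lasso") {
    hp$maxit <- min(hp$maxit, control$max_iter)
  }
  if (!is.null(control$n_trees) && !is.null(hp$n_trees)) {
    hp$n_trees <- min(hp$n_trees, control$n_trees)
  }
  if (!is.null(control$n_centers) && !is.null(hp$n_centers)) {
    hp$n_centers <- min(hp$n_centers, control$n_centers)
  }
  spec$hyperparameters <- hp
  spec
}

#' Train a model specification on raw windows
#'
#' Bundles the full per-model pipeline: optional polynomial expansion
#' (sparse linear models only), feature-wise standardization fitted on
#' the training data, then the learner itself, seeded from the spec.
#' The returned object applies the identical preprocessing inside
#' [predict.glyco_model()], so prediction always takes raw feature
#' windows.
#'
#' Expansion runs before standardization: the quadratic terms are built
#' from raw mg/dl readings and then all expanded features are put on a
#' comparable scale for the L1 penalty. Set `standardize_first = TRUE`
#' to standardize the raw readings and expand afterwards instead.
#'
#' @param spec a [model_spec()].
#' @param x numeric feature matrix, one raw window per row.
#' @param y numeric targets in mg/dl.
#' @param control a [benchmark_control()] of computational caps.
#' @param standardize_first expand standardized rather than raw features
#'   (default `FALSE`).
#' @return An object of class `glyco_model`.
#' @export
glyco_train <- function(spec, x, y, control = benchmark_control(),
                        standardize_first = FALSE) {
  stopifnot(inherits(spec, "model_spec"))
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (nrow(x) != length(y) || length(y) < 1) {
    stop("`x` rows and `y` length must match and be at least 1")
  }
  spec <- apply_control(spec, control)
  hp <- spec$hyperparameters

  pre <- list(
    expand = spec$uses_polynomial_features,
    standardize_first = standardize_first
  )
  xt <- x
  if (pre$expand && !standardize_first) xt <- expand_polynomial(xt)
  pre$standardizer <- fit_standardizer(xt)
  xs <- apply_standardizer(pre$standardizer, xt)
  if (pre$expand && standardize_first) xs <- expand_polynomial(xs)

  fit <- withr::with_seed(spec$seed, tryCatch(
    switch(spec$name,
      dummy = list(mean = mean(y)),
      lasso = fit_lasso(xs, y, hp),
      linear_svr = fit_linear_svr(xs, y, hp),
      decision_tree = fit_decision_tree(xs, y, hp),
      knn = fit_knn(xs, y, hp),
      rbf_svr = fit_rbf_svr(xs, y, hp),
      mlp_1 = fit_mlp(xs, y, hp),
      mlp_2 = fit_mlp(xs, y, hp),
      random_forest = fit_random_forest(xs, y, hp),
      gradient_boosting = fit_gradient_boosting(xs, y, hp)
    ),
    error = function(e) {
      stop(sprintf("training '%s' failed: %s", spec$name,
                   conditionMessage(e)), call. = FALSE)
    }
  ))
  structure(
    list(spec = spec, preprocessing = pre, fit = fit, d_input = ncol(x)),
    class = "glyco_model"
  )
}

#' Predict from a trained model on raw windows
#'
#' @param object a `glyco_model` from [glyco_train()].
#' @param x numeric matrix of raw feature windows with the training
#'   column count.
#' @param ... unused.
#' @return Numeric predictions in mg/dl, one per row, all finite.
#' @export
predict.glyco_model <- function(object, x, ...) {
  x <- as.matrix(x)
  if (ncol(x) != object$d_input) {
    stop(sprintf("expected %d feature columns, got %d", object$d_input,
                 ncol(x)))
  }
  pre <- object$preprocessing
  xt <- x
  if (pre$expand && !pre$standardize_first) xt <- expand_polynomial(xt)
  xs <- apply_standardizer(pre$standardizer, xt)
  if (pre$expand && pre$standardize_first) xs <- expand_polynomial(xs)

  out <- switch(object$spec$name,
    dummy = rep(object$fit$mean, nrow(xs)),
    lasso = predict_lasso(object$fit, xs),
    linear_svr = predict_linear_svr(object$fit, xs),
    decision_tree = .cart_predict(object$fit$tree, xs),
    knn = predict_knn(object$fit, xs),
    rbf_svr = predict_rbf_svr(object$fit, xs),
    mlp_1 = predict_mlp(object$fit, xs),
    mlp_2 = predict_mlp(object$fit, xs),
    random_forest = predict_random_forest(object$fit, xs),
    gradient_boosting = predict_gradient_boosting(object$fit, xs)
  )
  out <- as.numeric(out)
  if (any(!is.finite(out))) {
    stop(sprintf("model '%s' produced non-finite predictions",
                 object$spec$name))
  }
  out
}

#' @export
print.glyco_model <- function(x, ...) {
  cat(sprintf(
    "<glyco_model> %s (seed %d%s)\n", x$spec$name, x$spec$seed,
    if (x$spec$uses_polynomial_features) ", polynomial features" else ""
  ))
  invisible(x)
}
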