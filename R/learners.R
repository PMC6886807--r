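# Learner back ends behind the uniform train/predict contract.
#
# k-NN regression and neighbor search are delegated to FNN, the Lasso to
# glmnet. No CART/forest/boosting, MLP or SVM regression package is
# available in the target environment, so those learners are implemented
# here: a compiled least-squares CART (src/cart.cpp) backs the single
# tree and both ensembles, the MLPs are tanh networks trained with ADAM,
# and the SVRs minimize the epsilon-insensitive loss directly (proximal
# subgradient with an L1 penalty for the linear machine; a reduced-set
# RBF kernel machine with an L2 penalty for the non-linear one).

# ---- lasso ----------------------------------------------------------------

fit_lasso <- function(xs, y, hp) {
  n <- nrow(xs)
  nfolds <- max(3L, min(hp$nfolds, n %/% 2))
  foldid <- sample(rep_len(seq_len(nfolds), n))
  cv <- glmnet::cv.glmnet(xs, y,
    alpha = 1, foldid = foldid, standardize = FALSE, maxit = hp$maxit
  )
  list(cv = cv)
}

predict_lasso <- function(fit, xs) {
  as.numeric(stats::predict(fit$cv, newx = xs, s = "lambda.min"))
}

# ---- k-nearest neighbours -------------------------------------------------

fit_knn <- function(xs, y, hp) {
  list(x = xs, y = y, k = min(hp$k, nrow(xs)))
}

predict_knn <- function(fit, xs) {
  FNN::knn.reg(train = fit$x, test = xs, y = fit$y, k = fit$k)$pred
}

# ---- CART and tree ensembles ---------------------------------------------

fit_decision_tree <- function(xs, y, hp) {
  tree <- .cart_grow(xs, y, hp$max_depth, hp$min_split, hp$min_leaf,
                     ncol(xs), sample.int(.Machine$integer.max, 1))
  list(tree = tree)
}

fit_random_forest <- function(xs, y, hp) {
  n <- nrow(xs)
  mtry <- max(1L, ncol(xs) %/% 3L)
  trees <- lapply(seq_len(hp$n_trees), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    .cart_grow(xs[idx, , drop = FALSE], y[idx], hp$max_depth,
               hp$min_split, hp$min_leaf, mtry,
               sample.int(.Machine$integer.max, 1))
  })
  list(trees = trees)
}

predict_random_forest <- function(fit, xs) {
  preds <- vapply(fit$trees, function(tr) .cart_predict(tr, xs),
                  numeric(nrow(xs)))
  if (nrow(xs) == 1) preds <- matrix(preds, nrow = 1)
  rowMeans(preds)
}

fit_gradient_boosting <- function(xs, y, hp) {
  f <- rep(mean(y), length(y))
  trees <- vector("list", hp$n_trees)
  for (b in seq_len(hp$n_trees)) {
    tr <- .cart_grow(xs, y - f, hp$max_depth, hp$min_split, hp$min_leaf,
                     ncol(xs), sample.int(.Machine$integer.max, 1))
    f <- f + hp$shrinkage * .cart_predict(tr, xs)
    trees[[b]] <- tr
  }
  list(init = mean(y), shrinkage = hp$shrinkage, trees = trees)
}

predict_gradient_boosting <- function(fit, xs) {
  out <- rep(fit$init, nrow(xs))
  for (tr in fit$trees) out <- out + fit$shrinkage * .cart_predict(tr, xs)
  out
}

# ---- multilayer perceptron (tanh, ADAM) -----------------------------------

mlp_init <- function(sizes) {
  lapply(seq_len(length(sizes) - 1), function(l) {
    s <- sqrt(6 / (sizes[l] + sizes[l + 1]))
    list(
      W = matrix(stats::runif(sizes[l] * sizes[l + 1], -s, s),
                 sizes[l], sizes[l + 1]),
      b = rep(0, sizes[l + 1])
    )
  })
}

mlp_forward <- function(layers, x) {
  acts <- vector("list", length(layers) + 1)
  acts[[1]] <- x
  nl <- length(layers)
  for (l in seq_len(nl)) {
    z <- sweep(acts[[l]] %*% layers[[l]]$W, 2, layers[[l]]$b, "+")
    acts[[l + 1]] <- if (l < nl) tanh(z) else z
  }
  acts
}

fit_mlp <- function(xs, y, hp) {
  n <- nrow(xs)
  ym <- mean(y)
  ysd <- stats::sd(y)
  if (!is.finite(ysd) || ysd == 0) ysd <- 1
  yz <- (y - ym) / ysd

  sizes <- c(ncol(xs), hp$hidden, 1)
  layers <- mlp_init(sizes)
  nl <- length(layers)
  m <- lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0))
  v <- m
  lr <- hp$learning_rate
  b1 <- 0.9; b2 <- 0.999; epsa <- 1e-8
  batch <- min(hp$batch_size, n)
  eval_idx <- if (n > 2000) sample.int(n, 2000) else seq_len(n)

  best <- Inf; since_best <- 0L; t_adam <- 0
  check_every <- 200L; patience <- 15L
  for (step in seq_len(hp$maxit)) {
    idx <- if (batch == n) seq_len(n) else sample.int(n, batch)
    acts <- mlp_forward(layers, xs[idx, , drop = FALSE])
    delta <- (acts[[nl + 1]] - yz[idx]) / batch # d(mse/2)/d out
    t_adam <- t_adam + 1
    for (l in rev(seq_len(nl))) {
      gW <- crossprod(acts[[l]], delta)
      gb <- colSums(delta)
      if (l > 1) delta <- (delta %*% t(layers[[l]]$W)) * (1 - acts[[l]]^2)
      m[[l]]$W <- b1 * m[[l]]$W + (1 - b1) * gW
      m[[l]]$b <- b1 * m[[l]]$b + (1 - b1) * gb
      v[[l]]$W <- b2 * v[[l]]$W + (1 - b2) * gW^2
      v[[l]]$b <- b2 * v[[l]]$b + (1 - b2) * gb^2
      corr <- lr * sqrt(1 - b2^t_adam) / (1 - b1^t_adam)
      layers[[l]]$W <- layers[[l]]$W -
        corr * m[[l]]$W / (sqrt(v[[l]]$W) + epsa)
      layers[[l]]$b <- layers[[l]]$b -
        corr * m[[l]]$b / (sqrt(v[[l]]$b) + epsa)
    }
    if (step %% check_every == 0) {
      pred <- mlp_forward(layers, xs[eval_idx, , drop = FALSE])[[nl + 1]]
      loss <- mean((pred - yz[eval_idx])^2)
      if (loss < best * (1 - hp$tol)) {
        best <- loss; since_best <- 0L
      } else {
        since_best <- since_best + 1L
        if (since_best >= patience) break
      }
    }
  }
  list(layers = layers, y_mean = ym, y_sd = ysd)
}

predict_mlp <- function(fit, xs) {
  out <- mlp_forward(fit$layers, xs)[[length(fit$layers) + 1]]
  as.numeric(out) * fit$y_sd + fit$y_mean
}

# ---- linear SVR (L1-penalized epsilon-insensitive, proximal subgradient) --

fit_linear_svr <- function(xs, y, hp) {
  n <- nrow(xs); p <- ncol(xs)
  ym <- mean(y); ysd <- stats::sd(y)
  if (!is.finite(ysd) || ysd == 0) ysd <- 1
  yz <- (y - ym) / ysd
  eps <- hp$epsilon; lam <- hp$lambda

  # Lipschitz-scale step from the largest singular value of X/sqrt(n)
  v0 <- stats::rnorm(p)
  for (i in 1:10) {
    v0 <- crossprod(xs, xs %*% v0) / n
    v0 <- v0 / sqrt(sum(v0^2))
  }
  L <- sqrt(sum((crossprod(xs, xs %*% v0) / n)^2)) # ~ sigma_max^2 / n... of gram
  eta0 <- 1 / max(L, 1e-8)

  w <- rep(0, p); b <- 0
  best_obj <- Inf; since_best <- 0L
  for (it in seq_len(hp$maxit)) {
    r <- yz - xs %*% w - b
    s <- sign(r) * (abs(r) > eps)
    eta <- eta0 / sqrt(1 + it / 50)
    w <- w + eta * crossprod(xs, s)[, 1] / n
    w <- sign(w) * pmax(abs(w) - eta * lam, 0) # soft threshold (L1 prox)
    b <- b + eta * mean(s)
    if (it %% 25 == 0) {
      obj <- mean(pmax(abs(yz - xs %*% w - b) - eps, 0)) + lam * sum(abs(w))
      if (obj < best_obj - hp$tol) {
        best_obj <- obj; since_best <- 0L
      } else {
        since_best <- since_best + 1L
        if (since_best >= 10L) break
      }
    }
  }
  list(w = w, b = b, y_mean = ym, y_sd = ysd)
}

predict_linear_svr <- function(fit, xs) {
  as.numeric(xs %*% fit$w + fit$b) * fit$y_sd + fit$y_mean
}

# ---- RBF kernel SVR (reduced-set, smoothed loss, ADAM) --------------------

rbf_features <- function(x, centers, gamma) {
  d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") -
    2 * tcrossprod(x, centers)
  exp(-gamma * pmax(d2, 0))
}

fit_rbf_svr <- function(xs, y, hp) {
  n <- nrow(xs)
  ym <- mean(y); ysd <- stats::sd(y)
  if (!is.finite(ysd) || ysd == 0) ysd <- 1
  yz <- (y - ym) / ysd
  eps <- hp$epsilon; lam <- hp$lambda; delta <- 0.1

  centers <- xs[sample.int(n, min(hp$n_centers, n)), , drop = FALSE]
  gamma <- 1 / (ncol(xs) * max(mean(apply(xs, 2, stats::var)), 1e-8))
  phi <- rbf_features(xs, centers, gamma)
  mm <- ncol(phi)

  theta <- rep(0, mm + 1) # alpha, b
  ma <- va <- rep(0, mm + 1)
  b1 <- 0.9; b2 <- 0.999
  best_obj <- Inf; since_best <- 0L
  for (it in seq_len(hp$maxit)) {
    r <- yz - phi %*% theta[1:mm] - theta[mm + 1]
    ex <- abs(r) - eps
    # huberized epsilon-insensitive loss gradient wrt model output
    gout <- -sign(r) * pmin(pmax(ex, 0) / delta, 1)
    g <- c(crossprod(phi, gout)[, 1] / n + 2 * lam * theta[1:mm],
           mean(gout))
    ma <- b1 * ma + (1 - b1) * g
    va <- b2 * va + (1 - b2) * g^2
    corr <- 0.01 * sqrt(1 - b2^it) / (1 - b1^it)
    theta <- theta - corr * ma / (sqrt(va) + 1e-8)
    if (it %% 25 == 0) {
      obj <- mean(pmax(ex, 0)) + lam * sum(theta[1:mm]^2)
      if (obj < best_obj - hp$tol) {
        best_obj <- obj; since_best <- 0L
      } else {
        since_best <- since_best + 1L
        if (since_best >= 10L) break
      }
    }
  }
  list(alpha = theta[1:mm], b = theta[mm + 1], centers = centers,
       gamma = gamma, y_mean = ym, y_sd = ysd)
}

predict_rbf_svr <- function(fit, xs) {
  phi <- rbf_features(xs, fit$centers, fit$gamma)
  as.numeric(phi %*% fit$alpha + fit$b) * fit$y_sd + fit$y_mean
}
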