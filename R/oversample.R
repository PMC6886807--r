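#' Plan how many examples each glycemic class needs
#'
#' Computes, per pseudolabel class, the number of examples that must be
#' added so that every class reaches the size of the majority class
#' (normoglycemia, in realistic CGM data). Classes with no members at all
#' cannot be synthesized from and keep a deficit of 0, flagged with a
#' warning.
#'
#' @param ds a [windowed_dataset()].
#' @return A list of class `oversample_plan` with `counts`, `deficit`,
#'   `majority_class`, `majority_count` and `empty_classes`.
#' @export
make_plan <- function(ds) {
  stopifnot(inherits(ds, "windowed_dataset"))
  if (nrow(ds) == 0) stop("cannot plan oversampling for an empty dataset")
  counts <- table(ds$pseudolabel)
  majority_class <- names(counts)[which.max(counts)]
  majority_count <- max(counts)
  deficit <- majority_count - counts
  empty <- names(counts)[counts == 0 & deficit > 0]
  deficit[counts == 0] <- 0
  if (length(empty) > 0) {
    warning(sprintf(
      "class(es) with no examples cannot be oversampled: %s",
      paste(empty, collapse = ", ")
    ))
  }
  structure(
    list(
      counts = stats::setNames(as.integer(counts), names(counts)),
      deficit = stats::setNames(as.integer(deficit), names(deficit)),
      majority_class = majority_class,
      majority_count = as.integer(majority_count),
      empty_classes = empty
    ),
    class = "oversample_plan"
  )
}

#' Balance a windowed dataset across glycemic classes
#'
#' Front end to the three oversampling techniques. All of them add rows
#' to the non-majority pseudolabel classes until every (non-empty) class
#' matches the majority class size; `"none"` returns the input untouched.
#' The synthetic techniques interpolate the numeric target with the same
#' coefficient as the features, which is what makes them applicable to a
#' regression problem. Oversampling is meant for training data only; the
#' benchmark pipeline never touches test windows.
#'
#' @param ds a [windowed_dataset()].
#' @param method `"none"`, `"random"`, `"smote"` or `"adasyn"`.
#' @param k neighborhood size for SMOTE/ADASYN (default 5, reduced to
#'   class size − 1 when a class is smaller than k + 1).
#' @param seed integer seed; a fixed seed gives identical output.
#' @return A [windowed_dataset()] with the original rows first and any
#'   added rows appended. Synthetic rows carry a provenance table in
#'   `attr(, "provenance")` with the parent row indices and the
#'   interpolation coefficient `lambda`.
#' @export
oversample <- function(ds, method = c("none", "random", "smote", "adasyn"),
                       k = 5, seed = 1) {
  method <- match.arg(method)
  switch(method,
    none = ds,
    random = oversample_random(ds, seed = seed),
    smote = oversample_smote(ds, k = k, seed = seed),
    adasyn = oversample_adasyn(ds, k = k, seed = seed)
  )
}

#' Random oversampling by duplication
#'
#' Fills each class deficit with exact copies of rows of the same class,
#' drawn uniformly with replacement.
#'
#' @inheritParams oversample
#' @return A balanced [windowed_dataset()]; `attr(, "provenance")`
#'   records the duplicated source row for every added row
#'   (`lambda = 0`).
#' @export
oversample_random <- function(ds, seed = 1) {
  plan <- make_plan(ds)
  prov <- empty_provenance()
  add <- integer(0)
  withr::with_seed(seed, {
    for (cls in names(plan$deficit)) {
      d <- plan$deficit[[cls]]
      if (d == 0) next
      rows <- which(ds$pseudolabel == cls)
      picked <- rows[sample.int(length(rows), d, replace = TRUE)]
      add <- c(add, picked)
      prov <- rbind(prov, tibble::tibble(
        class = cls, parent_i = picked, parent_j = picked,
        lambda = 0
      ))
    }
  })
  bind_synthetic(ds, window_features(ds)[add, , drop = FALSE],
    ds$target[add], ds$pseudolabel[add], prov)
}

#' SMOTE for regression with target synthesis
#'
#' For each example a minority class is short of, a seed row is drawn
#' uniformly from the class, a neighbor is drawn uniformly from the
#' seed's `k` nearest same-class neighbors (Euclidean distance on the raw
#' mg/dl features), and a new example is created by linear interpolation
#' `x_new = x_i + lambda * (x_j − x_i)` with `lambda ~ Uniform[0, 1]`.
#' The numeric target is interpolated with the same `lambda`, so the
#' synthetic target always stays inside its parents' glycemic range and
#' the pseudolabel is inherited unchanged. A class with a single member
#' falls back to random duplication, with a warning.
#'
#' @inheritParams oversample
#' @return A balanced [windowed_dataset()] with provenance attribute.
#' @export
oversample_smote <- function(ds, k = 5, seed = 1) {
  synthesize_balanced(ds, k = k, seed = seed, adaptive = FALSE)
}

#' ADASYN for regression with target synthesis
#'
#' Like [oversample_smote()], but the number of synthetic examples seeded
#' from each minority row is proportional to that row's difficulty: the
#' fraction of its `k` nearest neighbors in the full dataset that carry a
#' different pseudolabel. Allocations are rounded by largest remainder so
#' they sum exactly to the class deficit (see [adasyn_allocation()]);
#' when every difficulty is zero the allocation is uniform. Synthesis
#' itself interpolates between same-class neighbors with a shared
#' `lambda`, exactly as in SMOTE.
#'
#' @inheritParams oversample
#' @return A balanced [windowed_dataset()] with provenance attribute.
#' @export
oversample_adasyn <- function(ds, k = 5, seed = 1) {
  synthesize_balanced(ds, k = k, seed = seed, adaptive = TRUE)
}

#' Largest-remainder allocation of synthetic examples
#'
#' Splits `deficit` synthetic examples across minority rows in proportion
#' to their difficulties `r`, rounding by largest remainder so the
#' allocations sum exactly to `deficit` (remainder ties go to the lower
#' index). If all difficulties are zero the allocation is uniform.
#'
#' @param r numeric vector of non-negative difficulties.
#' @param deficit non-negative integer total to allocate.
#' @return An integer vector of allocations summing to `deficit`.
#' @export
adasyn_allocation <- function(r, deficit) {
  stopifnot(all(r >= 0), deficit >= 0)
  n <- length(r)
  if (n == 0 || deficit == 0) return(integer(n))
  if (sum(r) == 0) {
    base <- deficit %/% n
    alloc <- rep.int(base, n)
    rem <- deficit - base * n
    if (rem > 0) alloc[seq_len(rem)] <- alloc[seq_len(rem)] + 1L
    return(as.integer(alloc))
  }
  raw <- deficit * r / sum(r)
  alloc <- floor(raw)
  rem <- deficit - sum(alloc)
  if (rem > 0) {
    take <- order(-(raw - alloc), seq_len(n))[seq_len(rem)]
    alloc[take] <- alloc[take] + 1
  }
  as.integer(alloc)
}

# shared synthesis engine behind SMOTE and ADASYN
synthesize_balanced <- function(ds, k, seed, adaptive) {
  plan <- make_plan(ds)
  X <- window_features(ds)
  prov <- empty_provenance()
  new_X <- NULL
  new_t <- numeric(0)
  new_lab <- character(0)

  withr::with_seed(seed, {
    # full-dataset neighborhoods for ADASYN difficulty
    if (adaptive && nrow(ds) >= 2) {
      k_full <- min(k, nrow(ds) - 1)
      nn_full <- FNN::get.knn(X, k = k_full)$nn.index
    }
    for (cls in names(plan$deficit)) {
      d <- plan$deficit[[cls]]
      if (d == 0) next
      rows <- which(ds$pseudolabel == cls)
      n_c <- length(rows)
      if (n_c == 1) {
        warning(sprintf(
          "class '%s' has a single example; falling back to random duplication",
          cls
        ))
        picked <- rep.int(rows, d)
        new_X <- rbind(new_X, X[picked, , drop = FALSE])
        new_t <- c(new_t, ds$target[picked])
        new_lab <- c(new_lab, rep.int(cls, d))
        prov <- rbind(prov, tibble::tibble(
          class = cls, parent_i = picked, parent_j = picked, lambda = 0
        ))
        next
      }
      k_eff <- min(k, n_c - 1)
      nn_cls <- FNN::get.knn(X[rows, , drop = FALSE], k = k_eff)$nn.index

      if (adaptive) {
        r <- vapply(seq_len(n_c), function(i) {
          nb <- nn_full[rows[i], ]
          mean(ds$pseudolabel[nb] != cls)
        }, numeric(1))
        alloc <- adasyn_allocation(r, d)
        seed_local <- rep.int(seq_len(n_c), alloc)
      } else {
        seed_local <- sample.int(n_c, d, replace = TRUE)
      }
      nbr_pick <- sample.int(k_eff, length(seed_local), replace = TRUE)
      nbr_local <- nn_cls[cbind(seed_local, nbr_pick)]
      lam <- stats::runif(length(seed_local))

      xi <- X[rows[seed_local], , drop = FALSE]
      xj <- X[rows[nbr_local], , drop = FALSE]
      new_X <- rbind(new_X, xi + lam * (xj - xi))
      ti <- ds$target[rows[seed_local]]
      tj <- ds$target[rows[nbr_local]]
      new_t <- c(new_t, ti + lam * (tj - ti))
      new_lab <- c(new_lab, rep.int(cls, length(seed_local)))
      prov <- rbind(prov, tibble::tibble(
        class = cls, parent_i = rows[seed_local],
        parent_j = rows[nbr_local], lambda = lam
      ))
    }
  })
  if (is.null(new_X)) {
    new_X <- matrix(numeric(0), nrow = 0, ncol = ncol(X))
  }
  bind_synthetic(ds, new_X, new_t,
    factor(new_lab, levels = pseudolabel_levels), prov)
}

empty_provenance <- function() {
  tibble::tibble(
    class = character(0), parent_i = integer(0),
    parent_j = integer(0), lambda = numeric(0)
  )
}

bind_synthetic <- function(ds, add_X, add_t, add_lab, prov) {
  X <- rbind(window_features(ds), add_X)
  target <- c(ds$target, add_t)
  lab <- factor(c(as.character(ds$pseudolabel), as.character(add_lab)),
                levels = pseudolabel_levels)
  end_time <- c(ds$end_time, as.POSIXct(rep(NA_real_, length(add_t)),
                                        tz = "UTC"))
  out <- windowed_dataset(X, target,
    pseudolabel = lab, end_time = end_time,
    thresholds = attr(ds, "thresholds"),
    patient_id = attr(ds, "patient_id")
  )
  attr(out, "provenance") <- prov
  attr(out, "n_original") <- nrow(ds)
  out
}
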