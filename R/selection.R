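#' Ceiling-halving schedule of retained-set sizes
#'
#' Iterative bisection schedule: starting from p features, each step keeps
#' `ceiling(k/2)` of them, down to a single feature. With the ceiling
#' convention a 286-feature panel passes exactly through a nine-feature set
#' at the fifth bisection (286, 143, 72, 36, 18, 9, 5, 3, 2, 1).
#'
#' @param p starting number of features (>= 1).
#' @return strictly decreasing integer vector from `p` to `1`.
#' @export
halving_schedule <- function(p) {
  p <- as.integer(p)
  if (is.na(p) || p < 1) .stopf("p must be a positive count")
  sizes <- p
  while (sizes[length(sizes)] > 1L)
    sizes <- c(sizes, as.integer(ceiling(sizes[length(sizes)] / 2)))
  sizes
}

#' Discard the less important half of a feature set
#'
#' Retains the `ceiling(k/2)` features with the largest importance; ties are
#' broken by feature id (ascending), which makes the step deterministic.
#'
#' @param features character vector of current feature ids.
#' @param importance an [oob_permutation_importance()] result (or any
#'   data.frame with `feature_id` and `importance`) covering exactly these
#'   features.
#' @param target optional retained-set size; default `ceiling(k/2)`.
#' @return retained feature ids, ordered by decreasing importance.
#' @export
halve <- function(features, importance, target = NULL) {
  if (!all(c("feature_id", "importance") %in% names(importance)))
    .stopf("importance must have feature_id and importance columns")
  if (!setequal(features, importance$feature_id) ||
      length(features) != nrow(importance))
    .stopf("importance does not cover exactly the given feature set")
  k <- length(features)
  target <- as.integer(target %||% ceiling(k / 2))
  if (target < 1 || target > k) .stopf("invalid target size %d", target)
  imp <- importance[match(features, importance$feature_id), ]
  ord <- order(-imp$importance, imp$feature_id)
  features[ord][seq_len(target)]
}

## Walk the halving schedule on (X, y) down to `target` features.
## When `target` is not on the ceiling-halving chain from p (possible when
## extra covariates were appended), halving proceeds while the next size is
## still >= target and the last step truncates to exactly `target` by the
## current importance ranking.
## Returns list(selected, chain = list(size -> ids), importances).
.halve_to <- function(X, y, params, target, seed) {
  X <- .as_predictor_matrix(X)
  feats <- colnames(X)
  chain <- list(); imps <- list()
  chain[[as.character(length(feats))]] <- feats
  step <- 0L
  while (length(feats) > target) {
    step <- step + 1L
    fseed <- .derive_seed(seed, step, 1)
    pseed <- .derive_seed(seed, step, 2)
    model <- fit_forest(X[, feats, drop = FALSE], y,
                        forest_params(n_trees = params$n_trees,
                                      mtry = params$mtry,
                                      min_node = params$min_node,
                                      seed = fseed,
                                      bootstrap = params$bootstrap))
    imp <- oob_permutation_importance(model, X[, feats, drop = FALSE], y,
                                      perm_seed = pseed)
    nxt <- as.integer(ceiling(length(feats) / 2))
    if (nxt < target) nxt <- as.integer(target)
    feats <- halve(feats, imp, target = nxt)
    chain[[as.character(nxt)]] <- feats
    imps[[as.character(length(imp$feature_id))]] <- imp
  }
  list(selected = feats, chain = chain, importances = imps)
}

#' Importance-halving feature selection on one data set
#'
#' Runs the iterative bisection on the full data: fit a forest on the
#' current feature set, compute out-of-bag permutation importance, keep the
#' more important ceiling-half, repeat until `target` features remain.
#' Inside cross-validation this is re-run per training fold (see
#' [cross_validate()]); calling it directly on all data is the exploratory
#' (non-validated) use.
#'
#' @param X predictor matrix (or [feature_matrix()]).
#' @param y response vector.
#' @param params [forest_params()] for every forest fit along the chain.
#' @param target retained-set size to stop at.
#' @param seed seed for the per-step forest and permutation seeds.
#' @return list with `selected` (feature ids, ordered by the final halving
#'   step's importance), `chain` (retained ids per visited size), and
#'   `importances` (per-step importance tables).
#' @export
halving_select <- function(X, y, params = forest_params(), target = 9,
                           seed = 1) {
  .halve_to(X, y, params, target = as.integer(target), seed = seed)
}

#' Importance-halving selection trace under cross-validation
#'
#' Runs the full iterative-bisection analysis: at every size of the halving
#' schedule it records (a) the retained feature set of the full-data halving
#' chain (these sets are nested by construction) and (b) the median
#' cross-validated accuracy of a forest restricted to that size, where the
#' halving selection is re-run *inside every training fold* so held-out
#' samples never influence feature choice. One schedule walk per training
#' fold yields test-fold predictions at every size, which are pooled per
#' repetition and summarised by the median over repetitions.
#'
#' @param X predictor matrix (or [feature_matrix()]).
#' @param y response vector.
#' @param params [forest_params()] for every forest fit.
#' @param cv a [cv_spec()].
#' @return object of class `selection_trace`: data.frame `summary` (size,
#'   median_cv_accuracy), matrix `cv_accuracy` (size x repeat), list
#'   `retained` (full-data chain, by size).
#' @export
run_selection_trace <- function(X, y, params = forest_params(),
                                cv = cv_spec()) {
  X <- .as_predictor_matrix(X)
  n <- nrow(X); p <- ncol(X)
  sizes <- halving_schedule(p)
  folds <- .fold_matrix(n, cv)

  acc <- matrix(NA_real_, length(sizes), cv$repeats,
                dimnames = list(as.character(sizes), NULL))
  for (r in seq_len(cv$repeats)) {
    pred <- matrix(NA_real_, n, length(sizes))
    for (k in seq_len(cv$folds)) {
      tr <- folds[, r] != k
      te <- !tr
      feats <- colnames(X)
      step <- 0L
      for (si in seq_along(sizes)) {
        s <- sizes[si]
        if (length(feats) > s) { # only possible via halving below
          .stopf("internal: schedule desync")
        }
        fseed <- .derive_seed(cv$seed, r, k, si, 1)
        model <- fit_forest(X[tr, feats, drop = FALSE], y[tr],
                            forest_params(n_trees = params$n_trees,
                                          mtry = params$mtry,
                                          min_node = params$min_node,
                                          seed = fseed,
                                          bootstrap = params$bootstrap))
        pred[te, si] <- predict(model, X[te, , drop = FALSE])
        if (si < length(sizes)) {
          pseed <- .derive_seed(cv$seed, r, k, si, 2)
          imp <- oob_permutation_importance(
            model, X[tr, feats, drop = FALSE], y[tr], perm_seed = pseed)
          feats <- halve(feats, imp, target = sizes[si + 1])
        }
      }
    }
    for (si in seq_along(sizes))
      acc[si, r] <- as.numeric(accuracy(y, pred[, si]))
  }

  full <- .halve_to(X, y, params, target = 1L,
                    seed = .derive_seed(cv$seed, 0))
  summary <- data.frame(size = sizes,
                        median_cv_accuracy = apply(acc, 1, median))
  structure(list(summary = summary, cv_accuracy = acc,
                 retained = full$chain, importances = full$importances),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("importance-halving selection trace\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Smallest feature set on the accuracy plateau
#'
#' Applies the plateau-stability rule to a selection trace: the selected
#' size is the smallest one whose median cross-validated accuracy is within
#' `delta` of the best median accuracy anywhere on the trace; the
#' corresponding retained feature ids (full-data halving chain) are
#' returned.
#'
#' @param trace a [run_selection_trace()] result.
#' @param delta stability tolerance in accuracy units (default 0.02).
#' @return list with `size`, `features`, `accuracy` (that size's median CV
#'   accuracy).
#' @export
select_stable_minimum <- function(trace, delta = 0.02) {
  stopifnot(inherits(trace, "selection_trace"))
  if (delta < 0) .stopf("delta must be >= 0")
  s <- trace$summary
  best <- max(s$median_cv_accuracy)
  ok <- s$size[s$median_cv_accuracy >= best - delta]
  size <- min(ok)
  list(size = size,
       features = trace$retained[[as.character(size)]],
       accuracy = s$median_cv_accuracy[s$size == size])
}

#' Plot a selection trace
#'
#' Median cross-validated accuracy against retained-set size (log2 x axis),
#' the classic bisection curve whose plateau edge marks the minimal
#' sufficient metabolite pattern.
#'
#' @param x a [run_selection_trace()] result.
#' @param file optional PNG path.
#' @param ... unused.
#' @return `x`, invisibly.
#' @export
plot.selection_trace <- function(x, file = NULL, ...) {
  if (!is.null(file)) {
    png(file, width = 700, height = 500)
    on.exit(dev.off())
  }
  s <- x$summary
  plot(s$size, s$median_cv_accuracy, log = "x", type = "b", pch = 19,
       xlab = "retained metabolites", ylab = "median CV accuracy (Pearson r)",
       main = "importance-halving feature selection")
  invisible(x)
}
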