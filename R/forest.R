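#' Random-forest hyperparameters
#'
#' Defaults follow the regression conventions of the random-forests
#' algorithm: `mtry = ceiling(p/3)` predictors tried per split, terminal
#' node size 5, 500 trees.
#'
#' @param n_trees number of trees (>= 1).
#' @param mtry predictors sampled per split; `NULL` means `ceiling(p/3)`.
#' @param min_node minimal terminal node size.
#' @param seed RNG seed for bootstrap and split sampling.
#' @param bootstrap `"resample"` (bootstrap of size n with replacement,
#'   default) or `"none"` (every tree sees all samples; no out-of-bag set —
#'   useful only for degenerate single-tree checks).
#' @return list of class `forest_params`.
#' @export
forest_params <- function(n_trees = 500, mtry = NULL, min_node = 5,
                          seed = 1, bootstrap = c("resample", "none")) {
  bootstrap <- match.arg(bootstrap)
  if (n_trees < 1) .stopf("n_trees must be >= 1")
  if (min_node < 1) .stopf("min_node must be >= 1")
  structure(list(n_trees = as.integer(n_trees), mtry = mtry,
                 min_node = as.integer(min_node), seed = as.integer(seed),
                 bootstrap = bootstrap),
            class = "forest_params")
}

.as_predictor_matrix <- function(X) {
  if (inherits(X, "feature_matrix")) X <- X$values
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("V%d", seq_len(ncol(X)))
  X
}

#' Fit a random-forest regression model with out-of-bag bookkeeping
#'
#' Trees are grown by [randomForest::randomForest()] on bootstrap resamples
#' of size n; the per-tree in-bag count matrix is retained so each tree's
#' out-of-bag (OOB) set — the samples its bootstrap missed — is known. A
#' fixed seed makes the forest reproducible.
#'
#' @param X predictor matrix (or [feature_matrix()]), n x p.
#' @param y numeric response, length n.
#' @param params a [forest_params()].
#' @return object of class `rf_model` with elements `rf` (the fitted
#'   forest), `feature_ids`, `params`.
#' @export
fit_forest <- function(X, y, params = forest_params()) {
  X <- .as_predictor_matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 5) .stopf("need at least 5 samples to fit a forest")
  if (length(y) != n) .stopf("response length does not match X")
  mtry <- params$mtry %||% max(1L, ceiling(p / 3))
  if (mtry > p) .stopf("mtry (%d) exceeds number of features (%d)", mtry, p)
  rf <- .with_seed(params$seed,
    randomForest::randomForest(
      x = X, y = y,
      ntree = params$n_trees,
      mtry = mtry,
      nodesize = params$min_node,
      replace = params$bootstrap == "resample",
      sampsize = n,
      keep.forest = TRUE,
      keep.inbag = TRUE))
  structure(list(rf = rf, feature_ids = colnames(X),
                 params = params, n = n),
            class = "rf_model")
}

#' @export
predict.rf_model <- function(object, newdata, ...) {
  newdata <- .as_predictor_matrix(newdata)
  unname(predict(object$rf, newdata[, object$feature_ids, drop = FALSE]))
}

#' Out-of-bag predictions of a fitted forest
#'
#' Each sample is predicted by the trees for which it was out-of-bag.
#'
#' @param model an [fit_forest()] result.
#' @return numeric vector of OOB predictions (NA where a sample was never
#'   out-of-bag).
#' @export
oob_predictions <- function(model) {
  stopifnot(inherits(model, "rf_model"))
  as.numeric(model$rf$predicted)
}

#' Out-of-bag permutation importance
#'
#' The importance measure used for feature selection: for each tree t and
#' feature j, the mean squared error of the tree on its out-of-bag samples
#' is computed twice — once on the true data and once with feature j's
#' values permuted within the OOB subset. The per-tree differences
#' \eqn{d_{tj} = MSE^{perm}_{tj} - MSE^{true}_{t}} are averaged over trees
#' (`raw`) and normalised by their standard error over trees
#' (`importance = raw / (sd/sqrt(T))`). A feature no tree splits on has
#' `raw = 0` exactly; features whose differences have zero spread over
#' trees are flagged (`sd_zero`) and report the raw mean as their
#' normalised score.
#'
#' Permutations are drawn from a deterministic stream keyed by
#' `(perm_seed, tree, feature)` (see [perm_indices()]), so the computation
#' is exactly reproducible.
#'
#' @param model an [fit_forest()] result.
#' @param X,y the training data the model was fitted on.
#' @param perm_seed integer seed for the permutation stream.
#' @return `data.frame` of class `importance_vector` with columns
#'   `feature_id`, `raw`, `importance`, `rank` (1 = most important,
#'   ties broken by feature id), `sd_zero`.
#' @export
oob_permutation_importance <- function(model, X, y, perm_seed = 1) {
  stopifnot(inherits(model, "rf_model"))
  X <- .as_predictor_matrix(X)
  if (!identical(colnames(X), model$feature_ids))
    .stopf("X columns do not match the model's training features")
  if (nrow(X) != model$n || length(y) != model$n)
    .stopf("X/y dimensions do not match the training data")
  if (model$params$bootstrap == "none")
    .stopf("model has no out-of-bag samples (bootstrap = 'none')")
  inbag <- model$rf$inbag
  if (any(rowSums(inbag == 0) == 0))
    .warnf("some samples are never out-of-bag; importance may be unstable")
  f <- model$rf$forest
  res <- .rf_oob_importance_cpp(
    f$leftDaughter, f$rightDaughter, f$bestvar, f$xbestsplit, f$nodepred,
    as.integer(f$ndbigtree), inbag, X, as.numeric(y), as.integer(perm_seed))
  raw <- res$raw
  se <- res$sd / sqrt(res$n_trees_used)
  sd_zero <- res$sd == 0
  imp <- ifelse(sd_zero, raw, raw / se)
  ord <- order(-imp, model$feature_ids)
  rk <- integer(length(imp)); rk[ord] <- seq_along(imp)
  out <- data.frame(feature_id = model$feature_ids,
                    raw = raw, importance = imp, rank = rk,
                    sd_zero = sd_zero, stringsAsFactors = FALSE)
  attr(out, "perm_seed") <- perm_seed
  attr(out, "n_trees_used") <- res$n_trees_used
  class(out) <- c("importance_vector", "data.frame")
  out
}

#' Deterministic permutation for one (tree, feature) pair
#'
#' The permutation of a tree's m out-of-bag positions used by
#' [oob_permutation_importance()]; exposed so an independent recomputation
#' can replay the identical shuffles.
#'
#' @param seed permutation seed.
#' @param tree tree index (1-based).
#' @param feature feature index (1-based).
#' @param m number of out-of-bag samples.
#' @return integer permutation of `1:m`.
#' @export
perm_indices <- function(seed, tree, feature, m) {
  .perm_indices_cpp(as.integer(seed), as.integer(tree),
                    as.integer(feature), as.integer(m))
}

#' Prediction accuracy: Pearson correlation of true and predicted response
#'
#' The shared accuracy metric of all models in the pipeline: the Pearson
#' product-moment correlation between the observed and the predicted
#' delta-glucose. Affine-invariant (any `a*y + b`, `a > 0`, scores 1).
#' If either vector is constant the correlation is undefined; `0` is
#' returned with attribute `degenerate = TRUE`.
#'
#' @param y_true,y_pred numeric vectors of equal length >= 3.
#' @return Pearson r in [-1, 1].
#' @export
accuracy <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) .stopf("length mismatch")
  if (length(y_true) < 3) .stopf("need at least 3 pairs")
  if (sd(y_true) == 0 || sd(y_pred) == 0)
    return(structure(0, degenerate = TRUE))
  unname(cor(y_true, y_pred))
}

#' Least-squares linear baseline
#'
#' Ordinary least squares of the response on the supplied predictor
#' columns. When the design is rank-deficient (e.g. duplicated predictors)
#' a warning is emitted and the minimum-norm coefficient vector is
#' reported; fitted values are the least-squares projection either way.
#'
#' @param X predictor matrix (or [feature_matrix()]).
#' @param y numeric response.
#' @return object of class `linear_model` with `coefficients` (intercept
#'   first), `fitted`, `rank`.
#' @export
fit_linear <- function(X, y) {
  X <- .as_predictor_matrix(X)
  n <- nrow(X)
  if (n < 2) .stopf("need at least 2 samples")
  if (length(y) != n) .stopf("response length does not match X")
  A <- cbind("(Intercept)" = 1, X)
  qr_ <- qr(A)
  if (qr_$rank < ncol(A)) {
    .warnf("rank-deficient design (rank %d < %d); reporting minimum-norm coefficients",
           qr_$rank, ncol(A))
    cf <- as.numeric(MASS::ginv(A) %*% y)
  } else {
    cf <- qr.coef(qr_, y)
  }
  names(cf) <- colnames(A)
  fitted <- as.numeric(A %*% cf)
  structure(list(coefficients = cf, fitted = fitted,
                 rank = qr_$rank, feature_ids = colnames(X)),
            class = "linear_model")
}

#' @export
predict.linear_model <- function(object, newdata, ...) {
  newdata <- .as_predictor_matrix(newdata)
  A <- cbind(1, newdata[, object$feature_ids, drop = FALSE])
  as.numeric(A %*% object$coefficients)
}
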