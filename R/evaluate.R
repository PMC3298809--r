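#' Repeated k-fold cross-validation specification
#'
#' The evaluation protocol: tenfold cross-validation repeated many times,
#' each repetition with a fresh uniform random partition (no
#' stratification); per repetition the held-out predictions of all folds
#' are pooled into one vector and scored once against the observed
#' response, and the median over repetitions is reported. The full-scale
#' profile uses 100 repetitions; `repeats = 5` is a practical desk-scale
#' default (see [analysis_profile()]).
#'
#' @param folds number of folds (2..n).
#' @param repeats number of repetitions (>= 1).
#' @param seed master seed; fold partitions and all fold-level model seeds
#'   derive from it deterministically.
#' @param pooling `"pooled"` (default: one accuracy per repetition on the
#'   pooled out-of-fold predictions) or `"per_fold_mean"` (mean of
#'   per-fold accuracies).
#' @return list of class `cv_spec`.
#' @export
cv_spec <- function(folds = 10, repeats = 5, seed = 1,
                    pooling = c("pooled", "per_fold_mean")) {
  pooling <- match.arg(pooling)
  if (folds < 2) .stopf("folds must be >= 2")
  if (repeats < 1) .stopf("repeats must be >= 1")
  structure(list(folds = as.integer(folds), repeats = as.integer(repeats),
                 seed = as.integer(seed), pooling = pooling),
            class = "cv_spec")
}

## n x repeats matrix of fold labels, derived from the master seed so the
## same spec yields the same partitions for every model being compared.
.fold_matrix <- function(n, cv) {
  if (cv$folds > n) .stopf("folds (%d) exceed sample size (%d)", cv$folds, n)
  .with_seed(.derive_seed(cv$seed, 9173),
    vapply(seq_len(cv$repeats),
           function(r) sample(rep_len(seq_len(cv$folds), n)),
           integer(n)))
}

#' Modelling pipeline specification
#'
#' The five pipelines of the model comparison. Every data-dependent step
#' (Spearman filter, importance halving) is part of the pipeline and is
#' re-fit inside each training fold when evaluated under cross-validation
#' (unless `nested = FALSE`, the deliberately leaky diagnostic variant
#' that runs feature selection once on the full data before
#' cross-validation).
#'
#' @param type one of `"spearman_linear"`, `"spearman_forest"`,
#'   `"halving_forest"`, `"halving_clinical_forest"`, `"clinical_forest"`.
#' @param alpha significance level of the Spearman filter.
#' @param n_select target size of the importance-halving selection.
#' @param params [forest_params()] used by forest fits.
#' @param nested logical; `FALSE` selects features on the full data before
#'   cross-validation (for leakage demonstrations only).
#' @return list of class `pipeline_spec`.
#' @export
pipeline_spec <- function(type = c("spearman_linear", "spearman_forest",
                                   "halving_forest",
                                   "halving_clinical_forest",
                                   "clinical_forest"),
                          alpha = 0.05, n_select = 9,
                          params = forest_params(), nested = TRUE) {
  type <- match.arg(type)
  structure(list(type = type, alpha = alpha,
                 n_select = as.integer(n_select),
                 params = params, nested = isTRUE(nested)),
            class = "pipeline_spec")
}

## Assemble the predictor matrix a pipeline operates on.
.pipeline_design <- function(spec, X, clinical) {
  X <- if (is.null(X)) NULL else .as_predictor_matrix(X)
  needs_clin <- spec$type %in% c("halving_clinical_forest", "clinical_forest")
  if (needs_clin && is.null(clinical))
    .stopf("pipeline '%s' requires a clinical table", spec$type)
  C <- if (needs_clin) encode_clinical(clinical) else NULL
  switch(spec$type,
         clinical_forest = C,
         halving_clinical_forest = cbind(X, C),
         X)
}

## Fit one pipeline on training rows; returns list(predict_fn, selected).
.pipeline_fit <- function(spec, D, y, seed) {
  p <- ncol(D)
  mean_model <- function() {
    mu <- mean(y)
    list(predict_fn = function(newD) rep(mu, nrow(newD)), selected = character())
  }
  fp <- function() forest_params(n_trees = spec$params$n_trees,
                                 mtry = spec$params$mtry,
                                 min_node = spec$params$min_node,
                                 seed = .derive_seed(seed, 7),
                                 bootstrap = spec$params$bootstrap)
  if (spec$type %in% c("spearman_linear", "spearman_forest")) {
    fm <- feature_matrix(D, stage = "log_normalized")
    sel <- select_significant(spearman_screen(fm, y, alpha = spec$alpha))
    if (!length(sel)) return(mean_model())
    Dtr <- D[, sel, drop = FALSE]
    if (spec$type == "spearman_linear") {
      model <- suppressWarnings(fit_linear(Dtr, y))
    } else {
      model <- fit_forest(Dtr, y, fp())
    }
    list(predict_fn = function(newD)
           predict(model, newD[, sel, drop = FALSE]),
         selected = sel)
  } else if (spec$type %in% c("halving_forest", "halving_clinical_forest")) {
    target <- min(spec$n_select, p)
    hv <- .halve_to(D, y, spec$params, target = target,
                    seed = .derive_seed(seed, 11))
    sel <- hv$selected
    model <- fit_forest(D[, sel, drop = FALSE], y, fp())
    list(predict_fn = function(newD)
           predict(model, newD[, sel, drop = FALSE]),
         selected = sel)
  } else { # clinical_forest
    model <- fit_forest(D, y, fp())
    list(predict_fn = function(newD) predict(model, newD),
         selected = colnames(D))
  }
}

#' Leakage-safe repeated cross-validation of a modelling pipeline
#'
#' Evaluates one [pipeline_spec()] under a [cv_spec()] protocol. Within
#' every training fold the entire pipeline — Spearman filtering or
#' importance-halving selection, then model fitting — is re-run on the
#' training rows only; held-out predictions are pooled per repetition and
#' scored with [accuracy()]; the median over repetitions is the headline
#' cross-validated accuracy. The all-sample (resubstitution) accuracy of
#' the pipeline fitted once on everything is reported alongside, as is the
#' out-of-bag accuracy for forest pipelines.
#'
#' @param X metabolite predictor matrix (or [feature_matrix()]), or `NULL`
#'   for the clinical-only pipeline.
#' @param y response vector.
#' @param spec a [pipeline_spec()].
#' @param cv a [cv_spec()].
#' @param clinical a [clinical_table()] (required by clinical pipelines).
#' @param folds optional precomputed fold matrix (n x repeats), used by
#'   [compare_models()] to share partitions across pipelines.
#' @return object of class `evaluation_result`: `accuracy_all`,
#'   `accuracy_oob` (NA for linear), `cv_accuracies` (per repetition),
#'   `cv_median`, `selected_full` (selection on the full data),
#'   `selection_freq` (how often each feature was selected across folds).
#' @export
cross_validate <- function(X, y, spec, cv = cv_spec(), clinical = NULL,
                           folds = NULL) {
  stopifnot(inherits(spec, "pipeline_spec"), inherits(cv, "cv_spec"))
  D <- .pipeline_design(spec, X, clinical)
  n <- nrow(D)
  if (length(y) != n) .stopf("response length does not match predictors")
  if (is.null(folds)) folds <- .fold_matrix(n, cv)

  ## full-data fit: resubstitution + OOB accuracy, and the full-data selection
  full <- .pipeline_fit(spec, D, y, seed = .derive_seed(cv$seed, 0))
  acc_all <- as.numeric(accuracy(y, full$predict_fn(D)))
  acc_oob <- NA_real_
  if (spec$type != "spearman_linear" && length(full$selected)) {
    oobm <- fit_forest(D[, full$selected, drop = FALSE], y,
                       forest_params(n_trees = spec$params$n_trees,
                                     mtry = spec$params$mtry,
                                     min_node = spec$params$min_node,
                                     seed = .derive_seed(cv$seed, 0, 7),
                                     bootstrap = spec$params$bootstrap))
    acc_oob <- as.numeric(accuracy(y, oob_predictions(oobm)))
  }

  sel_count <- setNames(numeric(ncol(D)), colnames(D))
  accs <- numeric(cv$repeats)
  degen <- logical(cv$repeats)
  for (r in seq_len(cv$repeats)) {
    pred <- rep(NA_real_, n)
    fold_acc <- numeric(cv$folds)
    for (k in seq_len(cv$folds)) {
      tr <- folds[, r] != k
      if (spec$nested) {
        fit <- .pipeline_fit(spec, D[tr, , drop = FALSE], y[tr],
                             seed = .derive_seed(cv$seed, r, k))
      } else {
        ## leaky variant: full-data selection, only the final model re-fit
        sel <- full$selected
        fit <- if (!length(sel)) {
          mu <- mean(y[tr]); list(predict_fn = function(nd) rep(mu, nrow(nd)),
                                  selected = sel)
        } else if (spec$type == "spearman_linear") {
          m <- suppressWarnings(fit_linear(D[tr, sel, drop = FALSE], y[tr]))
          list(predict_fn = function(nd) predict(m, nd[, sel, drop = FALSE]),
               selected = sel)
        } else {
          m <- fit_forest(D[tr, sel, drop = FALSE], y[tr],
                          forest_params(n_trees = spec$params$n_trees,
                                        mtry = spec$params$mtry,
                                        min_node = spec$params$min_node,
                                        seed = .derive_seed(cv$seed, r, k, 7),
                                        bootstrap = spec$params$bootstrap))
          list(predict_fn = function(nd) predict(m, nd[, sel, drop = FALSE]),
               selected = sel)
        }
      }
      te <- !tr
      pred[te] <- fit$predict_fn(D[te, , drop = FALSE])
      if (length(fit$selected))
        sel_count[fit$selected] <- sel_count[fit$selected] + 1
      if (cv$pooling == "per_fold_mean")
        fold_acc[k] <- as.numeric(accuracy(y[te], pred[te]))
    }
    a <- if (cv$pooling == "pooled") accuracy(y, pred) else mean(fold_acc)
    degen[r] <- isTRUE(attr(a, "degenerate"))
    accs[r] <- as.numeric(a)
  }
  structure(list(spec = spec, cv = cv,
                 accuracy_all = acc_all, accuracy_oob = acc_oob,
                 cv_accuracies = accs, cv_median = median(accs),
                 degenerate_repeats = degen,
                 selected_full = full$selected,
                 selection_freq = sel_count / (cv$repeats * cv$folds)),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("pipeline %-24s all-sample r = %.3f  median CV r = %.3f (%d repeats)\n",
              x$spec$type, x$accuracy_all, x$cv_median, x$cv$repeats))
  invisible(x)
}

#' Five-way model comparison
#'
#' Evaluates, under one shared fold structure per repetition, the five
#' pipelines of the headline comparison: Spearman-filtered linear model,
#' Spearman-filtered forest, importance-halving forest, importance-halving
#' forest with the established clinical risk markers added, and a forest on
#' the established markers alone.
#'
#' @param X metabolite predictor matrix (or [feature_matrix()]).
#' @param clinical a [clinical_table()].
#' @param y response vector.
#' @param cv a [cv_spec()].
#' @param params [forest_params()] shared by all forest fits.
#' @param alpha Spearman filter level.
#' @param n_select importance-halving target size.
#' @return data.frame of class `model_comparison` with one row per
#'   pipeline (`selection`, `model`, `accuracy_all`, `accuracy_oob`,
#'   `accuracy_cv`); the full [cross_validate()] results are in
#'   `attr(, "results")`.
#' @export
compare_models <- function(X, clinical, y, cv = cv_spec(),
                           params = forest_params(), alpha = 0.05,
                           n_select = 9) {
  X <- .as_predictor_matrix(X)
  folds <- .fold_matrix(nrow(X), cv)
  types <- c("spearman_linear", "spearman_forest", "halving_forest",
             "halving_clinical_forest", "clinical_forest")
  labels <- data.frame(
    selection = c("Spearman correlation", "Spearman correlation",
                  "RF importance", "RF importance + established markers",
                  "Established markers"),
    model = c("linear model", "random forest", "random forest",
              "random forest", "random forest"),
    stringsAsFactors = FALSE)
  results <- lapply(types, function(tp)
    cross_validate(X, y,
                   pipeline_spec(tp, alpha = alpha, n_select = n_select,
                                 params = params),
                   cv = cv, clinical = clinical, folds = folds))
  out <- cbind(labels,
               accuracy_all = vapply(results, `[[`, numeric(1), "accuracy_all"),
               accuracy_oob = vapply(results, `[[`, numeric(1), "accuracy_oob"),
               accuracy_cv = vapply(results, `[[`, numeric(1), "cv_median"))
  attr(out, "results") <- setNames(results, types)
  class(out) <- c("model_comparison", "data.frame")
  out
}
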