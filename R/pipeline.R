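#' Analysis profiles
#'
#' Bundled parameter profiles: `"desk"` (200 trees, 5 CV repetitions) keeps
#' a full run interactive on one CPU; `"faithful"` (500 trees, 100
#' repetitions of tenfold CV) is the full-study-scale protocol.
#'
#' @param profile `"desk"` or `"faithful"`.
#' @param seed master seed propagated to both specs.
#' @return list with `params` ([forest_params()]) and `cv` ([cv_spec()]).
#' @export
analysis_profile <- function(profile = c("desk", "faithful"), seed = 1) {
  profile <- match.arg(profile)
  if (profile == "desk")
    list(params = forest_params(n_trees = 200, seed = seed),
         cv = cv_spec(folds = 10, repeats = 5, seed = seed))
  else
    list(params = forest_params(n_trees = 500, seed = seed),
         cv = cv_spec(folds = 10, repeats = 100, seed = seed))
}

#' Run the full analysis and write a report bundle
#'
#' Executes the complete pipeline on a cohort — preprocessing (below-LOD
#' imputation, log-normalisation, delta-glucose), the univariate Spearman
#' screen, collinearity diagnostics (correlation matrix, heatmap,
#' condition number), the five-way model comparison under shared
#' cross-validation folds, the importance-halving selection trace with
#' plateau selection, and the importance table of the final metabolite
#' pattern — and writes delimited-text tables, figures and a run-metadata
#' JSON to `out_dir`.
#'
#' @param cohort a [generate_cohort()] result, or a list with elements
#'   `features` (raw [feature_matrix()]) and `clinical`
#'   ([clinical_table()]).
#' @param out_dir output directory (created if needed); `NULL` skips all
#'   file output.
#' @param profile `"desk"` or `"faithful"` (see [analysis_profile()]), or a
#'   list with elements `params` ([forest_params()]) and `cv` ([cv_spec()])
#'   for full control.
#' @param seed master seed for every stochastic stage.
#' @param alpha Spearman screen level.
#' @param stability_delta plateau tolerance for [select_stable_minimum()].
#' @return list (invisibly when writing): `screen`, `condition_number`,
#'   `comparison`, `trace`, `selection`, `importance`, `response_summary`.
#' @export
run_full_analysis <- function(cohort, out_dir = NULL,
                              profile = c("desk", "faithful"), seed = 1,
                              alpha = 0.05, stability_delta = 0.02) {
  prof <- if (is.list(profile)) profile
          else analysis_profile(match.arg(profile), seed = seed)
  stopifnot(inherits(prof$params, "forest_params"), inherits(prof$cv, "cv_spec"))
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- "preprocessing"
  res <- tryCatch({
    prep <- preprocess_cohort(cohort$features, cohort$clinical)
    X <- prep$features; y <- prep$delta
    resp <- summarize_response(y)

    stage <- "univariate screen"
    screen <- spearman_screen(X, y, alpha = alpha)
    sig <- select_significant(screen)

    stage <- "collinearity diagnostics"
    corr <- if (length(sig) >= 1) correlation_matrix(X, y, sig) else NULL
    kappa <- if (!is.null(corr)) condition_number(corr) else NA_real_

    stage <- "model comparison"
    comparison <- compare_models(X, cohort$clinical, y, cv = prof$cv,
                                 params = prof$params, alpha = alpha)

    stage <- "selection trace"
    trace <- run_selection_trace(X, y, params = prof$params, cv = prof$cv)
    selection <- select_stable_minimum(trace, delta = stability_delta)

    stage <- "importance table"
    Xsel <- select_features(X, selection$features)
    fmod <- fit_forest(Xsel, y,
                       forest_params(n_trees = prof$params$n_trees,
                                     seed = .derive_seed(seed, 99)))
    imp <- oob_permutation_importance(fmod, Xsel, y,
                                      perm_seed = .derive_seed(seed, 100))
    imp <- imp[order(imp$rank), ]

    list(screen = screen, significant = sig, correlation = corr,
         condition_number = kappa, comparison = comparison, trace = trace,
         selection = selection, importance = imp, response_summary = resp)
  }, error = function(e)
    .stopf("analysis failed at stage '%s': %s", stage, conditionMessage(e)))

  if (!is.null(out_dir)) {
    wt <- function(df, f) utils::write.table(
      df, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    wt(as.data.frame(res$screen), "screen.tsv")
    wt(as.data.frame(res$comparison), "model_comparison.tsv")
    wt(res$trace$summary, "selection_trace.tsv")
    wt(as.data.frame(res$importance), "importance.tsv")
    if (!is.null(res$correlation))
      plot_correlation_matrix(res$correlation,
                              file = file.path(out_dir, "correlation.png"))
    plot(res$trace, file = file.path(out_dir, "selection_trace.png"))
    meta <- list(seed = seed, profile = prof,
                 alpha = alpha, stability_delta = stability_delta,
                 condition_number = res$condition_number,
                 selected_size = res$selection$size,
                 selected_features = res$selection$features,
                 response_summary = res$response_summary,
                 r_version = as.character(getRversion()),
                 package_version = as.character(
                   utils::packageVersion("metaboforest")))
    jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
    return(invisible(res))
  }
  res
}
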