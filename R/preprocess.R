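#' Compute the glucose-development response
#'
#' The response of the whole analysis is the per-subject change in fasting
#' plasma glucose normalised by the elapsed time between the baseline and
#' follow-up measurement:
#' \deqn{\Delta glucose_i = (glucose^{followup}_i - glucose^{baseline}_i) /
#'   elapsed\_years_i}
#' in mg/(dl*a).
#'
#' @param clinical a [clinical_table()].
#' @return named numeric vector of delta-glucose values, one per subject.
#' @export
compute_delta_glucose <- function(clinical) {
  stopifnot(inherits(clinical, "clinical_table"))
  bad <- clinical$subject_id[clinical$elapsed_years <= 0]
  if (length(bad))
    .stopf("non-positive elapsed time for subject(s): %s",
           paste(head(bad, 5), collapse = ", "))
  setNames((clinical$glucose_followup - clinical$glucose_baseline) /
             clinical$elapsed_years,
           clinical$subject_id)
}

#' Impute below-limit-of-detection entries
#'
#' Missing entries arise only when a metabolite's concentration fell below
#' the instrument's detection limit, so each missing entry of feature j is
#' replaced by 0.7 times the minimum *observed* value of that feature.
#' Because the factor is strictly below 1, every imputed value sits strictly
#' below all observed values of its feature and within-feature ranks of the
#' observed entries are preserved; the operation is idempotent.
#'
#' @param fm a raw-stage [feature_matrix()].
#' @param factor multiplier on the per-feature minimum (default 0.7).
#' @return a `feature_matrix` at stage `"imputed"` with no missing entries.
#' @export
impute_lod <- function(fm, factor = 0.7) {
  stopifnot(inherits(fm, "feature_matrix"))
  v <- fm$values
  n_obs <- colSums(!is.na(v))
  if (any(n_obs == 0))
    .stopf("feature(s) with no observed value: %s",
           paste(fm$feature_ids[n_obs == 0], collapse = ", "))
  for (j in which(colSums(is.na(v)) > 0)) {
    mn <- min(v[, j], na.rm = TRUE)
    v[is.na(v[, j]), j] <- factor * mn
  }
  feature_matrix(v, feature_ids = fm$feature_ids,
                 subject_ids = fm$subject_ids,
                 feature_names = unname(fm$feature_names),
                 stage = "imputed")
}

#' Log-transform and normalise an intensity matrix
#'
#' Natural-log transform of the (imputed, strictly positive) relative
#' intensities followed by median centering. The default centers each
#' feature to zero median; this is strictly monotone within every feature,
#' so within-feature ranks — and hence the Spearman screen — are unchanged,
#' and tree-based models are insensitive to it. `mode = "sample_feature"`
#' first centers each sample's log-profile to zero median (a crude
#' total-signal correction) and then centers features; because each row is
#' shifted by its own constant, this mode can reorder values within a
#' feature and is a genuinely different normalisation, not a relabelling.
#'
#' @param fm an imputed-stage [feature_matrix()] (no missing, all > 0).
#' @param mode `"feature"` (default) or `"sample_feature"`.
#' @return a `feature_matrix` at stage `"log_normalized"`.
#' @export
log_normalize <- function(fm, mode = c("feature", "sample_feature")) {
  stopifnot(inherits(fm, "feature_matrix"))
  mode <- match.arg(mode)
  v <- fm$values
  if (anyNA(v))
    .stopf("matrix still contains missing entries; run impute_lod() first")
  bad <- which(v <= 0, arr.ind = TRUE)
  if (nrow(bad))
    .stopf("non-positive entry at subject '%s', feature '%s'",
           fm$subject_ids[bad[1, 1]], fm$feature_ids[bad[1, 2]])
  lv <- log(v)
  if (mode == "sample_feature") {
    lv <- lv - apply(lv, 1, median)
  }
  lv <- sweep(lv, 2, apply(lv, 2, median))
  feature_matrix(lv, feature_ids = fm$feature_ids,
                 subject_ids = fm$subject_ids,
                 feature_names = unname(fm$feature_names),
                 stage = "log_normalized")
}

#' Preprocess a raw cohort to the analysis-ready state
#'
#' Convenience wrapper: below-LOD imputation, log-normalisation, and the
#' delta-glucose response, with subject alignment checked.
#'
#' @param fm raw [feature_matrix()].
#' @param clinical [clinical_table()] with matching subjects.
#' @param mode normalisation mode, see [log_normalize()].
#' @return list with elements `features` (log-normalized `feature_matrix`),
#'   `delta` (response vector) and `clinical`.
#' @export
preprocess_cohort <- function(fm, clinical, mode = "feature") {
  stopifnot(inherits(fm, "feature_matrix"), inherits(clinical, "clinical_table"))
  if (!identical(fm$subject_ids, clinical$subject_id))
    .stopf("subject ids of feature matrix and clinical table do not match")
  feats <- log_normalize(impute_lod(fm), mode = mode)
  list(features = feats,
       delta = compute_delta_glucose(clinical),
       clinical = clinical)
}
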