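#' Synthetic cohort generator configuration
#'
#' Defines the study conditions the generator emulates: 172 subjects with
#' 286 positively valued, right-skewed (lognormal) metabolite features in
#' correlated blocks; per-feature lower-tail censoring standing in for
#' below-limit-of-detection missingness; a small signal set (default nine
#' features, partly non-linear) driving the glucose-development response
#' delta-glucose (median ~0.8, SD ~2.3 mg/(dl*a)); and clinical covariates
#' that by default carry no signal.
#'
#' The default effect sizes were fixed once by forward calculation and a
#' small calibration simulation against those response targets (see the
#' methods vignette): every signal feature combines an equal linear
#' coefficient on the standardized log scale with a symmetric two-threshold
#' "band" term (a non-monotone component invisible to rank correlation and
#' to least squares), and features 1 and 2 are additionally coupled by a
#' pairwise product. Roughly half of the planted signal variance is thus
#' available only to a forest.
#'
#' @param n_subjects number of subjects (default 172).
#' @param n_features number of metabolite features (default 286).
#' @param n_signal number of signal features (default 9; 0 gives a
#'   pure-noise cohort).
#' @param n_blocks number of correlated feature blocks (default 40).
#' @param block_rho within-block correlation of log-intensities, in [0, 1)
#'   (default 0.35).
#' @param lod_quantile fraction of each feature's lowest values censored as
#'   missing, in [0, 1) (default 0.05; the real matrix's missingness rate
#'   is unknown, this is a free choice).
#' @param effect_linear numeric vector, length `n_signal`: linear
#'   coefficients of the standardized signal log-intensities in the
#'   response, mg/(dl*a) per SD.
#' @param effect_nonlinear list with optional elements `products` (a list
#'   of `list(features = c(i, j), coef)`: coefficient on the product of two
#'   standardized signal features) and `thresholds` (a list of
#'   `list(feature = i, cut, coef)`: coefficient on the indicator that
#'   signal feature i exceeds `cut` SDs; two entries with opposite-sign
#'   coefficients on the same feature build a non-monotone "band" effect
#'   invisible to rank correlation). `NULL` disables all non-linear terms.
#' @param noise_sd residual SD of delta-glucose, mg/(dl*a) (default 0.4).
#' @param delta_intercept location of delta-glucose, mg/(dl*a)
#'   (default -3.35, calibrated so the median lands near 0.8; the band
#'   terms shift the location).
#' @param clinical_effect scalar >= 0: coefficient of standardized BMI in
#'   the response (default 0 — clinical covariates are pure noise).
#' @param seed RNG seed; identical config + seed gives bit-identical
#'   cohorts.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 172, n_features = 286, n_signal = 9,
                          n_blocks = 40, block_rho = 0.35,
                          lod_quantile = 0.05,
                          effect_linear = NULL,
                          effect_nonlinear = NULL,
                          noise_sd = 0.4, delta_intercept = -3.35,
                          clinical_effect = 0, seed = 1) {
  chk_count <- function(x, nm, min = 1) {
    if (length(x) != 1 || is.na(x) || x < min || x != round(x))
      .stopf("invalid configuration: %s must be an integer >= %d", nm, min)
  }
  chk_count(n_subjects, "n_subjects", 2)
  chk_count(n_features, "n_features")
  chk_count(n_signal, "n_signal", 0)
  chk_count(n_blocks, "n_blocks")
  if (n_signal > n_features)
    .stopf("invalid configuration: n_signal exceeds n_features")
  if (n_signal > min(n_blocks, n_features) && n_signal > 0)
    .stopf("invalid configuration: n_signal exceeds the number of occupied blocks (signal features occupy distinct blocks)")
  if (block_rho < 0 || block_rho >= 1)
    .stopf("invalid configuration: block_rho must be in [0, 1)")
  if (lod_quantile < 0 || lod_quantile >= 1)
    .stopf("invalid configuration: lod_quantile must be in [0, 1)")
  if (noise_sd < 0) .stopf("invalid configuration: noise_sd must be >= 0")
  if (clinical_effect < 0)
    .stopf("invalid configuration: clinical_effect must be >= 0")
  if (is.null(effect_linear) && n_signal > 0) {
    ## equal per-feature shares maximise the weakest feature's marginal
    ## signal at fixed response SD (see the methods vignette)
    effect_linear <- rep(0.52, n_signal)
  }
  if (n_signal == 0) effect_linear <- numeric(0)
  if (length(effect_linear) != n_signal)
    .stopf("invalid configuration: effect_linear must have length n_signal")
  if (is.null(effect_nonlinear) && n_signal >= 2) {
    band <- function(i, cut, coef) list(
      list(feature = i, cut = -cut, coef = coef),
      list(feature = i, cut = cut, coef = -coef))
    effect_nonlinear <- list(
      products = list(list(features = c(1, 2), coef = 0.85)),
      thresholds = do.call(c, lapply(seq_len(n_signal),
                                     function(i) band(i, 0.6, 1.0))))
  }
  if (!is.null(effect_nonlinear)) {
    idx <- c(unlist(lapply(effect_nonlinear$products, `[[`, "features")),
             vapply(effect_nonlinear$thresholds, `[[`, numeric(1), "feature"))
    if (length(idx) && (any(idx < 1) || any(idx > n_signal)))
      .stopf("invalid configuration: effect_nonlinear indexes outside 1..n_signal")
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 n_features = as.integer(n_features),
                 n_signal = as.integer(n_signal),
                 n_blocks = as.integer(n_blocks),
                 block_rho = block_rho,
                 lod_quantile = lod_quantile,
                 effect_linear = as.numeric(effect_linear),
                 effect_nonlinear = effect_nonlinear,
                 noise_sd = noise_sd,
                 delta_intercept = delta_intercept,
                 clinical_effect = clinical_effect,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

## Signal function on the standardized log-intensity matrix of the signal
## features (columns in signal order). Returned separately so the truth can
## reproduce the noise-free response.
.signal_function <- function(config) {
  force(config)
  function(Zs) {
    f <- rep(config$delta_intercept, nrow(Zs))
    if (config$n_signal > 0)
      f <- f + as.numeric(Zs %*% config$effect_linear)
    nl <- config$effect_nonlinear
    for (pr in nl$products)
      f <- f + pr$coef * Zs[, pr$features[1]] * Zs[, pr$features[2]]
    for (th in nl$thresholds)
      f <- f + th$coef * (Zs[, th$feature] > th$cut)
    f
  }
}

#' Generate a synthetic cohort
#'
#' Draws log-intensities from block-structured Gaussians (one shared factor
#' per block: within-block correlation is exactly `block_rho` in
#' population), exponentiates them into positive right-skewed intensities,
#' builds delta-glucose from the configured linear and non-linear terms on
#' the standardized signal log-intensities plus Gaussian noise, derives the
#' follow-up glucose as `baseline + elapsed_years * delta`, draws clinical
#' covariates from ranges typical of a late-middle-aged metabolic-syndrome
#' follow-up cohort (coupled to the response only through
#' `clinical_effect`), and finally censors each feature's lowest
#' `lod_quantile` fraction as missing.
#'
#' @param config a [cohort_config()].
#' @return object of class `synthetic_cohort`: `features` (raw
#'   [feature_matrix()] with missing entries), `clinical`
#'   ([clinical_table()]), and `truth` (signal feature ids, effect
#'   specification, the generating function, and the noise-free signal
#'   values).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_subjects; p <- config$n_features
  .with_seed(config$seed, {
    feature_ids <- sprintf("M%03d", seq_len(p))
    subject_ids <- sprintf("S%03d", seq_len(n))
    block <- rep_len(seq_len(config$n_blocks), p)

    ## signal features: one per (non-empty) block so collinear proxies exist
    ## but no two signal features share a block
    sig_idx <- if (config$n_signal > 0) {
      avail <- unique(block)
      blocks <- avail[sample.int(length(avail), config$n_signal)]
      vapply(blocks, function(b) {
        members <- which(block == b)
        members[sample.int(length(members), 1)]
      }, integer(1))
    } else integer(0)

    B <- matrix(rnorm(n * config$n_blocks), n, config$n_blocks)
    E <- matrix(rnorm(n * p), n, p)
    rho <- config$block_rho
    Z <- sqrt(rho) * B[, block, drop = FALSE] + sqrt(1 - rho) * E

    ## lognormal intensities with feature-specific location and scale
    mu <- runif(p, 3, 9)
    sigma <- runif(p, 0.3, 1)
    intens <- exp(sweep(sweep(Z, 2, sigma, `*`), 2, mu, `+`))

    f_signal <- .signal_function(config)
    Zs <- Z[, sig_idx, drop = FALSE]
    f <- f_signal(Zs)
    delta <- f + rnorm(n, 0, config$noise_sd)

    ## clinical covariates (units: cm, kg/m^2, years, mg/dl)
    gender <- rbinom(n, 1, 0.622)
    waist <- rnorm(n, 93.8, 13.8)
    bmi <- pmax(rnorm(n, 28.6, 5.2), 16)
    age <- pmin(pmax(rnorm(n, 55.7, 11.7), 25), 85)
    glucose_baseline <- pmax(rnorm(n, 92.1, 11.6), 55)
    elapsed <- pmax(rnorm(n, 5.6, 0.7), 1)
    if (config$clinical_effect > 0)
      delta <- delta + config$clinical_effect * as.numeric(scale(bmi))
    glucose_followup <- glucose_baseline + elapsed * delta

    ## below-LOD censoring last: lowest floor(q*n) values per feature
    k <- floor(config$lod_quantile * n)
    if (k > 0) {
      for (j in seq_len(p))
        intens[order(intens[, j])[seq_len(k)], j] <- NA_real_
    }

    features <- feature_matrix(intens, feature_ids = feature_ids,
                               subject_ids = subject_ids, stage = "raw")
    clinical <- clinical_table(subject_ids, gender, waist, bmi, age,
                               glucose_baseline, glucose_followup, elapsed)
    structure(list(features = features,
                   clinical = clinical,
                   truth = list(signal_ids = feature_ids[sig_idx],
                                signal_index = sig_idx,
                                effect_linear = config$effect_linear,
                                effect_nonlinear = config$effect_nonlinear,
                                delta_intercept = config$delta_intercept,
                                noise_sd = config$noise_sd,
                                f = f,
                                signal_function = f_signal),
                   config = config),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d subjects, %d features (%d signal), seed %d\n",
              x$config$n_subjects, x$config$n_features, x$config$n_signal,
              x$config$seed))
  invisible(x)
}

#' Summarise the glucose-development response of a cohort
#'
#' Median, range and SD (n-1 denominator) of delta-glucose, plus the counts
#' of subjects with decreased (delta <= 0) and increased (delta > 0)
#' fasting glucose.
#'
#' @param x a [generate_cohort()] result, a [clinical_table()], or a
#'   numeric delta-glucose vector.
#' @return list with `median`, `min`, `max`, `sd`, `n_decreased`,
#'   `n_increased`, `n`.
#' @export
summarize_response <- function(x) {
  delta <- if (inherits(x, "synthetic_cohort"))
    compute_delta_glucose(x$clinical)
  else if (inherits(x, "clinical_table"))
    compute_delta_glucose(x)
  else as.numeric(x)
  if (length(delta) < 2) .stopf("need at least 2 subjects")
  list(median = median(delta), min = min(delta), max = max(delta),
       sd = sd(delta),
       n_decreased = sum(delta <= 0), n_increased = sum(delta > 0),
       n = length(delta))
}

#' Write a synthetic cohort to delimited text plus a truth sidecar
#'
#' Features as TSV (empty cell = missing), clinical table as TSV, and the
#' generating truth (signal ids and effect specification) as JSON.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_matrix(cohort$features, file.path(dir, "features.tsv"))
  write_clinical_table(cohort$clinical, file.path(dir, "clinical.tsv"))
  truth <- cohort$truth[c("signal_ids", "effect_linear", "effect_nonlinear",
                          "delta_intercept", "noise_sd")]
  truth$config <- unclass(cohort$config)[c("n_subjects", "n_features",
                                           "n_signal", "n_blocks",
                                           "block_rho", "lod_quantile",
                                           "clinical_effect", "seed")]
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
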