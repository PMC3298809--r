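test_that("config validation names the offending field", {
  expect_error(cohort_config(n_subjects = 1), "n_subjects")
  expect_error(cohort_config(n_signal = 300), "n_signal")
  expect_error(cohort_config(lod_quantile = 1), "lod_quantile")
  expect_error(cohort_config(block_rho = 1), "block_rho")
  expect_error(cohort_config(noise_sd = -1), "noise_sd")
  expect_error(cohort_config(effect_linear = c(1, 2)), "effect_linear")
})

test_that("default dimensions match the study layout with censoring applied", {
  co <- generate_cohort(cohort_config(seed = 5))
  expect_equal(dim(co$features), c(172, 286))
  miss_per_feature <- colSums(is.na(co$features$values))
  expect_true(all(miss_per_feature == floor(0.05 * 172)))
  expect_gte(min(miss_per_feature), 1)
  obs <- co$features$values[!is.na(co$features$values)]
  expect_true(all(obs > 0))
  expect_length(co$truth$signal_ids, 9)
  expect_true(all(co$truth$signal_ids %in% co$features$feature_ids))
})

test_that("generation is bit-identical under a fixed seed", {
  c1 <- generate_cohort(cohort_config(seed = 77))
  c2 <- generate_cohort(cohort_config(seed = 77))
  expect_identical(c1$features$values, c2$features$values)
  expect_identical(as.data.frame(c1$clinical), as.data.frame(c2$clinical))
  c3 <- generate_cohort(cohort_config(seed = 78))
  expect_false(identical(c1$features$values, c3$features$values))
})

test_that("censored entries were the lowest values of their feature", {
  ## censoring is the last step, so the same seed without censoring
  ## reproduces the pre-censoring matrix
  cfg <- cohort_config(n_subjects = 50, n_features = 20, seed = 9,
                       lod_quantile = 0.1)
  cfg0 <- cohort_config(n_subjects = 50, n_features = 20, seed = 9,
                        lod_quantile = 0)
  cens <- generate_cohort(cfg)$features$values
  full <- generate_cohort(cfg0)$features$values
  k <- floor(0.1 * 50)
  for (j in seq_len(20)) {
    miss <- is.na(cens[, j])
    expect_equal(sum(miss), k)
    expect_lte(max(full[miss, j]), min(full[!miss, j]))
    expect_identical(cens[!miss, j], full[!miss, j])
  }
})

test_that("within-block correlation of log-intensities approaches block_rho", {
  cfg <- cohort_config(n_subjects = 5000, n_features = 60, n_blocks = 10,
                       block_rho = 0.35, n_signal = 0, lod_quantile = 0,
                       seed = 3)
  co <- generate_cohort(cfg)
  lv <- log(co$features$values)
  block <- rep_len(1:10, 60)
  within <- unlist(lapply(1:10, function(b) {
    C <- cor(lv[, block == b, drop = FALSE])
    C[upper.tri(C)]
  }))
  expect_lt(abs(mean(within) - 0.35), 0.05)
})

test_that("a noise-free single linear effect makes delta-glucose affine in the feature", {
  cfg <- cohort_config(n_subjects = 80, n_features = 12, n_signal = 1,
                       effect_linear = 1.3, effect_nonlinear = NULL,
                       noise_sd = 0, lod_quantile = 0, seed = 21)
  co <- generate_cohort(cfg)
  d <- compute_delta_glucose(co$clinical)
  z <- log(co$features$values[, co$truth$signal_ids])
  expect_equal(abs(cor(d, z)), 1, tolerance = 1e-9)
})

test_that("clinical covariates carry no signal when clinical_effect is zero", {
  rhos <- vapply(1:20, function(s) {
    co <- generate_cohort(cohort_config(n_subjects = 172, n_features = 20,
                                        seed = s))
    d <- compute_delta_glucose(co$clinical)
    covs <- encode_clinical(co$clinical)
    max(abs(apply(covs[, c("waist", "bmi", "age", "glucose_baseline")], 2,
                  function(v) cor(rank(v), rank(d)))))
  }, numeric(1))
  expect_lt(median(rhos), 0.2)
})

test_that("response summary matches hand-computed values and partitions the cohort", {
  s <- summarize_response(c(-1, 0, 2, 3))
  expect_equal(s$median, 1.0)
  expect_equal(s$n_decreased, 2)
  expect_equal(s$n_increased, 2)
  expect_equal(s$sd, sd(c(-1, 0, 2, 3)))
  s2 <- summarize_response(c(2, 2, 2))
  expect_equal(s2$sd, 0)
  expect_equal(c(s2$min, s2$max), c(2, 2))
  expect_error(summarize_response(1.5), "2 subjects")
  co <- generate_cohort(cohort_config(seed = 1))
  s3 <- summarize_response(co)
  expect_equal(s3$n_decreased + s3$n_increased, 172)
})

test_that("default cohorts reproduce the target response location", {
  meds <- vapply(1:50, function(s)
    summarize_response(generate_cohort(cohort_config(seed = s)))$median,
    numeric(1))
  expect_lt(abs(median(meds) - 0.8), 0.5)
})

test_that("planted linear-effect features are picked up by the Spearman screen", {
  hits <- vapply(1:20, function(s) {
    co <- generate_cohort(cohort_config(seed = s))
    pr <- preprocess_cohort(co$features, co$clinical)
    sel <- select_significant(spearman_screen(pr$features, pr$delta))
    ## every planted feature carries a linear component with ~85% marginal
    ## screen power, so most of the pattern screens in every time
    mean(co$truth$signal_ids %in% sel)
  }, numeric(1))
  expect_gte(mean(hits >= 6 / 9), 0.9)
})

test_that("cohort round-trips through the text formats", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(cohort_config(n_subjects = 25, n_features = 8,
                                      n_signal = 3, seed = 4))
  write_cohort(co, dir)
  fm <- read_feature_matrix(file.path(dir, "features.tsv"))
  cl <- read_clinical_table(file.path(dir, "clinical.tsv"))
  expect_equal(fm$values, co$features$values, tolerance = 1e-12)
  expect_identical(fm$feature_ids, co$features$feature_ids)
  expect_equal(cl$glucose_followup, co$clinical$glucose_followup,
               tolerance = 1e-12)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_identical(truth$signal_ids, co$truth$signal_ids)
})
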