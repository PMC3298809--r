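## Shared fixtures, built in code.

## Tiny raw feature matrix with a known missingness pattern.
tiny_raw_matrix <- function() {
  v <- matrix(c(2.0, NA, 4.0,
                5.0, 6.0, 7.0,
                NA, 10.0, 8.0), nrow = 3,
              dimnames = list(NULL, c("F1", "F2", "F3")))
  feature_matrix(v, subject_ids = c("A", "B", "C"), stage = "raw")
}

## Minimal clinical table with hand-set glucose pairs.
tiny_clinical <- function(baseline = c(100, 90, 100),
                          followup = c(100, 100, 90),
                          years = c(5, 5, 4)) {
  clinical_table(subject_ids = c("A", "B", "C"),
                 gender = c(0, 1, 0), waist = c(90, 95, 100),
                 bmi = c(25, 28, 31), age = c(50, 60, 55),
                 glucose_baseline = baseline, glucose_followup = followup,
                 elapsed_years = years)
}

## Small dense regression problem with one informative feature.
small_problem <- function(n = 20, p = 3, seed = 7, informative = 1,
                          beta = 2, noise = 0.5) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("V%d", seq_len(p))))
  y <- beta * X[, informative] + rnorm(n, 0, noise)
  list(X = X, y = y)
}

## Independent per-tree predictions through randomForest's own C predictor
## (used as the oracle route; the package's importance uses its own
## traversal).
rf_tree_predictions <- function(model, X) {
  predict(model$rf, X, predict.all = TRUE)$individual
}
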