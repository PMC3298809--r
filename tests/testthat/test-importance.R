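## Independent brute-force recomputation of the OOB permutation importance:
## per tree, per feature, permute the feature within the tree's OOB subset
## (replaying the same keyed permutations via perm_indices()) and re-predict
## through randomForest's own C predictor — a route entirely separate from
## the package's forest traversal.
brute_force_importance <- function(model, X, y, perm_seed) {
  inbag <- model$rf$inbag
  ntree <- ncol(inbag)
  p <- ncol(X)
  d <- matrix(0, ntree, p)
  for (t in seq_len(ntree)) {
    oob <- which(inbag[, t] == 0)
    m <- length(oob)
    base <- rf_tree_predictions(model, X)[oob, t]
    mse0 <- mean((y[oob] - base)^2)
    for (j in seq_len(p)) {
      Xp <- X
      Xp[oob, j] <- X[oob[perm_indices(perm_seed, t, j, m)], j]
      pred <- rf_tree_predictions(model, Xp)[oob, t]
      d[t, j] <- mean((y[oob] - pred)^2) - mse0
    }
  }
  raw <- colMeans(d)
  se <- apply(d, 2, sd) / sqrt(ntree)
  list(raw = raw, normalized = ifelse(se == 0, raw, raw / se))
}

test_that("importance matches a brute-force per-tree recomputation exactly", {
  for (ntree in c(5, 10)) {
    pr <- small_problem(n = 20, p = 3, seed = ntree)
    m <- fit_forest(pr$X, pr$y,
                    forest_params(n_trees = ntree, seed = ntree + 1))
    ## tiny forests legitimately warn that some samples are never OOB
    imp <- suppressWarnings(
      oob_permutation_importance(m, pr$X, pr$y, perm_seed = 42))
    oracle <- brute_force_importance(m, pr$X, pr$y, perm_seed = 42)
    expect_equal(imp$raw, oracle$raw, tolerance = 1e-12)
    expect_equal(imp$importance, oracle$normalized, tolerance = 1e-12)
  }
})

test_that("a feature no tree splits on has exactly zero raw importance", {
  pr <- small_problem(n = 25, p = 2, seed = 2)
  X <- cbind(pr$X, CONST = 1) # constant: never a split candidate winner
  m <- fit_forest(X, pr$y, forest_params(n_trees = 30, seed = 5))
  imp <- oob_permutation_importance(m, X, pr$y)
  row <- imp[imp$feature_id == "CONST", ]
  expect_identical(row$raw, 0)
  expect_true(row$sd_zero)
  expect_identical(row$importance, 0)
})

test_that("ranks are a permutation of 1..p and deterministic under the seed", {
  pr <- small_problem(n = 30, p = 5, seed = 3)
  m <- fit_forest(pr$X, pr$y, forest_params(n_trees = 40, seed = 6))
  i1 <- oob_permutation_importance(m, pr$X, pr$y, perm_seed = 9)
  i2 <- oob_permutation_importance(m, pr$X, pr$y, perm_seed = 9)
  expect_identical(i1, i2)
  expect_setequal(i1$rank, 1:5)
})

test_that("the sole informative feature almost always ranks first", {
  wins <- vapply(1:20, function(s) {
    set.seed(s)
    X <- matrix(rnorm(60 * 2), 60, 2, dimnames = list(NULL, c("sig", "noise")))
    y <- 1.5 * X[, "sig"] + rnorm(60, 0, 0.5)
    m <- fit_forest(X, y, forest_params(n_trees = 60, seed = s))
    imp <- oob_permutation_importance(m, X, y, perm_seed = s)
    imp$feature_id[imp$rank == 1] == "sig"
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("pure-noise importance concentrates at zero", {
  scores <- vapply(1:50, function(s) {
    set.seed(s)
    X <- matrix(rnorm(40 * 5), 40, 5)
    y <- rnorm(40)
    m <- fit_forest(X, y, forest_params(n_trees = 40, seed = s))
    imp <- oob_permutation_importance(m, X, y, perm_seed = s)
    imp$importance[1]
  }, numeric(1))
  expect_lt(abs(mean(scores)), 0.5)
})

test_that("duplicating a feature does not inflate the pair's raw importance", {
  set.seed(14)
  X <- matrix(rnorm(60 * 3), 60, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- 2 * X[, "a"] + rnorm(60, 0, 0.4)
  m1 <- fit_forest(X, y, forest_params(n_trees = 100, seed = 7))
  raw1 <- oob_permutation_importance(m1, X, y, perm_seed = 1)
  orig <- raw1$raw[raw1$feature_id == "a"]
  Xd <- cbind(X, a2 = X[, "a"])
  m2 <- fit_forest(Xd, y, forest_params(n_trees = 100, seed = 7))
  raw2 <- oob_permutation_importance(m2, Xd, y, perm_seed = 1)
  pair <- sum(raw2$raw[raw2$feature_id %in% c("a", "a2")])
  expect_lt(pair, 2 * orig + 0.1 * abs(orig))
})

test_that("importance demands the model's own training data", {
  pr <- small_problem(n = 20, p = 3)
  m <- fit_forest(pr$X, pr$y, forest_params(n_trees = 10, seed = 1))
  Xbad <- pr$X[, c(2, 1, 3)]
  expect_error(oob_permutation_importance(m, Xbad, pr$y), "features")
  m0 <- fit_forest(pr$X, pr$y,
                   forest_params(n_trees = 5, bootstrap = "none", seed = 1))
  expect_error(oob_permutation_importance(m0, pr$X, pr$y), "out-of-bag")
})
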