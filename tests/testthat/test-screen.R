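make_fm <- function(X) feature_matrix(X, stage = "log_normalized")

test_that("a perfect monotone association screens at rho = 1, p = 0", {
  x <- 1:10
  fm <- make_fm(cbind(F1 = as.numeric(x)))
  sc <- spearman_screen(fm, 2 * x)
  expect_equal(sc$rho, 1)
  expect_equal(sc$p_value, 0)
  expect_true(sc$significant)
  expect_equal(sc$var_explained_pct, 100)
})

test_that("variance explained is 100 * rho^2 to machine precision", {
  set.seed(3)
  X <- matrix(rnorm(40 * 8), 40, 8)
  y <- rnorm(40)
  sc <- spearman_screen(make_fm(X), y)
  expect_equal(sc$var_explained_pct, 100 * sc$rho^2, tolerance = 1e-14)
})

test_that("tied data use mid-ranks: matches brute-force Pearson-of-ranks", {
  x <- c(1, 2, 2, 4)
  y <- c(1, 3, 2, 4)
  ## independent oracle: mid-ranks by hand, then the product-moment formula
  rx <- c(1, 2.5, 2.5, 4); ry <- c(1, 3, 2, 4)
  oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  sc <- spearman_screen(make_fm(cbind(F1 = x)), y)
  expect_equal(sc$rho, oracle, tolerance = 1e-14)
})

test_that("t-approximation p-values match the closed form", {
  set.seed(9)
  x <- rnorm(25); y <- rnorm(25)
  sc <- spearman_screen(make_fm(cbind(F1 = x)), y)
  rho <- cor(rank(x), rank(y))
  tstat <- rho * sqrt((25 - 2) / (1 - rho^2))
  expect_equal(sc$p_value, 2 * pt(abs(tstat), 23, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("constant features are degenerate: rho 0, p 1, never significant", {
  X <- cbind(F1 = rep(1, 12), F2 = rnorm(12))
  sc <- spearman_screen(make_fm(X), rnorm(12))
  row <- sc[sc$feature_id == "F1", ]
  expect_equal(row$rho, 0)
  expect_equal(row$p_value, 1)
  expect_false(row$significant)
  expect_true(row$degenerate)
})

test_that("select_significant applies the alpha threshold and |rho| ordering", {
  sc <- data.frame(feature_id = c("a", "b", "c"),
                   feature_name = c("a", "b", "c"),
                   rho = c(0.3, -0.1, -0.5),
                   p_value = c(0.01, 0.2, 0.049),
                   var_explained_pct = c(9, 1, 25),
                   significant = c(TRUE, FALSE, TRUE),
                   degenerate = FALSE)
  class(sc) <- c("screen_result", "data.frame")
  expect_identical(select_significant(sc), c("c", "a"))
  sc$significant <- FALSE
  expect_identical(select_significant(sc), character(0))
})

test_that("screen output is invariant under a strictly increasing transform", {
  set.seed(21)
  X <- matrix(rexp(30 * 3) + 0.1, 30, 3,
              dimnames = list(NULL, c("F1", "F2", "F3")))
  y <- rnorm(30)
  sc1 <- spearman_screen(make_fm(X), y)
  X2 <- X; X2[, 2] <- exp(3 * X2[, 2]) # monotone transform of one feature
  sc2 <- spearman_screen(make_fm(X2), y)
  expect_equal(sc1$rho[order(sc1$feature_id)],
               sc2$rho[order(sc2$feature_id)], tolerance = 1e-12)
})

test_that("correlation matrix is symmetric with unit diagonal", {
  set.seed(5)
  X <- matrix(rnorm(50 * 4), 50, 4,
              dimnames = list(NULL, paste0("F", 1:4)))
  X[, 2] <- X[, 1] # identical pair
  fm <- make_fm(X)
  C <- correlation_matrix(fm, rnorm(50), paste0("F", 1:4))
  expect_identical(unclass(C), t(unclass(C)))
  expect_equal(unname(diag(C)), rep(1, 5))
  expect_equal(C["F1", "F2"], 1)
  expect_true(all(C >= -1 & C <= 1))
})

test_that("independent features have near-zero off-diagonal correlation", {
  set.seed(8)
  X <- matrix(rnorm(2000 * 5), 2000, 5,
              dimnames = list(NULL, paste0("F", 1:5)))
  C <- correlation_matrix(make_fm(X), rnorm(2000), paste0("F", 1:5))
  off <- C[upper.tri(C)]
  expect_lt(max(abs(off)), 0.05)
})

test_that("condition number: identity, 2x2 closed form, singular sentinel", {
  expect_equal(condition_number(diag(4)), 1)
  r <- 0.999
  C2 <- matrix(c(1, r, r, 1), 2)
  expect_equal(condition_number(C2), (1 + r) / (1 - r), tolerance = 1e-8)
  ## duplicated feature makes the matrix exactly singular
  Cs <- matrix(c(1, 1, 0.2,
                 1, 1, 0.2,
                 0.2, 0.2, 1), 3, byrow = TRUE)
  k <- condition_number(Cs)
  expect_true(is.infinite(k))
  expect_true(attr(k, "singular"))
  expect_error(condition_number(matrix(c(1, 0.5, 0.1, 1), 2)), "symmetric")
})

test_that("condition number never decreases when a duplicate column is appended", {
  set.seed(13)
  for (rep in 1:5) {
    X <- matrix(rnorm(60 * 4), 60, 4, dimnames = list(NULL, paste0("F", 1:4)))
    y <- rnorm(60)
    fm <- make_fm(X)
    k1 <- condition_number(correlation_matrix(fm, y, paste0("F", 1:4)))
    Xd <- cbind(X, F5 = X[, 4])
    k2 <- condition_number(correlation_matrix(make_fm(Xd), y, paste0("F", 1:5)))
    expect_gte(k1, 1)
    expect_true(is.infinite(k2) || k2 >= k1)
  }
})
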