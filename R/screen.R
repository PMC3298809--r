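## Univariate Spearman screen and collinearity diagnostics.

## Spearman rho with mid-ranks; p from the t approximation
## t = rho * sqrt((n-2)/(1-rho^2)) on n-2 df (two-sided). |rho| = 1 -> p = 0.
.spearman_one <- function(x, y, method = "t") {
  if (sd(x) == 0 || sd(y) == 0)
    return(list(rho = 0, p = 1, degenerate = TRUE))
  if (method == "exact") {
    ct <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = TRUE))
    return(list(rho = unname(ct$estimate), p = ct$p.value, degenerate = FALSE))
  }
  n <- length(x)
  rho <- cor(rank(x), rank(y))
  if (abs(rho) >= 1 - 1e-15) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  list(rho = rho, p = p, degenerate = FALSE)
}

#' Spearman screen of every metabolite against the response
#'
#' Computes, per feature, the Spearman rank correlation with delta-glucose
#' (mid-ranks for ties), a two-sided p-value from the t approximation
#' \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on n-2 degrees of freedom, the
#' percentage of response variance a single feature explains
#' (\eqn{100\rho^2}), and a significance flag at level `alpha`. No
#' multiple-testing correction is applied by default (the screen is a
#' filter, not a discovery claim); Benjamini-Hochberg adjustment is
#' available via `adjust = "BH"`.
#'
#' Constant features (and a constant response) have no defined rank
#' correlation; they are reported with `rho = 0`, `p = 1` and flagged in the
#' `degenerate` column.
#'
#' @param fm a [feature_matrix()] (any stage without missing entries).
#' @param y response vector aligned with the matrix rows.
#' @param alpha significance level for the `significant` flag (default 0.05).
#' @param method `"t"` (default, tie-corrected t approximation) or
#'   `"exact"` (exact null via [stats::cor.test()]; intended for small n).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return a `data.frame` of class `screen_result` with columns
#'   `feature_id`, `feature_name`, `rho`, `p_value`, `var_explained_pct`,
#'   `significant`, `degenerate`, sorted by decreasing `|rho|`.
#' @export
spearman_screen <- function(fm, y, alpha = 0.05, method = c("t", "exact"),
                            adjust = c("none", "BH")) {
  stopifnot(inherits(fm, "feature_matrix"))
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  X <- fm$values
  if (nrow(X) < 4) .stopf("need at least 4 subjects for the screen")
  if (length(y) != nrow(X)) .stopf("response length does not match matrix")
  if (anyNA(X)) .stopf("screen requires a complete matrix; impute first")
  res <- lapply(seq_len(ncol(X)), function(j) .spearman_one(X[, j], y, method))
  rho <- vapply(res, `[[`, numeric(1), "rho")
  p <- vapply(res, `[[`, numeric(1), "p")
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  out <- data.frame(feature_id = fm$feature_ids,
                    feature_name = unname(fm$feature_names),
                    rho = rho,
                    p_value = p,
                    var_explained_pct = 100 * rho^2,
                    significant = p < alpha,
                    degenerate = vapply(res, `[[`, logical(1), "degenerate"),
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$rho), out$feature_id), ]
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "n") <- nrow(X)
  attr(out, "p_method") <- method
  class(out) <- c("screen_result", "data.frame")
  out
}

#' Significant features of a screen, ordered by effect size
#'
#' @param screen a [spearman_screen()] result.
#' @return character vector of feature ids with `significant = TRUE`,
#'   ordered by decreasing `|rho|`, ties broken by feature id. May be empty.
#' @export
select_significant <- function(screen) {
  stopifnot(inherits(screen, "screen_result"))
  keep <- screen[screen$significant, , drop = FALSE]
  keep <- keep[order(-abs(keep$rho), keep$feature_id), ]
  keep$feature_id
}

#' Spearman correlation matrix over the response and a feature subset
#'
#' The matrix that motivates the move from linear models to forests: strong
#' off-diagonal structure among metabolites (they are coupled through
#' metabolism) makes least-squares coefficients unstable.
#'
#' @param fm a [feature_matrix()].
#' @param y response vector (included as the first row/column, `delta`).
#' @param subset feature ids to include (non-empty).
#' @return symmetric correlation matrix with unit diagonal, class
#'   `correlation_matrix`.
#' @export
correlation_matrix <- function(fm, y, subset) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (!length(subset)) .stopf("subset must be non-empty")
  Z <- cbind(delta = y, select_features(fm, subset)$values)
  C <- cor(apply(Z, 2, rank))
  C[is.na(C)] <- 0 # degenerate (constant) columns
  diag(C) <- 1
  C <- (C + t(C)) / 2
  class(C) <- c("correlation_matrix", class(C))
  C
}

#' Condition number of a correlation matrix
#'
#' Ratio of the largest to the smallest singular value. Values far above
#' 1000 indicate collinearity severe enough to destabilise least-squares
#' coefficient estimates. Exactly singular matrices are reported as `Inf`
#' with attribute `singular = TRUE`.
#'
#' @param corr symmetric numeric matrix (e.g. [correlation_matrix()]).
#' @return condition number `kappa >= 1`.
#' @export
condition_number <- function(corr) {
  m <- unclass(corr)
  if (!is.matrix(m) || nrow(m) != ncol(m) ||
      !isTRUE(all.equal(m, t(m), tolerance = 1e-8)))
    .stopf("condition_number() requires a symmetric square matrix")
  sv <- svd(m, nu = 0, nv = 0)$d
  tol <- max(sv) * .Machine$double.eps * nrow(m)
  if (min(sv) <= tol)
    return(structure(Inf, singular = TRUE))
  max(sv) / min(sv)
}

#' Plot a correlation heatmap
#'
#' Basic image-style heatmap of a [correlation_matrix()]: blue for positive,
#' red for negative correlation.
#'
#' @param corr a [correlation_matrix()].
#' @param file optional PNG path; when given the plot is written there.
#' @param max_labels axis labels are dropped above this dimension.
#' @return `corr`, invisibly.
#' @export
plot_correlation_matrix <- function(corr, file = NULL, max_labels = 60) {
  m <- unclass(corr)
  if (!is.null(file)) {
    png(file, width = 900, height = 900)
    on.exit(dev.off())
  }
  pal <- colorRampPalette(c("#B2182B", "#F7F7F7", "#2166AC"))(101)
  k <- nrow(m)
  op <- par(mar = c(6, 6, 2, 1))
  on.exit(par(op), add = TRUE)
  image(seq_len(k), seq_len(k), t(m[k:1, , drop = FALSE]),
        zlim = c(-1, 1), col = pal, axes = FALSE, xlab = "", ylab = "")
  if (k <= max_labels) {
    axis(1, seq_len(k), colnames(m), las = 2, cex.axis = 0.6)
    axis(2, seq_len(k), rev(rownames(m)), las = 2, cex.axis = 0.6)
  }
  invisible(corr)
}
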