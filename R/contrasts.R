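#' Cliff's Delta effect size
#'
#' `(#{x_i > y_j} - #{x_i < y_j}) / (n_x * n_y)`; tied pairs contribute 0.
#' Lies in \[-1, 1\]; positive values mean `x` tends to exceed `y`.
#'
#' @param x,y non-empty numeric vectors.
#' @return A single number in \[-1, 1\].
#' @export
cliffs_delta <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L)
    abort("cliffs_delta: empty input")
  # O((n+m) log(n+m)) via joint ranks rather than the n*m pair loop
  r <- rank(c(x, y))
  rx <- r[seq_along(x)]
  n <- length(x); m <- length(y)
  # sum of pairwise signs from rank sums, exact under average-tie ranks
  (2 * sum(rx) - n * (n + m + 1)) / (n * m)
}

#' Rank-based group contrast
#'
#' Two groups: two-sided Mann-Whitney (exact when both groups have at most
#' 25 observations and there are no ties, tie-corrected normal
#' approximation otherwise) plus Cliff's Delta. More than two groups:
#' Kruskal-Wallis chi-squared approximation (no effect size).
#'
#' @param values numeric vector of per-sample values.
#' @param groups group labels, same length as `values`.
#' @param feature optional feature id carried into the result.
#' @return One-row data frame: `feature`, `test`, `p`, `cliffs_delta`,
#'   `direction` and per-group sizes `n1`, `n2` (NA beyond two groups).
#' @export
rank_contrast <- function(values, groups, feature = NA_character_) {
  g <- factor(groups)
  if (nlevels(g) < 2L) abort("rank_contrast: need at least 2 groups")
  sizes <- table(g)
  if (any(sizes < 2L))
    abort(sprintf("rank_contrast: group(s) with fewer than 2 samples: %s",
                  paste(names(sizes)[sizes < 2], collapse = ", ")))
  if (nlevels(g) == 2L) {
    x <- values[g == levels(g)[1L]]
    y <- values[g == levels(g)[2L]]
    ties <- anyDuplicated(c(x, y)) > 0L
    exact_ok <- !ties && length(x) <= 25L && length(y) <= 25L
    p <- suppressWarnings(
      stats::wilcox.test(x, y, exact = exact_ok, correct = !exact_ok)$p.value)
    delta <- cliffs_delta(x, y)
    data.frame(feature = feature, test = "mann-whitney", p = p,
               cliffs_delta = delta, direction = sign(delta),
               n1 = length(x), n2 = length(y), stringsAsFactors = FALSE)
  } else {
    p <- stats::kruskal.test(values, g)$p.value
    data.frame(feature = feature, test = "kruskal-wallis", p = p,
               cliffs_delta = NA_real_, direction = NA_real_,
               n1 = NA_integer_, n2 = NA_integer_, stringsAsFactors = FALSE)
  }
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_i = min_{k >= rank(i)} m * p_(k) / k`, clipped at 1. One family per
#' call; the caller decides the family structure.
#'
#' @param p vector of p-values in \[0, 1\] (`NA` passed through).
#' @return Vector of q-values in the input order.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    abort("bh_adjust: p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  pp <- p[ok]
  m <- length(pp)
  if (m == 0L) return(q)
  o <- order(pp, decreasing = TRUE)
  qq <- pmin(1, cummin(m / seq(m, 1) * pp[o]))
  tmp <- numeric(m)
  tmp[o] <- qq
  q[ok] <- tmp
  q
}

#' Contrast every feature of a matrix between groups
#'
#' Applies [rank_contrast()] to each row and adjusts the p-values with
#' [bh_adjust()] as a single family.
#'
#' @param mat feature x sample matrix.
#' @param groups per-sample labels.
#' @param q_threshold significance threshold recorded in the output
#'   attributes (default 0.1).
#' @return Tidy data frame: `feature`, `test`, `p`, `q`, `cliffs_delta`,
#'   `direction`, `n1`, `n2`, `significant`.
#' @export
contrast_features <- function(mat, groups, q_threshold = 0.1) {
  res <- do.call(rbind, lapply(rownames(mat), function(f)
    rank_contrast(mat[f, ], groups, feature = f)))
  res$q <- bh_adjust(res$p)
  res$significant <- !is.na(res$q) & res$q <= q_threshold
  res <- res[, c("feature", "test", "p", "q", "cliffs_delta", "direction",
                 "n1", "n2", "significant")]
  attr(res, "q_threshold") <- q_threshold
  attr(res, "family") <- sprintf("all %d features in one BH family",
                                 nrow(mat))
  res
}

#' Spearman correlation panel
#'
#' Correlates every feature (rows of `features`) with every variable
#' (columns of `variables`) using Spearman's rank correlation with average
#' ties and the t-approximation for p-values; q-values are BH-adjusted over
#' the whole panel as one family. Cells with fewer than `min_pairs`
#' complete pairs, or with a constant vector, are returned as `NA` with a
#' warning.
#'
#' @param features feature x sample matrix.
#' @param variables sample x variable matrix or data frame of numeric
#'   variables, rows aligned with the columns of `features`.
#' @param min_pairs minimum complete pairs per cell (default 4).
#' @return Long data frame: `feature`, `variable`, `n`, `rho`, `p`, `q`,
#'   `strong` (q <= 0.1), `weak` (p <= 0.05).
#' @export
spearman_panel <- function(features, variables, min_pairs = 4L) {
  variables <- as.data.frame(variables)
  if (ncol(features) != nrow(variables))
    abort("features and variables must share the sample index")
  grid <- expand.grid(feature = rownames(features),
                      variable = colnames(variables),
                      stringsAsFactors = FALSE)
  res <- mapply(function(f, v) {
    x <- features[f, ]
    y <- variables[[v]]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    if (n < min_pairs) {
      warning(sprintf("spearman_panel: fewer than %d complete pairs for %s ~ %s",
                      min_pairs, f, v))
      return(c(n, NA, NA))
    }
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      warning(sprintf("spearman_panel: constant vector in %s ~ %s; rho undefined",
                      f, v))
      return(c(n, NA, NA))
    }
    c(n, spearman_test(x[ok], y[ok]))
  }, grid$feature, grid$variable)
  grid$n <- as.integer(res[1, ])
  grid$rho <- res[2, ]
  grid$p <- res[3, ]
  grid$q <- bh_adjust(grid$p)
  grid$strong <- !is.na(grid$q) & grid$q <= 0.1
  grid$weak <- !is.na(grid$p) & grid$p <= 0.05
  grid
}

# rho via average-tie ranks; two-sided p via the t approximation
spearman_test <- function(x, y) {
  n <- length(x)
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) return(c(rho, 0))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  c(rho, 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE))
}

#' Pearson chi-squared test on a contingency table
#'
#' Pearson chi-squared with `df = (r-1)(c-1)`. The Yates continuity
#' correction is applied only to 2x2 tables, and only when `continuity` is
#' `TRUE` (the default for 2x2 tables; larger tables are never corrected).
#'
#' @param counts r x c matrix of non-negative counts, r, c >= 2.
#' @param continuity apply the Yates correction (2x2 only). Default: `TRUE`
#'   for 2x2 tables, `FALSE` otherwise.
#' @return List with `statistic`, `df`, `p`.
#' @export
chi_squared_table <- function(counts, continuity = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    abort("chi_squared_table: need at least a 2x2 table")
  if (any(counts < 0)) abort("chi_squared_table: negative counts")
  rs <- rowSums(counts); cs <- colSums(counts)
  if (any(rs == 0) || any(cs == 0))
    abort("chi_squared_table: zero row or column margin")
  is2x2 <- nrow(counts) == 2L && ncol(counts) == 2L
  if (is.null(continuity)) continuity <- is2x2
  expected <- outer(rs, cs) / sum(counts)
  dev <- abs(counts - expected)
  if (continuity && is2x2)
    dev <- dev - min(0.5, dev)  # never overshoot past zero
  stat <- sum(dev^2 / expected)
  df <- (nrow(counts) - 1L) * (ncol(counts) - 1L)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Covariate-adjusted richness
#'
#' Residualizes richness on an intercept plus the supplied covariates by
#' ordinary least squares (categorical covariates one-hot with the
#' reference level dropped) and adds back the grand mean so that the
#' adjusted values stay on the richness scale. Samples with any missing
#' covariate are dropped with a message.
#'
#' @param richness named per-sample numeric vector.
#' @param covariates data frame of covariates, rows aligned with
#'   `richness`.
#' @return Named numeric vector of adjusted richness over the retained
#'   samples.
#' @export
adjust_richness <- function(richness, covariates) {
  covariates <- as.data.frame(covariates)
  if (length(richness) != nrow(covariates))
    abort("richness and covariates must be aligned")
  ok <- stats::complete.cases(covariates) & !is.na(richness)
  if (any(!ok))
    message(sprintf("adjust_richness: dropping %d sample(s) with missing data",
                    sum(!ok)))
  r <- richness[ok]
  cv <- droplevels(as.data.frame(lapply(covariates[ok, , drop = FALSE],
                                        function(x)
                                          if (is.character(x)) factor(x)
                                          else x)))
  X <- stats::model.matrix(~ ., data = cv)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    abort(sprintf("adjust_richness: collinear design; degenerate column(s): %s",
                  paste(bad, collapse = ", ")))
  }
  fit <- stats::lm.fit(X, r)
  stats::setNames(fit$residuals + mean(r), names(richness)[ok])
}
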