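#' Bray-Curtis dissimilarity on log10-transformed abundances
#'
#' Abundances are transformed as `y = log10(a + pseudocount) -
#' log10(pseudocount)`, so zeros map to 0 and all values are non-negative,
#' then the Bray-Curtis dissimilarity `sum|y_i - y_j| / sum(y_i + y_j)` is
#' computed between samples. The default pseudocount is half the smallest
#' non-zero abundance of the matrix and is recorded on the result.
#'
#' @param ab feature x sample abundance matrix.
#' @param pseudocount positive pseudocount; default half the minimum
#'   positive value.
#' @return Symmetric sample x sample matrix in \[0, 1\], zero diagonal,
#'   with attribute `"pseudocount"`.
#' @export
bray_curtis_log10 <- function(ab, pseudocount = NULL) {
  if (any(ab < 0)) abort("bray_curtis_log10: negative abundances")
  zero_samples <- colSums(ab) == 0
  if (any(zero_samples))
    abort(sprintf("all-zero sample(s) have undefined dissimilarity: %s",
                  paste(colnames(ab)[zero_samples], collapse = ", ")))
  if (is.null(pseudocount)) {
    pos <- ab[ab > 0]
    pseudocount <- min(pos) / 2
  }
  if (pseudocount <= 0) abort("pseudocount must be > 0")
  y <- log10(ab + pseudocount) - log10(pseudocount)
  n <- ncol(y)
  tot <- colSums(y)
  d <- matrix(0, n, n, dimnames = list(colnames(y), colnames(y)))
  for (i in seq_len(n - 1L)) {
    yi <- y[, i]
    for (j in (i + 1L):n) {
      shared <- sum(pmin(yi, y[, j]))
      d[i, j] <- d[j, i] <- (tot[i] + tot[j] - 2 * shared) /
        (tot[i] + tot[j])
    }
  }
  attr(d, "pseudocount") <- pseudocount
  d
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Double-centres `-D^2/2` and eigen-decomposes it; coordinates are the
#' eigenvectors scaled by the square root of the positive eigenvalues.
#' Negative eigenvalues are reported but contribute no axes.
#'
#' @param d symmetric distance matrix (or `dist`).
#' @param k number of axes (at most n-1).
#' @return List with `coordinates` (n x k), `eigenvalues` (all n, sorted
#'   decreasing) and `negative` (the negative part, if any).
#' @export
pcoa <- function(d, k = 2) {
  m <- as.matrix(d)
  if (!isSymmetric(unname(m), tol = 1e-8))
    abort("pcoa: distance matrix is not symmetric")
  n <- nrow(m)
  k <- assert_count(k, "k")
  if (k > n - 1L) abort("pcoa: k must be at most n - 1")
  fit <- stats::cmdscale(m, k = k, eig = TRUE)
  coords <- fit$points
  if (ncol(coords) < k) {  # fewer positive eigenvalues than requested axes
    coords <- cbind(coords, matrix(0, n, k - ncol(coords)))
  }
  colnames(coords) <- paste0("axis", seq_len(k))
  list(coordinates = coords,
       eigenvalues = fit$eig,
       negative = fit$eig[fit$eig < 0])
}

permanova_f <- function(d2, groups) {
  n <- nrow(d2)
  g <- factor(groups)
  k <- nlevels(g)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (lv in levels(g)) {
    idx <- which(g == lv)
    sub <- d2[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
  }
  f <- ((ss_total - ss_within) / (k - 1)) / (ss_within / (n - k))
  c(f = f, r2 = (ss_total - ss_within) / ss_total)
}

#' PERMANOVA: permutational multivariate analysis of variance
#'
#' One-factor PERMANOVA on a distance matrix. The pseudo-F compares
#' among-group to within-group sums of squared distances; the p-value comes
#' from `n_perm` free label permutations (no strata), with the observed
#' statistic included in the reference set:
#' `p = (1 + #permuted F >= observed F) / (1 + n_perm)`.
#'
#' @param d distance matrix (or `dist`).
#' @param groups per-sample labels; at least 2 groups of at least 2.
#' @param n_perm number of permutations (default 999).
#' @param seed permutation seed.
#' @param permutations optional matrix whose rows are explicit sample-index
#'   permutations (e.g. the full enumeration on tiny instances). When
#'   given, `n_perm`/`seed` are ignored and the p-value is the exhaustive
#'   `#\{F_perm >= F_obs\} / n_permutations` over the supplied rows (the
#'   identity ordering should be among them).
#' @return List of class `"permanova"`: `pseudo_F`, `R2`, `p`,
#'   `n_permutations`, `seed`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1L,
                      permutations = NULL) {
  m <- as.matrix(d)
  g <- factor(groups)
  if (nlevels(g) < 2L) abort("permanova: need at least 2 groups")
  if (any(table(g) < 2L))
    abort("permanova: every group needs at least 2 samples")
  if (length(g) != nrow(m)) abort("permanova: labels do not match matrix")
  d2 <- m^2
  obs <- permanova_f(d2, g)
  if (!is.null(permutations)) {
    fs <- apply(permutations, 1, function(ix)
      permanova_f(d2, g[ix])[["f"]])
    p <- mean(fs >= obs[["f"]] - 1e-12)
    n_perm <- nrow(permutations)
    seed <- NA_integer_
  } else {
    n_perm <- assert_count(n_perm, "n_perm")
    exceed <- withr::with_seed(seed, {
      sum(vapply(seq_len(n_perm), function(i)
        permanova_f(d2, sample(g))[["f"]] >= obs[["f"]], logical(1)))
    })
    p <- (1 + exceed) / (1 + n_perm)
  }
  structure(list(pseudo_F = obs[["f"]], R2 = obs[["r2"]], p = p,
                 n_permutations = n_perm, seed = seed),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4g, R2 = %.4g, p = %.4g (%d permutations)\n",
              x$pseudo_F, x$R2, x$p, x$n_permutations))
  invisible(x)
}

#' Pairwise PERMANOVA between all group pairs
#'
#' Runs [permanova()] on the sub-matrix of every pair of groups and adjusts
#' the permutation p-values across pairs with [bh_adjust()].
#'
#' @inheritParams permanova
#' @return Data frame: `group1`, `group2`, `pseudo_F`, `R2`, `p`, `q`.
#' @export
pairwise_permanova <- function(d, groups, n_perm = 999, seed = 1L) {
  m <- as.matrix(d)
  g <- factor(groups)
  pairs <- utils::combn(levels(g), 2)
  res <- lapply(seq_len(ncol(pairs)), function(i) {
    keep <- g %in% pairs[, i]
    fit <- permanova(m[keep, keep, drop = FALSE], droplevels(g[keep]),
                     n_perm = n_perm, seed = derive_seed(seed, i))
    data.frame(group1 = pairs[1, i], group2 = pairs[2, i],
               pseudo_F = fit$pseudo_F, R2 = fit$R2, p = fit$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_adjust(out$p)
  out
}

#' Alpha diversity: richness, Shannon, Chao1
#'
#' Richness is the number of features with positive abundance; Shannon uses
#' natural-log entropy of the per-sample proportions; Chao1 is
#' `S_obs + F1(F1 - 1) / (2(F2 + 1))` and requires integer counts (error
#' otherwise, since singleton/doubleton counts are meaningless on
#' continuous abundances).
#'
#' @param mat feature x sample matrix of non-negative abundances or counts.
#' @param metrics any of `"richness"`, `"shannon"`, `"chao1"`.
#' @return Data frame with one row per sample.
#' @export
alpha_diversity <- function(mat, metrics = c("richness", "shannon")) {
  metrics <- match.arg(metrics, c("richness", "shannon", "chao1"),
                       several.ok = TRUE)
  if (any(mat < 0)) abort("alpha_diversity: negative abundances")
  out <- data.frame(sample = colnames(mat) %||%
                      as.character(seq_len(ncol(mat))),
                    stringsAsFactors = FALSE)
  if ("richness" %in% metrics)
    out$richness <- as.integer(colSums(mat > 0))
  if ("shannon" %in% metrics)
    out$shannon <- apply(mat, 2, function(x) {
      p <- x[x > 0] / sum(x)
      -sum(p * log(p))
    })
  if ("chao1" %in% metrics) {
    if (max(abs(mat - round(mat))) > 1e-8)
      abort(paste("chao1 requires integer counts: supply a count matrix or",
                  "integerize (e.g. rarefied read-equivalents) first"))
    out$chao1 <- apply(round(mat), 2, function(x) {
      s_obs <- sum(x > 0)
      f1 <- sum(x == 1)
      f2 <- sum(x == 2)
      s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
    })
  }
  out
}
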