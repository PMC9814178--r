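#' Naive feature-covariate association screen
#'
#' Tests every feature against every covariate with a test matched to the
#' covariate's type: two-level covariates with Mann-Whitney, multi-level
#' categorical covariates with Kruskal-Wallis, continuous covariates with
#' Spearman correlation. P-values are BH-adjusted within each covariate's
#' family (across features). Covariates with a single observed level are
#' skipped with a warning; constant features yield `NA` with a warning.
#'
#' @param features feature x sample matrix.
#' @param metadata data frame of covariates, rows aligned with the samples.
#' @param covariates names of `metadata` columns to screen.
#' @param threshold q-value threshold for the association flag (default
#'   0.1).
#' @return Long data frame: `feature`, `covariate`, `test`, `p`, `q`,
#'   `flag`.
#' @export
naive_associations <- function(features, metadata, covariates,
                               threshold = 0.1) {
  stopifnot(all(covariates %in% names(metadata)))
  if (ncol(features) != nrow(metadata))
    abort("features and metadata must share the sample index")
  out <- list()
  for (cv in covariates) {
    v <- metadata[[cv]]
    ok_v <- !is.na(v)
    is_cat <- is.character(v) || is.factor(v) || is.logical(v)
    n_lev <- if (is_cat) length(unique(v[ok_v])) else Inf
    if (is_cat && n_lev < 2L) {
      warning(sprintf("naive_associations: covariate %s has a single level; skipped",
                      cv))
      next
    }
    rows <- lapply(rownames(features), function(f) {
      x <- features[f, ]
      ok <- ok_v & !is.na(x)
      if (stats::sd(x[ok]) == 0) {
        warning(sprintf("naive_associations: constant feature %s; no test vs %s",
                        f, cv))
        return(data.frame(feature = f, covariate = cv, test = "none",
                          p = NA_real_, stringsAsFactors = FALSE))
      }
      if (is_cat) {
        ct <- rank_contrast(x[ok], v[ok], feature = f)
        data.frame(feature = f, covariate = cv, test = ct$test, p = ct$p,
                   stringsAsFactors = FALSE)
      } else {
        st <- spearman_test(x[ok], as.numeric(v[ok]))
        data.frame(feature = f, covariate = cv, test = "spearman",
                   p = st[2], stringsAsFactors = FALSE)
      }
    })
    df <- do.call(rbind, rows)
    df$q <- bh_adjust(df$p)
    df$flag <- !is.na(df$q) & df$q <= threshold
    out[[cv]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "threshold") <- threshold
  res
}

# likelihood-ratio test p-value for nested OLS fits (chi-squared form)
lrt_nested <- function(y, X0, X1) {
  q0 <- qr(X0); q1 <- qr(X1)
  if (q1$rank <= q0$rank)
    abort("classify_confounding: degenerate rank design (nested model adds no rank)")
  rss0 <- sum(stats::lm.fit(X0, y)$residuals^2)
  rss1 <- sum(stats::lm.fit(X1, y)$residuals^2)
  n <- length(y)
  lr <- n * (log(rss0) - log(max(rss1, 1e-300)))
  stats::pchisq(lr, df = q1$rank - q0$rank, lower.tail = FALSE)
}

#' Classify the confounding status of one feature-status association
#'
#' For each flagged covariate C, the rank-transformed feature is fitted
#' against nested linear models: status is "retained" against C when adding
#' status to (intercept + C) significantly improves the fit
#' (likelihood-ratio test, p <= `p_threshold`), and C is retained against
#' status symmetrically. The label is **strictly deconfounded** when status
#' is retained against every flagged covariate (vacuously true with no
#' flagged covariates), **confounded** when some covariate is retained
#' while status is not, and **ambiguously deconfounded** otherwise (some
#' covariate where neither model separates the two).
#'
#' This is a re-derivation of the documented three-label contract, not a
#' port of any published implementation.
#'
#' @param values per-sample feature values.
#' @param status per-sample status labels (the exposure of interest).
#' @param covdata data frame with one column per flagged covariate (may
#'   have zero columns).
#' @param p_threshold nested-model LRT threshold (default 0.05).
#' @return List: `label`, `implicated` (covariates where status was not
#'   retained), `detail` (per-covariate retention table).
#' @export
classify_confounding <- function(values, status, covdata,
                                 p_threshold = 0.05) {
  covdata <- as.data.frame(covdata)
  r <- rank(values)  # rank transform: labels invariant to monotone maps
  st <- factor(status)
  X_status <- stats::model.matrix(~ st)
  if (ncol(covdata) == 0L)
    return(list(label = "strictly deconfounded", implicated = character(0),
                detail = NULL))
  status_ret <- cov_ret <- logical(ncol(covdata))
  for (i in seq_len(ncol(covdata))) {
    v <- covdata[[i]]
    if (is.character(v)) v <- factor(v)
    X_cov <- stats::model.matrix(~ v)
    X_both <- stats::model.matrix(~ v + st)
    status_ret[i] <- lrt_nested(r, X_cov, X_both) <= p_threshold
    cov_ret[i] <- lrt_nested(r, X_status, X_both) <= p_threshold
  }
  label <- if (all(status_ret)) "strictly deconfounded"
           else if (any(!status_ret & cov_ret)) "confounded"
           else "ambiguously deconfounded"
  list(label = label,
       implicated = names(covdata)[!status_ret],
       detail = data.frame(covariate = names(covdata),
                           status_retained = status_ret,
                           covariate_retained = cov_ret,
                           stringsAsFactors = FALSE))
}

#' Deconfound feature-status associations against measured covariates
#'
#' Runs the naive screen ([naive_associations()]) for status and the listed
#' covariates, then labels every feature: **not significant** when the
#' naive status association has q above `q_threshold`; otherwise one of
#' strictly deconfounded / ambiguously deconfounded / confounded from
#' nested rank-model likelihood-ratio tests against the covariates flagged
#' for that feature ([classify_confounding()]).
#'
#' @param features feature x sample matrix.
#' @param metadata data frame aligned with the samples.
#' @param status_col name of the status column in `metadata`.
#' @param covariates names of the candidate confounder columns.
#' @param q_threshold naive significance threshold (default 0.1).
#' @param p_threshold nested-model LRT threshold (default 0.05).
#' @return Data frame: `feature`, `naive_p`, `naive_q`, `label`,
#'   `implicated_covariates` (comma-separated, empty for strict labels).
#' @export
deconfound <- function(features, metadata, status_col = "status",
                       covariates, q_threshold = 0.1, p_threshold = 0.05) {
  naive <- naive_associations(features, metadata,
                              c(status_col, covariates),
                              threshold = q_threshold)
  st_rows <- naive[naive$covariate == status_col, ]
  out <- lapply(rownames(features), function(f) {
    sf <- st_rows[st_rows$feature == f, ]
    if (nrow(sf) == 0L || is.na(sf$q) || !sf$flag)
      return(data.frame(feature = f,
                        naive_p = if (nrow(sf)) sf$p else NA_real_,
                        naive_q = if (nrow(sf)) sf$q else NA_real_,
                        label = "not significant",
                        implicated_covariates = "",
                        stringsAsFactors = FALSE))
    flagged <- naive$covariate[naive$feature == f & naive$flag &
                                 naive$covariate != status_col]
    ok <- !is.na(features[f, ]) & !is.na(metadata[[status_col]]) &
      stats::complete.cases(metadata[, flagged, drop = FALSE])
    cls <- classify_confounding(features[f, ok],
                                metadata[[status_col]][ok],
                                metadata[ok, flagged, drop = FALSE],
                                p_threshold = p_threshold)
    data.frame(feature = f, naive_p = sf$p, naive_q = sf$q,
               label = cls$label,
               implicated_covariates = paste(cls$implicated, collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "q_threshold") <- q_threshold
  attr(res, "p_threshold") <- p_threshold
  res
}
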