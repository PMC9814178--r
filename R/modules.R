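#' Functional module catalogue
#'
#' A module is an ordered list of components; each component is a set of
#' alternative annotation ids, any one of which satisfies the component
#' (gut-metabolic-module style definitions require alternatives; the strict
#' complement/optional-reaction grammar is not modelled).
#'
#' @param x a list of modules, each a list with `module_id`, `name`,
#'   `database` (e.g. `"KEGG"`, `"GMM"`, `"GBM"`) and `components` (a list
#'   of character vectors of alternative ids).
#' @return The validated list with class `"module_catalog"`.
#' @export
module_catalog <- function(x) {
  stopifnot(is.list(x), length(x) > 0)
  for (m in x) {
    if (is.null(m$module_id) || is.null(m$components))
      abort("each module needs `module_id` and `components`")
    if (length(m$components) < 1L)
      abort(sprintf("module %s has no components", m$module_id))
    if (any(lengths(m$components) == 0L))
      abort(sprintf("module %s has a component with no alternatives",
                    m$module_id))
  }
  ids <- vapply(x, `[[`, "", "module_id")
  if (anyDuplicated(ids)) abort("duplicated module ids")
  names(x) <- ids
  structure(x, class = "module_catalog")
}

# gene id -> character vector of annotation ids, from the catalogue's
# comma-separated `components` column
gene_annotations <- function(genes_df) {
  ann <- strsplit(genes_df$components %||% character(nrow(genes_df)), ",",
                  fixed = TRUE)
  ann <- lapply(ann, function(x) x[nzchar(x)])
  names(ann) <- genes_df$gene_id
  ann
}

component_coverage <- function(components, annotated_ids) {
  mean(vapply(components, function(alts) any(alts %in% annotated_ids),
              logical(1)))
}

#' Module presence from core genes
#'
#' A module is considered present in an MGS when at least 90% of its
#' components are covered by annotations carried on the MGS's core genes
#' (coverage of a component means at least one of its alternative ids is
#' annotated on at least one core gene). The 90% threshold is inclusive.
#'
#' @param defs an [mgs_definitions()] object.
#' @param catalog gene catalogue data frame (or [generate_catalog()] result)
#'   with a `components` annotation column.
#' @param modules a [module_catalog()].
#' @param threshold coverage threshold (default 0.9, inclusive).
#' @return Logical MGS x module matrix with the coverage fractions attached
#'   as attribute `"coverage"`.
#' @export
module_core_presence <- function(defs, catalog, modules, threshold = 0.9) {
  stopifnot(inherits(defs, "mgs_definitions"),
            inherits(modules, "module_catalog"))
  genes_df <- if (inherits(catalog, "synthetic_catalog")) catalog$genes
              else catalog
  ann <- gene_annotations(genes_df)
  mgs_ids <- names(defs$core)
  cov <- matrix(0, length(mgs_ids), length(modules),
                dimnames = list(mgs_ids, names(modules)))
  for (m in mgs_ids) {
    core_ids <- unique(unlist(ann[defs$core[[m]]], use.names = FALSE))
    for (j in seq_along(modules))
      cov[m, j] <- component_coverage(modules[[j]]$components, core_ids)
  }
  out <- cov >= threshold - 1e-9
  attr(out, "coverage") <- cov
  out
}

#' Refine module presence sample by sample with accessory genes
#'
#' For each sample, the component coverage of each (MGS, module) pair is
#' recomputed over the MGS's core genes plus the accessory genes detected in
#' that sample (frequency strictly positive). An MGS not detected in a
#' sample (abundance 0) gets `FALSE` for every module there. Adding genes
#' can only increase coverage, so core-present modules remain present in
#' every sample where the MGS is detected.
#'
#' @param core_flags output of [module_core_presence()].
#' @param freq gene x sample frequency matrix (covers accessory genes).
#' @param defs an [mgs_definitions()] object.
#' @param catalog gene catalogue with annotations.
#' @param modules a [module_catalog()].
#' @param ab MGS x sample abundance matrix used for the detection mask.
#' @param threshold coverage threshold (default 0.9, inclusive).
#' @return Logical array `MGS x module x sample`.
#' @export
refine_presence_per_sample <- function(core_flags, freq, defs, catalog,
                                       modules, ab, threshold = 0.9) {
  stopifnot(inherits(defs, "mgs_definitions"),
            inherits(modules, "module_catalog"))
  genes_df <- if (inherits(catalog, "synthetic_catalog")) catalog$genes
              else catalog
  ann <- gene_annotations(genes_df)
  mgs_ids <- rownames(core_flags)
  samples <- colnames(freq)
  if (!setequal(rownames(ab), mgs_ids) ||
      !identical(colnames(ab), samples))
    abort("abundance matrix indices do not match the flags/frequency matrix")
  ab <- ab[mgs_ids, , drop = FALSE]
  detected <- ab > 0

  out <- array(FALSE, dim = c(length(mgs_ids), length(modules),
                              length(samples)),
               dimnames = list(mgs_ids, names(modules), samples))
  ncomp <- vapply(modules, function(m) length(m$components), 0L)
  for (m in mgs_ids) {
    core_ids <- unique(unlist(ann[defs$core[[m]]], use.names = FALSE))
    acc <- defs$accessory[[m]]
    acc <- acc[acc %in% rownames(freq)]
    acc_ann <- ann[acc]
    acc_has_ann <- lengths(acc_ann) > 0L
    for (j in seq_along(modules)) {
      if (core_flags[m, j]) {
        out[m, j, ] <- detected[m, ]
        next
      }
      comps <- modules[[j]]$components
      core_sat <- vapply(comps, function(alts) any(alts %in% core_ids),
                         logical(1))
      need <- which(!core_sat)
      # coverage already below threshold and no accessory gene can help
      cand <- lapply(need, function(cc) {
        acc[acc_has_ann &
              vapply(acc_ann, function(a) any(comps[[cc]] %in% a),
                     logical(1))]
      })
      if (all(lengths(cand) == 0L)) next
      sat_extra <- matrix(FALSE, length(need), length(samples))
      for (k in seq_along(need)) {
        if (length(cand[[k]]))
          sat_extra[k, ] <- colSums(freq[cand[[k]], , drop = FALSE] > 0) > 0
      }
      covs <- (sum(core_sat) + colSums(sat_extra)) / ncomp[j]
      out[m, j, ] <- detected[m, ] & (covs >= threshold - 1e-9)
    }
  }
  out
}

#' Module potential per sample
#'
#' The potential of a module in a sample is the summed abundance of every
#' MGS carrying the module in that sample. Computed on whatever abundance
#' scale is supplied; the scale tag is propagated.
#'
#' @param presence logical `MGS x module x sample` array from
#'   [refine_presence_per_sample()] (or an MGS x module matrix of core
#'   flags, applied uniformly across samples).
#' @param ab MGS x sample abundance matrix sharing the MGS and sample
#'   indices.
#' @return Module x sample matrix.
#' @export
module_potential <- function(presence, ab) {
  if (length(dim(presence)) == 2L) {
    pres <- array(rep(presence, ncol(ab)),
                  dim = c(nrow(presence), ncol(presence), ncol(ab)),
                  dimnames = c(dimnames(presence), list(colnames(ab))))
  } else pres <- presence
  if (!identical(rownames(pres), rownames(ab)) ||
      !identical(dimnames(pres)[[3]], colnames(ab)))
    abort("presence and abundance indices do not match")
  n_mod <- dim(pres)[2]
  out <- matrix(0, n_mod, ncol(ab),
                dimnames = list(dimnames(pres)[[2]], colnames(ab)))
  for (j in seq_len(n_mod)) {
    pj <- matrix(pres[, j, ], nrow(ab), ncol(ab))
    out[j, ] <- colSums(ab * pj)
  }
  if (!is.null(mgs_scale(ab))) mgs_scale(out) <- mgs_scale(ab)
  out
}
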