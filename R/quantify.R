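#' MGS definition set: marker / core / accessory genes plus taxonomy
#'
#' Builds the per-MGS gene partition used for quantification and functional
#' inference from a gene catalogue table. Markers must be core genes and
#' every gene belongs to at most one MGS.
#'
#' @param genes gene catalogue data frame (`gene_id`, `mgs_id`, `is_marker`,
#'   `is_core`, ...).
#' @param taxonomy data frame with `mgs_id` and the seven ranks `kingdom`,
#'   `phylum`, `class`, `order`, `family`, `genus`, `species` (`NA` for
#'   unclassified).
#' @return A list of class `"mgs_definitions"` with named lists `markers`,
#'   `core`, `accessory` (gene ids per MGS) and the `taxonomy` table.
#' @export
mgs_definitions <- function(genes, taxonomy) {
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "mgs_id", "is_marker", "is_core") %in%
                  names(genes)))
  if (anyDuplicated(genes$gene_id))
    abort("a gene may belong to at most one MGS: duplicated gene ids")
  if (any(genes$is_marker & !genes$is_core))
    abort("marker genes must be core genes")
  mgs_ids <- unique(genes$mgs_id)
  if (!is.null(taxonomy)) {
    stopifnot(is.data.frame(taxonomy), "mgs_id" %in% names(taxonomy))
    taxonomy <- taxonomy[match(mgs_ids, taxonomy$mgs_id), , drop = FALSE]
    if (anyNA(taxonomy$mgs_id))
      abort("taxonomy table is missing some MGS ids from the catalogue")
  } else {
    taxonomy <- data.frame(mgs_id = mgs_ids, kingdom = NA_character_,
                           phylum = NA_character_, class = NA_character_,
                           order = NA_character_, family = NA_character_,
                           genus = NA_character_, species = mgs_ids,
                           stringsAsFactors = FALSE)
  }
  f <- factor(genes$mgs_id, levels = mgs_ids)
  structure(list(
    markers = split(genes$gene_id[genes$is_marker],
                    f[genes$is_marker])[mgs_ids],
    core = split(genes$gene_id[genes$is_core], f[genes$is_core])[mgs_ids],
    accessory = split(genes$gene_id[!genes$is_core],
                      f[!genes$is_core])[mgs_ids],
    taxonomy = taxonomy
  ), class = "mgs_definitions")
}

#' MGS relative abundance from marker genes
#'
#' The relative abundance of an MGS in a sample is the mean frequency of its
#' marker genes (zeros included). If strictly fewer than 10% of the declared
#' markers are seen in a sample (frequency strictly positive), the MGS
#' abundance is set to 0; exactly 10% does not trigger the rule.
#'
#' @param freq gene x sample frequency matrix covering all marker genes.
#' @param defs an [mgs_definitions()] object.
#' @param detection_fraction detection threshold (default 0.10).
#' @return MGS x sample abundance matrix, scale tag `"relative"`.
#' @export
mgs_relative_abundance <- function(freq, defs, detection_fraction = 0.10) {
  stopifnot(inherits(defs, "mgs_definitions"))
  empty <- lengths(defs$markers) == 0L
  if (any(empty))
    abort(sprintf("MGS with zero declared marker genes: %s",
                  paste(names(defs$markers)[empty], collapse = ", ")))
  missing <- setdiff(unlist(defs$markers), rownames(freq))
  if (length(missing))
    abort(sprintf("marker gene(s) absent from the frequency matrix: %s",
                  paste(utils::head(missing, 5), collapse = ", ")))
  out <- t(vapply(defs$markers, function(mk) {
    sub <- freq[mk, , drop = FALSE]
    ab <- colMeans(sub)
    seen <- colSums(sub > 0)
    ab[seen < detection_fraction * length(mk)] <- 0  # strict "<"
    ab
  }, numeric(ncol(freq))))
  dimnames(out) <- list(names(defs$markers), colnames(freq))
  mgs_scale(out) <- "relative"
  out
}

#' Per-sample cell-count index
#'
#' Each measured sample's cell count divided by the mean cell count over the
#' measured samples; samples with a missing count get an index of 1
#' (logged).
#'
#' @param cells named numeric vector of cells per gram; `NA` for missing.
#' @return Named numeric index vector.
#' @export
cell_count_index <- function(cells) {
  if (all(is.na(cells))) abort("all cell counts are missing")
  if (any(cells[!is.na(cells)] <= 0)) abort("cell counts must be positive")
  idx <- cells / mean(cells, na.rm = TRUE)
  if (anyNA(idx)) {
    message(sprintf("cell_count_index: imputing index 1 for %d sample(s): %s",
                    sum(is.na(idx)),
                    paste(names(cells)[is.na(idx)], collapse = ", ")))
    idx[is.na(idx)] <- 1
  }
  idx
}

#' Correct relative MGS abundances to absolute abundances
#'
#' Multiplies each sample's relative abundances by its cell-count index,
#' yielding quantitative (absolute) microbiome profiles.
#'
#' @param rel MGS x sample matrix with scale tag `"relative"`.
#' @param index per-sample index from [cell_count_index()], covering every
#'   sample of `rel`.
#' @return MGS x sample matrix with scale tag `"absolute"`.
#' @export
to_absolute_abundance <- function(rel, index) {
  if (identical(mgs_scale(rel), "absolute"))
    abort("matrix is already absolute-scale: refusing to correct twice")
  if (is.null(names(index))) {
    if (length(index) != ncol(rel))
      abort("unnamed index must have one entry per sample")
  } else {
    if (!all(colnames(rel) %in% names(index)))
      abort("cell-count index missing for some samples")
    index <- index[colnames(rel)]
  }
  out <- sweep(rel, 2, index, "*")
  mgs_scale(out) <- "absolute"
  out
}

#' Aggregate MGS abundances to higher taxonomic ranks
#'
#' The abundance of a taxon is the sum of its member MGS abundances. MGS
#' unclassified at a rank are pooled into `unclassified_<parent>` bins,
#' where the parent is the nearest classified ancestor label. Operates on
#' whichever abundance scale it is given and propagates the scale tag.
#'
#' @param ab MGS x sample abundance matrix.
#' @param defs an [mgs_definitions()] object supplying the lineage.
#' @param ranks ranks to aggregate at (default all seven).
#' @return Named list of taxon x sample matrices, one per rank.
#' @export
aggregate_taxa <- function(ab, defs,
                           ranks = c("kingdom", "phylum", "class", "order",
                                     "family", "genus", "species")) {
  stopifnot(inherits(defs, "mgs_definitions"))
  tax <- defs$taxonomy[match(rownames(ab), defs$taxonomy$mgs_id), ,
                       drop = FALSE]
  if (anyNA(tax$mgs_id))
    abort("abundance matrix contains MGS without a taxonomy entry")
  all_ranks <- c("kingdom", "phylum", "class", "order", "family", "genus",
                 "species")
  out <- lapply(ranks, function(r) {
    lab <- tax[[r]]
    if (anyNA(lab)) {
      ri <- match(r, all_ranks)
      for (i in which(is.na(lab))) {
        parent <- "root"
        for (pr in rev(seq_len(ri - 1L))) {
          if (!is.na(tax[[all_ranks[pr]]][i])) {
            parent <- tax[[all_ranks[pr]]][i]
            break
          }
        }
        lab[i] <- paste0("unclassified_", parent)
      }
    }
    m <- rowsum(ab, lab)
    mgs_scale(m) <- mgs_scale(ab) %||% "relative"
    m
  })
  names(out) <- ranks
  out
}

#' MGS richness per sample
#'
#' Number of MGS with strictly positive abundance in each sample. Positivity
#' is invariant to the (strictly positive) cell-count correction, so
#' relative and absolute inputs agree.
#'
#' @param ab MGS x sample abundance matrix.
#' @return Named integer vector.
#' @export
mgs_richness <- function(ab) {
  stats::setNames(as.integer(colSums(ab > 0)), colnames(ab))
}
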