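#' Attribute mapped reads to genes by the unique-count ratio rule
#'
#' Reads mapping to a single catalogue gene contribute a count of 1 to that
#' gene. Reads mapping with equal best score to several genes ("shared"
#' reads) distribute their unit mass over the candidate genes proportionally
#' to those genes' unique-read counts in the same sample; when every
#' candidate has zero unique reads the mass is split equally (a symmetric
#' fallback that conserves total mass). Attribution is single-pass: shared
#' mass does not feed back into the unique counts.
#'
#' @param mappings read-mapping table: a data frame with columns `sample`,
#'   `read_id`, `genes` (comma-separated candidate gene ids).
#' @param catalog optional gene catalogue data frame (or
#'   [generate_catalog()] result); when supplied, records referencing
#'   unknown genes raise an error naming the gene, and the output has one
#'   row per catalogue gene.
#' @return Gene x sample matrix of (possibly fractional) counts, with
#'   attribute `mapped_total` = reads per sample. Column sums equal the
#'   number of records per sample.
#' @export
attribute_reads <- function(mappings, catalog = NULL) {
  stopifnot(is.data.frame(mappings),
            all(c("sample", "genes") %in% names(mappings)))
  if (nrow(mappings) == 0L) abort("empty read-mapping table")
  gl <- strsplit(mappings$genes, ",", fixed = TRUE)
  nl <- lengths(gl)
  if (any(nl == 0L) || any(!nzchar(unlist(gl))))
    abort("read-mapping record with empty candidate gene set")

  if (!is.null(catalog)) {
    genes_df <- if (inherits(catalog, "synthetic_catalog")) catalog$genes
                else catalog
    known <- genes_df$gene_id
    bad <- setdiff(unique(unlist(gl)), known)
    if (length(bad))
      abort(sprintf("read-mapping record references unknown gene(s): %s",
                    paste(utils::head(bad, 5), collapse = ", ")))
    gene_levels <- known
  } else {
    gene_levels <- sort(unique(unlist(gl)))
  }

  # a record is a *set* of candidates: collapse duplicate listings
  if (any(nl > 1L)) {
    gl[nl > 1L] <- lapply(gl[nl > 1L], unique)
    nl <- lengths(gl)
  }

  samples <- unique(mappings$sample)
  s_idx <- match(mappings$sample, samples)
  G <- length(gene_levels)
  S <- length(samples)

  g_all <- match(unlist(gl), gene_levels)
  rec <- rep.int(seq_len(nrow(mappings)), nl)

  is_uniq <- nl == 1L
  sel_u <- is_uniq[rec]
  ucount <- matrix(tabulate(g_all[sel_u] + (s_idx[rec[sel_u]] - 1L) * G,
                            nbins = G * S), G, S)
  out <- ucount
  if (any(!is_uniq)) {
    gsh <- g_all[!sel_u]
    rsh <- rec[!sel_u]
    ssh <- s_idx[rsh]
    w <- ucount[cbind(gsh, ssh)]
    rid <- match(rsh, unique(rsh))
    rec_tot <- rowsum(w, rid)[, 1]
    sz <- tabulate(rid)
    denom <- rec_tot[rid]
    mass <- ifelse(denom == 0, 1 / sz[rid], w / denom)  # equal-split fallback
    cell <- gsh + (ssh - 1L) * G
    add <- rowsum(mass, cell)
    ci <- as.integer(rownames(add))
    out[ci] <- out[ci] + add[, 1]
  }
  dimnames(out) <- list(gene_levels, samples)
  attr(out, "mapped_total") <- stats::setNames(tabulate(s_idx, S), samples)
  out
}

#' Rarefy a gene count matrix to a fixed depth
#'
#' Downsamples each sample's column to exactly `depth` read-equivalents
#' without replacement (multivariate hypergeometric sampling). Fractional
#' attributed counts are first integerized by the largest-remainder method so
#' that the integer column total equals the rounded mass. Samples with fewer
#' than `depth` mapped reads are dropped with a message.
#'
#' @param counts gene x sample count matrix (e.g. from [attribute_reads()]).
#' @param depth target depth (read-equivalents per sample).
#' @param seed seed for the subsampling.
#' @return Matrix with the retained samples, each column summing to `depth`.
#' @export
downsize_counts <- function(counts, depth, seed = 1L) {
  depth <- assert_count(depth, "depth")
  totals <- colSums(counts)
  keep <- round(totals) >= depth
  if (!any(keep))
    abort(sprintf("all %d samples have fewer than %d mapped reads",
                  ncol(counts), depth))
  if (any(!keep))
    message(sprintf("downsize_counts: dropping %d sample(s) below depth %d: %s",
                    sum(!keep), depth,
                    paste(colnames(counts)[!keep], collapse = ", ")))
  counts <- counts[, keep, drop = FALSE]
  withr::with_seed(seed, {
    out <- apply(counts, 2, function(col) {
      m <- integerize_mass(col)
      n_tot <- sum(m)
      if (n_tot == depth) return(m)
      drawn <- numeric(length(m))
      remaining_draw <- depth
      remaining_other <- n_tot
      for (g in which(m > 0L)) {
        remaining_other <- remaining_other - m[g]
        x <- stats::rhyper(1, m[g], remaining_other, remaining_draw)
        drawn[g] <- x
        remaining_draw <- remaining_draw - x
        if (remaining_draw == 0L) break
      }
      drawn
    })
  })
  dimnames(out) <- dimnames(counts)
  out
}

# Largest-remainder integerization: preserves the rounded column total.
integerize_mass <- function(x) {
  fl <- floor(x)
  deficit <- round(sum(x)) - sum(fl)
  if (deficit > 0) {
    frac <- x - fl
    top <- order(frac, decreasing = TRUE)[seq_len(deficit)]
    fl[top] <- fl[top] + 1
  }
  as.integer(fl)
}

#' Length-normalize counts into a gene frequency matrix
#'
#' Divides each gene's count by its length in nucleotides and rescales every
#' sample to sum to 1 (the scale constants of FPKM cancel in the
#' normalization, so they are omitted). All-zero samples yield an all-zero
#' column with a warning.
#'
#' @param counts gene x sample count matrix; row names are gene ids.
#' @param catalog gene catalogue (data frame with `gene_id`, `length_nt`, or
#'   a [generate_catalog()] result) providing lengths for every row.
#' @return Gene x sample frequency matrix; non-empty columns sum to 1.
#' @export
to_frequency_matrix <- function(counts, catalog) {
  genes_df <- if (inherits(catalog, "synthetic_catalog")) catalog$genes
              else catalog
  len <- genes_df$length_nt[match(rownames(counts), genes_df$gene_id)]
  if (anyNA(len))
    abort(sprintf("no catalogue length for gene(s): %s",
                  paste(utils::head(rownames(counts)[is.na(len)], 5),
                        collapse = ", ")))
  x <- counts / len
  cs <- colSums(x)
  if (any(cs == 0))
    warning(sprintf("all-zero sample(s) left as zero columns: %s",
                    paste(colnames(counts)[cs == 0], collapse = ", ")))
  cs[cs == 0] <- 1
  sweep(x, 2, cs, "/")
}

#' Gene richness per sample
#'
#' Number of genes with strictly positive abundance in each sample.
#'
#' @param freq gene x sample matrix (frequencies or counts).
#' @return Named integer vector, one entry per sample.
#' @export
gene_richness <- function(freq) {
  stats::setNames(as.integer(colSums(freq > 0)), colnames(freq))
}
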