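# Readers and writers for the pipeline's plain-text interchange formats.
# All matrices travel as TSV (feature ids in the first column, an optional
# "# scale:" header for abundance matrices) or as MatrixMarket MTX with
# .rows/.cols plain-text sidecars.

#' Write a matrix as TSV
#'
#' @param x matrix with row and column names. An `mgs_scale` attribute is
#'   recorded as a `# scale: <tag>` header line.
#' @param path output file.
#' @param id_col name of the id column (default `"feature_id"`).
#' @export
write_tsv_matrix <- function(x, path, id_col = "feature_id") {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(mgs_scale(x)))
    writeLines(sprintf("# scale: %s", mgs_scale(x)), con)
  df <- data.frame(rownames(x), as.data.frame(unclass(x)[, , drop = FALSE]),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c(id_col, colnames(x))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a matrix written by [write_tsv_matrix()]
#'
#' @param path TSV file; a leading `# scale:` line restores the scale tag.
#' @return Numeric matrix.
#' @export
read_tsv_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  scale_tag <- NULL
  skip <- 0L
  if (startsWith(first, "# scale:")) {
    scale_tag <- trimws(sub("^# scale:", "", first))
    skip <- 1L
  }
  df <- utils::read.delim(path, skip = skip, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (!is.null(scale_tag)) mgs_scale(m) <- scale_tag
  m
}

#' Write a matrix as MatrixMarket MTX with plain-text index sidecars
#'
#' Writes `<path>` (MTX), `<path>.rows` and `<path>.cols`.
#'
#' @param x matrix with dimnames.
#' @param path output `.mtx` file.
#' @export
write_matrix_mtx <- function(x, path) {
  Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(unclass(x)),
                                          "generalMatrix"), "CsparseMatrix"),
                  path)
  writeLines(rownames(x), paste0(path, ".rows"))
  writeLines(colnames(x), paste0(path, ".cols"))
  invisible(path)
}

#' Read a matrix written by [write_matrix_mtx()]
#'
#' @param path the `.mtx` file; `<path>.rows` / `<path>.cols` must exist.
#' @return Dense numeric matrix with dimnames.
#' @export
read_matrix_mtx <- function(path) {
  for (side in paste0(path, c(".rows", ".cols")))
    if (!file.exists(side))
      abort(sprintf("missing sidecar index file: %s", side))
  m <- as.matrix(Matrix::readMM(path))
  dimnames(m) <- list(readLines(paste0(path, ".rows")),
                      readLines(paste0(path, ".cols")))
  m
}

#' Write / read the gene catalogue annotation table
#'
#' Columns: `gene_id`, `length_nt`, `mgs_id`, `is_marker`, `is_core`,
#' `components` (comma-separated annotation ids, possibly empty).
#'
#' @param genes gene catalogue data frame.
#' @param path TSV file.
#' @export
write_gene_catalog <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' @rdname write_gene_catalog
#' @export
read_gene_catalog <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(components = "character"))
  need <- c("gene_id", "length_nt", "mgs_id", "is_marker", "is_core")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort(sprintf("gene catalogue %s lacks column(s): %s", path,
                  paste(miss, collapse = ", ")))
  if (is.null(df$components)) df$components <- ""
  df$components[is.na(df$components)] <- ""
  df
}

#' Write / read module definitions
#'
#' One module per line:
#' `module_id<TAB>name<TAB>database<TAB>comp1|comp1alt,comp2,...` where `|`
#' separates alternative ids within a component and `,` separates
#' components. Files with only three fields (no database column) are
#' accepted on read with database `"unknown"`.
#'
#' @param modules a [module_catalog()].
#' @param path text file.
#' @export
write_module_definitions <- function(modules, path) {
  stopifnot(inherits(modules, "module_catalog"))
  lines <- vapply(modules, function(m) {
    comps <- vapply(m$components, paste, "", collapse = "|")
    paste(m$module_id, m$name, m$database %||% "unknown",
          paste(comps, collapse = ","), sep = "\t")
  }, "")
  writeLines(lines, path)
}

#' @rdname write_module_definitions
#' @export
read_module_definitions <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  mods <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (!length(f) %in% 3:4)
      abort(sprintf("%s line %d: expected 3 or 4 tab-separated fields, got %d",
                    path, i, length(f)))
    comp_str <- f[length(f)]
    comps <- lapply(strsplit(comp_str, ",", fixed = TRUE)[[1]],
                    function(cc) strsplit(cc, "|", fixed = TRUE)[[1]])
    list(module_id = f[1], name = f[2],
         database = if (length(f) == 4L) f[3] else "unknown",
         components = comps)
  })
  module_catalog(mods)
}

#' Write / read read-mapping records
#'
#' TSV with columns `sample`, `read_id`, `genes` (comma-separated candidate
#' gene ids with equal best score).
#'
#' @param mappings read-mapping data frame.
#' @param path TSV file.
#' @export
write_read_mappings <- function(mappings, path) {
  utils::write.table(mappings, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' @rdname write_read_mappings
#' @export
read_read_mappings <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("sample", "read_id", "genes"), names(df))
  if (length(miss))
    abort(sprintf("mapping table %s lacks column(s): %s", path,
                  paste(miss, collapse = ", ")))
  bad <- which(is.na(df$genes) | !nzchar(df$genes))
  if (length(bad))
    abort(sprintf("mapping table %s: empty candidate set at data line %d",
                  path, bad[1]))
  df
}

#' Write / read sample metadata and cell counts
#'
#' Metadata is a plain TSV with a `sample` column; cell counts are a
#' two-column TSV `sample<TAB>cells_per_gram` with `NA` for missing
#' measurements.
#'
#' @param metadata data frame with a `sample` column.
#' @param path TSV file.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' @rdname write_metadata
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"sample" %in% names(df))
    abort(sprintf("metadata %s lacks a `sample` column", path))
  df
}

#' @rdname write_metadata
#' @param cells named numeric vector of cell counts.
#' @export
write_cell_counts <- function(cells, path) {
  utils::write.table(
    data.frame(sample = names(cells), cells_per_gram = unname(cells)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_metadata
#' @export
read_cell_counts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("sample", "cells_per_gram"), names(df))
  if (length(miss))
    abort(sprintf("cell-count table %s lacks column(s): %s", path,
                  paste(miss, collapse = ", ")))
  stats::setNames(df$cells_per_gram, df$sample)
}

#' Write / read the MGS taxonomy table
#'
#' Fixed seven-rank lineage per MGS; `NA` marks unclassified ranks.
#'
#' @param taxonomy data frame (`mgs_id` + seven ranks).
#' @param path TSV file.
#' @export
write_taxonomy <- function(taxonomy, path) {
  utils::write.table(taxonomy, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' @rdname write_taxonomy
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("mgs_id", "kingdom", "phylum", "class", "order", "family",
            "genus", "species")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort(sprintf("taxonomy %s lacks column(s): %s", path,
                  paste(miss, collapse = ", ")))
  df
}

#' Write every synthetic artifact in the pipeline's input formats
#'
#' Materializes a synthetic world (catalogue, cohort, optional read
#' mappings) as the plain-text files the pipeline consumes: gene catalogue,
#' taxonomy, module definitions, metadata, cell counts, cytokines, true
#' abundances, and mapping records.
#'
#' @param dir output directory (created if needed).
#' @param catalog a [generate_catalog()] result.
#' @param cohort a [generate_cohort()] result.
#' @param mappings optional [simulate_read_mappings()] result.
#' @return Invisibly, the named vector of written paths.
#' @export
write_synthetic_inputs <- function(dir, catalog, cohort, mappings = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    gene_catalog = file.path(dir, "gene_catalog.tsv"),
    taxonomy = file.path(dir, "taxonomy.tsv"),
    modules = file.path(dir, "module_definitions.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    cell_counts = file.path(dir, "cell_counts.tsv"),
    cytokines = file.path(dir, "cytokines.tsv"),
    true_absolute = file.path(dir, "true_absolute.tsv")
  )
  write_gene_catalog(catalog$genes, paths["gene_catalog"])
  write_taxonomy(catalog$defs$taxonomy, paths["taxonomy"])
  write_module_definitions(catalog$modules, paths["modules"])
  write_metadata(cohort$metadata, paths["metadata"])
  write_cell_counts(cohort$cell_counts, paths["cell_counts"])
  write_tsv_matrix(t(cohort$cytokines), paths["cytokines"],
                   id_col = "cytokine")
  ta <- cohort$truth$true_absolute
  mgs_scale(ta) <- "absolute"
  write_tsv_matrix(ta, paths["true_absolute"], id_col = "mgs_id")
  if (!is.null(mappings)) {
    paths["mappings"] <- file.path(dir, "read_mappings.tsv")
    write_read_mappings(mappings, paths["mappings"])
  }
  invisible(paths)
}
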