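#' Analysis configuration
#'
#' Collects the tunable parameters of the end-to-end analyses. `depth = NULL`
#' skips rarefaction (synthetic runs are usually generated at uniform
#' depth); the paper-scale default for real data would be 12e6.
#'
#' @param depth rarefaction depth or `NULL` to skip.
#' @param pseudocount Bray-Curtis log10 pseudocount (`NULL`: half the
#'   minimum positive abundance).
#' @param q_threshold FDR threshold for significance calls.
#' @param n_perm PERMANOVA permutations.
#' @param seed master seed for every stochastic stage.
#' @param covariates deconfounding covariates (metadata columns).
#' @param strict_only if `TRUE`, only strictly deconfounded features count
#'   as covariate-robust hits; if `FALSE`, ambiguously deconfounded
#'   features are kept too.
#' @return List of class `"analysis_config"`.
#' @export
analysis_config <- function(depth = NULL, pseudocount = NULL,
                            q_threshold = 0.1, n_perm = 999, seed = 1L,
                            covariates = c("age", "sex", "bmi", "smoking",
                                           "fecal_water"),
                            strict_only = FALSE) {
  if (q_threshold <= 0 || q_threshold >= 1)
    config_error("q_threshold must be in (0, 1)")
  structure(list(depth = depth, pseudocount = pseudocount,
                 q_threshold = q_threshold, n_perm = n_perm,
                 seed = assert_count(seed, "seed", min = 0L),
                 covariates = covariates, strict_only = strict_only),
            class = "analysis_config")
}

# Shared quantification front-end: reads/attribution -> frequencies ->
# MGS relative and absolute abundances.
quantify_pipeline <- function(data, config) {
  counts <- data$gene_counts
  if (is.null(counts)) {
    if (is.null(data$mappings))
      abort("need either `gene_counts` or `mappings` in the input data")
    counts <- attribute_reads(data$mappings, data$catalog)
  }
  if (!is.null(config$depth))
    counts <- downsize_counts(counts, config$depth,
                              seed = derive_seed(config$seed, 11L))
  freq <- to_frequency_matrix(counts, data$catalog)
  rel <- mgs_relative_abundance(freq, data$defs)
  index <- cell_count_index(data$cell_counts[colnames(rel)])
  abs <- to_absolute_abundance(rel, index)
  list(counts = counts, freq = freq, rel = rel, index = index, abs = abs)
}

#' Case-control analysis of a quantitative metagenome cohort
#'
#' Orchestrates the full pipeline: read attribution (or a supplied gene
#' count table), optional rarefaction, gene frequencies and richness, MGS
#' relative and cell-count-corrected absolute abundances, taxon
#' aggregation, functional-module presence and potentials, rank-based
#' case-control contrasts of MGS / genus / module features with BH control
#' and Cliff's Delta, deconfounding labels against the configured
#' covariates, Bray-Curtis beta diversity with PCoA and PERMANOVA (overall
#' and pairwise across treatment subgroups), alpha diversity, and Spearman
#' panels of contrasted species versus cytokines (treatment-naive cases
#' only, when available).
#'
#' @param data list with elements `mappings` (read-mapping table) or
#'   `gene_counts` (gene x sample matrix), `catalog` (gene catalogue),
#'   `defs` ([mgs_definitions()]), `modules` ([module_catalog()]),
#'   `cell_counts` (named vector), `metadata` (with `sample`, `status`,
#'   covariates, optionally `treatment`), and optionally `cytokines`
#'   (sample x cytokine matrix).
#' @param config an [analysis_config()].
#' @param out_dir optional directory; when given, all result tables and a
#'   `manifest.json` are written there.
#' @return List of result tables (see Details) plus a `manifest`.
#' @export
run_case_control <- function(data, config = analysis_config(),
                             out_dir = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  md <- data$metadata
  if (!all(c("sample", "status") %in% names(md)))
    abort("metadata needs `sample` and `status` columns")

  quant <- quantify_pipeline(data, config)
  md <- md[match(colnames(quant$rel), md$sample), , drop = FALSE]
  status <- md$status

  g_rich <- gene_richness(quant$freq)
  m_rich <- mgs_richness(quant$abs)
  taxa <- aggregate_taxa(quant$abs, data$defs, ranks = c("genus"))
  core_flags <- module_core_presence(data$defs, data$catalog, data$modules)
  presence <- refine_presence_per_sample(core_flags, quant$freq, data$defs,
                                         data$catalog, data$modules,
                                         quant$abs)
  potentials <- module_potential(presence, quant$abs)

  mgs_contrast <- contrast_features(quant$abs, status,
                                    q_threshold = config$q_threshold)
  genus_contrast <- contrast_features(taxa$genus, status,
                                      q_threshold = config$q_threshold)
  module_db <- vapply(data$modules, function(m) m$database %||% "unknown", "")
  module_contrast <- do.call(rbind, lapply(unique(module_db), function(db) {
    sub <- potentials[rownames(potentials) %in%
                        names(data$modules)[module_db == db], , drop = FALSE]
    res <- contrast_features(sub, status, q_threshold = config$q_threshold)
    res$database <- db
    res
  }))

  labels <- deconfound(quant$abs, md, status_col = "status",
                       covariates = intersect(config$covariates, names(md)),
                       q_threshold = config$q_threshold)
  robust <- if (config$strict_only) "strictly deconfounded"
            else c("strictly deconfounded", "ambiguously deconfounded")
  hits <- labels$feature[labels$label %in% robust]

  bc <- bray_curtis_log10(quant$abs, pseudocount = config$pseudocount)
  ord <- pcoa(bc, k = 2)
  perma <- permanova(bc, status, n_perm = config$n_perm,
                     seed = derive_seed(config$seed, 21L))
  pairwise <- NULL
  if ("treatment" %in% names(md) && length(unique(md$treatment)) > 1L) {
    subgroup <- ifelse(md$status == "control", "HC", md$treatment)
    if (all(table(subgroup) >= 2L))
      pairwise <- pairwise_permanova(bc, subgroup, n_perm = config$n_perm,
                                     seed = derive_seed(config$seed, 22L))
  }
  alpha <- alpha_diversity(quant$abs, metrics = c("richness", "shannon"))

  cyt_panel <- NULL
  if (!is.null(data$cytokines) && any(mgs_contrast$significant)) {
    sel <- md$sample
    if ("treatment" %in% names(md) && any(md$treatment == "naive"))
      sel <- md$sample[md$treatment == "naive"]
    contrasted <- mgs_contrast$feature[mgs_contrast$significant]
    cyt <- data$cytokines[rownames(data$cytokines) %in% sel, , drop = FALSE]
    if (nrow(cyt) >= 4L)
      cyt_panel <- spearman_panel(
        quant$abs[contrasted, rownames(cyt), drop = FALSE], cyt)
  }

  manifest <- list(
    tool = "mgsquant", version = as.character(utils::packageVersion("mgsquant")),
    analysis = "case_control",
    config = unclass(config),
    dims = list(genes = nrow(quant$freq), mgs = nrow(quant$rel),
                samples = ncol(quant$rel), modules = length(data$modules)),
    q_threshold = config$q_threshold,
    fdr_family = "one BH family per feature space (MGS; genus; one per module database)"
  )

  res <- list(gene_richness = g_rich, mgs_richness = m_rich,
              relative = quant$rel, absolute = quant$abs,
              cell_count_index = quant$index,
              module_potentials = potentials,
              mgs_contrast = mgs_contrast, genus_contrast = genus_contrast,
              module_contrast = module_contrast,
              deconfounding = labels, robust_hits = hits,
              bray_curtis = bc, pcoa = ord, permanova = perma,
              pairwise_permanova = pairwise, alpha = alpha,
              cytokine_panel = cyt_panel, manifest = manifest)
  if (!is.null(out_dir)) write_report_bundle(res, out_dir)
  res
}

#' Disease-activity analysis within cases
#'
#' Reproduces the activity arm of the analysis: within the treatment-naive
#' cases, richness adjusted for age, sex, BMI, smoking and fecal water is
#' correlated (Spearman) with the number of relapses over follow-up;
#' clinically active (CA, at least one relapse) and clinically non-active
#' (CNA, none) cases are contrasted on MGS and module features with
#' deconfounding; contrasted species are correlated with the cytokine
#' panel.
#'
#' @inheritParams run_case_control
#' @return List: `adjusted_richness`, `richness_vs_relapses` (rho, p, n),
#'   `ca_cna_mgs`, `ca_cna_modules`, `ca_cna_deconfounding`,
#'   `cytokine_panel`, `manifest`.
#' @export
run_activity_analysis <- function(data, config = analysis_config(),
                                  out_dir = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  md <- data$metadata
  if (!all(c("sample", "status", "relapses") %in% names(md)))
    abort("metadata needs `sample`, `status` and `relapses` columns")

  quant <- quantify_pipeline(data, config)
  md <- md[match(colnames(quant$rel), md$sample), , drop = FALSE]

  naive_sel <- md$status == "case" &
    (!"treatment" %in% names(md) | md$treatment %in% "naive") &
    !is.na(md$relapses)
  nmd <- md[naive_sel, , drop = FALSE]
  nmd$activity <- ifelse(nmd$relapses >= 1, "CA", "CNA")
  if (min(table(nmd$activity)) < 4L)
    abort(sprintf("activity subset too small: CA = %d, CNA = %d (need >= 4 each)",
                  sum(nmd$activity == "CA"), sum(nmd$activity == "CNA")))

  covs <- intersect(config$covariates, names(nmd))
  rich <- mgs_richness(quant$abs[, nmd$sample, drop = FALSE])
  adj <- adjust_richness(rich, nmd[, covs, drop = FALSE])
  if (stats::sd(nmd$relapses) == 0)
    abort("relapse counts are constant: richness-relapse correlation undefined")
  st <- spearman_test(adj, nmd$relapses[match(names(adj), nmd$sample)])
  richness_vs_relapses <- list(rho = st[1], p = st[2], n = length(adj))

  sub_abs <- quant$abs[, nmd$sample, drop = FALSE]
  ca_cna_mgs <- contrast_features(sub_abs, nmd$activity,
                                  q_threshold = config$q_threshold)
  core_flags <- module_core_presence(data$defs, data$catalog, data$modules)
  presence <- refine_presence_per_sample(
    core_flags, quant$freq[, nmd$sample, drop = FALSE], data$defs,
    data$catalog, data$modules, sub_abs)
  potentials <- module_potential(presence, sub_abs)
  ca_cna_modules <- contrast_features(potentials, nmd$activity,
                                      q_threshold = config$q_threshold)
  labels <- deconfound(sub_abs, nmd, status_col = "activity",
                       covariates = covs, q_threshold = config$q_threshold)

  cyt_panel <- NULL
  contrasted <- ca_cna_mgs$feature[!is.na(ca_cna_mgs$p) & ca_cna_mgs$p <= 0.05]
  if (!is.null(data$cytokines) && length(contrasted)) {
    cyt <- data$cytokines[rownames(data$cytokines) %in% nmd$sample, ,
                          drop = FALSE]
    if (nrow(cyt) >= 4L)
      cyt_panel <- spearman_panel(sub_abs[contrasted, rownames(cyt),
                                          drop = FALSE], cyt)
  }

  manifest <- list(
    tool = "mgsquant", version = as.character(utils::packageVersion("mgsquant")),
    analysis = "activity", config = unclass(config),
    n_ca = sum(nmd$activity == "CA"), n_cna = sum(nmd$activity == "CNA"))

  res <- list(adjusted_richness = adj,
              richness_vs_relapses = richness_vs_relapses,
              ca_cna_mgs = ca_cna_mgs, ca_cna_modules = ca_cna_modules,
              ca_cna_deconfounding = labels, cytokine_panel = cyt_panel,
              manifest = manifest)
  if (!is.null(out_dir)) write_report_bundle(res, out_dir)
  res
}

# Serialize a result bundle as TSV tables plus manifest.json.
write_report_bundle <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(res)) {
    x <- res[[nm]]
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    if (is.data.frame(x)) {
      utils::write.table(x, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    } else if (is.matrix(x)) {
      write_tsv_matrix(x, path)
    } else if (is.numeric(x) && !is.null(names(x))) {
      utils::write.table(data.frame(sample = names(x), value = unname(x)),
                         path, sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  jsonlite::write_json(res$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(out_dir)
}
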