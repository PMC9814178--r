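#' Configuration for the synthetic metagenome world
#'
#' Bundles every knob of the synthetic-data generator: the shape of the gene
#' catalogue (MGS pangenomes with marker, core and accessory genes; functional
#' modules), the cohort design (cases vs controls, planted differential MGS, a
#' planted BMI confounder, group-differing total microbial load) and the read
#' simulator (depth, fraction of multi-mapped reads).
#'
#' The defaults describe a deliberately small but structurally faithful world:
#' 100 marker genes per MGS (the nominal marker count used for MGS
#' quantification), an 80% core genome, a 4-fold (log2 fold change 2) planted
#' case effect on 10 of 100 MGS, and a BMI shift of 0.8 standard deviations
#' between groups driving 5 confounded MGS. See the methods vignette for the
#' rationale behind each default.
#'
#' @param n_mgs number of metagenomic species (MGS).
#' @param genes_per_mgs genes in each MGS pangenome.
#' @param n_markers_per_mgs marker genes per MGS (must fit inside the core).
#' @param core_fraction fraction of each pangenome that is core, in (0, 1].
#' @param n_modules number of functional modules in the catalogue.
#' @param components_per_module components (reaction steps) per module.
#' @param n_cases,n_controls cohort arm sizes.
#' @param n_da_mgs number of MGS with a planted case/control effect.
#' @param effect_log2fc planted effect size, log2 fold change on the absolute
#'   scale (alternating sign across the planted MGS).
#' @param load_ratio expected case:control ratio of total microbial load.
#' @param load_mode `"global"` multiplies every taxon of a case by
#'   `load_ratio`; `"driver"` concentrates the load excess on a designated
#'   high-abundance driver block, which is what produces a compositional
#'   artifact on relative abundances.
#' @param n_load_drivers size of the driver block (used when
#'   `load_mode = "driver"`).
#' @param confounder_strength BMI shift between cases and controls, in units
#'   of the BMI standard deviation.
#' @param confounder_beta effect of one BMI standard deviation on each
#'   confounded MGS, in log2 units.
#' @param n_confounded_mgs number of MGS driven by BMI rather than status.
#' @param n_cytokines size of the simulated plasma cytokine panel.
#' @param cytokine_rho correlation between the designated cytokine block and
#'   the designated MGS block.
#' @param read_depth simulated reads per sample.
#' @param shared_read_fraction fraction of reads mapping equally well to
#'   several genes, in [0, 1).
#' @param within_mgs_shared probability that a shared read's extra candidate
#'   gene comes from the same MGS.
#' @param accessory_carrier_fraction fraction of carrier (MGS, module) pairs
#'   in which one component is annotated only on an accessory gene, so that
#'   carriage is only recoverable by per-sample refinement.
#' @param missing_cellcount_fraction fraction of samples with a missing cell
#'   count (exercises the impute-to-1 rule).
#' @param sigma_log standard deviation of the per-sample log-normal abundance
#'   noise (natural-log scale).
#' @param cellcount_noise log-scale measurement noise on cell counts.
#' @param seed master seed; all generator randomness derives from it.
#' @return A list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_mgs = 100, genes_per_mgs = 150,
                             n_markers_per_mgs = 100, core_fraction = 0.8,
                             n_modules = 10, components_per_module = 5,
                             n_cases = 100, n_controls = 100,
                             n_da_mgs = 10, effect_log2fc = 2,
                             load_ratio = 1,
                             load_mode = c("global", "driver"),
                             n_load_drivers = 5,
                             confounder_strength = 0.8,
                             confounder_beta = 1.5,
                             n_confounded_mgs = 5,
                             n_cytokines = 10, cytokine_rho = 0.5,
                             read_depth = 10000,
                             shared_read_fraction = 0.1,
                             within_mgs_shared = 0.5,
                             accessory_carrier_fraction = 0,
                             missing_cellcount_fraction = 0.05,
                             sigma_log = 1, cellcount_noise = 0.05,
                             seed = 1) {
  load_mode <- match.arg(load_mode)
  cfg <- list(
    n_mgs = assert_count(n_mgs, "n_mgs"),
    genes_per_mgs = assert_count(genes_per_mgs, "genes_per_mgs"),
    n_markers_per_mgs = assert_count(n_markers_per_mgs, "n_markers_per_mgs"),
    core_fraction = assert_proportion(core_fraction, "core_fraction"),
    n_modules = assert_count(n_modules, "n_modules"),
    components_per_module = assert_count(components_per_module,
                                         "components_per_module"),
    n_cases = assert_count(n_cases, "n_cases"),
    n_controls = assert_count(n_controls, "n_controls"),
    n_da_mgs = assert_count(n_da_mgs, "n_da_mgs", min = 0L),
    effect_log2fc = assert_scalar_num(effect_log2fc, "effect_log2fc"),
    load_ratio = assert_scalar_num(load_ratio, "load_ratio", min = 1e-12),
    load_mode = load_mode,
    n_load_drivers = assert_count(n_load_drivers, "n_load_drivers"),
    confounder_strength = assert_scalar_num(confounder_strength,
                                            "confounder_strength"),
    confounder_beta = assert_scalar_num(confounder_beta, "confounder_beta"),
    n_confounded_mgs = assert_count(n_confounded_mgs, "n_confounded_mgs",
                                    min = 0L),
    n_cytokines = assert_count(n_cytokines, "n_cytokines"),
    cytokine_rho = assert_proportion(cytokine_rho, "cytokine_rho", -1, 1),
    read_depth = assert_count(read_depth, "read_depth"),
    shared_read_fraction = assert_proportion(shared_read_fraction,
                                             "shared_read_fraction"),
    within_mgs_shared = assert_proportion(within_mgs_shared,
                                          "within_mgs_shared"),
    accessory_carrier_fraction =
      assert_proportion(accessory_carrier_fraction,
                        "accessory_carrier_fraction"),
    missing_cellcount_fraction =
      assert_proportion(missing_cellcount_fraction,
                        "missing_cellcount_fraction"),
    sigma_log = assert_scalar_num(sigma_log, "sigma_log", min = 0),
    cellcount_noise = assert_scalar_num(cellcount_noise, "cellcount_noise",
                                        min = 0),
    seed = assert_count(seed, "seed", min = 0L)
  )
  if (cfg$core_fraction <= 0)
    config_error("`core_fraction` must be in (0, 1]")
  if (cfg$shared_read_fraction >= 1)
    config_error("`shared_read_fraction` must be in [0, 1)")
  n_core <- round(cfg$genes_per_mgs * cfg$core_fraction)
  if (cfg$n_markers_per_mgs > n_core)
    config_error(sprintf(
      "n_markers_per_mgs (%d) exceeds the core size (%d = round(%d x %.3g)): markers must be core genes",
      cfg$n_markers_per_mgs, n_core, cfg$genes_per_mgs, cfg$core_fraction))
  if (cfg$n_da_mgs > cfg$n_mgs)
    config_error("n_da_mgs exceeds n_mgs")
  n_special <- cfg$n_da_mgs + cfg$n_confounded_mgs +
    if (cfg$load_mode == "driver") cfg$n_load_drivers else 0L
  if (n_special > cfg$n_mgs)
    config_error(sprintf(
      "n_da_mgs + n_confounded_mgs (+ n_load_drivers in driver mode) = %d exceeds n_mgs = %d",
      n_special, cfg$n_mgs))
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate a synthetic gene catalogue with MGS pangenome structure
#'
#' Builds `n_mgs` pangenomes of `genes_per_mgs` genes each. The first
#' `round(genes_per_mgs * core_fraction)` genes of each MGS are core, the
#' first `n_markers_per_mgs` of those are markers; the rest are accessory.
#' Gene lengths are uniform on 300-3000 nt. Each module is carried by each
#' MGS with probability 1/2; carriers have every module component annotated
#' on core genes (except a configurable fraction rerouted to an accessory
#' gene), non-carriers receive at most enough components to stay strictly
#' below the 90% coverage threshold. A 7-rank taxonomy is attached, with
#' occasional unclassified genera to exercise aggregation bins.
#'
#' @param cfg a [synthetic_config()].
#' @return A list of class `"synthetic_catalog"` with elements `genes` (the
#'   gene catalogue data frame: `gene_id`, `length_nt`, `mgs_id`,
#'   `is_marker`, `is_core`, `components`), `defs` (an
#'   [mgs_definitions()] object), `modules` (a [module_catalog()]), and
#'   `module_carriage` (the MGS x module truth matrix).
#' @export
generate_catalog <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  withr::with_seed(derive_seed(cfg$seed, 0L), {
    n_core <- round(cfg$genes_per_mgs * cfg$core_fraction)
    mgs_ids <- sprintf("msp_%04d", seq_len(cfg$n_mgs))
    genes <- data.frame(
      gene_id = sprintf("%s_g%04d", rep(mgs_ids, each = cfg$genes_per_mgs),
                        rep(seq_len(cfg$genes_per_mgs), cfg$n_mgs)),
      length_nt = sample(300:3000, cfg$n_mgs * cfg$genes_per_mgs,
                         replace = TRUE),
      mgs_id = rep(mgs_ids, each = cfg$genes_per_mgs),
      is_marker = rep(seq_len(cfg$genes_per_mgs) <= cfg$n_markers_per_mgs,
                      cfg$n_mgs),
      is_core = rep(seq_len(cfg$genes_per_mgs) <= n_core, cfg$n_mgs),
      stringsAsFactors = FALSE
    )

    ## modules: components with 1-2 alternative annotation ids each
    dbs <- rep_len(c("GMM", "GBM", "KEGG"), cfg$n_modules)
    modules <- lapply(seq_len(cfg$n_modules), function(j) {
      comps <- lapply(seq_len(cfg$components_per_module), function(cc) {
        n_alt <- sample(1:2, 1)
        sprintf("KM%03dC%02d.%d", j, cc, seq_len(n_alt))
      })
      list(module_id = sprintf("mod_%03d", j),
           name = sprintf("synthetic module %d", j),
           database = dbs[j], components = comps)
    })
    modules <- module_catalog(modules)

    carriage <- matrix(stats::runif(cfg$n_mgs * cfg$n_modules) < 0.5,
                       nrow = cfg$n_mgs, ncol = cfg$n_modules,
                       dimnames = list(mgs_ids,
                                       vapply(modules, `[[`, "", "module_id")))
    ncomp <- cfg$components_per_module
    # maximum number of distinct components a non-carrier may expose while
    # staying strictly below 90% coverage
    max_noncarrier <- max(0L, ceiling(0.9 * ncomp) - 1L)

    ann <- vector("list", nrow(genes))  # per-gene component id sets
    gene_rows <- split(seq_len(nrow(genes)), genes$mgs_id)[mgs_ids]
    for (i in seq_len(cfg$n_mgs)) {
      rows <- gene_rows[[i]]
      core_rows <- rows[genes$is_core[rows]]
      acc_rows <- rows[!genes$is_core[rows]]
      for (j in seq_len(cfg$n_modules)) {
        comps <- modules[[j]]$components
        if (carriage[i, j]) {
          acc_only <- if (length(acc_rows) > 0 &&
                          stats::runif(1) < cfg$accessory_carrier_fraction)
            sample.int(ncomp, 1) else 0L
          for (cc in seq_len(ncomp)) {
            pool <- if (cc == acc_only) acc_rows else core_rows
            g <- pool[sample.int(length(pool), 1)]
            id <- comps[[cc]][sample.int(length(comps[[cc]]), 1)]
            ann[[g]] <- c(ann[[g]], id)
          }
        } else if (max_noncarrier > 0L) {
          keep <- sample.int(ncomp, sample.int(max_noncarrier + 1L, 1) - 1L)
          for (cc in keep) {
            g <- rows[sample.int(length(rows), 1)]
            id <- comps[[cc]][sample.int(length(comps[[cc]]), 1)]
            ann[[g]] <- c(ann[[g]], id)
          }
        }
      }
    }
    genes$components <- vapply(ann, function(x)
      paste(unique(x), collapse = ","), "")

    taxonomy <- data.frame(
      mgs_id = mgs_ids,
      kingdom = "Bacteria",
      phylum = sprintf("phylum_%d", (seq_len(cfg$n_mgs) - 1L) %/% 25L + 1L),
      class = sprintf("class_%d", (seq_len(cfg$n_mgs) - 1L) %/% 16L + 1L),
      order = sprintf("order_%d", (seq_len(cfg$n_mgs) - 1L) %/% 8L + 1L),
      family = sprintf("family_%d", (seq_len(cfg$n_mgs) - 1L) %/% 4L + 1L),
      genus = sprintf("genus_%d", (seq_len(cfg$n_mgs) - 1L) %/% 2L + 1L),
      species = sprintf("species_%d", seq_len(cfg$n_mgs)),
      stringsAsFactors = FALSE
    )
    # every 7th genus label withheld to exercise unclassified aggregation
    taxonomy$genus[seq_len(cfg$n_mgs) %% 7L == 0L] <- NA_character_

    defs <- mgs_definitions(genes, taxonomy)
    structure(list(genes = genes, defs = defs, modules = modules,
                   module_carriage = carriage),
              class = "synthetic_catalog")
  })
}

#' Generate a synthetic cohort with planted effects and a planted confounder
#'
#' Draws per-MGS log-normal baseline abundances, plants a status effect of
#' `effect_log2fc` (alternating sign) on `n_da_mgs` MGS, makes BMI shift by
#' `confounder_strength` standard deviations between groups and drive
#' `n_confounded_mgs` MGS, and gives cases a total-load difference of
#' `load_ratio` (globally or through a driver block, see
#' [synthetic_config()]). Cell counts are proportional to each sample's total
#' absolute abundance with small log-normal measurement noise, and a
#' configurable fraction is set missing. A cytokine block is correlated with
#' the first planted MGS block at strength `cytokine_rho`.
#'
#' @param cfg a [synthetic_config()].
#' @param catalog output of [generate_catalog()].
#' @return A list of class `"synthetic_cohort"`: `metadata` (sample, status,
#'   age, sex, bmi, smoking, fecal_water, treatment, relapses, activity),
#'   `cell_counts` (named numeric, cells per gram, may contain `NA`),
#'   `cytokines` (samples x cytokines matrix), and `truth` (list:
#'   `true_absolute`, `da_mgs_ids`, `da_direction`, `confounded_mgs_ids`,
#'   `load_driver_ids`, `module_carriage`, `cytokine_block`).
#' @export
generate_cohort <- function(cfg, catalog) {
  stopifnot(inherits(cfg, "synthetic_config"),
            inherits(catalog, "synthetic_catalog"))
  withr::with_seed(derive_seed(cfg$seed, 1L), {
    n <- cfg$n_cases + cfg$n_controls
    samples <- sprintf("S%04d", seq_len(n))
    is_case <- rep(c(TRUE, FALSE), c(cfg$n_cases, cfg$n_controls))
    mgs_ids <- catalog$defs$taxonomy$mgs_id

    ## metadata (marginals loosely matching a Danish adult cohort)
    age <- round(stats::rnorm(n, 36, 8.4), 1)
    sex <- ifelse(stats::runif(n) < 0.66, "F", "M")
    bmi <- round(stats::rnorm(n, 23, 3.4) +
                   is_case * cfg$confounder_strength * 3.4, 1)
    smoking <- sample(c("never", "previous", "current"), n, replace = TRUE,
                      prob = c(0.5, 0.3, 0.2))
    fecal_water <- round(pmin(95, pmax(30, stats::rnorm(n, 69, 11))), 1)
    treatment <- ifelse(is_case,
                        sample(c("naive", "first_line", "second_line"), n,
                               replace = TRUE, prob = c(0.36, 0.23, 0.41)),
                        "none")
    relapses <- ifelse(is_case, stats::rpois(n, 0.7), NA_integer_)
    activity <- ifelse(is_case, ifelse(relapses >= 1, "CA", "CNA"),
                       NA_character_)

    metadata <- data.frame(
      sample = samples,
      status = ifelse(is_case, "case", "control"),
      age = age, sex = sex, bmi = bmi, smoking = smoking,
      fecal_water = fecal_water, treatment = treatment,
      relapses = as.integer(relapses), activity = activity,
      stringsAsFactors = FALSE
    )

    ## planted structure: index blocks (drivers, then DA, then confounded)
    k <- 0L
    driver_idx <- integer(0)
    if (cfg$load_mode == "driver") {
      driver_idx <- seq_len(cfg$n_load_drivers)
      k <- cfg$n_load_drivers
    }
    da_idx <- if (cfg$n_da_mgs > 0) k + seq_len(cfg$n_da_mgs) else integer(0)
    k <- k + cfg$n_da_mgs
    conf_idx <- if (cfg$n_confounded_mgs > 0)
      k + seq_len(cfg$n_confounded_mgs) else integer(0)

    mu <- stats::rnorm(cfg$n_mgs, 0, 1.5)
    mu[driver_idx] <- mu[driver_idx] + 2.5  # drivers dominate the load

    lw <- matrix(mu, nrow = cfg$n_mgs, ncol = n) +
      matrix(stats::rnorm(cfg$n_mgs * n, 0, cfg$sigma_log), cfg$n_mgs, n)
    da_dir <- rep_len(c(1, -1), length(da_idx))
    if (length(da_idx))
      lw[da_idx, is_case] <- lw[da_idx, is_case] +
        da_dir * cfg$effect_log2fc * log(2)
    bmi_z <- as.numeric(scale(bmi))
    if (length(conf_idx))
      lw[conf_idx, ] <- lw[conf_idx, ] +
        cfg$confounder_beta * log(2) * rep(bmi_z, each = length(conf_idx))
    w <- exp(lw)

    ## total-load difference between groups
    if (cfg$load_mode == "global") {
      w[, is_case] <- w[, is_case] * cfg$load_ratio
    } else {
      ew <- exp(mu + cfg$sigma_log^2 / 2)
      phi <- sum(ew[driver_idx]) / sum(ew)
      gamma <- (cfg$load_ratio - 1 + phi) / phi
      if (gamma <= 0)
        config_error(sprintf(
          "load_ratio %.3g unreachable by scaling the driver block (driver load share %.3g)",
          cfg$load_ratio, phi))
      w[driver_idx, is_case] <- w[driver_idx, is_case] * gamma
    }
    dimnames(w) <- list(mgs_ids, samples)

    ## cell counts track total absolute load
    total <- colSums(w)
    cells <- total / mean(total) * 2e10 *
      exp(stats::rnorm(n, 0, cfg$cellcount_noise))
    n_miss <- round(cfg$missing_cellcount_fraction * n)
    if (n_miss > 0) cells[sample.int(n, n_miss)] <- NA_real_
    names(cells) <- samples

    ## cytokine panel with a block tied to the first planted MGS block
    cyt_names <- c("IL17A", "IL6", "TNFa", "CRP", "IL22", "IL33", "IFNb",
                   "IL10", "CCL2", "TGFb")
    cyt_names <- make.unique(rep_len(cyt_names, cfg$n_cytokines))
    block_mgs <- if (length(da_idx)) mgs_ids[da_idx[seq_len(min(3, length(da_idx)))]]
                 else mgs_ids[seq_len(min(3, cfg$n_mgs))]
    block_cyt <- cyt_names[seq_len(min(3, cfg$n_cytokines))]
    z <- as.numeric(scale(colMeans(log(w[block_mgs, , drop = FALSE]))))
    cyt <- matrix(stats::rnorm(n * cfg$n_cytokines), n, cfg$n_cytokines,
                  dimnames = list(samples, cyt_names))
    rho <- cfg$cytokine_rho
    cyt[, block_cyt] <- rho * z + sqrt(1 - rho^2) * cyt[, block_cyt]
    cyt <- exp(cyt)  # concentrations are positive

    truth <- list(
      true_absolute = w,
      da_mgs_ids = mgs_ids[da_idx],
      da_direction = stats::setNames(da_dir, mgs_ids[da_idx]),
      confounded_mgs_ids = mgs_ids[conf_idx],
      load_driver_ids = mgs_ids[driver_idx],
      module_carriage = catalog$module_carriage,
      cytokine_block = list(mgs = block_mgs, cytokines = block_cyt)
    )
    structure(list(metadata = metadata, cell_counts = cells,
                   cytokines = cyt, truth = truth),
              class = "synthetic_cohort")
  })
}

#' Simulate read-mapping records from true abundances
#'
#' Draws `read_depth` read records per sample, each landing on a gene with
#' probability proportional to gene length times the absolute abundance of
#' the gene's MGS (multinomial sampling; no base-level error model). A
#' fraction `shared_read_fraction` of records are "shared": they list two or
#' three candidate genes with equal best score, the extra candidates coming
#' from the same MGS with probability `within_mgs_shared` and from anywhere
#' in the catalogue otherwise.
#'
#' @param true_absolute MGS x sample abundance matrix (e.g.
#'   `truth$true_absolute` from [generate_cohort()]).
#' @param catalog a [generate_catalog()] result or its `genes` data frame.
#' @param cfg a [synthetic_config()].
#' @return A data frame (`sample`, `read_id`, `genes`) where `genes` is a
#'   comma-separated candidate list; the read-mapping table consumed by
#'   [attribute_reads()].
#' @export
simulate_read_mappings <- function(true_absolute, catalog, cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  genes <- if (inherits(catalog, "synthetic_catalog")) catalog$genes
           else catalog
  if (is.null(dim(true_absolute)) || length(true_absolute) == 0L ||
      ncol(true_absolute) == 0L)
    abort("empty abundance matrix: nothing to simulate reads from")
  G <- nrow(genes)
  mgs_of <- match(genes$mgs_id, rownames(true_absolute))
  if (anyNA(mgs_of))
    abort("catalogue references MGS absent from the abundance matrix")
  idx_by_mgs <- split(seq_len(G), genes$mgs_id)

  withr::with_seed(derive_seed(cfg$seed, 2L), {
    out <- vector("list", ncol(true_absolute))
    for (s in seq_len(ncol(true_absolute))) {
      p <- genes$length_nt * true_absolute[mgs_of, s]
      if (sum(p) <= 0)
        abort(sprintf("sample %s has zero total abundance",
                      colnames(true_absolute)[s]))
      prim <- sample.int(G, cfg$read_depth, replace = TRUE, prob = p)
      gstr <- genes$gene_id[prim]
      n_shared <- round(cfg$shared_read_fraction * cfg$read_depth)
      if (n_shared > 0) {
        sh <- seq_len(n_shared)  # read order carries no meaning
        within <- stats::runif(n_shared) < cfg$within_mgs_shared
        partner <- integer(n_shared)
        for (i in sh) {
          if (within[i]) {
            pool <- idx_by_mgs[[genes$mgs_id[prim[i]]]]
            pool <- pool[pool != prim[i]]
            partner[i] <- if (length(pool)) pool[sample.int(length(pool), 1)]
                          else sample.int(G, 1)
          } else {
            partner[i] <- sample.int(G, 1)
          }
        }
        gstr[sh] <- paste(gstr[sh], genes$gene_id[partner], sep = ",")
        # occasionally a third equally-scoring candidate
        triple <- sh[stats::runif(n_shared) < 0.25]
        if (length(triple))
          gstr[triple] <- paste(gstr[triple],
                                genes$gene_id[sample.int(G, length(triple),
                                                         replace = TRUE)],
                                sep = ",")
      }
      out[[s]] <- data.frame(
        sample = colnames(true_absolute)[s],
        read_id = sprintf("r%07d", seq_len(cfg$read_depth)),
        genes = gstr, stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}
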