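test_that("catalogue counts are forced by construction", {
  cfg <- synthetic_config(n_mgs = 5, genes_per_mgs = 200,
                          n_markers_per_mgs = 100, core_fraction = 0.5,
                          n_cases = 4, n_controls = 4, n_da_mgs = 1,
                          n_confounded_mgs = 0, seed = 1)
  cat_ <- generate_catalog(cfg)
  expect_equal(nrow(cat_$genes), 1000)
  expect_equal(sum(cat_$genes$is_marker), 5 * 100)
  expect_equal(sum(cat_$genes$is_core), 5 * 100)
  expect_true(all(cat_$genes$is_core[cat_$genes$is_marker]))
  expect_equal(anyDuplicated(cat_$genes$gene_id), 0)
  expect_true(all(cat_$genes$length_nt >= 300 & cat_$genes$length_nt <= 3000))
  expect_equal(lengths(cat_$defs$markers), setNames(rep(100L, 5),
                                                    names(cat_$defs$markers)))
})

test_that("inconsistent sizes raise configuration errors naming the constraint", {
  expect_error(synthetic_config(n_markers_per_mgs = 150, genes_per_mgs = 200,
                                core_fraction = 0.5),
               "n_markers_per_mgs.*core", class = "mgsquant_config_error")
  expect_error(synthetic_config(n_da_mgs = 50, n_mgs = 10),
               class = "mgsquant_config_error")
  expect_error(synthetic_config(shared_read_fraction = 1),
               class = "mgsquant_config_error")
  expect_error(synthetic_config(core_fraction = 0),
               class = "mgsquant_config_error")
})

test_that("identical seed and config give byte-identical outputs", {
  w1 <- tiny_world(seed = 99)
  w2 <- tiny_world(seed = 99)
  expect_identical(w1$catalog, w2$catalog)
  expect_identical(w1$cohort, w2$cohort)
  m1 <- simulate_read_mappings(w1$cohort$truth$true_absolute, w1$catalog,
                               w1$cfg)
  m2 <- simulate_read_mappings(w2$cohort$truth$true_absolute, w2$catalog,
                               w2$cfg)
  expect_identical(m1, m2)
  w3 <- tiny_world(seed = 100)
  expect_false(identical(w1$cohort$truth$true_absolute,
                         w3$cohort$truth$true_absolute))
})

test_that("planted-effect bookkeeping matches the configuration", {
  w <- tiny_world(n_da_mgs = 3, effect_log2fc = 2)
  expect_length(w$cohort$truth$da_mgs_ids, 3)
  expect_true(all(w$cohort$truth$da_mgs_ids %in%
                    rownames(w$cohort$truth$true_absolute)))
  expect_true(all(w$cohort$truth$true_absolute >= 0))
  # missing cell counts at the configured fraction
  w2 <- tiny_world(n_cases = 20, n_controls = 20,
                   missing_cellcount_fraction = 0.1)
  expect_equal(sum(is.na(w2$cohort$cell_counts)), 4)
})

test_that("global load_ratio scales every taxon absolutely but not relatively", {
  # closed form: multiplying all case samples by a constant leaves the
  # composition invariant while absolute abundances shift by the constant
  w <- tiny_world(n_mgs = 30, n_cases = 150, n_controls = 150, n_da_mgs = 0,
                  n_confounded_mgs = 0, load_ratio = 2, sigma_log = 0.4,
                  seed = 5)
  truth <- w$cohort$truth$true_absolute
  is_case <- w$cohort$metadata$status == "case"
  lfc_abs <- log2(rowMeans(truth[, is_case]) / rowMeans(truth[, !is_case]))
  expect_equal(median(lfc_abs), 1, tolerance = 0.15)
  rel <- sweep(truth, 2, colSums(truth), "/")
  lfc_rel <- log2(rowMeans(rel[, is_case]) / rowMeans(rel[, !is_case]))
  expect_equal(median(lfc_rel), 0, tolerance = 0.15)
})

test_that("null configuration plants nothing", {
  w <- tiny_world(n_da_mgs = 0, n_confounded_mgs = 0, load_ratio = 1)
  expect_length(w$cohort$truth$da_mgs_ids, 0)
  expect_length(w$cohort$truth$confounded_mgs_ids, 0)
  expect_length(w$cohort$truth$load_driver_ids, 0)
})

test_that("read simulation respects shared fraction and abundance support", {
  w <- tiny_world(shared_read_fraction = 0, read_depth = 500)
  maps <- simulate_read_mappings(w$cohort$truth$true_absolute, w$catalog,
                                 w$cfg)
  expect_true(all(!grepl(",", maps$genes)))
  expect_equal(nrow(maps), 500 * ncol(w$cohort$truth$true_absolute))

  # support restriction: all mass on one MGS
  ta <- w$cohort$truth$true_absolute
  ta[] <- 0
  ta["msp_0003", ] <- 1
  cfg0 <- tiny_config(shared_read_fraction = 0, read_depth = 1000)
  maps0 <- simulate_read_mappings(ta[, 1:2], w$catalog, cfg0)
  hit_mgs <- w$catalog$genes$mgs_id[match(maps0$genes,
                                          w$catalog$genes$gene_id)]
  expect_true(all(hit_mgs == "msp_0003"))

  # shared records list >= 2 candidates at the configured rate
  wS <- tiny_world(shared_read_fraction = 0.4, read_depth = 1000)
  mapsS <- simulate_read_mappings(wS$cohort$truth$true_absolute, wS$catalog,
                                  wS$cfg)
  n_cand <- lengths(strsplit(mapsS$genes, ","))
  per_sample <- tapply(n_cand >= 2, mapsS$sample, sum)
  expect_true(all(per_sample == 400))

  expect_error(simulate_read_mappings(ta[, integer(0), drop = FALSE],
                                      w$catalog, cfg0),
               "empty|zero")
})

test_that("driver-mode load_ratio reaches the target total-load ratio", {
  w <- tiny_world(n_mgs = 40, n_cases = 200, n_controls = 200, n_da_mgs = 0,
                  n_confounded_mgs = 0, load_mode = "driver", load_ratio = 2,
                  n_load_drivers = 4, seed = 8)
  truth <- w$cohort$truth$true_absolute
  is_case <- w$cohort$metadata$status == "case"
  ratio <- mean(colSums(truth[, is_case])) / mean(colSums(truth[, !is_case]))
  expect_equal(ratio, 2, tolerance = 0.25)
  expect_length(w$cohort$truth$load_driver_ids, 4)
})

test_that("cytokine block correlates with the designated MGS block", {
  w <- tiny_world(n_cases = 100, n_controls = 100, cytokine_rho = 0.6,
                  seed = 3)
  blk <- w$cohort$truth$cytokine_block
  z <- colMeans(log(w$cohort$truth$true_absolute[blk$mgs, , drop = FALSE]))
  rho <- cor(z, log(w$cohort$cytokines[, blk$cytokines[1]]),
             method = "spearman")
  expect_gt(rho, 0.4)
})
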