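# Small synthetic worlds reused across test files. Everything is generated
# in code at test time; nothing is read from disk.

tiny_config <- function(...) {
  defaults <- list(n_mgs = 10, genes_per_mgs = 20, n_markers_per_mgs = 8,
                   core_fraction = 0.8, n_modules = 4,
                   components_per_module = 5, n_cases = 10, n_controls = 10,
                   n_da_mgs = 2, n_confounded_mgs = 1, effect_log2fc = 2,
                   read_depth = 2000, seed = 42)
  args <- utils::modifyList(defaults, list(...))
  do.call(synthetic_config, args)
}

tiny_world <- function(...) {
  cfg <- tiny_config(...)
  cat_ <- generate_catalog(cfg)
  coh <- generate_cohort(cfg, cat_)
  list(cfg = cfg, catalog = cat_, cohort = coh)
}

# toy frequency matrix for hand-computed marker examples
toy_freq <- function(values, genes, samples = paste0("s", seq_len(ncol(values)))) {
  m <- matrix(values, nrow = length(genes), dimnames = list(genes, samples))
  m
}

# random mapping table over a small gene universe
random_mappings <- function(n_records, genes, n_samples = 2,
                            shared_prob = 0.3, seed = 1) {
  withr::with_seed(seed, {
    recs <- vapply(seq_len(n_records), function(i) {
      k <- if (stats::runif(1) < shared_prob) sample(2:3, 1) else 1L
      paste(sample(genes, k), collapse = ",")
    }, "")
    data.frame(sample = sample(paste0("s", seq_len(n_samples)), n_records,
                               replace = TRUE),
               read_id = paste0("r", seq_len(n_records)),
               genes = recs, stringsAsFactors = FALSE)
  })
}
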