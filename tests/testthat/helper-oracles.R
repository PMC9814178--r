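# Independent brute-force oracles. Each one re-derives an operation from its
# definition with the dumbest possible loop, deliberately sharing no code
# with the implementation it checks.

oracle_attribute <- function(mappings, gene_levels) {
  samples <- unique(mappings$sample)
  out <- matrix(0, length(gene_levels), length(samples),
                dimnames = list(gene_levels, samples))
  for (s in samples) {
    recs <- lapply(strsplit(mappings$genes[mappings$sample == s], ","),
                   unique)
    uniq <- table(unlist(recs[lengths(recs) == 1]))
    for (r in recs) {
      if (length(r) == 1) {
        out[r, s] <- out[r, s] + 1
      } else {
        w <- as.numeric(uniq[r])
        w[is.na(w)] <- 0
        if (sum(w) == 0) w <- rep(1, length(r))
        out[r, s] <- out[r, s] + w / sum(w)
      }
    }
  }
  out
}

oracle_cliffs <- function(x, y) {
  s <- 0
  for (i in seq_along(x))
    for (j in seq_along(y))
      s <- s + sign(x[i] - y[j])
  s / (length(x) * length(y))
}

oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(i:m, function(k) m * p[o[k]] / k, 0)
    q[o[i]] <- min(1, min(cand))
  }
  q
}

# set-cover module presence: component satisfied by any alternative on any
# gene of the supplied set
oracle_module_presence <- function(gene_ids, ann, components,
                                   threshold = 0.9) {
  ids <- unique(unlist(ann[gene_ids]))
  covered <- sum(vapply(components, function(alts)
    length(intersect(alts, ids)) > 0, logical(1)))
  covered / length(components) >= threshold
}

oracle_permanova_f <- function(d, groups) {
  d <- as.matrix(d)
  g <- factor(groups)
  n <- nrow(d)
  ss_tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    ss_tot <- ss_tot + d[i, j]^2
  ss_tot <- ss_tot / n
  ss_w <- 0
  for (lv in levels(g)) {
    idx <- which(g == lv)
    for (a in seq_along(idx)) for (b in seq_along(idx))
      if (a < b) ss_w <- ss_w + d[idx[a], idx[b]]^2 / length(idx)
  }
  k <- nlevels(g)
  ((ss_tot - ss_w) / (k - 1)) / (ss_w / (n - k))
}

oracle_bray_curtis <- function(y) {
  n <- ncol(y)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- sum(abs(y[, i] - y[, j])) / sum(y[, i] + y[, j])
  d
}

# all distinct orderings of a label vector (tiny n only)
all_label_permutations <- function(g) {
  n <- length(g)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    out
  }
  unique(lapply(perms(seq_len(n)), function(ix) g[ix]))
}
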