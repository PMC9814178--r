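test_that("Bray-Curtis on log10 abundances has the stated metric properties", {
  withr::with_seed(14, {
    ab <- matrix(rexp(60) * (runif(60) < 0.7), 10, 6,
                 dimnames = list(paste0("m", 1:10), paste0("s", 1:6)))
    ab[, 6] <- ab[, 5]                      # duplicate sample
    ab[1, ] <- pmax(ab[1, ], 0.1)           # keep every column non-zero
    d <- bray_curtis_log10(ab)
    expect_true(isSymmetric(unname(d)))
    expect_equal(unname(diag(d)), rep(0, 6))
    expect_true(all(d >= 0 & d <= 1))
    expect_equal(d["s5", "s6"], 0)          # identity of indiscernibles
    # cross-check against the direct formula on the transformed matrix
    pc <- attr(d, "pseudocount")
    y <- log10(ab + pc) - log10(pc)
    expect_equal(unname(d), oracle_bray_curtis(y), ignore_attr = TRUE,
                 tolerance = 1e-12)
    # and against vegan on the same transformed matrix
    expect_equal(unname(d),
                 as.matrix(vegan::vegdist(t(y), method = "bray")),
                 ignore_attr = TRUE, tolerance = 1e-12)
  })
})

test_that("disjoint supports give distance 1 and zero samples error", {
  ab <- matrix(c(1, 2, 0, 0, 0, 0, 3, 4), 4,
               dimnames = list(paste0("m", 1:4), c("s1", "s2")))
  expect_equal(bray_curtis_log10(ab)["s1", "s2"], 1)
  ab0 <- cbind(ab, s3 = c(0, 0, 0, 0))
  expect_error(bray_curtis_log10(ab0), "s3")
})

test_that("halving the pseudocount changes distances continuously", {
  withr::with_seed(15, {
    # fixed triplet with clearly separated pairwise distances
    ab <- cbind(a = c(5, 4, 3, 2, 1, 0, 0, 0, 0, 0),
                b = c(5, 4, 3, 0, 0, 2, 1, 0, 0, 0),
                c = c(0, 0, 0, 0, 0, 1, 2, 3, 4, 5))
    rownames(ab) <- paste0("m", 1:10)
    d1 <- bray_curtis_log10(ab, pseudocount = 1e-3)
    d2 <- bray_curtis_log10(ab, pseudocount = 5e-4)
    expect_lt(max(abs(d1 - d2)), 0.1)
    # ordering of the triplet is preserved
    expect_equal(order(c(d1["a", "b"], d1["a", "c"], d1["b", "c"])),
                 order(c(d2["a", "b"], d2["a", "c"], d2["b", "c"])))
  })
})

test_that("PCoA recovers collinear configurations and duplicates", {
  x <- c(0, 1, 3, 6, 10)
  d <- abs(outer(x, x, "-"))
  dimnames(d) <- list(paste0("s", 1:5), paste0("s", 1:5))
  fit <- pcoa(d, k = 2)
  rec <- abs(outer(fit$coordinates[, 1], fit$coordinates[, 1], "-"))
  expect_lt(max(abs(rec - d)), 1e-8)
  # a 1-D configuration has a single meaningful eigenvalue
  expect_lt(abs(fit$eigenvalues[2]), 1e-8 * fit$eigenvalues[1])

  ab <- matrix(runif(20, 1, 2), 4, 5,
               dimnames = list(paste0("m", 1:4), paste0("s", 1:5)))
  ab[, 2] <- ab[, 1]
  f2 <- pcoa(bray_curtis_log10(ab), k = 2)
  expect_equal(f2$coordinates["s1", ], f2$coordinates["s2", ],
               tolerance = 1e-8)
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2), k = 1), "symmetric")
  expect_error(pcoa(d, k = 5), "at most")
})

test_that("PERMANOVA pseudo-F matches the two-loop oracle and vegan", {
  withr::with_seed(16, {
    for (rep in 1:3) {
      pts <- matrix(rnorm(12 * 3), 12)
      d <- as.matrix(dist(pts))
      g <- sample(rep(c("a", "b", "c"), each = 4))
      fit <- permanova(d, g, n_perm = 9, seed = 1)
      expect_equal(fit$pseudo_F, oracle_permanova_f(d, g), tolerance = 1e-12)
      ref <- vegan::adonis2(as.dist(d) ~ g, permutations = 9)
      expect_equal(fit$pseudo_F, ref$F[1], tolerance = 1e-10)
      expect_equal(fit$R2, ref$R2[1], tolerance = 1e-10)
    }
  })
})

test_that("PERMANOVA p equals the exhaustive permutation p on tiny instances", {
  withr::with_seed(17, {
    pts <- matrix(rnorm(6 * 2), 6)
    d <- as.matrix(dist(pts))
    g <- rep(c("a", "b"), each = 3)
    perm_mat <- do.call(rbind, lapply(all_label_permutations(1:6), identity))
    fit <- permanova(d, g, permutations = perm_mat)
    fs <- apply(perm_mat, 1, function(ix) oracle_permanova_f(d, g[ix]))
    expect_equal(fit$p, mean(fs >= fit$pseudo_F - 1e-12))
    expect_gte(fit$p, 1 / nrow(perm_mat))
  })
})

test_that("PERMANOVA is invariant to joint relabeling and maximal when separated", {
  withr::with_seed(18, {
    pts <- matrix(rnorm(10 * 2), 10)
    d <- as.matrix(dist(pts))
    g <- rep(c("a", "b"), each = 5)
    ix <- sample(10)
    f1 <- permanova(d, g, n_perm = 49, seed = 2)$pseudo_F
    f2 <- permanova(d[ix, ix], g[ix], n_perm = 49, seed = 2)$pseudo_F
    expect_equal(f1, f2, tolerance = 1e-12)

    # two well-separated clouds: observed F beats every permutation
    clouds <- rbind(matrix(rnorm(10, 0, 0.1), 5),
                    matrix(rnorm(10, 50, 0.1), 5))
    ds <- as.matrix(dist(clouds))
    fit <- permanova(ds, g, n_perm = 99, seed = 3)
    expect_equal(fit$p, 1 / 100)
    expect_error(permanova(ds, g, n_perm = 0), "n_perm")
    expect_error(permanova(ds, rep("a", 10)), "2 groups")
  })
})

test_that("pairwise PERMANOVA reduces to PERMANOVA for two groups", {
  withr::with_seed(19, {
    d <- as.matrix(dist(matrix(rnorm(16 * 2), 16)))
    g <- rep(c("x", "y"), each = 8)
    pw <- pairwise_permanova(d, g, n_perm = 99, seed = 5)
    expect_equal(nrow(pw), 1)
    single <- permanova(d, g, n_perm = 99, seed = 6)  # pairwise derives 5+1
    expect_equal(pw$pseudo_F, single$pseudo_F, tolerance = 1e-12)
    g3 <- rep(c("x", "y", "z"), c(6, 5, 5))
    pw3 <- pairwise_permanova(d, g3, n_perm = 49, seed = 5)
    expect_equal(nrow(pw3), 3)
    expect_equal(pw3$q, bh_adjust(pw3$p))
  })
})

test_that("alpha diversity formulas are right on closed-form cases", {
  ab <- matrix(c(rep(1, 5), 0, 0, 0, 0, 0,
                 10, rep(0, 9)), 10, 2,
               dimnames = list(paste0("m", 1:10), c("uniform5", "single")))
  a <- alpha_diversity(ab, metrics = c("richness", "shannon"))
  expect_equal(a$shannon[1], log(5))
  expect_equal(a$shannon[2], 0)
  expect_equal(a$richness, c(5L, 1L))

  counts <- matrix(c(1, 1, 2, 5, 0, 3, 3, 4, 5, 0), 5, 2,
                   dimnames = list(paste0("m", 1:5), c("s1", "s2")))
  ch <- alpha_diversity(counts, metrics = "chao1")
  # s1: S=4, F1=2, F2=1 -> 4 + 2*1/(2*2) = 4.5; s2: no singletons -> S
  expect_equal(ch$chao1, c(4.5, 4))
  expect_error(alpha_diversity(counts / 3, metrics = "chao1"),
               "integer counts")
})
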