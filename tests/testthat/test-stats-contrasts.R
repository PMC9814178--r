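test_that("two-group contrast gives the exact Mann-Whitney p on small data", {
  res <- rank_contrast(c(1, 2, 3, 10, 20, 30),
                       rep(c("a", "b"), each = 3))
  expect_equal(res$p, 0.1)           # most extreme of the 20 arrangements, x2
  expect_equal(res$cliffs_delta, -1)
  expect_equal(res$test, "mann-whitney")

  same <- rank_contrast(c(1, 2, 3, 4, 1, 2, 3, 4),
                        rep(c("a", "b"), each = 4))
  expect_gt(same$p, 0.95)
  expect_equal(same$cliffs_delta, 0)

  expect_error(rank_contrast(1:3, c("a", "a", "b")), "fewer than 2")
  kw <- rank_contrast(rnorm(30), rep(c("a", "b", "c"), each = 10))
  expect_equal(kw$test, "kruskal-wallis")
  expect_true(is.na(kw$cliffs_delta))
})

test_that("Cliff's Delta matches the pairwise brute force and is antisymmetric", {
  expect_equal(cliffs_delta(c(1, 2, 3), c(4, 5, 6)), -1)
  expect_equal(cliffs_delta(c(1, 2), c(1, 3)), -0.25)
  expect_equal(cliffs_delta(c(2, 2, 2), c(2, 2, 2)), 0)
  expect_error(cliffs_delta(numeric(0), 1), "empty")
  withr::with_seed(5, {
    for (rep in 1:20) {
      x <- sample(1:8, sample(2:10, 1), replace = TRUE)  # heavy ties
      y <- sample(1:8, sample(2:10, 1), replace = TRUE)
      expect_equal(cliffs_delta(x, y), oracle_cliffs(x, y))
      expect_equal(cliffs_delta(x, y), -cliffs_delta(y, x))
    }
  })
})

test_that("BH adjustment reproduces the step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  withr::with_seed(6, {
    for (rep in 1:20) {
      p <- runif(sample(1:40, 1))
      expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
      expect_equal(bh_adjust(p), p.adjust(p, "BH"), tolerance = 1e-12)
      expect_true(all(bh_adjust(p) >= p - 1e-12))
    }
  })
  # NA passthrough keeps the family at the non-missing size
  q <- bh_adjust(c(0.01, NA, 0.04))
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], oracle_bh(c(0.01, 0.04)))
})

test_that("Spearman panel computes rank rho with t-approximate p", {
  f <- rbind(up = 1:5, down = 5:1, perm = c(2, 1, 4, 3, 5))
  v <- data.frame(x = c(10, 20, 30, 40, 50))
  pan <- spearman_panel(f, v)
  expect_equal(pan$rho[pan$feature == "up"], 1)
  expect_equal(pan$rho[pan$feature == "down"], -1)
  # 1 - 6*4/(5*24) = 0.8 for d^2 = (1,1,1,1,0)
  expect_equal(pan$rho[pan$feature == "perm"], 0.8)
  # t-approximation computed independently: t = rho*sqrt((n-2)/(1-rho^2))
  p_ref <- 2 * pt(0.8 * sqrt(3 / (1 - 0.64)), df = 3, lower.tail = FALSE)
  expect_equal(pan$p[pan$feature == "perm"], p_ref, tolerance = 1e-12)
  expect_warning(
    spearman_panel(rbind(flat = rep(1, 5)), v), "constant")
  warns <- testthat::capture_warnings(
    spearman_panel(f[, 1:3], data.frame(x = c(1, 2, 3))))
  expect_true(all(grepl("complete pairs", warns)))
})

test_that("chi-squared reproduces the printed demographic contrasts", {
  # smoking never/previous/current, cases vs controls
  tab1 <- rbind(cases = c(50, 56, 40), hc = c(90, 41, 15))
  r1 <- chi_squared_table(tab1, continuity = FALSE)
  expect_equal(r1$df, 2)
  expect_equal(signif(r1$p, 2), 3.5e-06)
  # CA/CNA sex split with Yates correction
  r2 <- chi_squared_table(rbind(ca = c(8, 4), cna = c(11, 8)))
  expect_equal(round(r2$p, 2), 0.91)
  # identical rows: statistic exactly 0 even with the correction
  r0 <- chi_squared_table(rbind(c(98, 50), c(98, 50)))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
  expect_error(chi_squared_table(rbind(c(0, 0), c(1, 2))), "margin")
  expect_error(chi_squared_table(matrix(1:3, 1)), "2x2")
  # agreement with the standard implementation on random tables
  withr::with_seed(7, {
    for (rep in 1:10) {
      tab <- matrix(rpois(6, 20) + 1, 2)
      ours <- chi_squared_table(tab, continuity = FALSE)
      ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
      expect_equal(ours$statistic, unname(ref$statistic))
      expect_equal(ours$p, ref$p.value)
      oursy <- chi_squared_table(tab[, 1:2], continuity = TRUE)
      refy <- suppressWarnings(chisq.test(tab[, 1:2], correct = TRUE))
      expect_equal(oursy$statistic, unname(refy$statistic))
    }
  })
})

test_that("adjusted richness residualizes on covariates", {
  withr::with_seed(8, {
    n <- 40
    bmi <- rnorm(n, 24, 3)
    sex <- sample(c("F", "M"), n, replace = TRUE)
    rich <- setNames(rnorm(n, 300, 20), paste0("s", 1:n))

    # covariate orthogonal to richness: adjustment changes little
    orth <- residuals(lm(rnorm(n) ~ rich))   # exactly orthogonal
    adj <- adjust_richness(rich, data.frame(orth = orth))
    expect_equal(unname(adj), unname(rich), tolerance = 1e-8)

    # richness exactly linear in BMI: adjusted collapses to the mean
    rich2 <- setNames(100 + 5 * bmi, paste0("s", 1:n))
    adj2 <- adjust_richness(rich2, data.frame(bmi = bmi))
    expect_equal(unname(adj2), rep(mean(rich2), n), tolerance = 1e-8)

    # collinear design errors naming the degenerate column
    expect_error(adjust_richness(rich, data.frame(bmi = bmi, bmi2 = 2 * bmi)),
                 "bmi2")
    # missing covariates drop samples
    bmi_na <- bmi; bmi_na[1] <- NA
    expect_message(adj3 <- adjust_richness(rich, data.frame(bmi = bmi_na)),
                   "dropping 1")
    expect_length(adj3, n - 1)
  })
})

test_that("adjustment strengthens a confounded richness-relapse signal", {
  # richness = f(covariates) + gamma*relapses + noise, with BMI also driving
  # relapses; scaled down to 30 replicates
  withr::with_seed(9, {
    hits_adj <- hits_raw <- numeric(30)
    for (r in 1:30) {
      n <- 31
      bmi <- rnorm(n, 24, 3)
      relapses <- rpois(n, pmax(0.1, 1.2 - 0.15 * (bmi - 24)))
      rich <- setNames(300 - 12 * bmi + 8 * relapses + rnorm(n, 0, 10),
                       paste0("s", 1:n))
      adj <- adjust_richness(rich, data.frame(bmi = bmi))
      hits_adj[r] <- cor(adj, relapses, method = "spearman")
      hits_raw[r] <- cor(rich, relapses, method = "spearman")
    }
    expect_gt(mean(hits_adj), 0)                 # recovers gamma's sign
    expect_gt(mean(hits_adj), mean(hits_raw))    # stronger than unadjusted
  })
})
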