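test_that("Spearman correlation matches the exhaustive rank oracle", {
  expect_equal(spearman_cor(1:5, c(2, 4, 6, 8, 10))$r, 1)
  expect_equal(spearman_cor(1:5, 5:1)$r, -1)
  expect_equal(spearman_cor(1:5, c(2, 4, 6, 8, 10))$p, 0)
  with_seed_test(31, {
    for (i in 1:20) {
      x <- sample(1:4, 6, replace = TRUE) + rnorm(6, 0, 0.01)
      y <- rnorm(6)
      got <- spearman_cor(x, y)
      want <- brute_spearman(x, y)
      expect_equal(got$r, want$r, tolerance = 1e-12)
      expect_equal(got$p, want$p, tolerance = 1e-6)
      ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                             exact = FALSE))
      expect_equal(got$r, unname(ct$estimate), tolerance = 1e-12)
    }
  })
  expect_error(spearman_cor(rep(1, 6), 1:6), "constant")
  expect_error(spearman_cor(1:3, 1:3), "at least 4")
})

test_that("Spearman is invariant under strictly monotone transforms", {
  with_seed_test(12, {
    x <- rnorm(15); y <- rnorm(15)
    base <- spearman_cor(x, y)$r
    expect_equal(spearman_cor(exp(x), y)$r, base)
    expect_equal(spearman_cor(x, y^3 + 5 * y)$r, base)
    expect_equal(spearman_cor(rank(x), y)$r, base)
  })
})

test_that("step-up FDR adjustment matches direct enumeration", {
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)),
               brute_stepup(c(0.01, 0.02, 0.03, 0.04)))
  with_seed_test(44, {
    for (i in 1:20) {
      p <- round(runif(25), sample(c(1, 2, 3), 1))   # induce ties
      expect_equal(fdr_adjust(p), brute_stepup(p), tolerance = 1e-12)
    }
  })
  expect_error(fdr_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("adjusted p-values preserve order and never decrease", {
  with_seed_test(45, {
    p <- runif(40)
    q <- fdr_adjust(p)
    expect_true(all(q >= p))
    expect_true(all(q <= 1))
    o <- order(p)
    expect_true(all(diff(q[o]) >= 0))
  })
})

test_that("partial correlation matches the residualisation oracle", {
  with_seed_test(71, {
    x <- rnorm(20); z <- rnorm(20)
    y <- 0.5 * x + 0.3 * z + rnorm(20)
    got <- partial_cor(x, y, z)
    rx <- stats::residuals(stats::lm(x ~ z))
    ry <- stats::residuals(stats::lm(y ~ z))
    expect_equal(got$r, stats::cor(rx, ry), tolerance = 1e-10)
    # z orthogonal to both recovers the plain correlation
    z0 <- stats::residuals(stats::lm(rnorm(20) ~ x + y))
    expect_equal(partial_cor(x, y, z0)$r, stats::cor(x, y), tolerance = 1e-10)
    expect_error(partial_cor(x, x, x), "degenerate|collinear")
    expect_error(partial_cor(x, z, z), "degenerate|collinear")
  })
})

test_that("split-plot ANOVA reproduces the textbook decomposition", {
  d <- rm_design(seed = 5)
  got <- mixed_rm_anova(d, "value")
  want <- brute_splitplot(d)
  expect_equal(got$F[got$effect == "group"], want$F_group, tolerance = 1e-10)
  expect_equal(got$F[got$effect == "region"], want$F_region, tolerance = 1e-10)
  expect_equal(got$F[got$effect == "group:region"], want$F_int,
               tolerance = 1e-10)
  expect_equal(got$df1, c(1, 2, 2))
  expect_equal(got$df2, c(13, 26, 26))
})

test_that("degenerate ANOVA inputs are rejected", {
  d <- rm_design(seed = 6)
  d0 <- d; d0$value <- 1
  expect_error(mixed_rm_anova(d0, "value"), "zero error variance")
  d1 <- d[-1, ]
  expect_error(mixed_rm_anova(d1, "value"), "incomplete design")
  d2 <- rm_design(n_case = 1, n_ctrl = 5, seed = 7)
  expect_error(mixed_rm_anova(d2, "value"), "2 subjects per group")
})

test_that("Greenhouse-Geisser correction shrinks within-subject dfs", {
  d <- rm_design(seed = 8)
  plain <- mixed_rm_anova(d, "value")
  gg <- mixed_rm_anova(d, "value", correction = "greenhouse-geisser")
  expect_equal(gg$F, plain$F)
  i <- gg$effect == "region"
  expect_true(gg$df2[i] <= plain$df2[i])
  expect_true(gg$df2[i] >= plain$df2[i] / 2)   # epsilon in [1/(r-1), 1]
})

test_that("paired t matches the textbook formula and guards zero variance", {
  with_seed_test(91, {
    x <- rnorm(10); y <- rnorm(10)
    got <- paired_t(x, y)
    d <- x - y
    tt <- mean(d) / (sd(d) / sqrt(10))
    expect_equal(got$t, tt, tolerance = 1e-12)
    expect_equal(got$df, 9)
    expect_equal(got$p, 2 * stats::pt(-abs(tt), 9), tolerance = 1e-12)
    expect_error(paired_t(x, x), "zero variance")
    expect_error(paired_t(x, x + 2), "zero variance")
  })
})

test_that("the correlation battery runs 5 x 6 x 3 tests with joint adjustment", {
  co <- add_planted_diffusion(make_cohort(cohort_spec(seed = 13L)), seed = 14L)
  res <- correlation_battery(co$table)
  expect_identical(nrow(res), 90L)
  expect_identical(unique(res$region), c("BA9", "BA41", "V1"))
  expect_identical(res$metric[1:6], rep("AngleR", 6))
  expect_equal(res$p_fdr, brute_stepup(res$p), tolerance = 1e-12)
  expect_true(all(res$n == 15))
  # deterministic ordering: rerun is identical
  expect_identical(res, correlation_battery(co$table))
  # missing measure errors by name
  tab <- co$table[co$table$measure != "bundle_width", ]
  expect_error(correlation_battery(tab), "bundle_width")
})

test_that("a planted perfect association attains the smallest adjusted p", {
  with_seed_test(55, {
    tab <- null_cohort_table(n = 9)
    k <- rnorm(9)
    i_m <- tab$measure == "AngleR" & tab$region == "BA9"
    i_h <- tab$measure == "minicolumn_width" & tab$region == "BA9"
    tab$value[i_m] <- k[match(tab$subject[i_m], sprintf("S%02d", 1:9))]
    tab$value[i_h] <- 2 * tab$value[i_m] + 1
    res <- correlation_battery(tab)
    best <- res[which.min(res$p_fdr), ]
    expect_identical(best$metric, "AngleR")
    expect_identical(best$histology, "minicolumn_width")
    expect_identical(best$region, "BA9")
    expect_equal(best$r, 1)
  })
})

test_that("the joint adjustment controls false discoveries on null cohorts", {
  frac <- with_seed_test(66, vapply(1:200, function(i) {
    res <- correlation_battery(null_cohort_table(n = 9))
    mean(res$p_fdr < 0.05)
  }, numeric(1)))
  expect_lte(mean(frac), 0.05 + 0.03)
})
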