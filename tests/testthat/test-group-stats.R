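test_that("significance_stars maps strict thresholds", {
  expect_identical(significance_stars(c(0.049, 0.0099, 0.0005, 0.2)),
                   c("*", "**", "***", "ns"))
  # boundaries are strict: p = 0.05 / 0.01 / 0.001 earn no extra star
  expect_identical(significance_stars(c(0.05, 0.01, 0.001)),
                   c("ns", "*", "**"))
  expect_error(significance_stars(-0.1), class = "npcquant_domain_error")
  expect_error(significance_stars(1.2), class = "npcquant_domain_error")
  # monotone non-increasing in p
  p <- sort(runif(50))
  stars <- significance_stars(p)
  lvl <- c(ns = 0, `*` = 1, `**` = 2, `***` = 3)
  expect_true(all(diff(lvl[stars]) <= 0))
})

test_that("dunnett_test agrees with the mvtnorm joint-t oracle", {
  skip_if_not_installed("mvtnorm")
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(4:10, 4, replace = TRUE)
    g <- list(ctrl = rnorm(n[1]), a = rnorm(n[2], 0.5),
              b = rnorm(n[3], 1), c = rnorm(n[4], -0.3))
    d <- dunnett_test(g, "ctrl")
    nn <- vapply(g, length, integer(1))
    lam <- sqrt((1 / nn["ctrl"]) / (1 / nn[c("a", "b", "c")] + 1 / nn["ctrl"]))
    R <- outer(lam, lam); diag(R) <- 1
    p_oracle <- vapply(abs(d$t), function(q)
      1 - mvtnorm::pmvt(lower = rep(-q, 3), upper = rep(q, 3),
                        df = d$df[1], corr = R,
                        algorithm = mvtnorm::GenzBretz(abseps = 1e-5))[1],
      numeric(1))
    expect_equal(d$p_adjusted, p_oracle, tolerance = 1e-3)
  }
})

test_that("dunnett_test is deterministic and exceeds unadjusted p", {
  set.seed(1)
  g <- list(ctrl = rnorm(8), t1 = rnorm(8, 0.8), t2 = rnorm(8, -0.2))
  d1 <- dunnett_test(g, "ctrl")
  d2 <- dunnett_test(g, "ctrl")
  expect_identical(d1, d2)  # quadrature, not Monte Carlo
  p_raw <- 2 * pt(-abs(d1$t), d1$df)
  expect_true(all(d1$p_adjusted >= p_raw - 1e-10))
  expect_true(all(d1$p_adjusted <= pmin(3 * p_raw, 1) + 1e-10))  # <= Bonferroni
})

test_that("dunn_test computes tie-corrected rank comparisons with Bonferroni", {
  # tie-free case: pooled ranks are 1..12 and mean ranks are 2.5/10.5/6.5
  g <- list(ctrl = c(1, 2, 3, 4), a = c(10, 11, 12, 13), b = c(5, 6, 7, 8))
  d <- dunn_test(g, "ctrl")
  expect_identical(d$group, c("a", "b"))
  expect_equal(d$p_adjusted, pmin(d$p_unadjusted * 2, 1))
  z_hand <- (10.5 - 2.5) / sqrt((12 * 13 / 12) * (1 / 4 + 1 / 4))
  expect_equal(d$z[d$group == "a"], z_hand)
  # hand-checked tie correction: pooled c(1,2,2,3 | 2,4,4,5) has a
  # triple at 2 and a pair at 4, mean ranks 3 vs 6
  g2 <- list(ctrl = c(1, 2, 2, 3), a = c(2, 4, 4, 5))
  tie <- (3^3 - 3 + 2^3 - 2) / (12 * (8 - 1))
  z2 <- (6 - 3) / sqrt((8 * 9 / 12 - tie) * (1 / 4 + 1 / 4))
  expect_equal(dunn_test(g2, "ctrl")$z, z2)
})

test_that("two-group data route to the unpaired Student t-test", {
  set.seed(6)
  g <- list(DMSO = rnorm(6, 1), treated = rnorm(6, 2))
  res <- choose_and_run_test(g, "DMSO")
  expect_identical(res$test_used, "t_test")
  tt <- t.test(g$treated, g$DMSO, var.equal = TRUE)
  expect_equal(res$comparisons$p_adjusted, tt$p.value)
  # identical control and treated values give p ~ 1 and no stars
  same <- list(DMSO = c(1, 2, 3, 4), treated = c(1, 2, 3, 4))
  res2 <- choose_and_run_test(same, "DMSO")
  expect_gt(res2$comparisons$p_adjusted, 0.99)
  expect_identical(res2$comparisons$stars, "ns")
})

test_that("the normality gate picks the designed path on fixed fixtures", {
  # all groups exactly normal-scored -> ANOVA + Dunnett
  g_norm <- list(ctrl = normal_scores(8, 1, 0.2),
                 a = normal_scores(8, 1.3, 0.2),
                 b = normal_scores(8, 0.9, 0.2))
  res <- choose_and_run_test(g_norm, "ctrl")
  expect_identical(res$test_used, "anova_dunnett")
  expect_true(all(res$normality_pass))
  # one heavy-tailed group verified to fail Shapiro-Wilk -> Kruskal + Dunn
  expect_lt(shapiro.test(heavy_tail_fixture)$p.value, 0.05)
  g_heavy <- g_norm
  g_heavy$b <- heavy_tail_fixture
  res2 <- choose_and_run_test(g_heavy, "ctrl")
  expect_identical(res2$test_used, "kruskal_dunn")
  expect_false(res2$normality_pass[["b"]])
  # path selection is a pure function of the data
  expect_identical(choose_and_run_test(g_heavy, "ctrl")$test_used,
                   "kruskal_dunn")
})

test_that("choose_and_run_test validates group structure", {
  expect_error(choose_and_run_test(list(a = 1:5), "a"),
               class = "npcquant_validation_error")
  expect_error(choose_and_run_test(list(a = 1:5, b = 1:2), "a"),
               regexp = "b", class = "npcquant_validation_error")
  expect_error(choose_and_run_test(list(a = 1:5, b = 1:5), "zz"),
               class = "npcquant_validation_error")
  const <- list(a = rep(2, 4), b = rep(2, 4), c = rep(2, 4))
  expect_error(choose_and_run_test(const, "a"),
               class = "npcquant_degenerate_error")
  # data.frame input is accepted
  df <- data.frame(group = rep(c("ctrl", "t"), each = 4),
                   value = c(normal_scores(4), normal_scores(4, 2)))
  expect_identical(choose_and_run_test(df, "ctrl")$test_used, "t_test")
})

test_that("a zero-variance treatment group routes to the rank-based path", {
  g <- list(ctrl = normal_scores(6), a = rep(3, 6),
            b = normal_scores(6, 0.5))
  res <- choose_and_run_test(g, "ctrl")
  expect_identical(res$test_used, "kruskal_dunn")
  expect_false(res$normality_pass[["a"]])
})
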