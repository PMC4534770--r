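test_that("Mann-Whitney matches exact enumeration and symmetry", {
  # identical multisets: U at its null mean, two-sided p = 1
  r <- mann_whitney(c(1, 2), c(1, 2))
  expect_equal(unname(r$statistic), 2)
  expect_equal(r$p_value, 1)
  # all 6 rank assignments of {1,2} vs {3,4}: only one as extreme each side
  r2 <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(r2$p_value, 1 / 3)
  expect_error(mann_whitney(numeric(0), 1), "non-empty")
})

test_that("Mann-Whitney has power against a 2 SD shift at n = 62", {
  set.seed(100)
  reps <- replicate(20, {
    mann_whitney(rnorm(62), rnorm(62, 2))$p_value
  })
  expect_true(all(reps < 1e-6))
})

test_that("Kruskal-Wallis H matches the hand rank computation", {
  # groups {1,2},{3,4},{5,6}: rank means 1.5/3.5/5.5, no ties
  # H = 12/(6*7) * sum n_i (rbar_i - 3.5)^2 = 12/42 * 16
  r <- kruskal_dunn(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(unname(r$statistic), 12 / 42 * 16)
  expect_equal(nrow(r$post_hoc), 2)
  expect_true(all(r$post_hoc$adjusted >= r$post_hoc$p_value))
})

test_that("identical groups give H = 0 and post hoc p = 1", {
  r <- kruskal_dunn(list(c(2, 2), c(2, 2), c(2, 2)))
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p_value, 1)
  expect_true(all(r$post_hoc$adjusted == 1))
  expect_error(kruskal_dunn(list(1:3, 4:6)), "mann_whitney")
})

test_that("Dunn post hoc flags only the shifted group", {
  set.seed(20)
  res <- t(replicate(100, {
    g <- list(rnorm(5), rnorm(5), rnorm(5, 3))
    ph <- kruskal_dunn(g)$post_hoc
    c(shifted = ph$p_value[2] < 0.05, null = ph$adjusted[1] < 0.05)
  }))
  expect_gte(mean(res[, "shifted"] & !res[, "null"]), 0.9)
  expect_lte(mean(res[, "null"]), 0.1)
})

test_that("Jonckheere-Terpstra matches the exhaustive oracle on small instances", {
  g <- list(c(1, 2), c(3, 4), c(5, 6))
  r <- jonckheere_terpstra(g, n_perm = 500, seed = 1)
  expect_equal(unname(r$statistic), oracle_jt(g))
  expect_equal(unname(r$statistic), 12) # maximal: every pair concordant
  expect_true(r$exact)
  expect_equal(r$p_value, oracle_jt_exact_p(g))
  expect_equal(r$p_value, 2 / 90)
})

test_that("JT permutation p converges to the exhaustive p", {
  set.seed(7)
  g <- list(rnorm(3), rnorm(3, 0.5), rnorm(3, 1))
  exact <- jonckheere_terpstra(g, n_perm = 500, seed = 1)
  expect_true(exact$exact)
  expect_equal(exact$p_value, oracle_jt_exact_p(g))
  perm <- jonckheere_terpstra(g, n_perm = 4000, seed = 2, exact_limit = 1)
  expect_false(perm$exact)
  expect_lt(abs(perm$p_value - exact$p_value), 0.05)
})

test_that("JT statistic is maximal minus reversed on untied data", {
  set.seed(3)
  g <- lapply(1:3, function(i) rnorm(4))
  jt_f <- jonckheere_terpstra(g, n_perm = 200, seed = 1,
                              exact_limit = 1)$statistic
  jt_r <- jonckheere_terpstra(rev(g), n_perm = 200, seed = 1,
                              exact_limit = 1)$statistic
  n_pairs <- 3 * 16
  expect_equal(jt_f + jt_r, n_pairs)
  expect_error(jonckheere_terpstra(g, n_perm = 50), "at least 100")
})

test_that("all-identical groups put JT at its null mean with p near 1", {
  g <- list(c(1, 1), c(1, 1), c(1, 1))
  r <- jonckheere_terpstra(g, n_perm = 500, seed = 1)
  expect_equal(unname(r$statistic), 0.5 * 12)
  expect_equal(r$p_value, 1)
})

test_that("linear trend contrast: closed form, zero-sum coefficients, degenerate cases", {
  set.seed(5)
  g <- lapply(1:4, function(i) rnorm(6, i, 0.01))
  r <- linear_trend_contrast(g)
  expect_equal(sum(r$coefficients), 0)
  expect_equal(r$coefficients, c(-3, -1, 1, 3))
  expect_lt(r$p_value, 1e-6)
  # hand-computed t for a tiny fixture
  g2 <- list(c(1, 2), c(2, 3), c(3, 4))
  means <- c(1.5, 2.5, 3.5)
  s2 <- 0.5 * 6 / 3 / 1 # pooled: each group SS = 0.5, df = 3
  est <- sum(c(-2, 0, 2) * means)
  se <- sqrt((0.5 * 3 / 3) * sum(c(-2, 0, 2)^2 / 2))
  r2 <- linear_trend_contrast(g2)
  expect_equal(unname(r2$statistic), est / se)
  # equal group means: estimate 0, p = 1
  r3 <- linear_trend_contrast(list(c(1, 3), c(1, 3), c(1, 3)))
  expect_equal(r3$estimate, 0)
  expect_equal(r3$p_value, 1)
  expect_error(linear_trend_contrast(list(1, 2, 3)), "singleton")
})

test_that("Spearman rho matches the no-ties rank formula", {
  expect_equal(unname(spearman(1:10, (1:10)^3)$statistic), 1)
  expect_equal(unname(spearman(1:10, -(1:10))$statistic), -1)
  set.seed(9)
  x <- rnorm(10)
  y <- rnorm(10)
  d <- rank(x) - rank(y)
  rho_hand <- 1 - 6 * sum(d^2) / (10 * (100 - 1))
  expect_equal(unname(spearman(x, y)$statistic), rho_hand)
  expect_error(spearman(1:3, 1:3), "at least 4")
})

test_that("KS statistic equals the brute-force ECDF supremum", {
  expect_equal(unname(ks_two_sample(1:5, 1:5)$statistic), 0)
  expect_equal(unname(ks_two_sample(c(1, 2, 3), c(4, 5, 6))$statistic), 1)
  set.seed(11)
  for (i in 1:5) {
    x <- rnorm(20)
    y <- rnorm(20, 0.5)
    expect_equal(unname(ks_two_sample(x, y)$statistic), oracle_ks_D(x, y))
  }
})

test_that("KS permutation p agrees with the asymptotic p on clear separations", {
  set.seed(12)
  x <- rnorm(25)
  y <- rnorm(25, 2)
  pa <- ks_two_sample(x, y)$p_value
  pp <- ks_two_sample(x, y, mode = "permutation", n_perm = 999,
                      seed = 4)$p_value
  expect_lt(pa, 0.001)
  expect_lt(pp, 0.01)
})

test_that("ANOVA with Bonferroni post hoc behaves at the reference and degenerate cases", {
  set.seed(13)
  g <- list(rnorm(8), rnorm(8), rnorm(8, 3))
  r <- anova_bonferroni(g)
  expect_lt(r$p_value, 0.01)
  expect_lt(r$post_hoc$adjusted[2], 0.05)
  # all values equal across groups: F defined as 0
  r2 <- anova_bonferroni(list(c(1, 1), c(1, 1), c(1, 1)))
  expect_equal(unname(r2$statistic), 0)
  expect_equal(r2$p_value, 1)
  # matches stats::aov on a random fixture
  set.seed(14)
  g3 <- list(rnorm(6), rnorm(6, 1), rnorm(6, 2))
  r3 <- anova_bonferroni(g3)
  df <- data.frame(y = unlist(g3), g = factor(rep(1:3, each = 6)))
  f_ref <- summary(aov(y ~ g, df))[[1]]$`F value`[1]
  expect_equal(unname(r3$statistic), f_ref)
})

test_that("tests are invariant to subject order", {
  set.seed(15)
  x <- rnorm(12)
  y <- rnorm(12, 1)
  perm <- sample(12)
  expect_equal(mann_whitney(x, y)$p_value,
               mann_whitney(x[perm], y[perm])$p_value)
  expect_equal(unname(ks_two_sample(x, y)$statistic),
               unname(ks_two_sample(x[perm], y[perm])$statistic))
  expect_equal(spearman(x, y)$statistic,
               spearman(x[perm], y[perm])$statistic)
})

test_that("severity battery returns one tidy row per composite parameter", {
  tab <- generate_cohort(generator_config(seed = 21))
  cm <- preprocess_cohort(tab)
  out <- severity_battery(cm)
  expect_equal(nrow(out), ncol(cm$values))
  expect_true(all(out$kw_p >= 0 & out$kw_p <= 1))
  expect_true(all(out$kw_p_bonferroni >= out$kw_p))
  # planted MAIT severity gradient is among the strongest trends
  expect_lt(out$trend_p[out$parameter == "MAIT_cells"], 1e-4)
})
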