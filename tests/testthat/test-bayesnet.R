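test_that("discretization respects binary columns and the Sturges clamp", {
  x <- cbind(flag = rep(c(0, 1), 31), cont = rnorm(62))
  dt <- discretize(x)
  expect_equal(dt$n_levels[["flag"]], 2L)
  # ceil(1 + log2(62)) = 7, inside [5, 9]
  expect_equal(dt$n_levels[["cont"]], 7L)
  expect_true(all(dt$codes[, "flag"] == x[, "flag"] + 1))
})

test_that("quantile bins are balanced on distinct values", {
  set.seed(1)
  dt <- discretize(cbind(v = rnorm(62)))
  occ <- table(dt$codes[, "v"])
  expect_lte(max(occ) - min(occ), 1)
  # fewer distinct values than bins: count reduced with a warning
  expect_warning(dt2 <- discretize(cbind(v = rep(1:3, 10))), "reducing")
  expect_lte(dt2$n_levels[["v"]], 3L)
  # bin-count clamp at larger n
  dt3 <- discretize(cbind(v = rnorm(2000)))
  expect_equal(dt3$n_levels[["v"]], 9L)
})

test_that("mutual information matches the double-sum oracle and closed forms", {
  # identical columns with k equiprobable bins: MI = log2 k
  a <- rep(1:4, 25)
  expect_equal(mutual_information(a, a), 2)
  set.seed(2)
  b <- sample(1:3, 100, replace = TRUE)
  cc <- sample(1:4, 100, replace = TRUE)
  expect_equal(mutual_information(b, cc), oracle_mi(b, cc))
  # data-processing bound: MI <= min(H(X), H(Y))
  h <- function(v) {
    p <- table(v) / length(v)
    -sum(p * log2(p))
  }
  expect_lte(mutual_information(b, cc), min(h(b), h(cc)) + 1e-12)
})

test_that("independent columns carry vanishing mutual information", {
  # plug-in MI is biased up by ~ (r-1)(c-1)/(2n ln 2); with two binary
  # columns at n = 1000 that bias is negligible and MI must sit near 0
  small <- 0
  for (s in 1:20) {
    set.seed(s)
    dt <- discretize(cbind(a = rbinom(1000, 1, 0.5),
                           b = rbinom(1000, 1, 0.5)))
    small <- small + (mutual_information(dt$codes[, 1],
                                         dt$codes[, 2]) < 0.02)
  }
  expect_gte(small, 19)
  # at 7x7 bins the bias term dominates but stays near its theory value
  set.seed(99)
  dt7 <- discretize(cbind(a = rnorm(1000), b = rnorm(1000)))
  mi7 <- mutual_information(dt7$codes[, 1], dt7$codes[, 2])
  expect_lt(mi7, 36 / (2 * 1000 * log(2)) + 0.02)
})

test_that("hill climbing leaves independent columns unconnected", {
  empty <- 0
  for (s in 1:20) {
    set.seed(s)
    x <- matrix(rnorm(4000), ncol = 4,
                dimnames = list(NULL, paste0("V", 1:4)))
    net <- learn_structure(discretize(x), restarts = 1, seed = s)
    empty <- empty + (nrow(net$edges) == 0)
  }
  expect_gte(empty, 18)
})

test_that("hill climbing recovers a strong chain skeleton", {
  ok <- 0
  for (s in 1:20) {
    set.seed(s)
    a <- rbinom(1000, 1, 0.5)
    b <- flip_copy(a, 0.85)
    cc <- flip_copy(b, 0.85)
    net <- learn_structure(discretize(cbind(A = a, B = b, C = cc)),
                           restarts = 3, seed = s)
    sk <- apply(unique(t(apply(as.matrix(net$edges[, 1:2]), 1, sort))),
                1, paste, collapse = "-")
    ok <- ok + setequal(sk, c("A-B", "B-C"))
  }
  expect_gte(ok, 18)
})

test_that("learned structures are acyclic with scores above the empty network", {
  cm <- preprocess_cohort(generate_cohort(generator_config(seed = 12)))
  dt <- discretize(cm)
  net <- learn_structure(dt, restarts = 2, seed = 1)
  expect_gte(net$score, net$empty_score)
  # topological sort must consume every node
  parents <- net$parents
  remaining <- seq_along(parents)
  repeat {
    roots <- remaining[vapply(remaining, function(v) {
      length(intersect(parents[[v]], remaining)) == 0
    }, logical(1))]
    if (length(roots) == 0) break
    remaining <- setdiff(remaining, roots)
  }
  expect_length(remaining, 0)
  # determinism under seed
  net2 <- learn_structure(dt, restarts = 2, seed = 1)
  expect_identical(net$edges, net2$edges)
  # single column: nothing to connect
  net1 <- learn_structure(discretize(cbind(x = rnorm(50))),
                          restarts = 1, seed = 1)
  expect_equal(nrow(net1$edges), 0)
})

test_that("edge strengths are the endpoint mutual informations", {
  set.seed(3)
  a <- rbinom(500, 1, 0.5)
  b <- flip_copy(a, 0.9)
  dt <- discretize(cbind(A = a, B = b))
  net <- learn_structure(dt, restarts = 1, seed = 1)
  net <- edge_strength(net, dt)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$strength[1],
               oracle_mi(dt$codes[, "A"], dt$codes[, "B"]))
  expect_true(all(net$edges$strength > 0))
})

test_that("edge sign classification separates monotone from nonlinear", {
  set.seed(4)
  x <- rnorm(500)
  expect_equal(as.character(classify_edge_sign(x, 2 * x + rnorm(500, 0, 0.1))),
               "positive")
  expect_equal(as.character(classify_edge_sign(x, -x^3)), "negative")
  nl <- 0
  for (s in 1:20) {
    set.seed(s)
    x <- rnorm(500)
    y <- (x - mean(x))^2
    cls <- classify_edge_sign(x, y, seed = s)
    nl <- nl + (as.character(cls) == "nonlinear" &&
                  isTRUE(attr(cls, "mi_significant")))
  }
  expect_gte(nl, 19)
  expect_equal(as.character(classify_edge_sign(rep(1, 10), rnorm(10))),
               "degenerate")
})

test_that("the full network stage annotates every arc", {
  cm <- preprocess_cohort(generate_cohort(generator_config(seed = 13)))
  lenses <- compute_lenses(cm)
  net <- bayes_network_run(cm, restarts = 2, seed = 5, lenses = lenses)
  expect_gt(nrow(net$edges), 0)
  expect_true(all(net$edges$sign_class %in%
                    c("positive", "negative", "nonlinear", "degenerate")))
  expect_true(all(net$edges$strength > 0))
  expect_true(all(net$edges$loading_distance >= 0))
  expect_true(length(net$isolated) >= 0)
})
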