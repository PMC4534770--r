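std <- function(x) {
  z <- scale(x)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  z
}

test_that("lens scores match a brute-force eigendecomposition", {
  x <- std(matrix(c(1, 0, -1, 0, 1, -1), ncol = 2,
                  dimnames = list(NULL, c("a", "b"))))
  l <- compute_lenses(list(values = x))
  ev <- eigen(cov(x) * (2 / 3)) # eigen of X'X / n relates to svd by scale
  # compare squared singular values against eigenvalues of X'X
  expect_equal(l$singular_values^2, eigen(t(x) %*% x)$values,
               tolerance = 1e-9)
  # scores reproduce the projections onto the eigenvectors up to sign
  for (i in 1:2) {
    proj <- x %*% eigen(t(x) %*% x)$vectors[, i]
    expect_equal(abs(unname(l$scores[, i])), abs(as.vector(proj)),
                 tolerance = 1e-9)
  }
  # sign convention: the largest-magnitude loading is positive
  expect_true(all(apply(l$loadings, 2, function(v) v[which.max(abs(v))]) > 0))
})

test_that("lens coordinate vectors are orthogonal and centered", {
  cm <- preprocess_cohort(generate_cohort(generator_config(seed = 2)))
  l <- compute_lenses(cm)
  expect_lt(abs(sum(l$scores[, 1] * l$scores[, 2])), 1e-9)
  expect_lt(abs(mean(l$scores[, 1])), 1e-9)
})

test_that("rank-1 input degrades to a zero secondary lens", {
  x <- matrix(rep(c(-1, 0, 1), 2), ncol = 2)
  expect_warning(l <- compute_lenses(list(values = x)), "rank 1")
  expect_true(all(abs(l$scores[, 2]) < 1e-9))
  expect_error(compute_lenses(list(values = matrix(0, 3, 2))), "rank 0")
})

test_that("doubling the cohort leaves lens directions unchanged", {
  cm <- preprocess_cohort(generate_cohort(generator_config(seed = 3)))
  l1 <- compute_lenses(cm)
  l2 <- compute_lenses(list(values = rbind(cm$values, cm$values)))
  expect_equal(abs(l1$loadings), abs(l2$loadings), tolerance = 1e-6)
})

test_that("uniform lens cover arithmetic matches the dilation formula", {
  # resolution 2, gain 2, equalize off, lens on [0,1]:
  # base [0,.5],[.5,1] dilated to [-0.25,0.75],[0.25,1.25]
  scores <- cbind(lens1 = seq(0, 1, length.out = 11),
                  lens2 = rep(c(0, 1), length.out = 11))
  l <- structure(list(scores = scores), class = "lens_matrix")
  cov <- build_cover(l, cover_spec(resolution = 2, gain = 2,
                                   equalize = FALSE))
  iv <- attr(cov, "intervals")$lens1
  expect_equal(iv$lo, c(-0.25, 0.25))
  expect_equal(iv$hi, c(0.75, 1.25))
  # the point at 0.5 lies in both intervals
  in_both <- vapply(cov, function(cell) 6 %in% cell$subjects, logical(1))
  expect_gte(sum(in_both), 2)
})

test_that("resolution 1 yields a single cell holding everyone", {
  scores <- cbind(lens1 = rnorm(10), lens2 = rnorm(10))
  l <- structure(list(scores = scores), class = "lens_matrix")
  cov <- build_cover(l, cover_spec(resolution = 1, gain = 4))
  expect_length(cov, 1)
  expect_setequal(cov[[1]]$subjects, 1:10)
})

test_that("gain 1 without equalization tiles the lens space without overlap", {
  set.seed(4)
  scores <- cbind(lens1 = runif(40), lens2 = runif(40))
  l <- structure(list(scores = scores), class = "lens_matrix")
  cov <- build_cover(l, cover_spec(resolution = 3, gain = 1,
                                   equalize = FALSE))
  counts <- table(unlist(lapply(cov, function(c) c$subjects)))
  # generic points fall in exactly one cell (boundary hits measure zero)
  expect_true(all(counts == 1))
})

test_that("every subject lies inside each assigned cell and no other", {
  cm <- preprocess_cohort(generate_cohort(generator_config(seed = 5)))
  l <- compute_lenses(cm)
  cov <- build_cover(l, cover_spec())
  iv <- attr(cov, "intervals")
  # brute-force containment over the full cell grid
  n1 <- nrow(iv$lens1)
  n2 <- nrow(iv$lens2)
  assigned <- matrix(FALSE, nrow(l$scores), n1 * n2)
  for (cell in cov) {
    assigned[cell$subjects, (cell$i - 1) * n2 + cell$j] <- TRUE
  }
  expected <- matrix(FALSE, nrow(l$scores), n1 * n2)
  for (i in seq_len(n1)) {
    in1 <- l$scores[, 1] >= iv$lens1$lo[i] & l$scores[, 1] <= iv$lens1$hi[i]
    for (j in seq_len(n2)) {
      expected[, (i - 1) * n2 + j] <-
        in1 & l$scores[, 2] >= iv$lens2$lo[j] &
        l$scores[, 2] <= iv$lens2$hi[j]
    }
  }
  expect_identical(assigned, expected)
})

test_that("preimage clustering separates distant clouds and keeps tight ones whole", {
  set.seed(6)
  a <- matrix(rnorm(8, 0, 0.1), ncol = 2)
  b <- matrix(rnorm(8, 10, 0.1), ncol = 2)
  m <- list(values = rbind(a, b))
  nodes <- cluster_preimage(1:8, m)
  expect_length(nodes, 2)
  expect_setequal(nodes[[1]], 1:4)
  expect_setequal(nodes[[2]], 5:8)
  # all identical points form one node
  m2 <- list(values = matrix(1, nrow = 5, ncol = 3))
  expect_length(cluster_preimage(1:5, m2), 1)
  # lone subject is discarded, not clustered
  n3 <- cluster_preimage(3L, m)
  expect_length(n3, 0)
  expect_equal(attr(n3, "discarded"), 3L)
})

test_that("preimage nodes equal a naive single-linkage cut on small instances", {
  for (s in 1:5) {
    set.seed(s)
    x <- matrix(rnorm(16), ncol = 2)
    m <- list(values = x)
    nodes <- cluster_preimage(1:8, m)
    cut_h <- attr(nodes, "cut")
    if (is.na(cut_h)) cut_h <- Inf
    ref <- oracle_single_linkage_cut(x, cut_h)
    ref <- ref[lengths(ref) >= 2]
    key <- function(l) sort(vapply(l, paste, character(1), collapse = ","))
    expect_equal(key(nodes), key(ref))
  }
})

test_that("graph edges are exactly the pairwise subject-set intersections", {
  g <- build_graph(list(c(1, 2), c(2, 3), c(4, 5)), n_subjects = 5)
  expect_equal(nrow(g$edges), 1)
  expect_equal(unname(g$edges[1, ]), c(1L, 2L))
  # duplicated node collapses
  g2 <- build_graph(list(c(1, 2), c(2, 1), c(3, 4)), n_subjects = 4)
  expect_length(g2$nodes, 2)
  # quadratic oracle on a random node collection
  set.seed(8)
  nodes <- replicate(30, sort(sample(40, sample(2:6, 1))),
                     simplify = FALSE)
  g3 <- build_graph(nodes, n_subjects = 40)
  ref <- NULL
  for (i in seq_along(g3$nodes)) {
    for (j in seq_along(g3$nodes)) {
      if (i < j && length(intersect(g3$nodes[[i]], g3$nodes[[j]])) > 0) {
        ref <- rbind(ref, c(i, j))
      }
    }
  }
  expect_equal(unname(g3$edges), unname(ref))
})

test_that("adjusted Rand index reproduces hand-computed values", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b")), 1)
  expect_equal(adjusted_rand_index(rep(1, 6), 1:6), 0)
  # {12|34} vs {13|24}: contingency all-ones, ARI = -0.5
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
})

test_that("cluster extraction reports planted differences and stays quiet on noise", {
  hit_both <- 0
  for (s in 1:20) {
    set.seed(s)
    x <- matrix(rnorm(20 * 8), ncol = 8,
                dimnames = list(NULL, paste0("p", 1:8)))
    x[1:10, 1] <- x[1:10, 1] + 3
    m <- list(values = x)
    g <- build_graph(list(1:5, 4:10, 11:15, 14:20), n_subjects = 20)
    rep_ <- extract_clusters(g, m, alpha = 0.05, adjust = "bh")
    feats <- lapply(rep_$defining_features, function(f) f$parameter)
    if (length(feats) == 2 && all(vapply(feats, function(f) "p1" %in% f,
                                         logical(1)))) {
      hit_both <- hit_both + 1
    }
  }
  expect_gte(hit_both, 19)
  # random split of pure noise: no defining features most of the time
  quiet <- 0
  for (s in 1:20) {
    set.seed(s + 100)
    x <- matrix(rnorm(20 * 8), ncol = 8,
                dimnames = list(NULL, paste0("p", 1:8)))
    perm <- sample(20)
    g <- build_graph(list(perm[1:5], perm[4:10], perm[11:15],
                          perm[14:20]), n_subjects = 20)
    rep_ <- extract_clusters(g, list(values = x), alpha = 0.05,
                             adjust = "bh")
    quiet <- quiet + (length(rep_$clusters) == 0)
  }
  expect_gte(quiet, 18)
  expect_error(extract_clusters(g, list(values = x), alpha = 1.2), "alpha")
})

test_that("mapper subjects are conserved across nodes and discards", {
  cfg <- generator_config(seed = 9)
  tab <- generate_cohort(cfg)
  cm <- preprocess_cohort(tab)
  fit <- mapper_run(cm)
  covered <- sort(unique(c(unlist(fit$graph$nodes), fit$discarded)))
  expect_equal(covered, seq_len(nrow(cm$values)))
  # clusters are disjoint
  all_members <- unlist(fit$report$clusters)
  expect_equal(anyDuplicated(all_members), 0L)
  # edges exist iff node subject sets intersect
  for (e in seq_len(nrow(fit$graph$edges))) {
    a <- fit$graph$nodes[[fit$graph$edges[e, 1]]]
    b <- fit$graph$nodes[[fit$graph$edges[e, 2]]]
    expect_gt(length(intersect(a, b)), 0)
  }
})

test_that("mapper runs are bit-reproducible", {
  cfg <- generator_config(seed = 10)
  cm <- preprocess_cohort(generate_cohort(cfg))
  f1 <- mapper_run(cm)
  f2 <- mapper_run(cm)
  expect_identical(f1$report$membership, f2$report$membership)
  expect_identical(f1$graph$nodes, f2$graph$nodes)
})
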