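# Brute-force oracles, kept deliberately naive and independent of the
# package's own implementations.

# sup |ECDF_x - ECDF_y| by direct evaluation at every pooled point
oracle_ks_D <- function(x, y) {
  pts <- c(x, y)
  max(vapply(pts, function(t) {
    abs(mean(x <= t) - mean(y <= t))
  }, numeric(1)))
}

# Jonckheere-Terpstra count statistic (ties at half weight)
oracle_jt <- function(groups) {
  s <- 0
  k <- length(groups)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      for (xi in groups[[i]]) {
        for (yj in groups[[j]]) {
          s <- s + (xi < yj) + 0.5 * (xi == yj)
        }
      }
    }
  }
  s
}

# exhaustive two-sided permutation p for JT over all label assignments
oracle_jt_exact_p <- function(groups) {
  pooled <- unlist(groups)
  sizes <- lengths(groups)
  obs <- oracle_jt(groups)
  assigns <- list()
  rec <- function(avail, sizes, acc) {
    if (length(sizes) == 0) {
      assigns[[length(assigns) + 1L]] <<- acc
      return(invisible())
    }
    for (f in utils::combn(avail, sizes[1], simplify = FALSE)) {
      rec(setdiff(avail, f), sizes[-1], c(acc, list(f)))
    }
  }
  rec(seq_along(pooled), sizes, list())
  stats_null <- vapply(assigns, function(a) {
    oracle_jt(lapply(a, function(ix) pooled[ix]))
  }, numeric(1))
  min(1, 2 * min(mean(stats_null >= obs - 1e-9),
                 mean(stats_null <= obs + 1e-9)))
}

# plug-in mutual information (bits) by an explicit double sum
oracle_mi <- function(a, b) {
  n <- length(a)
  s <- 0
  for (va in unique(a)) {
    for (vb in unique(b)) {
      p_ab <- mean(a == va & b == vb)
      if (p_ab > 0) {
        s <- s + p_ab * log2(p_ab / (mean(a == va) * mean(b == vb)))
      }
    }
  }
  s
}

# naive single-linkage merge heights via iterative set merging
oracle_single_linkage_cut <- function(x, cut_h) {
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  groups <- as.list(seq_len(n))
  repeat {
    best <- Inf
    pair <- NULL
    for (i in seq_along(groups)) {
      for (j in seq_along(groups)) {
        if (i >= j) next
        link <- min(d[groups[[i]], groups[[j]]])
        if (link < best) {
          best <- link
          pair <- c(i, j)
        }
      }
    }
    if (is.null(pair) || best > cut_h) break
    groups[[pair[1]]] <- c(groups[[pair[1]]], groups[[pair[2]]])
    groups <- groups[-pair[2]]
  }
  lapply(groups, sort)
}

# tiny cohort configuration used where full size is unnecessary
small_config <- function(seed = 1, ...) {
  generator_config(seed = seed, ...)
}

# single-profile (healthy only) configuration for marginal-shape checks
single_profile_config <- function(seed, n = 62) {
  prof <- default_profiles()[1]
  prof[[1]]$severity_weights <- c(healthy = 1)
  generator_config(
    n_subjects = n,
    group_sizes = c(healthy = n, mild = 0, moderate = 0, severe = 0),
    cluster_profiles = prof, missing_rate = 0, seed = seed)
}

# noisy binary copy used in the Bayesian-network recovery fixtures
flip_copy <- function(x, keep_prob) {
  ifelse(stats::runif(length(x)) < keep_prob, x,
         stats::rbinom(length(x), 1, 0.5))
}

count_asthma_clusters <- function(fit, table) {
  sum(vapply(fit$report$clusters, function(ix) {
    mean(table$labels$status[ix] != "healthy") > 0.5
  }, logical(1)))
}
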