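cohort_test <- function(statistic, p_value, method, n_per_group,
                        extra = list()) {
  structure(c(list(statistic = unname(statistic),
                   p_value = unname(p_value), method = method,
                   n_per_group = n_per_group), extra),
            class = "cohort_test")
}

#' @export
print.cohort_test <- function(x, ...) {
  cat(x$method, "\n  statistic =", format(x$statistic),
      " p =", format.pval(x$p_value), "\n")
  if (!is.null(x$post_hoc)) {
    cat("  post hoc vs reference:\n")
    print(x$post_hoc, row.names = FALSE)
  }
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two samples, with midrank tie
#' handling (exact p for small untied samples, normal approximation with
#' continuity correction otherwise). The reported statistic is U for the
#' first sample.
#'
#' @param x,y numeric samples.
#' @return a `cohort_test` with fields `statistic` (U), `p_value`,
#'   `method`, `n_per_group`.
#' @export
mann_whitney <- function(x, y) {
  if (length(x) < 1 || length(y) < 1) stop("both samples must be non-empty")
  wt <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE))
  cohort_test(wt$statistic, min(1, wt$p.value), "Mann-Whitney U",
              c(length(x), length(y)))
}

# Tie-corrected Kruskal-Wallis H and the shared rank bookkeeping used by
# the Dunn post hoc.
kw_ranks <- function(groups) {
  all_v <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  r <- rank(all_v)
  n <- length(all_v)
  ties <- table(all_v)
  tie_sum <- sum(ties^3 - ties)
  list(r = r, g = g, n = n, tie_sum = tie_sum)
}

#' Kruskal-Wallis test with Dunn post hoc versus a reference group
#'
#' Tie-corrected Kruskal-Wallis H across three or more groups, followed
#' by Dunn z tests of each group against the reference (by default the
#' first, i.e. the healthy group), Bonferroni-adjusted over the number
#' of comparisons. Set `all_pairs = TRUE` for the full pairwise battery.
#'
#' @param groups list of numeric samples (length >= 3, each >= 2 values).
#' @param reference index of the reference group (default 1).
#' @param all_pairs compare all pairs instead of only versus reference.
#' @param tie_correction apply the tie correction in the Dunn variance
#'   (default `TRUE`).
#' @return a `cohort_test` with `post_hoc` data.frame (`comparison`, `z`,
#'   `p_value`, `adjusted`).
#' @export
kruskal_dunn <- function(groups, reference = 1L, all_pairs = FALSE,
                         tie_correction = TRUE) {
  if (length(groups) < 3L) {
    stop("need at least 3 groups; use mann_whitney() for two")
  }
  if (any(lengths(groups) < 2L)) stop("each group needs at least 2 values")
  all_v <- unlist(groups, use.names = FALSE)
  if (length(unique(all_v)) == 1L) {
    # every observation tied: no evidence of any group difference (the
    # tie-corrected H is 0/0 here)
    ph <- data.frame(
      comparison = paste(setdiff(seq_along(groups), reference),
                         "vs", reference),
      z = 0, p_value = 1, adjusted = 1, stringsAsFactors = FALSE)
    return(cohort_test(0, 1, "Kruskal-Wallis + Dunn post hoc",
                       lengths(groups), list(post_hoc = ph)))
  }
  kw <- suppressWarnings(stats::kruskal.test(groups))
  rk <- kw_ranks(groups)
  rbar <- tapply(rk$r, rk$g, mean)
  ns <- lengths(groups)
  n <- rk$n
  tie_term <- if (tie_correction) rk$tie_sum / (12 * (n - 1)) else 0
  v0 <- n * (n + 1) / 12 - tie_term
  pairs <- if (all_pairs) {
    utils::combn(seq_along(groups), 2, simplify = FALSE)
  } else {
    lapply(setdiff(seq_along(groups), reference),
           function(i) c(reference, i))
  }
  ph <- do.call(rbind, lapply(pairs, function(pr) {
    z <- (rbar[pr[2]] - rbar[pr[1]]) /
      sqrt(v0 * (1 / ns[pr[1]] + 1 / ns[pr[2]]))
    if (!is.finite(z)) z <- 0
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(comparison = paste(pr[2], "vs", pr[1]),
               z = unname(z), p_value = p,
               stringsAsFactors = FALSE)
  }))
  ph$adjusted <- pmin(1, ph$p_value * nrow(ph))
  cohort_test(kw$statistic, kw$p.value, "Kruskal-Wallis + Dunn post hoc",
              ns, list(post_hoc = ph))
}

# Jonckheere-Terpstra statistic: sum over ordered group pairs (i < j) of
# #{x in group i, y in group j : x < y} + 0.5 #{ties}.
jt_statistic <- function(groups) {
  k <- length(groups)
  s <- 0
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      s <- s + sum(outer(groups[[i]], groups[[j]], "<")) +
        0.5 * sum(outer(groups[[i]], groups[[j]], "=="))
    }
  }
  s
}

# All assignments of the pooled values to groups of the given sizes
# (as index subsets), used for exhaustive JT enumeration.
enumerate_assignments <- function(sizes) {
  n <- sum(sizes)
  rec <- function(avail, sizes) {
    if (length(sizes) == 0) return(list(list()))
    first <- utils::combn(avail, sizes[1], simplify = FALSE)
    out <- list()
    for (f in first) {
      rest <- rec(setdiff(avail, f), sizes[-1])
      out <- c(out, lapply(rest, function(r) c(list(f), r)))
    }
    out
  }
  rec(seq_len(n), sizes)
}

#' Jonckheere-Terpstra trend test
#'
#' Tests for a monotone trend across ordered groups. The statistic is the
#' sum of pairwise Mann-Whitney counts over ordered group pairs; the
#' two-sided p-value is obtained by permutation of group labels, with the
#' observed statistic included in the null set. When the number of
#' distinct group assignments is at most `exact_limit` the permutation
#' distribution is enumerated exhaustively instead.
#'
#' @param groups list of numeric samples in increasing order of the
#'   grouping variable (length >= 3).
#' @param n_perm number of label permutations (>= 100).
#' @param seed RNG seed for the permutations.
#' @param exact_limit maximum number of arrangements enumerated exactly.
#' @return a `cohort_test`; field `exact` records whether enumeration
#'   was exhaustive.
#' @export
jonckheere_terpstra <- function(groups, n_perm = 10000L, seed = 1L,
                                exact_limit = 1e6) {
  if (length(groups) < 3L) stop("need at least 3 ordered groups")
  if (n_perm < 100L) stop("n_perm must be at least 100")
  sizes <- lengths(groups)
  pooled <- unlist(groups, use.names = FALSE)
  obs <- jt_statistic(groups)
  n_arrange <- exp(lgamma(sum(sizes) + 1) - sum(lgamma(sizes + 1)))
  split_at <- function(idx_sets) {
    lapply(idx_sets, function(ix) pooled[ix])
  }
  if (n_arrange <= exact_limit) {
    stats_null <- vapply(enumerate_assignments(sizes),
                         function(a) jt_statistic(split_at(a)), numeric(1))
    exact <- TRUE
  } else {
    stats_null <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      jt_statistic(split(sample(pooled), rep(seq_along(sizes), sizes)))
    }, numeric(1)))
    stats_null <- c(stats_null, obs) # observed statistic in the null set
    exact <- FALSE
  }
  eps <- 1e-9
  p_hi <- mean(stats_null >= obs - eps)
  p_lo <- mean(stats_null <= obs + eps)
  p <- min(1, 2 * min(p_hi, p_lo))
  cohort_test(obs, p, "Jonckheere-Terpstra (permutation)", sizes,
              list(exact = exact))
}

#' Polynomial linear-trend contrast across ordered groups
#'
#' Contrast of group means with equally spaced, zero-sum coefficients
#' (e.g. -3, -1, 1, 3 for four groups), tested with a pooled-variance t
#' statistic. Groups of size one contribute their mean but no variance.
#'
#' @param groups list of numeric samples in severity order (length >= 3).
#' @return a `cohort_test` with fields `estimate` and `coefficients`.
#' @export
linear_trend_contrast <- function(groups) {
  if (length(groups) < 3L) stop("need at least 3 ordered groups")
  k <- length(groups)
  coefs <- 2 * (seq_len(k) - (k + 1) / 2) # -3,-1,1,3 pattern
  ns <- lengths(groups)
  means <- vapply(groups, mean, numeric(1))
  df_i <- ns - 1
  if (sum(df_i) == 0) stop("all groups are singletons; no pooled variance")
  ss <- vapply(groups, function(g) sum((g - mean(g))^2), numeric(1))
  s2 <- sum(ss) / sum(df_i)
  est <- sum(coefs * means)
  se <- sqrt(s2 * sum(coefs^2 / ns))
  if (se == 0) {
    t_stat <- if (est == 0) 0 else sign(est) * Inf
  } else {
    t_stat <- est / se
  }
  p <- 2 * stats::pt(-abs(t_stat), df = sum(df_i))
  cohort_test(t_stat, p, "Linear trend contrast", ns,
              list(estimate = est, coefficients = coefs))
}

#' Spearman rank correlation
#'
#' Midrank-based rho with a t-approximation p-value
#' (`t = rho * sqrt((n-2)/(1-rho^2))` on `n - 2` df).
#'
#' @param x,y paired numeric vectors, `n >= 4`.
#' @return a `cohort_test`; `statistic` is rho.
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 4) stop("need at least 4 pairs")
  rho <- stats::cor(rank(x), rank(y))
  if (!is.finite(rho)) stop("correlation undefined (constant input)")
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  }
  cohort_test(rho, p, "Spearman rank correlation", n)
}

# Two-sample KS statistic D = sup |ECDF_x - ECDF_y|.
ks_D <- function(x, y) {
  n_x <- length(x)
  n_y <- length(y)
  pooled <- sort(unique(c(x, y)))
  fx <- vapply(pooled, function(t) sum(x <= t), numeric(1)) / n_x
  fy <- vapply(pooled, function(t) sum(y <= t), numeric(1)) / n_y
  max(abs(fx - fy))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum distance between the two empirical CDFs. The
#' p-value is asymptotic (exact for small untied samples, via
#' [stats::ks.test()]) by default, or by pooled permutation.
#'
#' @param x,y numeric samples, each of length >= 2.
#' @param mode `"asymptotic"` or `"permutation"`.
#' @param n_perm permutations when `mode = "permutation"`.
#' @param seed RNG seed for the permutation mode.
#' @return a `cohort_test`; `statistic` is D.
#' @export
ks_two_sample <- function(x, y, mode = c("asymptotic", "permutation"),
                          n_perm = 2000L, seed = 1L) {
  mode <- match.arg(mode)
  if (length(x) < 2 || length(y) < 2) stop("each sample needs >= 2 values")
  d <- ks_D(x, y)
  if (mode == "asymptotic") {
    p <- suppressWarnings(stats::ks.test(x, y))$p.value
  } else {
    pooled <- c(x, y)
    n_x <- length(x)
    null_d <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      ix <- sample.int(length(pooled), n_x)
      ks_D(pooled[ix], pooled[-ix])
    }, numeric(1)))
    p <- (1 + sum(null_d >= d - 1e-12)) / (n_perm + 1)
  }
  cohort_test(d, p, paste0("Two-sample Kolmogorov-Smirnov (", mode, ")"),
              c(length(x), length(y)))
}

#' One-way ANOVA with Bonferroni-adjusted post hoc t tests
#'
#' F test across groups, then pooled-variance t tests of each group
#' against the reference with Bonferroni adjustment over the number of
#' comparisons. Degenerate all-equal input yields `F = 0`, `p = 1`.
#'
#' @param groups list of numeric samples (length >= 3, each >= 2 values).
#' @param reference index of the reference group.
#' @return a `cohort_test` with `post_hoc` data.frame.
#' @export
anova_bonferroni <- function(groups, reference = 1L) {
  if (length(groups) < 3L) stop("need at least 3 groups")
  if (any(lengths(groups) < 2L)) stop("each group needs at least 2 values")
  ns <- lengths(groups)
  n <- sum(ns)
  k <- length(groups)
  means <- vapply(groups, mean, numeric(1))
  grand <- mean(unlist(groups, use.names = FALSE))
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  msb <- ssb / (k - 1)
  msw <- ssw / (n - k)
  if (ssb == 0) {
    f_stat <- 0
    p <- 1
  } else {
    f_stat <- msb / msw
    p <- stats::pf(f_stat, k - 1, n - k, lower.tail = FALSE)
  }
  idx <- setdiff(seq_len(k), reference)
  ph <- do.call(rbind, lapply(idx, function(i) {
    se <- sqrt(msw * (1 / ns[i] + 1 / ns[reference]))
    t_stat <- if (se == 0) 0 else (means[i] - means[reference]) / se
    pv <- 2 * stats::pt(-abs(t_stat), df = n - k)
    data.frame(comparison = paste(i, "vs", reference), t = t_stat,
               p_value = pv, stringsAsFactors = FALSE)
  }))
  ph$adjusted <- pmin(1, ph$p_value * nrow(ph))
  cohort_test(f_stat, p, "One-way ANOVA + Bonferroni post hoc", ns,
              list(post_hoc = ph))
}

#' Run the severity-stratified test battery over a composite matrix
#'
#' For every composite parameter: Kruskal-Wallis across severity groups
#' with Dunn post hoc versus healthy, plus the linear trend contrast over
#' the severity ordering. One tidy row per parameter.
#'
#' @param m a `composite_matrix` carrying subject labels.
#' @param by label column defining the groups (default `"status"`).
#' @param reference reference group label (default `"healthy"`).
#' @return data.frame, one row per parameter.
#' @export
severity_battery <- function(m, by = "status", reference = "healthy") {
  stopifnot(inherits(m, "composite_matrix"), !is.null(m$labels))
  fac <- factor(m$labels[[by]])
  lev <- levels(fac)
  if (!reference %in% lev) stop("reference group '", reference,
                                "' not present")
  ref_idx <- match(reference, lev)
  rows <- lapply(colnames(m$values), function(p) {
    groups <- split(m$values[, p], fac)
    kd <- kruskal_dunn(groups, reference = ref_idx)
    tr <- linear_trend_contrast(groups)
    data.frame(parameter = p, kw_H = kd$statistic, kw_p = kd$p_value,
               trend_t = tr$statistic, trend_p = tr$p_value,
               min_dunn_adj_p = min(kd$post_hoc$adjusted),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$kw_p_bonferroni <- pmin(1, out$kw_p * nrow(out))
  out
}
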