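#' Discretize a composite matrix
#'
#' Binary columns (at most two distinct values) get two bins; continuous
#' columns get quantile (or uniform-width) bins, with the count set per
#' column by Sturges' rule clamped to `[5, 9]`
#' (`clamp(ceil(1 + log2(n)), 5, 9)`, i.e. 7 bins at n = 62) unless
#' overridden. Columns with fewer distinct values than requested bins
#' have their bin count reduced (never below 2) with a warning.
#'
#' @param m a `composite_matrix`, or any numeric matrix.
#' @param n_bins optional fixed bin count for continuous columns.
#' @param method `"quantile"` (default; every bin non-empty) or
#'   `"uniform"`.
#' @return object of class `"discrete_table"`: list with `codes`
#'   (integer matrix of 1-based ordinal bin ids), `n_levels` per column
#'   and `breaks` (the mapping, for inversion).
#' @export
discretize <- function(m, n_bins = NULL, method = c("quantile", "uniform")) {
  method <- match.arg(method)
  x <- if (inherits(m, "composite_matrix")) m$values else m
  stopifnot(is.matrix(x), !any(is.na(x)))
  n <- nrow(x)
  default_bins <- min(9L, max(5L, as.integer(ceiling(1 + log2(n)))))
  codes <- matrix(NA_integer_, nrow = n, ncol = ncol(x),
                  dimnames = dimnames(x))
  n_levels <- stats::setNames(integer(ncol(x)), colnames(x))
  breaks_list <- stats::setNames(vector("list", ncol(x)), colnames(x))
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    distinct <- sort(unique(v))
    if (length(distinct) <= 2L) {
      codes[, j] <- match(v, distinct)
      n_levels[j] <- length(distinct)
      breaks_list[[j]] <- distinct
      next
    }
    b <- n_bins %||% default_bins
    if (length(distinct) < b) {
      warning("column '", colnames(x)[j], "' has ", length(distinct),
              " distinct values; reducing bin count")
      b <- max(2L, length(distinct))
    }
    br <- if (method == "quantile") {
      unique(stats::quantile(v, probs = seq(0, 1, length.out = b + 1),
                             names = FALSE, type = 7))
    } else {
      seq(min(v), max(v), length.out = b + 1)
    }
    codes[, j] <- as.integer(cut(v, breaks = br, include.lowest = TRUE,
                                 labels = FALSE))
    n_levels[j] <- max(codes[, j])
    breaks_list[[j]] <- br
  }
  structure(list(codes = codes, n_levels = n_levels,
                 breaks = breaks_list),
            class = "discrete_table")
}

# Decomposable BIC family score: log-likelihood of the child given its
# parent configuration minus 0.5 log(n) * q * (r - 1) free parameters.
family_score <- function(codes, n_levels, child, parents) {
  n <- nrow(codes)
  r <- n_levels[child]
  if (length(parents) == 0) {
    counts <- tabulate(codes[, child], nbins = r)
    nz <- counts[counts > 0]
    ll <- sum(nz * log(nz / n))
    q <- 1
  } else {
    pc <- codes[, parents[1]]
    if (length(parents) > 1) {
      mult <- 1
      pc <- rep(0L, n)
      for (p in parents) {
        pc <- pc + (codes[, p] - 1L) * mult
        mult <- mult * n_levels[p]
      }
    } else {
      pc <- pc - 1L
    }
    joint <- pc * r + (codes[, child] - 1L)
    jt <- table(joint)
    pt <- table(pc)
    ll <- sum(jt * log(as.numeric(jt))) -
      sum(as.numeric(pt) * log(as.numeric(pt)))
    q <- prod(n_levels[parents])
  }
  ll - 0.5 * log(n) * q * (r - 1)
}

parents_to_adjacency <- function(parents) {
  p <- length(parents)
  a <- matrix(FALSE, p, p)
  for (to in seq_len(p)) a[parents[[to]], to] <- TRUE
  a
}

# Transitive closure by repeated boolean squaring: reach[i, j] is TRUE
# when a directed path i -> ... -> j exists.
reachability <- function(a) {
  r <- a
  repeat {
    r2 <- r | ((r %*% r) > 0)
    if (identical(r2, r)) return(r)
    r <- r2
  }
}

# TRUE when `from` can still reach `to` after dropping the direct edge
# from -> to; reversing that edge would then close a cycle.
path_exists_without <- function(a, from, to) {
  a[from, to] <- FALSE
  frontier <- from
  seen <- logical(nrow(a))
  while (length(frontier) > 0) {
    v <- frontier[[1]]
    frontier <- frontier[-1]
    if (v == to) return(TRUE)
    if (seen[v]) next
    seen[v] <- TRUE
    frontier <- c(frontier, which(a[v, ]))
  }
  FALSE
}

#' Learn a Bayesian network structure by BIC hill climbing
#'
#' Greedy search over add/delete/reverse arc moves maximizing the BIC
#' score of a discrete network, with random restarts from sparse random
#' DAGs, a maximum of `max_parents` parents per node and acyclicity
#' checked on every accepted move. Deterministic given the seed. Nodes
#' left without any arc are reported separately as `isolated` (in the
#' study data five such parameters stayed outside the network).
#'
#' @param dt a `discrete_table` from [discretize()].
#' @param restarts number of hill-climbing starts (first start is the
#'   empty graph).
#' @param seed RNG seed for the random restarts.
#' @param max_parents parent limit per node (default 3).
#' @return object of class `"bayes_network"`: list with `nodes`,
#'   `edges` (data.frame `from`, `to` as labels), `parents` (list of
#'   integer vectors), `score`, `empty_score`, `isolated`.
#' @export
learn_structure <- function(dt, restarts = 3L, seed = 1L,
                            max_parents = 3L) {
  if (!inherits(dt, "discrete_table")) {
    stop("input must be a discrete_table from discretize()")
  }
  codes <- dt$codes
  p <- ncol(codes)
  if (p < 1L) stop("need at least one column")
  labels <- colnames(codes) %||% paste0("V", seq_len(p))
  cache <- new.env(parent = emptyenv())
  fs <- function(child, parents) {
    key <- paste0(child, "|", paste(sort(parents), collapse = ","))
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    val <- family_score(codes, dt$n_levels, child, sort(parents))
    cache[[key]] <- val
    val
  }
  empty_score <- sum(vapply(seq_len(p), function(j) fs(j, integer(0)),
                            numeric(1)))
  climb <- function(parents) {
    node_scores <- vapply(seq_len(p), function(j) fs(j, parents[[j]]),
                          numeric(1))
    repeat {
      adj <- parents_to_adjacency(parents)
      reach <- reachability(adj)
      best_delta <- 0
      best_move <- NULL
      for (to in seq_len(p)) {
        pa <- parents[[to]]
        for (from in seq_len(p)) {
          if (from == to) next
          if (from %in% pa) {
            # delete
            d <- fs(to, setdiff(pa, from)) - node_scores[to]
            if (d > best_delta + 1e-9) {
              best_delta <- d
              best_move <- list(op = "delete", from = from, to = to)
            }
            # reverse: legal unless another from -> ... -> to path remains
            if (length(parents[[from]]) < max_parents &&
                  !path_exists_without(adj, from, to)) {
              d <- (fs(to, setdiff(pa, from)) - node_scores[to]) +
                (fs(from, c(parents[[from]], to)) - node_scores[from])
              if (d > best_delta + 1e-9) {
                best_delta <- d
                best_move <- list(op = "reverse", from = from, to = to)
              }
            }
          } else if (length(pa) < max_parents && !reach[to, from]) {
            d <- fs(to, c(pa, from)) - node_scores[to]
            if (d > best_delta + 1e-9) {
              best_delta <- d
              best_move <- list(op = "add", from = from, to = to)
            }
          }
        }
      }
      if (is.null(best_move)) break
      m <- best_move
      if (m$op == "add") {
        parents[[m$to]] <- c(parents[[m$to]], m$from)
      } else if (m$op == "delete") {
        parents[[m$to]] <- setdiff(parents[[m$to]], m$from)
      } else {
        parents[[m$to]] <- setdiff(parents[[m$to]], m$from)
        parents[[m$from]] <- c(parents[[m$from]], m$to)
      }
      node_scores <- vapply(seq_len(p), function(j) fs(j, parents[[j]]),
                            numeric(1))
    }
    list(parents = parents, score = sum(node_scores))
  }
  random_dag <- function() {
    ord <- sample.int(p)
    parents <- rep(list(integer(0)), p)
    for (pos in seq_len(p)) {
      preds <- ord[seq_len(pos - 1)]
      if (length(preds) == 0) next
      k <- min(length(preds), stats::rbinom(1, 2, 0.3))
      if (k > 0) {
        parents[[ord[pos]]] <-
          sort(preds[sample.int(length(preds), k)])
      }
    }
    parents
  }
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(max(1L, restarts))) {
      start <- if (r == 1L) rep(list(integer(0)), p) else random_dag()
      fit <- climb(start)
      if (is.null(best) || fit$score > best$score) best <- fit
    }
  })
  edges <- do.call(rbind, lapply(seq_len(p), function(to) {
    if (length(best$parents[[to]]) == 0) return(NULL)
    data.frame(from = labels[sort(best$parents[[to]])], to = labels[to],
               stringsAsFactors = FALSE)
  }))
  if (is.null(edges)) {
    edges <- data.frame(from = character(0), to = character(0),
                        stringsAsFactors = FALSE)
  }
  connected <- unique(c(edges$from, edges$to))
  structure(list(nodes = labels, edges = edges, parents = best$parents,
                 score = best$score, empty_score = empty_score,
                 isolated = setdiff(labels, connected),
                 n_levels = dt$n_levels),
            class = "bayes_network")
}

#' @export
print.bayes_network <- function(x, ...) {
  cat("bayes_network:", length(x$nodes), "nodes,", nrow(x$edges),
      "arcs (", length(x$isolated), "isolated ) BIC =",
      format(x$score), "\n")
  invisible(x)
}

#' Mutual information between two discrete columns
#'
#' Plug-in estimate in bits from the joint contingency table.
#'
#' @param a,b integer code vectors of equal length.
#' @return nonnegative numeric scalar (bits).
#' @export
mutual_information <- function(a, b) {
  stopifnot(length(a) == length(b))
  jt <- table(a, b)
  n <- sum(jt)
  pj <- jt / n
  pa <- rowSums(pj)
  pb <- colSums(pj)
  nz <- pj > 0
  sum(pj[nz] * log2(pj[nz] / outer(pa, pb)[nz]))
}

#' Score the strength of every learned arc
#'
#' Arc strength is the mutual information (bits) between the two
#' endpoints' discretized values — a symmetric dependence measure that
#' maps monotonically to display thickness.
#'
#' @param net a `bayes_network`.
#' @param dt the `discrete_table` it was learned from.
#' @return the network with a `strength` column added to `edges`.
#' @export
edge_strength <- function(net, dt) {
  stopifnot(inherits(net, "bayes_network"), inherits(dt, "discrete_table"))
  codes <- dt$codes
  net$edges$strength <- vapply(seq_len(nrow(net$edges)), function(i) {
    mutual_information(codes[, net$edges$from[i]],
                       codes[, net$edges$to[i]])
  }, numeric(1))
  net
}

#' Classify the sign of an edge association
#'
#' Monotone associations (|Spearman rho| at or above `rho_threshold`)
#' are classed `positive` or `negative` by the sign of rho; the
#' remainder are classed `nonlinear`, with a permutation test of the
#' mutual information between the discretized values recording whether
#' the nonlinear dependence is itself significant (`mi_p` attribute).
#' Constant input yields class `degenerate`.
#'
#' @param x,y paired continuous (pre-discretization) values.
#' @param rho_threshold monotone-association threshold (default 0.3).
#' @param alpha significance level of the MI permutation test.
#' @param n_perm permutations for the MI null.
#' @param seed RNG seed.
#' @return character scalar (`"positive"`, `"negative"`, `"nonlinear"`,
#'   `"degenerate"`), with attributes `rho`, `mi`, `mi_p`,
#'   `mi_significant`.
#' @export
classify_edge_sign <- function(x, y, rho_threshold = 0.3, alpha = 0.05,
                               n_perm = 200L, seed = 1L) {
  stopifnot(length(x) == length(y))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(structure("degenerate", rho = NA_real_, mi = NA_real_,
                     mi_p = NA_real_, mi_significant = FALSE))
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= rho_threshold) {
    cls <- if (rho > 0) "positive" else "negative"
    return(structure(cls, rho = rho, mi = NA_real_, mi_p = NA_real_,
                     mi_significant = NA))
  }
  xm <- matrix(c(x, y), ncol = 2, dimnames = list(NULL, c("x", "y")))
  dt <- discretize(xm)
  mi <- mutual_information(dt$codes[, 1], dt$codes[, 2])
  null_mi <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    mutual_information(dt$codes[sample.int(nrow(dt$codes)), 1],
                       dt$codes[, 2])
  }, numeric(1)))
  mi_p <- (1 + sum(null_mi >= mi - 1e-12)) / (n_perm + 1)
  structure("nonlinear", rho = rho, mi = mi, mi_p = mi_p,
            mi_significant = mi_p < alpha)
}

#' Full Bayesian-network stage
#'
#' Discretizes the composite matrix, learns the structure, scores arc
#' strengths and classifies every arc's association sign from the
#' continuous (pre-discretization) values. Also exports, per arc, the
#' Euclidean distance between the two parameters' positions in lens
#' loading space when lenses are supplied.
#'
#' @param m a `composite_matrix`.
#' @param restarts,seed,max_parents passed to [learn_structure()].
#' @param rho_threshold passed to [classify_edge_sign()].
#' @param lenses optional `lens_matrix` for the loading-distance export.
#' @return a `bayes_network` whose `edges` carry `strength`,
#'   `sign_class` and (optionally) `loading_distance`.
#' @export
bayes_network_run <- function(m, restarts = 3L, seed = 1L,
                              max_parents = 3L, rho_threshold = 0.3,
                              lenses = NULL) {
  dt <- discretize(m)
  net <- learn_structure(dt, restarts = restarts, seed = seed,
                         max_parents = max_parents)
  net <- edge_strength(net, dt)
  if (nrow(net$edges) > 0) {
    net$edges$sign_class <- vapply(seq_len(nrow(net$edges)), function(i) {
      as.character(classify_edge_sign(
        m$values[, net$edges$from[i]], m$values[, net$edges$to[i]],
        rho_threshold = rho_threshold,
        seed = stage_seed(seed, paste0("edge", i))))
    }, character(1))
    if (!is.null(lenses)) {
      ld <- lenses$loadings
      rownames(ld) <- colnames(m$values)
      net$edges$loading_distance <-
        vapply(seq_len(nrow(net$edges)), function(i) {
          sqrt(sum((ld[net$edges$from[i], ] - ld[net$edges$to[i], ])^2))
        }, numeric(1))
    }
  } else {
    net$edges$sign_class <- character(0)
  }
  net$discrete <- dt
  net
}
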