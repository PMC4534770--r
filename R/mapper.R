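#' SVD lens functions
#'
#' Projects every subject onto the first two right singular vectors of
#' the variance-normalized composite matrix (equivalently, the first two
#' principal-component scores). A deterministic sign convention — the
#' largest-magnitude loading of each singular vector is positive — makes
#' runs bit-reproducible.
#'
#' @param m a `composite_matrix` (variance-normalized).
#' @return object of class `"lens_matrix"`: list with `scores`
#'   (subjects x 2), `loadings`, `singular_values`.
#' @export
compute_lenses <- function(m) {
  x <- m$values
  sv <- svd(x)
  tol <- max(dim(x)) * max(sv$d) * .Machine$double.eps
  rank <- sum(sv$d > tol)
  if (rank < 1) {
    stop("matrix has rank 0; nothing to project")
  }
  if (rank < 2) {
    warning("matrix has rank 1; the secondary lens is identically 0 — ",
            "consider jitter or fewer constraints")
    sv$d[2] <- 0
  }
  u <- sv$u[, 1:2, drop = FALSE]
  v <- sv$v[, 1:2, drop = FALSE]
  d <- sv$d[1:2]
  for (i in 1:2) {
    piv <- which.max(abs(v[, i]))
    if (v[piv, i] < 0) {
      v[, i] <- -v[, i]
      u[, i] <- -u[, i]
    }
  }
  scores <- sweep(u, 2, d, "*")
  rownames(scores) <- rownames(x)
  colnames(scores) <- c("lens1", "lens2")
  structure(list(scores = scores, loadings = v, singular_values = d),
            class = "lens_matrix")
}

#' Overlapping cover specification
#'
#' @param resolution base intervals per lens axis (default 32).
#' @param gain per-axis dilation factor of the base intervals; overlap
#'   fraction between adjacent intervals is `1 - 1/gain`. Defaults to
#'   4.0 on the first lens and 3.5 on the second. A scalar is recycled.
#' @param equalize place base-interval boundaries at occupancy quantiles
#'   (`TRUE`, default) rather than at equal widths.
#' @return object of class `"cover_spec"`.
#' @export
cover_spec <- function(resolution = 32L, gain = c(4.0, 3.5),
                       equalize = TRUE) {
  resolution <- as.integer(resolution)
  if (length(gain) == 1L) gain <- rep(gain, 2)
  stopifnot(resolution >= 1L, all(gain >= 1), length(gain) == 2L)
  structure(list(resolution = resolution, gain = gain,
                 equalize = equalize), class = "cover_spec")
}

# Base intervals on one axis, dilated about their centers by the axis
# gain. Equalized covers work in occupancy (quantile) space: base
# intervals hold equal numbers of points and dilation widens each by the
# gain in occupancy, so no cell balloons in a sparse stretch of the
# lens; the dilated bounds are then mapped back to lens units. Without
# equalization everything happens in raw lens units.
axis_intervals <- function(x, resolution, gain, equalize) {
  n_distinct <- length(unique(x))
  if (resolution > n_distinct) {
    warning("resolution exceeds distinct lens values; collapsing to ",
            n_distinct, " bins")
    resolution <- n_distinct
  }
  if (equalize) {
    p <- seq(0, 1, length.out = resolution + 1)
    p_lo <- p[-length(p)]
    p_hi <- p[-1]
    center <- (p_lo + p_hi) / 2
    half <- gain * (p_hi - p_lo) / 2
    q <- function(pr) stats::quantile(x, pmin(1, pmax(0, pr)),
                                      names = FALSE, type = 7)
    data.frame(lo = q(center - half), hi = q(center + half))
  } else {
    breaks <- seq(min(x), max(x), length.out = resolution + 1)
    lo <- breaks[-length(breaks)]
    hi <- breaks[-1]
    center <- (lo + hi) / 2
    half <- gain * (hi - lo) / 2
    data.frame(lo = center - half, hi = center + half)
  }
}

#' Build the overlapping 2-D cover of the lens space
#'
#' Each axis gets `resolution` base intervals (equal-occupancy when
#' equalized, equal-width otherwise), dilated about their centers by the
#' axis gain; a cover cell is the product of one dilated interval per
#' axis, and a subject belongs to every cell whose closed rectangle
#' contains its lens point. With gain > 1, adjacent cells overlap, which
#' is what lets the node graph connect.
#'
#' @param lenses a `lens_matrix`.
#' @param spec a [cover_spec()].
#' @return object of class `"mapper_cover"`: list of non-empty cells
#'   (`i`, `j`, axis ranges, `subjects` as integer row indices), with the
#'   per-axis interval tables in attribute `"intervals"`.
#' @export
build_cover <- function(lenses, spec = cover_spec()) {
  stopifnot(inherits(lenses, "lens_matrix"), inherits(spec, "cover_spec"))
  s <- lenses$scores
  iv1 <- axis_intervals(s[, 1], spec$resolution, spec$gain[1],
                        spec$equalize)
  iv2 <- axis_intervals(s[, 2], spec$resolution, spec$gain[2],
                        spec$equalize)
  cells <- list()
  for (i in seq_len(nrow(iv1))) {
    in1 <- which(s[, 1] >= iv1$lo[i] & s[, 1] <= iv1$hi[i])
    if (length(in1) == 0) next
    for (j in seq_len(nrow(iv2))) {
      members <- in1[s[in1, 2] >= iv2$lo[j] & s[in1, 2] <= iv2$hi[j]]
      if (length(members) == 0) next
      cells[[length(cells) + 1L]] <-
        list(i = i, j = j,
             lens1 = c(iv1$lo[i], iv1$hi[i]),
             lens2 = c(iv2$lo[j], iv2$hi[j]),
             subjects = members)
    }
  }
  structure(cells, class = "mapper_cover",
            intervals = list(lens1 = iv1, lens2 = iv2))
}

#' Cluster the preimage of one cover cell into nodes
#'
#' Single-linkage clustering of the cell's subjects under the
#' variance-normalized Euclidean metric, cut at the first empty bin of
#' the 10-bin histogram of merge distances (the classical Mapper gap
#' heuristic: a gap in the merge-height distribution separates
#' within-microcluster from between-microcluster joins). Clusters
#' smaller than `min_size` are discarded as singletons and reported via
#' the `"discarded"` attribute.
#'
#' In two-subject cells (or when every histogram bin is occupied) the
#' heuristic is vacuous; such cells fall back to `fallback_cut` when one
#' is supplied — [mapper_run()] passes the Tukey upper fence
#' (Q3 + 1.5 IQR) of the merge heights pooled over all cover cells, so
#' that only outlying joins are severed — and otherwise keep the
#' canonical single-cluster outcome.
#'
#' @param subjects integer row indices of the cell's members.
#' @param m the `composite_matrix` the distances are computed on.
#' @param min_size minimum node size (default 2).
#' @param n_bins histogram bins for the gap heuristic (default 10).
#' @param fallback_cut optional cut height used when the histogram shows
#'   no gap.
#' @return list of integer vectors (nodes); attribute `"discarded"`
#'   lists subjects dropped as singletons within this cell, attribute
#'   `"cut"` the gap-cut height (`NA` when the heuristic was vacuous).
#' @export
cluster_preimage <- function(subjects, m, min_size = 2L, n_bins = 10L,
                             fallback_cut = NULL) {
  stopifnot(length(subjects) >= 1L)
  if (length(subjects) == 1L) {
    out <- list()
    attr(out, "discarded") <- subjects
    attr(out, "cut") <- NA_real_
    return(out)
  }
  d <- stats::dist(m$values[subjects, , drop = FALSE])
  hc <- stats::hclust(d, method = "single")
  h <- hc$height
  diam <- max(d)
  cut_h <- NA_real_
  if (diam <= 0) {
    cl <- rep(1L, length(subjects))
  } else {
    if (diam > max(h)) {
      # histogram of merge heights (diameter appended) between the
      # lowest merge and the diameter; cut at the midpoint of the first
      # empty bin
      edges <- seq(min(h), diam, length.out = n_bins + 1)
      counts <- graphics::hist(c(h, diam), breaks = edges,
                               plot = FALSE)$counts
      empty <- which(counts == 0)
      if (length(empty) > 0) {
        cut_h <- (edges[empty[1]] + edges[empty[1] + 1]) / 2
      }
    }
    if (is.na(cut_h) && !is.null(fallback_cut)) cut_h <- fallback_cut
    cl <- if (is.na(cut_h)) rep(1L, length(subjects))
          else stats::cutree(hc, h = cut_h)
  }
  nodes <- split(subjects, cl)
  keep <- lengths(nodes) >= min_size
  out <- unname(nodes[keep])
  attr(out, "discarded") <- unlist(nodes[!keep], use.names = FALSE)
  attr(out, "cut") <- cut_h
  attr(out, "heights") <- h
  out
}

#' Assemble the Mapper graph from all nodes
#'
#' Deduplicates nodes with identical subject sets (overlapping cells
#' routinely reproduce the same microcluster) and connects two nodes by
#' an undirected edge exactly when their subject sets share at least one
#' subject.
#'
#' @param nodes list of integer vectors from [cluster_preimage()] over
#'   all cover cells.
#' @param n_subjects total number of subjects in the matrix.
#' @return object of class `"mapper_graph"`: list with `nodes` (list of
#'   sorted subject-index vectors), `edges` (two-column matrix of node
#'   ids) and `n_subjects`.
#' @export
build_graph <- function(nodes, n_subjects) {
  nodes <- lapply(nodes, function(s) sort(unique(s)))
  keys <- vapply(nodes, paste, character(1), collapse = ",")
  nodes <- nodes[!duplicated(keys)]
  ord <- order(vapply(nodes, min, numeric(1)),
               -lengths(nodes),
               vapply(nodes, paste, character(1), collapse = ","))
  nodes <- nodes[ord]
  k <- length(nodes)
  edges <- matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("from", "to")))
  if (k >= 2) {
    memb <- matrix(FALSE, nrow = k, ncol = n_subjects)
    for (i in seq_len(k)) memb[i, nodes[[i]]] <- TRUE
    shared <- tcrossprod(memb * 1)
    hits <- which(shared > 0 & upper.tri(shared), arr.ind = TRUE)
    if (nrow(hits) > 0) {
      edges <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
      dimnames(edges) <- list(NULL, c("from", "to"))
    }
  }
  structure(list(nodes = nodes, edges = edges, n_subjects = n_subjects),
            class = "mapper_graph")
}

#' @export
print.mapper_graph <- function(x, ...) {
  cat("mapper_graph:", length(x$nodes), "nodes,", nrow(x$edges),
      "edges over", x$n_subjects, "subjects\n")
  invisible(x)
}

as_igraph <- function(g) {
  ig <- igraph::make_empty_graph(n = length(g$nodes), directed = FALSE)
  if (nrow(g$edges) > 0) {
    ig <- igraph::add_edges(ig, t(g$edges))
  }
  igraph::V(ig)$size <- lengths(g$nodes)
  ig
}

#' Extract KS-characterized clusters from a Mapper graph
#'
#' Candidate subgroups are the connected components of the node graph;
#' a component whose subjects are more than half contained in a larger
#' component is absorbed into it, and subjects claimed by several
#' components are assigned to the one holding them in more nodes (ties
#' to the larger component). Each candidate is then screened with
#' two-sample Kolmogorov-Smirnov tests of every composite parameter,
#' members versus all other subjects in the graph; candidates with at
#' least one parameter passing the adjusted threshold become clusters,
#' and those parameters are its defining features (direction = sign of
#' the member-vs-rest median difference).
#'
#' @param g a `mapper_graph`.
#' @param m the `composite_matrix` the graph was built on.
#' @param alpha adjusted significance threshold in (0, 1).
#' @param adjust `"bh"` (Benjamini-Hochberg, default) or `"bonferroni"`.
#' @return object of class `"cluster_report"`: list with `clusters`
#'   (named list of subject-index vectors), `defining_features` (named
#'   list of data.frames: `parameter`, `D`, `adjusted_p`, `direction`),
#'   `unassigned` (subjects in no cluster) and `membership` (per-subject
#'   cluster label, `"unassigned"` where none).
#' @export
extract_clusters <- function(g, m, alpha = 0.05,
                             adjust = c("bh", "bonferroni")) {
  adjust <- match.arg(adjust)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  if (length(g$nodes) == 0) stop("graph has no nodes")
  ig <- as_igraph(g)
  comp <- igraph::components(ig)$membership
  cand_subj <- lapply(seq_len(max(comp)), function(cc) {
    sort(unique(unlist(g$nodes[comp == cc], use.names = FALSE)))
  })
  # absorb candidates >50% contained in a larger candidate
  ord <- order(lengths(cand_subj), decreasing = TRUE)
  owner <- seq_along(cand_subj)
  for (pos in seq_along(ord)) {
    i <- ord[pos]
    if (owner[i] != i) next
    for (qos in seq_len(pos - 1)) {
      j <- ord[qos]
      if (owner[j] != j) next
      if (length(intersect(cand_subj[[i]], cand_subj[[j]])) >
          0.5 * length(cand_subj[[i]])) {
        owner[i] <- j
        break
      }
    }
  }
  comp_owner <- owner[comp]
  cands <- unique(comp_owner)
  # disjoint subject assignment: subject -> candidate holding it in the
  # most nodes; ties to the larger candidate
  node_count <- matrix(0L, nrow = length(cands), ncol = g$n_subjects)
  for (v in seq_along(g$nodes)) {
    r <- match(comp_owner[v], cands)
    node_count[r, g$nodes[[v]]] <- node_count[r, g$nodes[[v]]] + 1L
  }
  cand_sizes <- vapply(cands, function(cc)
    length(unique(unlist(cand_subj[owner == cc]))), integer(1))
  assign_to <- rep(NA_integer_, g$n_subjects)
  for (s in seq_len(g$n_subjects)) {
    counts <- node_count[, s]
    if (all(counts == 0)) next
    best <- which(counts == max(counts))
    if (length(best) > 1) best <- best[which.max(cand_sizes[best])]
    assign_to[s] <- best
  }
  params <- colnames(m$values)
  clusters <- list()
  features <- list()
  for (r in seq_along(cands)) {
    members <- which(assign_to == r)
    others <- which(!is.na(assign_to) & assign_to != r)
    if (length(members) < 2 || length(others) < 2) next
    res <- lapply(params, function(p) {
      kt <- ks_two_sample(m$values[members, p], m$values[others, p])
      c(D = kt$statistic, p = kt$p_value,
        dir = sign(stats::median(m$values[members, p]) -
                     stats::median(m$values[others, p])))
    })
    res <- do.call(rbind, res)
    adj <- stats::p.adjust(res[, "p"],
                           method = if (adjust == "bh") "BH"
                                    else "bonferroni")
    pass <- which(adj < alpha)
    if (length(pass) == 0) next
    id <- paste0("C", length(clusters) + 1L)
    clusters[[id]] <- members
    feat <- data.frame(parameter = params[pass], D = res[pass, "D"],
                       adjusted_p = adj[pass],
                       direction = res[pass, "dir"],
                       stringsAsFactors = FALSE)
    features[[id]] <- feat[order(-feat$D), , drop = FALSE]
  }
  membership <- rep("unassigned", g$n_subjects)
  for (id in names(clusters)) membership[clusters[[id]]] <- id
  structure(list(clusters = clusters, defining_features = features,
                 unassigned = which(membership == "unassigned"),
                 membership = membership),
            class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat("cluster_report:", length(x$clusters), "clusters,",
      length(x$unassigned), "unassigned subjects\n")
  for (id in names(x$clusters)) {
    top <- x$defining_features[[id]]$parameter[1]
    cat(" ", id, ": n =", length(x$clusters[[id]]),
        " top feature:", top, "\n")
  }
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same
#' subjects: 1 for identical partitions, about 0 for independent ones.
#'
#' @param labels_a,labels_b vectors of cluster labels of equal length.
#' @return numeric scalar in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  stopifnot(length(labels_a) == length(labels_b))
  tab <- table(labels_a, labels_b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  expected <- a * b / choose(n, 2)
  max_index <- (a + b) / 2
  if (max_index == expected) return(0)
  (sum_ij - expected) / (max_index - expected)
}

#' Run the full Mapper stage
#'
#' Lenses, cover, per-cell single-linkage nodes, node-overlap graph and
#' KS cluster extraction in one call.
#'
#' @param m a `composite_matrix`.
#' @param spec a [cover_spec()].
#' @param alpha,adjust passed to [extract_clusters()].
#' @param min_size minimum node size.
#' @return list with `lenses`, `cover`, `graph`, `report`, `discarded`
#'   (subjects that were singletons in every cell containing them).
#' @export
#' @examples
#' tab <- generate_cohort(generator_config(seed = 1))
#' cm <- preprocess_cohort(tab)
#' fit <- mapper_run(cm, cover_spec(resolution = 16))
#' fit$graph
mapper_run <- function(m, spec = cover_spec(), alpha = 0.05,
                       adjust = "bh", min_size = 2L) {
  lenses <- compute_lenses(m)
  cov <- build_cover(lenses, spec)
  # first pass; cells whose merge-height histogram shows no gap are
  # then re-cut at the Tukey upper fence of the pooled merge heights,
  # so a lone far-apart pair cannot weld two structures together
  first <- lapply(cov, function(cell) {
    cluster_preimage(cell$subjects, m, min_size = min_size)
  })
  cuts <- vapply(first, function(nd) attr(nd, "cut"), numeric(1))
  pooled_h <- unlist(lapply(first, function(nd) attr(nd, "heights")))
  fallback <- if (length(pooled_h) > 0) {
    unname(stats::quantile(pooled_h, 0.75) +
             1.5 * stats::IQR(pooled_h))
  } else NULL
  nodes <- list()
  discarded <- integer(0)
  for (i in seq_along(cov)) {
    nd <- first[[i]]
    if (is.na(cuts[i]) && length(cov[[i]]$subjects) > 1 &&
          !is.null(fallback)) {
      nd <- cluster_preimage(cov[[i]]$subjects, m, min_size = min_size,
                             fallback_cut = fallback)
    }
    discarded <- c(discarded, attr(nd, "discarded"))
    nodes <- c(nodes, nd)
  }
  g <- build_graph(nodes, n_subjects = nrow(m$values))
  covered <- unique(unlist(g$nodes, use.names = FALSE))
  discarded <- sort(setdiff(unique(discarded), covered))
  report <- extract_clusters(g, m, alpha = alpha, adjust = adjust)
  list(lenses = lenses, cover = cov, graph = g, report = report,
       discarded = discarded)
}
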