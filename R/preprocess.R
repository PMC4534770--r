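#' Decide the analysis scale of a measurement column
#'
#' Shapiro-Wilk normality screen: columns rejecting normality at `alpha`
#' are carried through the pipeline as `log10(x + c)`, with offset
#' `c` equal to half the smallest positive observed value when zeros are
#' present (zero medians do occur for low-abundance mediators).
#' Constant columns are treated as normal (the test is undefined) and
#' columns containing negative values fall back to the raw scale with a
#' warning.
#'
#' @param x numeric vector (may contain `NA`).
#' @param alpha significance level for the Shapiro-Wilk test.
#' @return list with `scale` (`"raw"` or `"log"`) and `offset` (0 unless
#'   a zero-handling offset was needed).
#' @export
decide_scale <- function(x, alpha = 0.05) {
  obs <- x[!is.na(x)]
  if (length(obs) < 3L) stop("need at least 3 non-missing values")
  if (stats::sd(obs) == 0) return(list(scale = "raw", offset = 0))
  p <- stats::shapiro.test(obs)$p.value
  if (p >= alpha) return(list(scale = "raw", offset = 0))
  if (any(obs < 0)) {
    warning("column rejects normality but has negative values; keeping raw scale")
    return(list(scale = "raw", offset = 0))
  }
  offset <- if (any(obs == 0)) min(obs[obs > 0]) / 2 else 0
  list(scale = "log", offset = offset)
}

apply_scale <- function(x, decision) {
  if (decision$scale == "log") log10(x + decision$offset) else x
}

#' Impute missing values by severity subgroup mean
#'
#' Each missing entry is replaced by the mean of the observed values of
#' the same measurement among subjects with the same severity label —
#' tissue specificity is inherent to the measurement column, which is
#' compartment-resolved. Observed entries are never touched.
#'
#' @param table a `cohort_table`.
#' @param fallback_overall if `TRUE`, a subgroup with no observed value
#'   falls back to the overall column mean instead of erroring.
#' @return the table with an empty missing mask.
#' @export
impute_subgroup_mean <- function(table, fallback_overall = FALSE) {
  stopifnot(inherits(table, "cohort_table"))
  status <- as.character(table$labels$status)
  values <- table$values
  for (j in seq_len(ncol(values))) {
    miss_j <- which(is.na(values[, j]))
    if (length(miss_j) == 0) next
    for (s in unique(status[miss_j])) {
      rows <- which(status == s)
      obs <- values[rows, j]
      obs <- obs[!is.na(obs)]
      fill <- if (length(obs) > 0) {
        mean(obs)
      } else if (fallback_overall) {
        mean(values[, j], na.rm = TRUE)
      } else {
        stop("all values missing for measurement '",
             colnames(values)[j], "' in severity subgroup '", s, "'")
      }
      idx <- intersect(miss_j, rows)
      values[idx, j] <- fill
    }
  }
  table$values <- values
  table$missing[] <- FALSE
  table
}

#' Compartment-composite weighting specification
#'
#' @param weights optional named numeric vector
#'   `"parameter.compartment" -> weight`; unspecified measurements get
#'   weight 1. Weights are renormalized within each parameter over the
#'   compartments actually measured.
#' @return object of class `"composite_spec"`.
#' @export
composite_spec <- function(weights = NULL) {
  stopifnot(is.null(weights) || (is.numeric(weights) && all(weights >= 0)))
  structure(list(weights = weights), class = "composite_spec")
}

#' Composite each parameter across its compartments
#'
#' Collapses the compartment-resolved measurement columns to one column
#' per parameter by a weighted average (equal weights by default) over
#' the compartments in which the parameter was measured, yielding the
#' airway/tissue composite readouts the network analyses run on.
#' Averaging happens on the analysis scale, so decide scales and impute
#' first.
#'
#' @param table a fully imputed `cohort_table` (values already on the
#'   analysis scale).
#' @param spec a [composite_spec()].
#' @return list with `values` (subjects x parameters matrix),
#'   `provenance` (per parameter: source measurements and weights) and
#'   `annotations` (parameter-level class/kind).
#' @export
composite_average <- function(table, spec = composite_spec()) {
  stopifnot(inherits(table, "cohort_table"))
  if (any(is.na(table$values))) {
    stop("table contains missing values; impute before compositing")
  }
  ann <- table$annotations
  params <- unique(ann$parameter)
  out <- matrix(NA_real_, nrow = nrow(table$values), ncol = length(params),
                dimnames = list(rownames(table$values), params))
  provenance <- vector("list", length(params))
  names(provenance) <- params
  for (p in params) {
    cols <- which(ann$parameter == p)
    w <- rep(1, length(cols))
    if (!is.null(spec$weights)) {
      keys <- ann$measurement[cols]
      hit <- keys %in% names(spec$weights)
      w[hit] <- spec$weights[keys[hit]]
    }
    if (sum(w) <= 0) stop("parameter '", p, "' has zero total weight")
    w <- w / sum(w)
    out[, p] <- as.vector(table$values[, cols, drop = FALSE] %*% w)
    provenance[[p]] <- list(measurements = ann$measurement[cols],
                            weights = w)
  }
  param_ann <- ann[!duplicated(ann$parameter),
                   c("parameter", "class", "value_kind")]
  rownames(param_ann) <- NULL
  list(values = out, provenance = provenance, annotations = param_ann)
}

#' Variance-normalize a composite matrix
#'
#' Centers and scales every column to unit standard deviation (sample
#' SD, denominator `n - 1` by default), so Euclidean distance on the
#' result is the variance-normalized Euclidean metric. Constant columns
#' carry no metric information (their contribution would be 0/0) and are
#' dropped with a warning. Centering/scaling constants are stored for
#' inverse mapping.
#'
#' @param m a `composite_matrix` or the list returned by
#'   [composite_average()].
#' @param denominator `"n-1"` (sample SD, default) or `"n"`.
#' @return object of class `"composite_matrix"` with fields `values`,
#'   `column_means`, `column_sds`, `provenance`, `annotations`,
#'   `dropped`.
#' @export
variance_normalize <- function(m, denominator = c("n-1", "n")) {
  denominator <- match.arg(denominator)
  x <- m$values
  n <- nrow(x)
  mu <- colMeans(x)
  sds <- apply(x, 2, stats::sd)
  if (denominator == "n") sds <- sds * sqrt((n - 1) / n)
  const <- which(sds == 0 | !is.finite(sds))
  if (length(const) > 0) {
    warning("dropping constant column(s): ",
            paste(colnames(x)[const], collapse = ", "))
    x <- x[, -const, drop = FALSE]
    mu <- mu[-const]
    sds <- sds[-const]
  }
  z <- sweep(sweep(x, 2, mu, "-"), 2, sds, "/")
  structure(list(values = z, column_means = mu, column_sds = sds,
                 provenance = m$provenance,
                 annotations = m$annotations,
                 labels = m$labels,
                 dropped = if (length(const)) colnames(m$values)[const]
                           else character(0)),
            class = "composite_matrix")
}

#' Run the full preprocessing chain
#'
#' Scale decision per measurement column, subgroup-mean imputation on the
#' analysis scale, compartment compositing, then variance normalization.
#' Deciding scales before imputing keeps imputed means from being
#' dominated by skew; binary flags are never log-transformed.
#'
#' @param table a `cohort_table`.
#' @param alpha Shapiro-Wilk significance level for [decide_scale()].
#' @param spec a [composite_spec()].
#' @param denominator SD convention passed to [variance_normalize()].
#' @param fallback_overall passed to [impute_subgroup_mean()].
#' @return a `composite_matrix` carrying subject labels and per-column
#'   scale decisions.
#' @export
#' @examples
#' tab <- generate_cohort(generator_config(seed = 1))
#' cm <- preprocess_cohort(tab)
#' range(colMeans(cm$values))
preprocess_cohort <- function(table, alpha = 0.05,
                              spec = composite_spec(),
                              denominator = "n-1",
                              fallback_overall = FALSE) {
  stopifnot(inherits(table, "cohort_table"))
  decisions <- vector("list", ncol(table$values))
  names(decisions) <- colnames(table$values)
  for (j in seq_len(ncol(table$values))) {
    kind <- table$annotations$value_kind[j]
    decisions[[j]] <- if (kind == "binary") {
      list(scale = "raw", offset = 0)
    } else {
      decide_scale(table$values[, j], alpha = alpha)
    }
    table$values[, j] <- apply_scale(table$values[, j], decisions[[j]])
  }
  table <- impute_subgroup_mean(table, fallback_overall = fallback_overall)
  comp <- composite_average(table, spec = spec)
  comp$labels <- table$labels
  out <- variance_normalize(comp, denominator = denominator)
  out$scale_decisions <- decisions
  out
}

#' @export
print.composite_matrix <- function(x, ...) {
  cat("composite_matrix:", nrow(x$values), "subjects x", ncol(x$values),
      "parameters (variance-normalized)\n")
  if (length(x$dropped)) cat("dropped constant:",
                             paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}
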