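#' Synthetic cohort generator configuration
#'
#' Defines the study conditions emulated by [generate_cohort()]: cohort
#' size, severity group sizes, planted phenotype profiles, the
#' missing-at-random rate within biological compartments and the
#' within-profile dispersion multiplier.
#'
#' @param n_subjects number of subjects (default 62, the network-analysis
#'   cohort size).
#' @param group_sizes named integer vector of severity group sizes
#'   (`healthy`, `mild`, `moderate`, `severe`). Defaults to the enrolled
#'   24/15/23/22 proportions rescaled to `n_subjects` by largest
#'   remainder.
#' @param cluster_profiles list of [phenotype_profile()] objects;
#'   defaults to [default_profiles()].
#' @param missing_rate probability in `[0, 1)` that a measurement taken
#'   in a biological compartment is missing (completely at random);
#'   either a scalar or a named vector per compartment.
#' @param noise_scale positive multiplier on within-profile dispersions.
#' @param seed integer RNG seed.
#' @return an object of class `"generator_config"`.
#' @export
generator_config <- function(n_subjects = 62L,
                             group_sizes = NULL,
                             cluster_profiles = default_profiles(),
                             missing_rate = 0.05,
                             noise_scale = 0.2,
                             seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  stopifnot(n_subjects >= 1L, noise_scale >= 0,
            all(missing_rate >= 0), all(missing_rate < 1))
  if (is.null(group_sizes)) {
    group_sizes <- largest_remainder(c(24, 15, 23, 22), n_subjects)
    names(group_sizes) <- c("healthy", "mild", "moderate", "severe")
  }
  stopifnot(sum(group_sizes) == n_subjects,
            setequal(names(group_sizes),
                     c("healthy", "mild", "moderate", "severe")))
  structure(list(n_subjects = n_subjects,
                 group_sizes = group_sizes[c("healthy", "mild",
                                             "moderate", "severe")],
                 cluster_profiles = cluster_profiles,
                 missing_rate = missing_rate,
                 noise_scale = noise_scale,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# Deterministic allocation of subjects to (severity, profile): within
# each severity group, profiles receive counts proportional to their
# severity weights (largest-remainder rounding).
allocate_profiles <- function(config) {
  sev_levels <- c("healthy", "mild", "moderate", "severe")
  profiles <- config$cluster_profiles
  pnames <- vapply(profiles, function(p) p$name, character(1))
  out <- data.frame(status = character(0), profile = character(0))
  for (s in sev_levels) {
    n_s <- config$group_sizes[[s]]
    if (n_s == 0) next
    w <- vapply(profiles, function(p) {
      unname(p$severity_weights[s] %||% 0)
    }, numeric(1))
    w[is.na(w)] <- 0
    if (sum(w) == 0) {
      stop("no profile carries weight for severity group '", s, "'")
    }
    counts <- largest_remainder(w, n_s)
    out <- rbind(out, data.frame(status = s,
                                 profile = rep(pnames, counts)))
  }
  out
}

# Compartment-level multiplicative offsets applied to concentration
# parameters (airway mediators are more dilute in lavage than sputum).
compartment_multiplier <- function(compartment) {
  c(blood = 1, sputum = 1, BAL = 0.15, serum = 0.4, biopsy = 1,
    none = 1)[compartment]
}

draw_measurement <- function(kind, mean, disp, n, compartment) {
  switch(kind,
    concentration = {
      mu <- log10(pmax(mean, 1e-6) * compartment_multiplier(compartment))
      10^stats::rnorm(n, mu, disp)
    },
    percentage = {
      p <- pmin(pmax(mean / 100, 1e-4), 1 - 1e-4)
      100 * stats::plogis(stats::rnorm(n, stats::qlogis(p), disp))
    },
    score = pmax(0, stats::rnorm(n, mean, disp)),
    binary = as.numeric(stats::rbinom(n, 1L, pmin(pmax(mean, 0), 1))),
    count = round(pmax(0, stats::rnorm(n, mean, disp))),
    stop("unknown value kind: ", kind)
  )
}

#' Generate a synthetic cohort
#'
#' Draws a subject-by-measurement table from planted phenotype profiles.
#' Concentrations are log-normal on their natural scale, cell frequencies
#' are logit-normal scaled to `[0, 100]`, scores are truncated normal,
#' flags Bernoulli and counts Poisson. Measurements taken in biological
#' compartments are masked missing completely at random at the configured
#' rate. The function is a pure function of `(config, panel)`: the same
#' seed reproduces the table exactly.
#'
#' @param config a [generator_config()].
#' @param panel a panel data.frame as from [default_panel()].
#' @return an object of class `"cohort_table"`: a list with elements
#'   `values` (numeric matrix, `NA` where missing), `missing` (logical
#'   mask), `annotations` (per-measurement metadata), `labels`
#'   (per-subject status, sex, atopy and medication flags) and the
#'   planted assignment used by [ground_truth()].
#' @export
#' @examples
#' tab <- generate_cohort(generator_config(seed = 1))
#' dim(tab$values)
generate_cohort <- function(config, panel = default_panel()) {
  stopifnot(inherits(config, "generator_config"))
  meas <- panel_measurements(panel)
  for (prof in config$cluster_profiles) {
    miss <- setdiff(panel$parameter, names(prof$means))
    if (length(miss) > 0) {
      stop("profile '", prof$name, "' has no mean for parameter '",
           miss[1], "'")
    }
    pct <- panel$parameter[panel$value_kind == "percentage"]
    bad <- pct[prof$means[pct] < 0 | prof$means[pct] > 100]
    if (length(bad) > 0) {
      stop("profile '", prof$name, "': percentage mean out of [0,100] for '",
           bad[1], "'")
    }
  }
  alloc <- allocate_profiles(config)
  stopifnot(nrow(alloc) == config$n_subjects)
  prof_by_name <- stats::setNames(config$cluster_profiles,
                                  vapply(config$cluster_profiles,
                                         function(p) p$name, character(1)))
  n <- config$n_subjects
  subject_id <- sprintf("S%03d", seq_len(n))

  with_seed(config$seed, {
    values <- matrix(NA_real_, nrow = n, ncol = nrow(meas),
                     dimnames = list(subject_id, meas$measurement))
    for (j in seq_len(nrow(meas))) {
      par <- meas$parameter[j]
      kind <- meas$value_kind[j]
      for (pn in names(prof_by_name)) {
        idx <- which(alloc$profile == pn)
        if (length(idx) == 0) next
        prof <- prof_by_name[[pn]]
        values[idx, j] <- draw_measurement(
          kind, unname(prof$means[par]),
          unname(prof$dispersions[par]) * config$noise_scale,
          length(idx), meas$compartment[j])
      }
    }
    rate <- config$missing_rate
    missing <- matrix(FALSE, nrow = n, ncol = nrow(meas),
                      dimnames = dimnames(values))
    for (j in seq_len(nrow(meas))) {
      comp <- meas$compartment[j]
      if (comp == "none") next
      r <- if (length(rate) > 1L) unname(rate[comp] %||% 0) else rate
      if (is.na(r)) r <- if (length(rate) > 1L) 0 else rate
      if (r > 0) missing[, j] <- stats::runif(n) < r
    }
    values[missing] <- NA_real_

    labels <- data.frame(
      subject_id = subject_id,
      status = factor(alloc$status,
                      levels = c("healthy", "mild", "moderate", "severe")),
      sex = ifelse(values[, "sex_female"] > 0.5, "F", "M"),
      atopy = values[, "atopy"] > 0.5,
      OCS = values[, "OCS_maintenance"] > 0.5,
      SABA = values[, "SABA_use"] > 0.5,
      LABA = values[, "LABA_use"] > 0.5,
      stringsAsFactors = FALSE
    )
    structure(list(values = values, missing = missing,
                   annotations = meas, labels = labels,
                   planted = stats::setNames(alloc$profile, subject_id),
                   generator = list(seed = config$seed,
                                    n_subjects = config$n_subjects)),
              class = "cohort_table")
  })
}

#' Planted profile assignment of a generated cohort
#'
#' Returns the ground-truth phenotype label of every subject, in the
#' table's current row order, for scoring recovered clusterings (e.g.
#' with [adjusted_rand_index()]).
#'
#' @param config the [generator_config()] the table was generated with.
#' @param table a [generate_cohort()] output.
#' @return named character vector, one profile label per subject row.
#' @export
ground_truth <- function(config, table) {
  stopifnot(inherits(config, "generator_config"))
  if (!inherits(table, "cohort_table") || is.null(table$planted)) {
    stop("table was not produced by generate_cohort()")
  }
  if (!identical(table$generator$seed, config$seed) ||
      !identical(table$generator$n_subjects, config$n_subjects)) {
    stop("table does not match this generator configuration")
  }
  table$planted[rownames(table$values)]
}

#' Reorder the rows of a cohort table
#'
#' Permutes subjects consistently across values, missing mask, labels and
#' the planted assignment.
#'
#' @param table a `cohort_table`.
#' @param perm integer permutation of the row indices.
#' @return the permuted `cohort_table`.
#' @export
permute_subjects <- function(table, perm) {
  stopifnot(inherits(table, "cohort_table"),
            setequal(perm, seq_len(nrow(table$values))))
  table$values <- table$values[perm, , drop = FALSE]
  table$missing <- table$missing[perm, , drop = FALSE]
  table$labels <- table$labels[perm, , drop = FALSE]
  rownames(table$labels) <- NULL
  table
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("cohort_table:", nrow(x$values), "subjects x", ncol(x$values),
      "measurements (", sum(x$missing), "missing )\n")
  print(table(x$labels$status))
  invisible(x)
}
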