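#' Sputum granulocytic subtype rule
#'
#' Cut points on the sputum differential: neutrophilic above 61%
#' neutrophils, eosinophilic above 3% eosinophils. Inequalities are
#' strict: a subject exactly at a cut is not above it.
#'
#' @param neutrophil_cut percentage cut for neutrophilia (default 61).
#' @param eosinophil_cut percentage cut for eosinophilia (default 3).
#' @return object of class `"subtype_rule"`.
#' @export
subtype_rule <- function(neutrophil_cut = 61, eosinophil_cut = 3) {
  stopifnot(neutrophil_cut > 0, neutrophil_cut < 100,
            eosinophil_cut > 0, eosinophil_cut < 100)
  structure(list(neutrophil_cut = neutrophil_cut,
                 eosinophil_cut = eosinophil_cut),
            class = "subtype_rule")
}

SUBTYPE_LEVELS <- c("neutrophilic", "eosinophilic", "mixed granulocytic",
                    "paucigranulocytic")

#' Classify inflammatory subtype from sputum differentials
#'
#' Exhaustive and mutually exclusive: both cuts exceeded gives mixed
#' granulocytic, one gives the respective granulocytic subtype, neither
#' gives paucigranulocytic. Subjects with a missing differential are
#' returned as `NA` and counted as having no valid data downstream.
#'
#' @param neut_pct,eos_pct sputum neutrophil / eosinophil percentages
#'   (vectors, values in `[0, 100]` or `NA`).
#' @param rule a [subtype_rule()].
#' @return factor with levels neutrophilic, eosinophilic,
#'   mixed granulocytic, paucigranulocytic.
#' @export
#' @examples
#' classify_subtype(c(65, 65, 61), c(1, 4, 3))
classify_subtype <- function(neut_pct, eos_pct, rule = subtype_rule()) {
  stopifnot(length(neut_pct) == length(eos_pct))
  ok <- !is.na(neut_pct) & !is.na(eos_pct)
  if (any(neut_pct[ok] < 0 | neut_pct[ok] > 100 |
            eos_pct[ok] < 0 | eos_pct[ok] > 100)) {
    stop("percentages must lie in [0, 100]")
  }
  n_hi <- neut_pct > rule$neutrophil_cut
  e_hi <- eos_pct > rule$eosinophil_cut
  out <- rep(NA_character_, length(neut_pct))
  out[ok & n_hi & e_hi] <- "mixed granulocytic"
  out[ok & n_hi & !e_hi] <- "neutrophilic"
  out[ok & !n_hi & e_hi] <- "eosinophilic"
  out[ok & !n_hi & !e_hi] <- "paucigranulocytic"
  factor(out, levels = SUBTYPE_LEVELS)
}

#' Subtype frequency table by group
#'
#' Counts and percentages of each inflammatory subtype per group, with
#' the valid-data total as denominator and percentages rounded to the
#' nearest integer (raw fractions are kept alongside). Groups with no
#' valid subjects report `NA` percentages rather than zeros.
#'
#' @param subtypes factor from [classify_subtype()] (`NA` = no valid
#'   data).
#' @param groups group label per subject.
#' @return data.frame with columns `group`, `subtype`, `count`,
#'   `valid_total`, `percent`, `fraction`.
#' @export
subtype_table <- function(subtypes, groups) {
  stopifnot(length(subtypes) == length(groups))
  groups <- factor(groups)
  out <- do.call(rbind, lapply(levels(groups), function(g) {
    s <- subtypes[groups == g]
    valid <- sum(!is.na(s))
    counts <- table(factor(s, levels = SUBTYPE_LEVELS))
    frac <- if (valid > 0) as.numeric(counts) / valid else
      rep(NA_real_, length(counts))
    data.frame(group = g, subtype = names(counts),
               count = as.integer(counts), valid_total = valid,
               percent = ifelse(is.na(frac), NA_real_,
                                round(100 * frac)),
               fraction = frac, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Subtype report from a cohort table
#'
#' Classifies every subject from the raw sputum differential columns
#' (`neutrophils.sputum`, `eosinophils.sputum`; missing values are never
#' imputed here) and tabulates by severity group.
#'
#' @param table a `cohort_table`.
#' @param rule a [subtype_rule()].
#' @return list with `subtypes` (per-subject factor) and `table` (the
#'   [subtype_table()] output by severity).
#' @export
subtype_report <- function(table, rule = subtype_rule()) {
  stopifnot(inherits(table, "cohort_table"))
  need <- c("neutrophils.sputum", "eosinophils.sputum")
  miss <- setdiff(need, colnames(table$values))
  if (length(miss) > 0) {
    stop("cohort lacks sputum differential column '", miss[1], "'")
  }
  st <- classify_subtype(table$values[, need[1]],
                         table$values[, need[2]], rule = rule)
  list(subtypes = st,
       table = subtype_table(st, table$labels$status))
}
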