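#' Default measurement panel
#'
#' The analysis matrix pairs 26 pathobiologic with 26 clinical parameters.
#' T-cell subset frequencies are measured in blood, sputum, BAL fluid and
#' endobronchial biopsy; soluble mediators in sputum, BAL fluid and serum;
#' mast cell proteases and granulocyte differentials in the airway
#' compartments; clinical parameters are single-valued (compartment
#' `"none"`). The published parameter list was never deposited in full, so
#' this panel is a reconstruction from parameters named in the study
#' narrative, padded with standard clinical descriptors to the stated
#' 26 + 26 shape; treat individual identities as representative rather
#' than authoritative.
#'
#' @return a data.frame with one row per parameter and columns
#'   `parameter`, `class` (`"pathobiologic"` or `"clinical"`),
#'   `value_kind` (`"concentration"`, `"percentage"`, `"score"`,
#'   `"binary"`, `"count"`) and `compartments` (comma-separated).
#' @export
#' @examples
#' p <- default_panel()
#' table(p$class)
default_panel <- function() {
  cell4 <- "blood,sputum,BAL,biopsy"
  airway <- "sputum,BAL"
  med3 <- "sputum,BAL,serum"
  row <- function(parameter, class, value_kind, compartments)
    data.frame(parameter = parameter, class = class,
               value_kind = value_kind, compartments = compartments,
               stringsAsFactors = FALSE)
  patho <- rbind(
    row("TH1_cells",        "pathobiologic", "percentage", cell4),
    row("TH2_IL13_cells",   "pathobiologic", "percentage", cell4),
    row("TH17_cells",       "pathobiologic", "percentage", cell4),
    row("Treg_cells",       "pathobiologic", "percentage", cell4),
    row("TC1_cells",        "pathobiologic", "percentage", cell4),
    row("TC2_cells",        "pathobiologic", "percentage", cell4),
    row("gd17_cells",       "pathobiologic", "percentage", cell4),
    row("MAIT_cells",       "pathobiologic", "percentage", cell4),
    row("eosinophils",      "pathobiologic", "percentage", "blood,sputum,BAL"),
    row("neutrophils",      "pathobiologic", "percentage", airway),
    row("macrophages",      "pathobiologic", "percentage", airway),
    row("lymphocytes",      "pathobiologic", "percentage", airway),
    row("IL4",              "pathobiologic", "concentration", med3),
    row("IL5",              "pathobiologic", "concentration", med3),
    row("IL13",             "pathobiologic", "concentration", med3),
    row("IFNg",             "pathobiologic", "concentration", med3),
    row("IL2",              "pathobiologic", "concentration", med3),
    row("IL12p70",          "pathobiologic", "concentration", med3),
    row("IL10",             "pathobiologic", "concentration", med3),
    row("IL17A",            "pathobiologic", "concentration", med3),
    row("tryptase",         "pathobiologic", "concentration", airway),
    row("chymase",          "pathobiologic", "concentration", airway),
    row("CPA3",             "pathobiologic", "concentration", airway),
    row("basogranulin",     "pathobiologic", "concentration", airway),
    row("eNO",              "pathobiologic", "score", "none"),
    row("vitamin_D",        "pathobiologic", "concentration", "serum")
  )
  clin <- rbind(
    row("age",                    "clinical", "score", "none"),
    row("sex_female",             "clinical", "binary", "none"),
    row("BMI",                    "clinical", "score", "none"),
    row("atopy",                  "clinical", "binary", "none"),
    row("FEV1_pct",               "clinical", "score", "none"),
    row("FEV1_reversibility",     "clinical", "score", "none"),
    row("PEFR_pct",               "clinical", "score", "none"),
    row("PEFR_variability",       "clinical", "score", "none"),
    row("ACQ",                    "clinical", "score", "none"),
    row("GINA_step",              "clinical", "score", "none"),
    row("GINA_control",           "clinical", "score", "none"),
    row("ICS_dose",               "clinical", "score", "none"),
    row("OCS_maintenance",        "clinical", "binary", "none"),
    row("IgE",                    "clinical", "concentration", "serum"),
    row("asthma_duration",        "clinical", "score", "none"),
    row("onset_age",              "clinical", "score", "none"),
    row("allergic_rhinitis",      "clinical", "binary", "none"),
    row("nasal_polyps",           "clinical", "binary", "none"),
    row("eczema",                 "clinical", "binary", "none"),
    row("salicylate_sensitivity", "clinical", "binary", "none"),
    row("pack_years",             "clinical", "score", "none"),
    row("blood_eos_count",        "clinical", "concentration", "blood"),
    row("skin_test_positives",    "clinical", "count", "none"),
    row("SABA_use",               "clinical", "binary", "none"),
    row("LABA_use",               "clinical", "binary", "none"),
    row("LTRA_use",               "clinical", "binary", "none")
  )
  panel <- rbind(patho, clin)
  rownames(panel) <- NULL
  panel
}

#' Expand a panel into its measurement columns
#'
#' One measurement per (parameter, compartment) pair, named
#' `parameter.compartment` (bare parameter name when the compartment is
#' `"none"`).
#'
#' @param panel a panel data.frame as from [default_panel()].
#' @return data.frame with columns `measurement`, `parameter`, `class`,
#'   `compartment`, `value_kind`.
#' @export
panel_measurements <- function(panel) {
  out <- do.call(rbind, lapply(seq_len(nrow(panel)), function(i) {
    comps <- strsplit(panel$compartments[i], ",", fixed = TRUE)[[1]]
    data.frame(
      measurement = ifelse(comps == "none", panel$parameter[i],
                           paste(panel$parameter[i], comps, sep = ".")),
      parameter = panel$parameter[i],
      class = panel$class[i],
      compartment = comps,
      value_kind = panel$value_kind[i],
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Construct a phenotype profile
#'
#' A profile is a named cluster archetype: a distribution of disease
#' severities (as expected-count weights) plus per-parameter locations and
#' dispersions on each parameter's natural scale (percent for cell
#' frequencies, concentration units for mediators, probability for binary
#' flags).
#'
#' @param name profile label.
#' @param severity_weights named numeric vector over
#'   `c("healthy","mild","moderate","severe")`; used as relative
#'   expected counts when subjects are allocated.
#' @param means named numeric vector of parameter locations.
#' @param dispersions named numeric vector of parameter dispersions
#'   (log10 SD for concentrations, logit-scale SD for percentages,
#'   absolute SD for scores; ignored for binary/count parameters).
#' @return an object of class `"phenotype_profile"`.
#' @export
phenotype_profile <- function(name, severity_weights, means, dispersions) {
  stopifnot(is.character(name), length(name) == 1L,
            all(names(severity_weights) %in%
                  c("healthy", "mild", "moderate", "severe")),
            all(severity_weights >= 0), sum(severity_weights) > 0)
  structure(list(name = name, severity_weights = severity_weights,
                 means = means, dispersions = dispersions),
            class = "phenotype_profile")
}

# Baseline (healthy) locations and dispersions for the default panel.
# Percentages are percent of parent population, concentrations are pg/mL
# (mediators), ng/mL (proteases, IgE as IU/mL), nmol/L (vitamin D) or
# 10^9/L (blood eosinophils); dispersions are on the generator's
# analysis scale at unit noise_scale.
baseline_means <- function() {
  c(TH1_cells = 2.0, TH2_IL13_cells = 0.5, TH17_cells = 0.5,
    Treg_cells = 8.0, TC1_cells = 2.0, TC2_cells = 1.0,
    gd17_cells = 0.3, MAIT_cells = 4.0,
    eosinophils = 0.5, neutrophils = 31, macrophages = 52,
    lymphocytes = 1.0,
    IL4 = 0.02, IL5 = 0.01, IL13 = 0.005, IFNg = 0.2, IL2 = 0.05,
    IL12p70 = 0.05, IL10 = 0.05, IL17A = 0.008,
    tryptase = 5, chymase = 1, CPA3 = 1, basogranulin = 2,
    eNO = 16, vitamin_D = 60,
    age = 28, sex_female = 0.45, BMI = 24.5, atopy = 0.05,
    FEV1_pct = 108, FEV1_reversibility = 3.3, PEFR_pct = 108,
    PEFR_variability = 2, ACQ = 0.15, GINA_step = 0, GINA_control = 0,
    ICS_dose = 0, OCS_maintenance = 0.01, IgE = 26,
    asthma_duration = 0, onset_age = 0, allergic_rhinitis = 0.02,
    nasal_polyps = 0.01, eczema = 0.05, salicylate_sensitivity = 0.01,
    pack_years = 0.5, blood_eos_count = 0.1, skin_test_positives = 0.2,
    SABA_use = 0.01, LABA_use = 0.01, LTRA_use = 0.01)
}

baseline_dispersions <- function() {
  disp <- c(age = 8, BMI = 2.5, FEV1_pct = 6, FEV1_reversibility = 1.5,
            PEFR_pct = 7, PEFR_variability = 2, ACQ = 0.3,
            GINA_step = 0.25, GINA_control = 0.25, ICS_dose = 60,
            asthma_duration = 1, onset_age = 1, pack_years = 1.5,
            eNO = 4)
  kinds <- split(default_panel()$parameter, default_panel()$value_kind)
  disp[setdiff(kinds$concentration, names(disp))] <- 1.5 # log10 SD
  disp[setdiff(kinds$percentage, names(disp))] <- 0.4    # logit SD
  disp[setdiff(kinds$score, names(disp))] <- 1
  disp[kinds$binary] <- 0
  disp[kinds$count] <- 2.5
  disp
}

# Overrides shared by all asthma profiles (generic asthma drift relative
# to health); each cluster profile then overrides its own signature.
asthma_base_overrides <- function() {
  c(atopy = 0.95, allergic_rhinitis = 0.9, SABA_use = 0.97, ACQ = 1.0,
    FEV1_pct = 90, FEV1_reversibility = 12, PEFR_pct = 95,
    PEFR_variability = 18, asthma_duration = 20, onset_age = 12,
    IgE = 120, eNO = 30, skin_test_positives = 3, blood_eos_count = 0.2,
    eosinophils = 2, GINA_step = 2, GINA_control = 1, IFNg = 0.15)
}

#' Default planted phenotype profiles
#'
#' Seven archetypes: one healthy profile and six asthma cluster profiles
#' with ordinal fidelity to the published cluster descriptions — e.g. a
#' mild-atopic cluster with high IL-13-secreting TH2 cells but low IL-13
#' and tryptase and a paucigranulocytic sputum; a severe, obese,
#' predominantly female, nonatopic cluster with profound MAIT-cell
#' deficiency and high carboxypeptidase A3 and tryptase. Locations encode
#' which cluster is high or low in which parameter; they are not the real
#' cohort's medians, which were never deposited.
#'
#' @param panel panel data.frame; defaults to [default_panel()].
#' @return list of seven [phenotype_profile()] objects.
#' @export
default_profiles <- function(panel = default_panel()) {
  base <- baseline_means()
  disp <- baseline_dispersions()
  ab <- asthma_base_overrides()
  mk <- function(name, severity, overrides = c(), disp_over = c()) {
    m <- base
    if (name != "healthy") m[names(ab)] <- ab
    m[names(overrides)] <- overrides
    d <- disp
    d[names(disp_over)] <- disp_over
    phenotype_profile(name, severity, m, d)
  }
  list(
    mk("healthy", c(healthy = 18)),
    # mild atopic: TH2-cell high but mediator-low, paucigranulocytic,
    # steroid-naive, atopic-march comorbidity
    mk("cluster1", c(mild = 8),
       c(TH2_IL13_cells = 2.5, IL13 = 0.002, tryptase = 2,
         neutrophils = 22, eosinophils = 0.8, FEV1_pct = 95, ACQ = 0.88,
         eNO = 45, GINA_step = 1, IgE = 172, MAIT_cells = 3.2,
         GINA_control = 0.5, atopy = 0.97, allergic_rhinitis = 0.95,
         eczema = 0.95, skin_test_positives = 6, macrophages = 49)),
    # well controlled on low-dose ICS; eosinophilia the only
    # inflammatory signal; Treg and TC1 low
    mk("cluster2", c(mild = 3, moderate = 3),
       c(ACQ = 0.5, eosinophils = 6, blood_eos_count = 0.4,
         Treg_cells = 4.5, TC1_cells = 0.7, ICS_dose = 300,
         FEV1_pct = 95, FEV1_reversibility = 6, eNO = 18, IgE = 40,
         GINA_control = 0.3, allergic_rhinitis = 0.05,
         MAIT_cells = 3.5, macrophages = 48)),
    # moderate, partially controlled, type-2 high: top IL-5/IL-13,
    # reversibility and eNO; broad T-cell activation
    mk("cluster3", c(moderate = 8),
       c(FEV1_reversibility = 20, eNO = 70, IL5 = 0.6, IL13 = 0.3,
         IL4 = 0.06, TH2_IL13_cells = 1.6, TH1_cells = 3.5,
         TH17_cells = 1.2, Treg_cells = 10, eosinophils = 5,
         ICS_dose = 500, GINA_step = 3, ACQ = 1.2, GINA_control = 1.2,
         LABA_use = 0.95, MAIT_cells = 3.0, macrophages = 45)),
    # small later-onset group: nasal polyposis, salicylate sensitivity,
    # low IL-17, nonatopic
    mk("cluster4", c(moderate = 3, severe = 1),
       c(onset_age = 28, nasal_polyps = 0.95, salicylate_sensitivity = 0.95,
         IL17A = 0.002, ICS_dose = 800, GINA_step = 3, ACQ = 1.4,
         FEV1_pct = 85, age = 45, atopy = 0.1, allergic_rhinitis = 0.1,
         eosinophils = 0.6, eNO = 20, LABA_use = 0.95, LTRA_use = 0.95,
         skin_test_positives = 1, MAIT_cells = 2.5, macrophages = 42)),
    # older, obese, high-treatment type-2 high: mast cell mediators and
    # TC2 up, Treg down, neutrophilic sputum
    mk("cluster5", c(moderate = 3, severe = 6),
       c(age = 50, BMI = 32.6, FEV1_pct = 70, PEFR_pct = 72, ACQ = 2.1,
         ICS_dose = 1500, GINA_step = 4.5, GINA_control = 2,
         IL5 = 0.45, IL13 = 0.2, IL4 = 0.05, IL10 = 0.03, IFNg = 0.1,
         TC2_cells = 3.0, tryptase = 22, chymase = 6, CPA3 = 8,
         basogranulin = 6, Treg_cells = 5.0, neutrophils = 58,
         eosinophils = 5, MAIT_cells = 1.2, LABA_use = 0.95,
         LTRA_use = 0.95, blood_eos_count = 0.3, asthma_duration = 30,
         macrophages = 35, lymphocytes = 0.6, vitamin_D = 45,
         pack_years = 8)),
    # most severe: female, obese, nonatopic, OCS-dependent; profound
    # MAIT deficiency, CPA3/tryptase high, type-2 cytokines low
    mk("cluster6", c(severe = 9),
       c(sex_female = 0.9, BMI = 35, atopy = 0.05,
         allergic_rhinitis = 0.05, salicylate_sensitivity = 0.95,
         onset_age = 25, ACQ = 3.2, FEV1_pct = 62, PEFR_pct = 60,
         GINA_step = 5, GINA_control = 2, ICS_dose = 1800,
         OCS_maintenance = 0.95, CPA3 = 12, tryptase = 20, chymase = 6,
         MAIT_cells = 0.3, TC1_cells = 0.5, TH17_cells = 0.15,
         TH2_IL13_cells = 0.15, neutrophils = 66, eosinophils = 0.8,
         Treg_cells = 5.3, age = 48, IgE = 60, LABA_use = 0.95,
         LTRA_use = 0.95, IL10 = 0.02, IFNg = 0.08, macrophages = 30,
         lymphocytes = 0.4, vitamin_D = 35, pack_years = 6,
         skin_test_positives = 0.3))
  )
}
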