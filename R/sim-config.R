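#' Simulation configuration for the synthetic registers
#'
#' Builds and validates the configuration driving [simulate_registers()].
#' The defaults encode the study conditions the generator emulates: an
#' incident adult SLE population diagnosed between 1 July 2005 and
#' 1 September 2021 with register follow-up through 31 January 2024, a
#' female fraction of 0.825, and per-calendar-cohort treatment parameters
#' calibrated so that the cohort medians of 5-year cumulative
#' glucocorticoid dose (7500/7000/6500 mg for the first three cohorts) and
#' of hydroxychloroquine coverage reproduce the published register
#' marginals.
#'
#' @param n_persons number of persons to simulate (cases plus background
#'   non-cases).
#' @param seed integer master seed; the population, visit and dispensation
#'   stages use `seed`, `seed + 1L` and `seed + 2L` so each stage is
#'   reproducible in isolation.
#' @param study_start,study_end first and last admissible date of a first
#'   SLE-coded visit.
#' @param data_end administrative end of register coverage.
#' @param case_fraction probability that a person is an SLE case.
#' @param prevalent_fraction probability that a case has an SLE-coded
#'   visit before `study_start` (exercises the washout filter).
#' @param recent_immigrant_fraction probability that a case immigrated
#'   less than two years before diagnosis (exercises the residency filter).
#' @param underage_fraction probability that a case is younger than 18 at
#'   diagnosis (exercises the adult filter).
#' @param death_hazard,emigration_hazard yearly rates of the two censoring
#'   processes ending registration after diagnosis.
#' @param cohort_effects named list (one element per calendar cohort label
#'   `r toString(COHORT_LABELS)`) of treatment parameters:
#'   `gc_use_prob` (probability of any oral GC after diagnosis),
#'   `gc_continuation_prob` (yearly probability of staying on GC),
#'   `gc_median_5yr_dose_mg` (median cumulative prednisolone-equivalent
#'   dose over 5 years among GC users), `gc_scale` (log-normal sigma of
#'   that dose), `hcq_initiation_prob`, `hcq_discontinuation_hazard`
#'   (per-year) and `is_use_prob`.
#' @param demography list with `female_prob`, `age_mean`, `age_sd`,
#'   `age_min`, `age_max`, `non_nordic_prob`,
#'   `birth_region_missing_prob` and `education_probs` (named,
#'   sums to 1 over `r toString(EDUCATION_LEVELS)`).
#' @param utilization list with `hosp_prob` (probability of any
#'   hospitalization in the pre-diagnosis year for a person of average
#'   severity), `hosp_days_meanlog`, `hosp_days_sdlog` (log-normal stay
#'   length), `outpatient_mu` and `outpatient_size` (negative-binomial
#'   pre-diagnosis specialist visit count).
#'
#' @return an object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_persons = 100, seed = 1)
#' cfg$demography$female_prob
#' @export
sim_config <- function(n_persons,
                       seed = 1L,
                       study_start = as.Date("2005-07-01"),
                       study_end = as.Date("2021-09-01"),
                       data_end = as.Date("2024-01-31"),
                       case_fraction = 0.8,
                       prevalent_fraction = 0.10,
                       recent_immigrant_fraction = 0.02,
                       underage_fraction = 0.01,
                       death_hazard = 0.02,
                       emigration_hazard = 0.005,
                       cohort_effects = default_cohort_effects(),
                       demography = default_demography(),
                       utilization = default_utilization()) {
  cfg <- list(
    n_persons = n_persons, seed = as.integer(seed),
    study_start = as.Date(study_start), study_end = as.Date(study_end),
    data_end = as.Date(data_end),
    case_fraction = case_fraction,
    prevalent_fraction = prevalent_fraction,
    recent_immigrant_fraction = recent_immigrant_fraction,
    underage_fraction = underage_fraction,
    death_hazard = death_hazard, emigration_hazard = emigration_hazard,
    cohort_effects = cohort_effects,
    demography = demography, utilization = utilization
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @export
default_cohort_effects <- function() {
  # gc_use_prob / gc_continuation_prob reproduce the published year-1 and
  # year-5 any-GC proportions; medians and hazards reproduce the published
  # 5-year cumulative-dose and HCQ-coverage medians (see methods vignette)
  list(
    "2005-2008" = list(gc_use_prob = 0.680, gc_continuation_prob = 0.944,
                       gc_median_5yr_dose_mg = 7500, gc_scale = 1.0,
                       hcq_initiation_prob = 0.442,
                       hcq_discontinuation_hazard = 0.263,
                       is_use_prob = 0.50),
    "2009-2012" = list(gc_use_prob = 0.731, gc_continuation_prob = 0.908,
                       gc_median_5yr_dose_mg = 7000, gc_scale = 1.0,
                       hcq_initiation_prob = 0.639,
                       hcq_discontinuation_hazard = 0.197,
                       is_use_prob = 0.55),
    "2013-2016" = list(gc_use_prob = 0.731, gc_continuation_prob = 0.892,
                       gc_median_5yr_dose_mg = 6500, gc_scale = 1.0,
                       hcq_initiation_prob = 0.730,
                       hcq_discontinuation_hazard = 0.171,
                       is_use_prob = 0.57),
    "2017-2021" = list(gc_use_prob = 0.683, gc_continuation_prob = 0.885,
                       gc_median_5yr_dose_mg = 6000, gc_scale = 1.0,
                       hcq_initiation_prob = 0.802,
                       hcq_discontinuation_hazard = 0.140,
                       is_use_prob = 0.60)
  )
}

#' @rdname sim_config
#' @export
default_demography <- function() {
  list(female_prob = 0.825,
       age_mean = 48.8, age_sd = 18.1, age_min = 18, age_max = 96,
       non_nordic_prob = 0.155, birth_region_missing_prob = 0.014,
       education_probs = c("0-9y" = 0.220, "10-12y" = 0.436,
                           ">=13y" = 0.337, "missing" = 0.007))
}

#' @rdname sim_config
#' @export
default_utilization <- function() {
  list(hosp_prob = 0.37, hosp_days_meanlog = log(5), hosp_days_sdlog = 1.3,
       outpatient_mu = 4, outpatient_size = 1.2)
}

validate_sim_config <- function(cfg) {
  if (!is.numeric(cfg$n_persons) || length(cfg$n_persons) != 1L ||
      is.na(cfg$n_persons) || cfg$n_persons < 1 ||
      cfg$n_persons != round(cfg$n_persons))
    stop_cfg("n_persons", "must be a positive integer")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L || is.na(cfg$seed))
    stop_cfg("seed", "must be a single integer")
  if (!(cfg$study_start < cfg$study_end))
    stop_cfg("study_start/study_end", "must satisfy start < end")
  if (!(cfg$study_end < cfg$data_end))
    stop_cfg("study_end/data_end", "must satisfy study_end < data_end")
  for (f in c("case_fraction", "prevalent_fraction",
              "recent_immigrant_fraction", "underage_fraction"))
    check_prob(cfg[[f]], f)
  check_nonneg(cfg$death_hazard, "death_hazard")
  check_nonneg(cfg$emigration_hazard, "emigration_hazard")

  if (!identical(sort(names(cfg$cohort_effects)), sort(COHORT_LABELS)))
    stop_cfg("cohort_effects",
             paste("must have one element per calendar cohort:",
                   toString(COHORT_LABELS)))
  for (lab in names(cfg$cohort_effects)) {
    eff <- cfg$cohort_effects[[lab]]
    check_prob(eff$gc_use_prob, paste0("cohort_effects$`", lab, "`$gc_use_prob"))
    check_prob(eff$gc_continuation_prob,
               paste0("cohort_effects$`", lab, "`$gc_continuation_prob"))
    check_pos(eff$gc_median_5yr_dose_mg,
              paste0("cohort_effects$`", lab, "`$gc_median_5yr_dose_mg"))
    check_pos(eff$gc_scale, paste0("cohort_effects$`", lab, "`$gc_scale"))
    check_prob(eff$hcq_initiation_prob,
               paste0("cohort_effects$`", lab, "`$hcq_initiation_prob"))
    check_nonneg(eff$hcq_discontinuation_hazard,
                 paste0("cohort_effects$`", lab, "`$hcq_discontinuation_hazard"))
    check_prob(eff$is_use_prob, paste0("cohort_effects$`", lab, "`$is_use_prob"))
  }

  dem <- cfg$demography
  check_prob(dem$female_prob, "demography$female_prob")
  check_prob(dem$non_nordic_prob, "demography$non_nordic_prob")
  check_prob(dem$birth_region_missing_prob,
             "demography$birth_region_missing_prob")
  check_pos(dem$age_sd, "demography$age_sd")
  if (!(dem$age_min < dem$age_max))
    stop_cfg("demography$age_min/age_max", "must satisfy min < max")
  check_prob(dem$education_probs, "demography$education_probs")
  if (abs(sum(dem$education_probs) - 1) > 1e-8 ||
      !identical(sort(names(dem$education_probs)), sort(EDUCATION_LEVELS)))
    stop_cfg("demography$education_probs",
             paste("must be named probabilities over",
                   toString(EDUCATION_LEVELS), "summing to 1"))

  utl <- cfg$utilization
  check_prob(utl$hosp_prob, "utilization$hosp_prob")
  check_pos(utl$hosp_days_sdlog, "utilization$hosp_days_sdlog")
  check_pos(utl$outpatient_mu, "utilization$outpatient_mu")
  check_pos(utl$outpatient_size, "utilization$outpatient_size")
  cfg
}

#' Calendar cohort of a diagnosis date
#'
#' @param diagnosis_date Date vector.
#' @return factor with levels `r toString(COHORT_LABELS)` (`NA` outside
#'   2005--2021).
#' @export
calendar_cohort <- function(diagnosis_date) {
  yr <- as.integer(format(as.Date(diagnosis_date), "%Y"))
  lab <- rep(NA_character_, length(yr))
  lab[yr >= 2005 & yr <= 2008] <- "2005-2008"
  lab[yr >= 2009 & yr <= 2012] <- "2009-2012"
  lab[yr >= 2013 & yr <= 2016] <- "2013-2016"
  lab[yr >= 2017 & yr <= 2021] <- "2017-2021"
  factor(lab, levels = COHORT_LABELS)
}
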