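# Incident-cohort construction
#
# Case definition: at least two SLE-coded visits (ICD-10 M32.1/M32.8/
# M32.9) within 365 days, with at least one of the person's SLE-coded
# visits at a specialist department; the candidate diagnosis date is the
# first SLE-coded visit ever recorded.  Incidence filters (in order):
# first SLE-coded visit not after the window end, not before the window
# start (washout of prevalent disease), at least 2 years of residency
# before diagnosis, age 18 or older at diagnosis, and at least 1 year of
# register follow-up.

split_icd <- function(icd_codes) strsplit(icd_codes, ";", fixed = TRUE)

#' Find SLE case candidates in a visit table
#'
#' @param visits visit table (`person_id`, `visit_date`, `icd_codes` as a
#'   ";"-separated string, `department`, ...).
#' @param sle_codes ICD-10 codes counting as SLE-coded.
#' @param specialist_departments departments counting as specialist care.
#' @param max_gap_days maximum days between the two qualifying visits
#'   ("within 1 year").
#' @return `data.table` with one row per qualifying person: `person_id`,
#'   `candidate_date` (first SLE-coded visit), `n_sle_visits`.
#'   Malformed ICD entries are ignored with a warning.
#' @examples
#' v <- data.table::data.table(
#'   person_id = "A",
#'   visit_date = as.Date(c("2010-03-01", "2010-09-01")),
#'   icd_codes = "M32.9",
#'   department = c("rheumatology", "other"))
#' find_case_candidates(v)
#' @export
find_case_candidates <- function(visits,
                                 sle_codes = SLE_ICD10,
                                 specialist_departments = SPECIALIST_DEPARTMENTS,
                                 max_gap_days = CASE_PAIR_MAX_GAP_DAYS) {
  visits <- as.data.table(visits)
  codes <- split_icd(visits$icd_codes)
  bad <- vapply(codes, function(x) any(!grepl("^[A-Z][0-9]{2}(\\.[0-9A-Z]+)?$", x)),
                logical(1))
  if (any(bad)) {
    warning(sum(bad), " visit(s) carry malformed ICD codes; those codes are ignored")
    codes[bad] <- lapply(codes[bad],
                         function(x) x[grepl("^[A-Z][0-9]{2}(\\.[0-9A-Z]+)?$", x)])
  }
  is_sle <- vapply(codes, function(x) any(x %in% sle_codes), logical(1))
  sle <- visits[is_sle]
  if (nrow(sle) == 0L)
    return(data.table(person_id = character(),
                      candidate_date = as.Date(character()),
                      n_sle_visits = integer()))
  setorder(sle, person_id, visit_date)
  sle[, specialist := department %in% specialist_departments]
  cand <- sle[, .(
    candidate_date = visit_date[1L],
    n_sle_visits = .N,
    # two SLE-coded visits within the gap: check consecutive visit dates
    pair_ok = .N >= 2L &&
      min(diff(as.numeric(visit_date))) <= max_gap_days,
    specialist_ok = any(specialist)
  ), by = person_id]
  cand[pair_ok == TRUE & specialist_ok == TRUE,
       .(person_id, candidate_date, n_sle_visits)]
}

#' Apply incidence filters and build cohort entries
#'
#' Filters candidates in a fixed order so exclusion counts are
#' reproducible: (1) first SLE-coded visit after the window end,
#' (2) first SLE-coded visit before the window start (prevalent disease,
#' washout), (3) residency started less than 2 years before diagnosis,
#' (4) younger than 18 at diagnosis, (5) less than 1 year of follow-up.
#'
#' @param candidates output of [find_case_candidates()].
#' @param persons population table.
#' @param study_start,study_end inclusion window for the first SLE-coded
#'   visit.
#' @param data_end administrative end of follow-up.
#' @return list with `cohort` (one `CohortEntry` row per retained person:
#'   diagnosis date, calendar cohort, age, demographics, follow-up) and
#'   `exclusions` (`data.table` of reason/count in application order, plus
#'   the retained count).
#' @export
apply_incidence_filters <- function(candidates, persons,
                                    study_start = as.Date("2005-07-01"),
                                    study_end = as.Date("2021-09-01"),
                                    data_end = as.Date("2024-01-31")) {
  candidates <- as.data.table(candidates)
  persons <- as.data.table(persons)
  missing_ids <- setdiff(candidates$person_id, persons$person_id)
  if (length(missing_ids) > 0)
    stop("persons referenced by visits but absent from the population table: ",
         toString(head(missing_ids, 10)))

  x <- merge(candidates, persons, by = "person_id")
  x[, diagnosis_date := candidate_date]
  x[, age_at_diagnosis := as.numeric(diagnosis_date - birth_date) / YEAR_DAYS]

  n0 <- nrow(x)
  drop_after <- x[diagnosis_date > study_end]
  x <- x[diagnosis_date <= study_end]
  drop_prev <- x[diagnosis_date < study_start]
  x <- x[diagnosis_date >= study_start]
  drop_resid <- x[residency_start > diagnosis_date - RESIDENCY_MIN_DAYS]
  x <- x[residency_start <= diagnosis_date - RESIDENCY_MIN_DAYS]
  drop_age <- x[age_at_diagnosis < 18]
  x <- x[age_at_diagnosis >= 18]
  drop_fu <- x[registration_end < diagnosis_date + FOLLOWUP_MIN_DAYS]
  x <- x[registration_end >= diagnosis_date + FOLLOWUP_MIN_DAYS]

  exclusions <- data.table(
    reason = c("first_sle_visit_after_window",
               "prevalent_case_washout",
               "residency_under_2_years",
               "age_under_18",
               "followup_under_1_year",
               "retained"),
    n = c(nrow(drop_after), nrow(drop_prev), nrow(drop_resid),
          nrow(drop_age), nrow(drop_fu), nrow(x)))
  stopifnot(sum(exclusions$n) == n0)

  cohort <- x[, .(
    person_id, diagnosis_date,
    calendar_cohort = calendar_cohort(diagnosis_date),
    age_at_diagnosis,
    age_category = cut(age_at_diagnosis, c(18, 40, 60, Inf),
                       labels = AGE_CATEGORIES, right = FALSE),
    sex = factor(sex, c("female", "male")),
    education = factor(education, EDUCATION_LEVELS),
    birth_region = factor(birth_region, BIRTH_REGIONS),
    follow_up_end = pmin(registration_end, data_end))]
  cohort[, follow_up_years := as.numeric(follow_up_end - diagnosis_date) /
           YEAR_DAYS]
  setorder(cohort, person_id)
  list(cohort = cohort[], exclusions = exclusions)
}

#' Derive pre-diagnosis utilization covariates and diagnosis hospital
#'
#' `prior_hospital_days` sums inpatient days from stays admitted in the
#' 365 days before diagnosis, each stay contributing
#' `min(discharge, diagnosis) - admission` days (stays running past the
#' diagnosis are clipped at it).  `prior_outpatient_visits` counts
#' non-inpatient specialist visits in the same window.
#' `diagnosis_hospital` is the hospital type of the first SLE-coded
#' visit.
#'
#' @param cohort cohort table from [apply_incidence_filters()].
#' @param visits the visit table.
#' @param specialist_departments departments counting as specialist care.
#' @param sle_codes ICD-10 codes counting as SLE-coded.
#' @return the cohort with `prior_hospital_days`, `prior_hospital_cat`,
#'   `prior_outpatient_visits`, `prior_outpatient_cat` and
#'   `diagnosis_hospital` added.
#' @export
derive_covariates <- function(cohort, visits,
                              specialist_departments = SPECIALIST_DEPARTMENTS,
                              sle_codes = SLE_ICD10) {
  cohort <- copy(as.data.table(cohort))
  visits <- as.data.table(visits)
  v <- merge(visits, cohort[, .(person_id, diagnosis_date)],
             by = "person_id")

  inp <- v[inpatient == TRUE &
           visit_date >= diagnosis_date - 365 & visit_date < diagnosis_date]
  inp[, stay_days := as.numeric(pmin(discharge_date, diagnosis_date) -
                                  visit_date)]
  hosp <- inp[, .(prior_hospital_days = sum(stay_days)), by = person_id]

  outp <- v[inpatient == FALSE &
            department %in% specialist_departments &
            visit_date >= diagnosis_date - 365 & visit_date < diagnosis_date,
            .(prior_outpatient_visits = .N), by = person_id]

  sle_flag <- vapply(split_icd(v$icd_codes),
                     function(x) any(x %in% sle_codes), logical(1))
  first_sle <- v[sle_flag][order(visit_date),
                           .(diagnosis_hospital = hospital_type[1L]),
                           by = person_id]

  for (tab in list(hosp, outp, first_sle))
    cohort <- merge(cohort, tab, by = "person_id", all.x = TRUE)
  cohort[is.na(prior_hospital_days), prior_hospital_days := 0]
  cohort[is.na(prior_outpatient_visits), prior_outpatient_visits := 0L]
  cohort[, prior_hospital_cat := cut(prior_hospital_days, c(-Inf, 0, 7, Inf),
                                     labels = HOSPDAYS_CATEGORIES)]
  cohort[, prior_outpatient_cat := cut(prior_outpatient_visits,
                                       c(-Inf, 2, 6, Inf),
                                       labels = OUTPATIENT_CATEGORIES)]
  cohort[, diagnosis_hospital := factor(diagnosis_hospital, HOSPITAL_TYPES)]
  setorder(cohort, person_id)
  cohort[]
}

#' Build the incident cohort from register tables
#'
#' Convenience wrapper: [find_case_candidates()] then
#' [apply_incidence_filters()] then [derive_covariates()].
#'
#' @inheritParams apply_incidence_filters
#' @inheritParams find_case_candidates
#' @return list with `cohort`, `exclusions` and `candidates`.
#' @examples
#' sim <- simulate_registers(sim_config(n_persons = 300, seed = 1))
#' built <- build_cohort(sim$population, sim$visits)
#' built$exclusions
#' @export
build_cohort <- function(persons, visits,
                         study_start = as.Date("2005-07-01"),
                         study_end = as.Date("2021-09-01"),
                         data_end = as.Date("2024-01-31"),
                         sle_codes = SLE_ICD10,
                         specialist_departments = SPECIALIST_DEPARTMENTS) {
  candidates <- find_case_candidates(visits, sle_codes,
                                     specialist_departments)
  res <- apply_incidence_filters(candidates, persons, study_start,
                                 study_end, data_end)
  cohort <- derive_covariates(res$cohort, visits, specialist_departments,
                              sle_codes)
  list(cohort = cohort, exclusions = res$exclusions,
       candidates = candidates)
}
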