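# Synthetic register generation
#
# The three stages mirror the register linkage the package analyses: a
# population table (Total Population Register shape), a care-visit table
# (National Patient Register shape) and a dispensation table (Prescribed
# Drug Register shape).  Every case is generated with explicit
# ground-truth flags for each eligibility filter and with known treatment
# parameters so downstream estimates can be validated by parameter
# recovery.

# minimum follow-up required after diagnosis, days ("at least 1 year")
FOLLOWUP_MIN_DAYS <- 365
# minimum pre-diagnosis residency, days ("at least 2 years")
RESIDENCY_MIN_DAYS <- 730
# maximum gap between the two qualifying SLE-coded visits, days
CASE_PAIR_MAX_GAP_DAYS <- 365

# internal realism constants (not part of the user-facing configuration):
# fractions of non-cases given near-miss SLE histories, fraction of cases
# with first onset after the inclusion window, GC year-over-year dose
# taper, and the share of GC users on methylprednisolone rather than
# prednisolone
NONCASE_SINGLE_SLE_VISIT_FRAC <- 0.04
NONCASE_WIDE_PAIR_FRAC <- 0.02
CASE_LATE_ONSET_FRAC <- 0.01
GC_DOSE_TAPER <- 0.55
GC_METHYLPRED_FRAC <- 0.10
BACKGROUND_ICD <- c("I10", "E11.9", "N18.3", "M79.1", "J45.9")

#' Generate the synthetic population table
#'
#' Draws demographics, residency and registration intervals for
#' `config$n_persons` persons.  Case status, diagnosis dates and latent
#' severity are drawn here as well and carried as the `"latent"` attribute
#' consumed by [generate_visits()]; the returned columns are only those a
#' population register would hold.
#'
#' @param config a [sim_config()] object.
#' @return `data.table` with columns `person_id`, `sex`, `birth_date`,
#'   `birth_region`, `education`, `residency_start`, `registration_end`,
#'   plus a `"latent"` attribute.
#' @export
generate_population <- function(config) {
  config <- validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_persons
  dem <- config$demography

  lat <- data.table(person_id = sprintf("P%06d", seq_len(n)))
  lat[, is_case := runif(n) < config$case_fraction]
  lat[, severity := rlnorm(n, 0, 0.5)]

  # index date: candidate first SLE-coded visit for cases, an arbitrary
  # reference date for background persons
  span <- as.numeric(config$study_end - config$study_start)
  lat[, index_date := config$study_start + floor(runif(n, 0, span + 1))]

  # cases violating individual filters, to exercise every exclusion path
  lat[, prevalent := is_case & runif(n) < config$prevalent_fraction]
  lat[, late_onset := is_case & !prevalent & runif(n) < CASE_LATE_ONSET_FRAC]
  late_gap <- as.numeric(config$data_end - config$study_end) - 30
  lat[late_onset == TRUE,
      index_date := config$study_end + ceiling(runif(.N, 1, late_gap))]
  lat[, underage_draw := is_case & runif(n) < config$underage_fraction]
  lat[, recent_immigrant := is_case & runif(n) < config$recent_immigrant_fraction]

  # age at the index date: truncated normal on [age_min, age_max]
  lo <- pnorm(dem$age_min, dem$age_mean, dem$age_sd)
  hi <- pnorm(dem$age_max, dem$age_mean, dem$age_sd)
  lat[, age := qnorm(runif(n, lo, hi), dem$age_mean, dem$age_sd)]
  lat[underage_draw == TRUE, age := runif(.N, 8, 17.5)]

  # onset for prevalent cases predates the inclusion window by up to the
  # 4.5-year washout span
  lat[, onset_date := index_date]
  lat[prevalent == TRUE,
      onset_date := config$study_start - ceiling(runif(.N, 30, 4.5 * YEAR_DAYS))]

  lat[, sex := fifelse(runif(n) < dem$female_prob, "female", "male")]
  u <- runif(n)
  lat[, birth_region := fcase(
    u < dem$non_nordic_prob, "non-Nordic",
    u < dem$non_nordic_prob + dem$birth_region_missing_prob, "missing",
    default = "Nordic")]
  lat[recent_immigrant == TRUE, birth_region := "non-Nordic"]
  lat[, education := sample(names(dem$education_probs), n, replace = TRUE,
                            prob = dem$education_probs)]

  lat[, birth_date := onset_date - round(age * YEAR_DAYS)]
  lat[, residency_start := birth_date]
  lat[birth_region == "non-Nordic" & !recent_immigrant,
      residency_start := pmax(birth_date,
                              onset_date - round(runif(.N, 3, 30) * YEAR_DAYS))]
  lat[recent_immigrant == TRUE,
      residency_start := onset_date - round(runif(.N, 30, RESIDENCY_MIN_DAYS - 30))]

  # censoring by death or emigration after the index date
  haz_day <- (config$death_hazard + config$emigration_hazard) / YEAR_DAYS
  cens <- if (haz_day > 0) round(rexp(n, haz_day)) else rep(Inf, n)
  lat[, registration_end := pmin(config$data_end, onset_date + cens)]

  # filter flags re-derived from the realized dates so they agree with
  # the cohort builder's arithmetic exactly
  lat[, in_window := onset_date >= config$study_start &
                     onset_date <= config$study_end]
  lat[, underage := (as.numeric(onset_date - birth_date) / YEAR_DAYS) < 18]
  lat[, short_residency := residency_start >
        onset_date - RESIDENCY_MIN_DAYS]
  lat[, insufficient_followup := registration_end <
        onset_date + FOLLOWUP_MIN_DAYS]
  lat[, eligible := is_case & in_window & !prevalent & !short_residency &
                    !underage & !insufficient_followup]

  persons <- lat[, .(person_id, sex, birth_date, birth_region, education,
                     residency_start, registration_end)]
  setattr(persons, "latent", lat)
  persons[]
}

#' Generate the synthetic care-visit table
#'
#' Every case receives two SLE-coded visits within
#' `r CASE_PAIR_MAX_GAP_DAYS` days of onset, at least one at a specialist
#' department; prevalent cases receive that pair before the study window
#' plus an SLE-coded visit inside it.  A small fraction of non-cases
#' receive near-miss histories (a single SLE-coded visit, or a pair more
#' than a year apart).  Pre-diagnosis healthcare utilization
#' (hospitalization stays and specialist outpatient visits in the year
#' before the index date) is drawn correlated with latent severity.
#'
#' @param persons output of [generate_population()] (must carry its
#'   `"latent"` attribute).
#' @param config the same [sim_config()] object.
#' @return list with `visits` (`data.table`: `person_id`, `visit_date`,
#'   `icd_codes` (";"-separated), `department`, `hospital_type`,
#'   `inpatient`, `discharge_date`) and `ground_truth` (one row per
#'   person: case status, per-filter flags, true diagnosis date, calendar
#'   cohort, severity).
#' @export
generate_visits <- function(persons, config) {
  config <- validate_sim_config(config)
  if (nrow(persons) == 0L) stop("'persons' must be non-empty")
  lat <- attr(persons, "latent")
  if (is.null(lat))
    stop("'persons' must come from generate_population() (latent attribute missing)")
  set.seed(config$seed + 1L)

  lat <- copy(lat)
  n <- nrow(lat)
  lat[, hospital_type := fifelse(runif(n) < 0.489, "university", "other")]

  sle_dept_probs <- c(rheumatology = 0.55, dermatology = 0.08,
                      nephrology = 0.07, internal_medicine = 0.15,
                      paediatrics = 0, other = 0.15)
  draw_sle_dept <- function(m, underage) {
    d <- sample(names(sle_dept_probs), m, replace = TRUE, prob = sle_dept_probs)
    d[underage] <- "paediatrics"
    d
  }
  draw_icd <- function(m) {
    code <- sample(SLE_ICD10, m, replace = TRUE, prob = c(0.15, 0.15, 0.70))
    extra <- runif(m) < 0.2
    code[extra] <- paste(code[extra],
                         sample(BACKGROUND_ICD, sum(extra), replace = TRUE),
                         sep = ";")
    code
  }

  cases <- lat[is_case == TRUE]
  nc <- nrow(cases)
  pieces <- list()

  if (nc > 0) {
    # qualifying pair anchored at onset
    gap <- pmin(round(runif(nc, 14, 300)),
                pmax(7, as.numeric(cases$registration_end - cases$onset_date)))
    d1 <- draw_sle_dept(nc, cases$underage)
    d2 <- draw_sle_dept(nc, cases$underage)
    force_spec <- d1 == "other" & d2 == "other"
    d2[force_spec] <- "rheumatology"
    pieces$pair <- data.table(
      person_id = rep(cases$person_id, 2L),
      visit_date = c(cases$onset_date, cases$onset_date + gap),
      icd_codes = draw_icd(2L * nc),
      department = c(d1, d2),
      hospital_type = rep(cases$hospital_type, 2L))

    # prevalent cases resurface inside the window
    prev <- cases[prevalent == TRUE]
    if (nrow(prev) > 0)
      pieces$prevalent_return <- data.table(
        person_id = prev$person_id,
        visit_date = prev$index_date,
        icd_codes = draw_icd(nrow(prev)),
        department = draw_sle_dept(nrow(prev), prev$underage),
        hospital_type = prev$hospital_type)

    # later SLE-coded follow-up visits
    n_extra <- rpois(nc, 1.2)
    idx <- rep(seq_len(nc), n_extra)
    if (length(idx) > 0) {
      off <- round(runif(length(idx), 320, 5 * YEAR_DAYS))
      vd <- cases$onset_date[idx] + off
      keep <- vd <= cases$registration_end[idx]
      if (any(keep))
        pieces$followup <- data.table(
          person_id = cases$person_id[idx][keep],
          visit_date = vd[keep],
          icd_codes = draw_icd(sum(keep)),
          department = draw_sle_dept(sum(keep), cases$underage[idx][keep]),
          hospital_type = cases$hospital_type[idx][keep])
    }
  }

  # near-miss non-cases: single SLE visit, or a pair further apart than
  # the case definition allows
  noncases <- lat[is_case == FALSE]
  if (nrow(noncases) > 0) {
    u <- runif(nrow(noncases))
    single <- noncases[u < NONCASE_SINGLE_SLE_VISIT_FRAC]
    wide <- noncases[u >= NONCASE_SINGLE_SLE_VISIT_FRAC &
                     u < NONCASE_SINGLE_SLE_VISIT_FRAC + NONCASE_WIDE_PAIR_FRAC]
    if (nrow(single) > 0)
      pieces$single_sle <- data.table(
        person_id = single$person_id,
        visit_date = single$index_date,
        icd_codes = draw_icd(nrow(single)),
        department = draw_sle_dept(nrow(single), FALSE),
        hospital_type = single$hospital_type)
    if (nrow(wide) > 0) {
      wgap <- round(runif(nrow(wide), CASE_PAIR_MAX_GAP_DAYS + 35, 900))
      pieces$wide_pair <- data.table(
        person_id = rep(wide$person_id, 2L),
        visit_date = c(wide$index_date, wide$index_date + wgap),
        icd_codes = draw_icd(2L * nrow(wide)),
        department = draw_sle_dept(2L * nrow(wide), FALSE),
        hospital_type = rep(wide$hospital_type, 2L))
    }
  }

  # pre-index utilization: specialist outpatient visits ...
  utl <- config$utilization
  sev_mult <- lat$severity / exp(0.125)   # mean-one severity multiplier
  n_outp <- rnbinom(n, size = utl$outpatient_size,
                    mu = utl$outpatient_mu * sev_mult)
  n_outp[lat$is_case == FALSE] <- rnbinom(sum(!lat$is_case),
                                          size = utl$outpatient_size,
                                          mu = utl$outpatient_mu / 2)
  idx <- rep(seq_len(n), n_outp)
  if (length(idx) > 0) {
    m <- length(idx)
    spec <- runif(m) < 0.75
    dept <- ifelse(spec,
                   sample(SPECIALIST_DEPARTMENTS, m, replace = TRUE),
                   "other")
    pieces$outpatient <- data.table(
      person_id = lat$person_id[idx],
      visit_date = lat$onset_date[idx] - round(runif(m, 1, 365)),
      icd_codes = sample(BACKGROUND_ICD, m, replace = TRUE),
      department = dept,
      hospital_type = lat$hospital_type[idx])
  }

  # ... and hospitalization stays, possibly running past the index date
  p_hosp <- plogis(qlogis(utl$hosp_prob) + log(lat$severity))
  n_stay <- rbinom(n, 1L, p_hosp) + rbinom(n, 1L, p_hosp / 4)
  n_stay[lat$is_case == FALSE] <- rbinom(sum(!lat$is_case), 1L,
                                         utl$hosp_prob / 2)
  idx <- rep(seq_len(n), n_stay)
  if (length(idx) > 0) {
    m <- length(idx)
    adm <- lat$onset_date[idx] - round(runif(m, 1, 365))
    days <- pmax(1, round(rlnorm(m, utl$hosp_days_meanlog,
                                 utl$hosp_days_sdlog)))
    pieces$inpatient <- data.table(
      person_id = lat$person_id[idx],
      visit_date = adm,
      icd_codes = sample(BACKGROUND_ICD, m, replace = TRUE),
      department = sample(c("internal_medicine", "other"), m,
                          replace = TRUE),
      hospital_type = lat$hospital_type[idx],
      inpatient = TRUE,
      discharge_date = adm + days)
  }

  visits <- rbindlist(pieces, use.names = TRUE, fill = TRUE)
  visits[is.na(inpatient), inpatient := FALSE]
  setorder(visits, person_id, visit_date, department)

  ground_truth <- lat[, .(
    person_id, is_case, prevalent, in_window, underage, short_residency,
    insufficient_followup, eligible,
    diagnosis_date = onset_date,
    calendar_cohort = calendar_cohort(onset_date),
    severity, registration_end, hospital_type)]

  list(visits = visits[], ground_truth = ground_truth[])
}

#' Generate the synthetic dispensation table
#'
#' Glucocorticoid users draw a log-normal 5-year cumulative
#' prednisolone-equivalent dose whose per-cohort median equals the
#' configured `gc_median_5yr_dose_mg`; the dose is spread over the active
#' treatment years with a geometric taper and dispensed in quarterly
#' fills.  Hydroxychloroquine users initiate shortly after diagnosis and
#' refill every 80--120 days until an exponentially distributed
#' discontinuation time.  Immunosuppressant users draw one class
#' (AZA/MTX/MMF and minor classes) and refill quarterly.  All fills are
#' clipped to the drug-register coverage window
#' `[config$study_start, config$data_end]` and to each person's
#' registration interval.
#'
#' @param persons output of [generate_population()].
#' @param ground_truth ground-truth table from [generate_visits()].
#' @param config the same [sim_config()] object.
#' @return list with `dispensations` (`data.table`: `person_id`,
#'   `fill_date`, `atc_code`, `n_packages`, `pills_per_package`,
#'   `strength_mg`, `n_ddd`) and `ground_truth` augmented with the true
#'   treatment parameters per person (`gc_user`, `gc_true_5yr_dose_mg`,
#'   `gc_active_years`, `hcq_user`, `hcq_init_offset_days`,
#'   `hcq_persist_years`, `is_user`, `is_class`).
#' @export
generate_dispensations <- function(persons, ground_truth, config) {
  config <- validate_sim_config(config)
  set.seed(config$seed + 2L)
  gt <- copy(ground_truth)

  cases <- gt[is_case == TRUE]
  nc <- nrow(cases)
  eff_of <- function(lab, field) {
    lab <- as.character(lab)
    lab[is.na(lab)] <- COHORT_LABELS[1L]   # pre-window onset: earliest era
    vapply(lab, function(l) config$cohort_effects[[l]][[field]], numeric(1))
  }
  pieces <- list()

  if (nc > 0) {
    cases[, supply_end := pmin(registration_end, config$data_end)]
    cohort <- cases$calendar_cohort

    ## glucocorticoids -------------------------------------------------
    cases[, gc_user := runif(nc) < eff_of(cohort, "gc_use_prob")]
    cases[, gc_true_5yr_dose_mg := fifelse(
      gc_user,
      rlnorm(nc, log(eff_of(cohort, "gc_median_5yr_dose_mg")),
             eff_of(cohort, "gc_scale")),
      NA_real_)]
    # active years: stay on treatment with yearly continuation probability
    cont <- eff_of(cohort, "gc_continuation_prob")
    keep_on <- matrix(runif(nc * 4L), nc, 4L) < cont
    active <- t(apply(cbind(TRUE, keep_on), 1L, cumprod)) > 0
    cases[, gc_active_years := rowSums(active)]
    cases[gc_user == FALSE, gc_active_years := 0L]
    cases[, gc_methylpred := gc_user & runif(nc) < GC_METHYLPRED_FRAC]

    gcu <- cases[gc_user == TRUE]
    if (nrow(gcu) > 0) {
      grid <- gcu[, .(year_k = seq_len(gc_active_years)),
                  by = .(person_id, diagnosis_date, supply_end,
                         gc_true_5yr_dose_mg, gc_active_years, gc_methylpred)]
      grid[, w := GC_DOSE_TAPER^(year_k - 1)]
      grid[, w := w / sum(w), by = person_id]
      fills <- grid[rep(seq_len(.N), each = 4L)]
      fills[, fill_no := seq_len(.N), by = .(person_id, year_k)]
      fills[, offset := (year_k - 1) * YEAR_DAYS +
              (fill_no - 1) * 91.3 + runif(.N, 0, 14)]
      fills[, fill_date := diagnosis_date + round(offset)]
      fills[, dose_mg := gc_true_5yr_dose_mg * w / 4]
      fills <- fills[fill_date >= config$study_start &
                     fill_date <= supply_end]
      eq <- gc_equivalence_table()
      pred <- eq[substance == "prednisolone"]
      mp <- eq[substance == "methylprednisolone"]
      fills[, atc_code := fifelse(gc_methylpred, mp$atc_code, pred$atc_code)]
      fills[, n_ddd := fifelse(gc_methylpred,
                               dose_mg / (mp$ddd_mg * mp$factor),
                               dose_mg / (pred$ddd_mg * pred$factor))]
      fills[, strength_mg := fifelse(gc_methylpred, 4, 5)]
      pieces$gc <- fills[, .(person_id, fill_date, atc_code,
                             n_packages = pmax(1L, round(dose_mg / 500)),
                             pills_per_package = 100L, strength_mg, n_ddd)]
    }

    ## hydroxychloroquine ----------------------------------------------
    cases[, hcq_user := runif(nc) < eff_of(cohort, "hcq_initiation_prob")]
    cases[, hcq_init_offset_days := fifelse(hcq_user, round(runif(nc, 0, 60)),
                                            NA_real_)]
    haz <- eff_of(cohort, "hcq_discontinuation_hazard")
    persist <- ifelse(haz > 0, rexp(nc, pmax(haz, 1e-12)), Inf)
    cases[, hcq_persist_years := fifelse(hcq_user, persist, NA_real_)]

    hcu <- cases[hcq_user == TRUE]
    if (nrow(hcu) > 0) {
      max_span <- as.numeric(config$data_end - config$study_start)
      max_fills <- ceiling(max_span / 80) + 1L
      gaps <- matrix(runif(nrow(hcu) * max_fills, 80, 120),
                     nrow(hcu), max_fills)
      offs <- cbind(hcu$hcq_init_offset_days,
                    hcu$hcq_init_offset_days +
                      t(apply(gaps, 1L, cumsum))[, -max_fills, drop = FALSE])
      active_end <- pmin(hcu$hcq_init_offset_days +
                           hcu$hcq_persist_years * YEAR_DAYS,
                         as.numeric(hcu$supply_end - hcu$diagnosis_date))
      keep <- offs <= active_end
      idx <- rep(seq_len(nrow(hcu)), times = rowSums(keep))
      off_kept <- t(offs)[t(keep)]
      if (length(idx) > 0) {
        hf <- data.table(person_id = hcu$person_id[idx],
                         fill_date = hcu$diagnosis_date[idx] + round(off_kept))
        hf <- hf[fill_date >= config$study_start]
        hf[, n_packages := 1L + rbinom(.N, 1L, 0.1)]
        pieces$hcq <- hf[, .(person_id, fill_date, atc_code = "P01BA02",
                             n_packages, pills_per_package = 100L,
                             strength_mg = 200,
                             n_ddd = n_packages * 100 * 200 / 516)]
      }
    }

    ## immunosuppressants ----------------------------------------------
    cases[, is_user := runif(nc) < eff_of(cohort, "is_use_prob")]
    is_classes <- c("IS:AZA", "IS:MTX", "IS:MMF", "IS:CYC", "IS:LEF",
                    "IS:TAC", "IS:CSA")
    is_atc <- c("L04AX01", "L04AX03", "L04AA06", "L01AA01", "L04AA13",
                "L04AD02", "L04AD01")
    cases[, is_class := fifelse(
      is_user,
      sample(is_classes, nc, replace = TRUE,
             prob = c(0.33, 0.30, 0.20, 0.04, 0.05, 0.04, 0.04)),
      NA_character_)]
    isu <- cases[is_user == TRUE]
    if (nrow(isu) > 0) {
      start_off <- round(runif(nrow(isu), 0, 120))
      dur_days <- rexp(nrow(isu), 0.35) * YEAR_DAYS
      n_fill <- pmax(1L, ceiling(pmin(
        dur_days,
        as.numeric(isu$supply_end - isu$diagnosis_date) - start_off) / 90))
      idx <- rep(seq_len(nrow(isu)), pmax(n_fill, 0L))
      fno <- sequence(pmax(n_fill, 0L))
      if (length(idx) > 0) {
        fd <- isu$diagnosis_date[idx] + start_off[idx] +
          round((fno - 1) * 90 + runif(length(idx), 0, 15))
        keep <- fd >= config$study_start & fd <= isu$supply_end[idx]
        pieces$is <- data.table(
          person_id = isu$person_id[idx][keep],
          fill_date = fd[keep],
          atc_code = is_atc[match(isu$is_class[idx][keep], is_classes)],
          n_packages = 1L, pills_per_package = 100L, strength_mg = 50,
          n_ddd = round(runif(sum(keep), 50, 120)))
      }
    }
  }

  dispensations <- rbindlist(pieces, use.names = TRUE)
  if (nrow(dispensations) == 0L)
    dispensations <- data.table(person_id = character(), fill_date = as.Date(character()),
                                atc_code = character(), n_packages = integer(),
                                pills_per_package = integer(),
                                strength_mg = numeric(), n_ddd = numeric())
  setorder(dispensations, person_id, fill_date, atc_code)

  truth_cols <- cases[, .(person_id, gc_user, gc_true_5yr_dose_mg,
                          gc_active_years, hcq_user, hcq_init_offset_days,
                          hcq_persist_years, is_user, is_class)]
  gt <- merge(gt, truth_cols, by = "person_id", all.x = TRUE)
  gt[is.na(gc_user) & is_case == FALSE,
     `:=`(gc_user = FALSE, hcq_user = FALSE, is_user = FALSE)]
  setorder(gt, person_id)

  list(dispensations = dispensations[], ground_truth = gt[])
}

#' Simulate a full synthetic register linkage
#'
#' Runs [generate_population()], [generate_visits()] and
#' [generate_dispensations()] under one master seed.
#'
#' @param config a [sim_config()] object.
#' @return list with `population`, `visits`, `dispensations`,
#'   `ground_truth` and the `config` used.
#' @examples
#' sim <- simulate_registers(sim_config(n_persons = 200, seed = 7))
#' nrow(sim$population)
#' @export
simulate_registers <- function(config) {
  population <- generate_population(config)
  vis <- generate_visits(population, config)
  disp <- generate_dispensations(population, vis$ground_truth, config)
  list(population = population, visits = vis$visits,
       dispensations = disp$dispensations,
       ground_truth = disp$ground_truth, config = config)
}

#' Write simulated registers as delimited text
#'
#' Writes `population.csv`, `visits.csv`, `dispensations.csv` and
#' `ground_truth.csv` (ISO-8601 dates) into `dir`.
#'
#' @param sim result of [simulate_registers()].
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_registers <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("population.csv", "visits.csv",
                            "dispensations.csv", "ground_truth.csv"))
  fwrite(sim$population, paths[1], dateTimeAs = "ISO")
  fwrite(sim$visits, paths[2], dateTimeAs = "ISO")
  fwrite(sim$dispensations, paths[3], dateTimeAs = "ISO")
  fwrite(sim$ground_truth, paths[4], dateTimeAs = "ISO")
  invisible(paths)
}
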