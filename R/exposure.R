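# Dispensation-based exposure measures
#
# All window arithmetic uses half-open intervals measured in days since
# diagnosis, with an analysis year of 365.25 days.  Coverage follows the
# truncation-at-next-fill rule: when a new dispensation occurs while the
# previous supply is still nominally running, the previous supply is
# treated as fully consumed at the new fill date (no stockpiling).

#' Yearly analysis windows after diagnosis
#'
#' Window `k` is `[(k-1)*365.25, k*365.25)` days since diagnosis,
#' truncated at the end of follow-up; windows of zero length are omitted.
#'
#' @param diagnosis_date diagnosis date (`Date`), or 0 to work in plain
#'   day offsets.
#' @param follow_up_end end of follow-up (`Date`, or days since
#'   diagnosis).
#' @param k_max number of yearly windows.
#' @return `data.table` with columns `window` (`"y1"`, ..., `"y<k_max>"`),
#'   `start_day`, `end_day` (days since diagnosis, half-open) and
#'   `window_days`.
#' @examples
#' yearly_windows(as.Date("2010-01-01"), as.Date("2012-06-30"))
#' @export
yearly_windows <- function(diagnosis_date, follow_up_end, k_max = 5L) {
  if (k_max < 1) stop("k_max must be at least 1")
  fu <- as_day_number(follow_up_end, origin = diagnosis_date)
  if (fu <= 0) stop("follow_up_end must be after diagnosis_date")
  k <- seq_len(k_max)
  out <- data.table(window = paste0("y", k),
                    start_day = (k - 1) * YEAR_DAYS,
                    end_day = pmin(k * YEAR_DAYS, fu))
  out <- out[end_day > start_day]
  out[, window_days := end_day - start_day]
  out[]
}

#' Cumulative prednisolone-equivalent glucocorticoid dose
#'
#' Sums `n_ddd * ddd_mg * factor` over glucocorticoid dispensations: the
#' number of defined daily doses dispensed, times the substance's DDD in
#' mg, rescaled to prednisolone-equivalent mg by its potency factor.  The
#' whole dose of a fill is attributed to the window containing the fill
#' date, so callers filter records to the window first.
#'
#' @param dispensations `data.frame` of GC records with `atc_code` and
#'   `n_ddd`.
#' @param equivalence equivalence table as from [gc_equivalence_table()].
#' @return cumulative dose in prednisolone-equivalent mg.
#' @examples
#' gc_cumulative_dose(data.frame(atc_code = "H02AB06", n_ddd = 100))
#' @export
gc_cumulative_dose <- function(dispensations,
                               equivalence = gc_equivalence_table()) {
  d <- as.data.table(dispensations)
  if (nrow(d) == 0L) return(0)
  i <- match(d$atc_code, equivalence$atc_code)
  if (anyNA(i))
    stop("ATC code(s) missing from the equivalence table: ",
         toString(unique(d$atc_code[is.na(i)])))
  sum(d$n_ddd * equivalence$ddd_mg[i] * equivalence$factor[i])
}

#' Hydroxychloroquine coverage intervals
#'
#' A dispensation of one package nominally covers
#' `r HCQ_DAYS_SINGLE_PACKAGE` days; a single dispensation of several
#' packages covers `r HCQ_DAYS_PER_PACKAGE_MULTI` days per package.
#' Same-day fills are merged (packages summed) before the rule is
#' applied.  When the next fill occurs inside the running supply, the
#' running supply is treated as fully consumed at that date and coverage
#' continues from the new fill (truncation, no carry-over).  Coverage is
#' truncated at the end of follow-up; fills on or after the end of
#' follow-up are dropped with a warning.
#'
#' @param fills `data.frame` with `fill_date` (`Date` or days since
#'   diagnosis) and `n_packages`.
#' @param follow_up_end end of follow-up, same scale as `fill_date`.
#' @param diagnosis_date origin when `fill_date` is a `Date`.
#' @return `data.table` of disjoint, ordered intervals with columns
#'   `start` and `end` (half-open, days since diagnosis) and
#'   `source_fill` (row index of the merged fill event).
#' @examples
#' hcq_coverage_intervals(data.frame(fill_date = c(0, 60),
#'                                   n_packages = c(1, 1)), 365)
#' @export
hcq_coverage_intervals <- function(fills, follow_up_end,
                                   diagnosis_date = 0) {
  f <- as.data.table(fills)
  fu <- as_day_number(follow_up_end, origin = diagnosis_date)
  if (nrow(f) == 0L)
    return(data.table(start = numeric(), end = numeric(),
                      source_fill = integer()))
  f[, day := as_day_number(fill_date, origin = diagnosis_date)]
  late <- f$day >= fu
  if (any(late)) {
    warning(sum(late), " fill(s) on or after the end of follow-up dropped")
    f <- f[!late]
  }
  if (nrow(f) == 0L)
    return(data.table(start = numeric(), end = numeric(),
                      source_fill = integer()))
  ev <- f[, .(n_packages = sum(n_packages)), keyby = day]
  ev[, duration := fifelse(n_packages == 1L,
                           HCQ_DAYS_SINGLE_PACKAGE,
                           HCQ_DAYS_PER_PACKAGE_MULTI * as.numeric(n_packages))]
  ev[, next_day := shift(day, type = "lead", fill = Inf)]
  ev[, `:=`(start = day, end = pmin(day + duration, next_day, fu))]
  ev[, source_fill := .I]
  ev[end > start, .(start, end, source_fill)]
}

#' Proportion of days covered
#'
#' Total length of `intervals` intersected with the window, divided by
#' the window length (the window is assumed already truncated at the end
#' of follow-up, as produced by [yearly_windows()]).
#'
#' @param intervals coverage intervals (`start`, `end`) as from
#'   [hcq_coverage_intervals()].
#' @param window_start,window_end half-open analysis window, days since
#'   diagnosis.
#' @return proportion in `[0, 1]`.
#' @export
pdc <- function(intervals, window_start, window_end) {
  len <- window_end - window_start
  if (!is.finite(len) || len <= 0) stop("window must have positive length")
  if (NROW(intervals) == 0L) return(0)
  covered <- sum(pmax(0, pmin(intervals$end, window_end) -
                         pmax(intervals$start, window_start)))
  min(1, covered / len)
}

#' Any-use flags per drug class in a window
#'
#' `TRUE` for a class iff at least one dispensation of that class has its
#' fill date inside the half-open window; the immunosuppressant flag is
#' the union over the seven IS subclasses.
#'
#' @param dispensations `data.frame` with `atc_code` and `fill_date`
#'   (`Date` or days since diagnosis).
#' @param window_start,window_end half-open window, days since diagnosis.
#' @param diagnosis_date origin when `fill_date` is a `Date`.
#' @param map ATC class map as from [atc_class_map()].
#' @return named logical vector `c(gc = , hcq = , is = )`.
#' @export
any_use_flags <- function(dispensations, window_start, window_end,
                          diagnosis_date = 0, map = atc_class_map()) {
  d <- as.data.table(dispensations)
  if (nrow(d) == 0L) return(c(gc = FALSE, hcq = FALSE, is = FALSE))
  day <- as_day_number(d$fill_date, origin = diagnosis_date)
  cls <- classify_atc(d$atc_code, map)
  inw <- day >= window_start & day < window_end
  c(gc = any(inw & cls == "GC", na.rm = TRUE),
    hcq = any(inw & cls == "HCQ", na.rm = TRUE),
    is = any(inw & is_is_class(cls), na.rm = TRUE))
}

#' Treatment-combination state from any-use flags
#'
#' @param any_gc,any_hcq,any_is logical vectors.
#' @return factor with levels `r toString(COMBINATION_LEVELS)`.
#' @examples
#' combination_state(TRUE, TRUE, FALSE)
#' @export
combination_state <- function(any_gc, any_hcq, any_is) {
  lab <- fcase(
    !any_gc & !any_hcq & !any_is, "None",
    any_gc & !any_hcq & !any_is, "GC",
    !any_gc & any_hcq & !any_is, "HCQ",
    !any_gc & !any_hcq & any_is, "IS",
    any_gc & any_hcq & !any_is, "HCQ+GC",
    any_gc & !any_hcq & any_is, "IS+GC",
    !any_gc & any_hcq & any_is, "IS+HCQ",
    default = "IS+HCQ+GC")
  factor(lab, levels = COMBINATION_LEVELS)
}

#' Average daily glucocorticoid dose category
#'
#' Average daily dose is cumulative prednisolone-equivalent mg divided by
#' the observed window length; categories `none`, `(0,5]`, `(5,7.5]` and
#' `>7.5` mg/day follow the guideline thresholds of 5 and 7.5 mg.
#'
#' @param gc_cum_dose_mg cumulative dose in the window, mg.
#' @param window_days observed window length, days.
#' @return factor with levels `r toString(GC_DOSE_CATEGORIES)`.
#' @export
avg_daily_dose_category <- function(gc_cum_dose_mg, window_days) {
  if (any(window_days <= 0)) stop("window_days must be positive")
  dose <- gc_cum_dose_mg / window_days
  lab <- fcase(dose <= 0, "none",
               dose <= 5, "(0,5]",
               dose <= 7.5, "(5,7.5]",
               default = ">7.5")
  factor(lab, levels = GC_DOSE_CATEGORIES)
}

#' Hydroxychloroquine PDC category
#'
#' Bins `{0, (0,0.2], (0.2,0.8], >0.8}`; the 0.8 boundary is the
#' "at least 80% of days covered" adherence threshold.
#'
#' @param hcq_pdc proportion of days covered in `[0, 1]`.
#' @return factor with levels `r toString(HCQ_PDC_CATEGORIES)`.
#' @export
hcq_pdc_category <- function(hcq_pdc) {
  lab <- fcase(hcq_pdc <= 0, "0",
               hcq_pdc <= 0.2, "(0,0.2]",
               hcq_pdc <= 0.8, "(0.2,0.8]",
               default = ">0.8")
  factor(lab, levels = HCQ_PDC_CATEGORIES)
}

#' Derive windowed exposure summaries for a cohort
#'
#' Computes, per person and per window (years 1..`k_max` after diagnosis
#' plus the combined `y1_5` window), any-use flags for GC/HCQ/IS,
#' cumulative prednisolone-equivalent GC dose and its average-daily-dose
#' category, HCQ covered days and PDC with its category, and the 8-way
#' treatment-combination state.  Dispensations before diagnosis or after
#' the end of follow-up are excluded.
#'
#' @param cohort cohort table with `person_id`, `diagnosis_date`,
#'   `follow_up_end`.
#' @param dispensations dispensation table (`person_id`, `fill_date`,
#'   `atc_code`, `n_packages`, `n_ddd`).
#' @param k_max number of yearly windows (the combined window spans years
#'   1..`k_max`).
#' @param equivalence GC equivalence table.
#' @param map ATC class map.
#' @return `data.table`, one row per person-window, with columns
#'   `person_id`, `window`, `start_day`, `end_day`, `window_days`,
#'   `any_gc`, `any_hcq`, `any_is`, `gc_cum_dose_mg`,
#'   `gc_avg_daily_dose_mg`, `gc_dose_cat`, `hcq_days_covered`,
#'   `hcq_pdc`, `hcq_pdc_cat`, `combination`.
#' @examples
#' sim <- simulate_registers(sim_config(n_persons = 200, seed = 2))
#' built <- build_cohort(sim$population, sim$visits)
#' expo <- derive_exposures(built$cohort, sim$dispensations)
#' expo[window == "y1_5"][1:3]
#' @export
derive_exposures <- function(cohort, dispensations, k_max = 5L,
                             equivalence = gc_equivalence_table(),
                             map = atc_class_map()) {
  cohort <- as.data.table(cohort)
  d <- as.data.table(dispensations)

  # person-level window grid (yearly windows truncated at follow-up)
  ch <- cohort[, .(person_id, diagnosis_date,
                   fu_days = as.numeric(follow_up_end - diagnosis_date))]
  k <- seq_len(k_max)
  win <- ch[rep(seq_len(.N), each = k_max)]
  win[, window := rep(paste0("y", k), times = nrow(ch))]
  win[, start_day := rep((k - 1) * YEAR_DAYS, times = nrow(ch))]
  win[, end_day := pmin(rep(k * YEAR_DAYS, times = nrow(ch)), fu_days)]
  win <- win[end_day > start_day]
  win[, window_days := end_day - start_day]

  d <- merge(d, ch, by = "person_id")
  d[, day := as.numeric(fill_date - diagnosis_date)]
  # treatment after diagnosis, inside follow-up and inside the analysed
  # years only (a fill beyond year k_max cannot affect any window: the
  # truncation-at-next-fill rule only shortens coverage past that fill)
  d <- d[day >= 0 & day < pmin(fu_days, k_max * YEAR_DAYS)]
  d[, drug_class := classify_atc(atc_code, map)]
  d <- d[!is.na(drug_class)]
  d[, window := paste0("y", floor(day / YEAR_DAYS) + 1)]

  # any-use flags and GC dose per yearly window
  gc <- d[drug_class == "GC"]
  if (nrow(gc) > 0) {
    i <- match(gc$atc_code, equivalence$atc_code)
    if (anyNA(i))
      stop("GC ATC code(s) missing from the equivalence table: ",
           toString(unique(gc$atc_code[is.na(i)])))
    gc[, dose_mg := n_ddd * equivalence$ddd_mg[i] * equivalence$factor[i]]
  }
  agg <- d[, .(any_gc = any(drug_class == "GC"),
               any_hcq = any(drug_class == "HCQ"),
               any_is = any(is_is_class(drug_class))),
           by = .(person_id, window)]
  dose <- if (nrow(gc) > 0)
    gc[, .(gc_cum_dose_mg = sum(dose_mg)), by = .(person_id, window)]
  else data.table(person_id = character(), window = character(),
                  gc_cum_dose_mg = numeric())

  # HCQ coverage intervals per person, overlapped with each window
  hcq <- d[drug_class == "HCQ"]
  if (nrow(hcq) > 0) {
    ev <- hcq[, .(n_packages = sum(n_packages)), keyby = .(person_id, day)]
    ev[, duration := fifelse(n_packages == 1L,
                             HCQ_DAYS_SINGLE_PACKAGE,
                             HCQ_DAYS_PER_PACKAGE_MULTI * as.numeric(n_packages))]
    ev <- merge(ev, ch[, .(person_id, fu_days)], by = "person_id")
    ev[, next_day := shift(day, type = "lead", fill = Inf), by = person_id]
    ev[, `:=`(start = day, end = pmin(day + duration, next_day, fu_days))]
    ev <- ev[end > start]
    ov <- merge(win[, .(person_id, window, start_day, end_day)], ev,
                by = "person_id", allow.cartesian = TRUE)
    ov[, covered := pmax(0, pmin(end, end_day) - pmax(start, start_day))]
    cov <- ov[, .(hcq_days_covered = sum(covered)), by = .(person_id, window)]
  } else {
    cov <- data.table(person_id = character(), window = character(),
                      hcq_days_covered = numeric())
  }

  out <- Reduce(function(a, b) merge(a, b, by = c("person_id", "window"),
                                     all.x = TRUE),
                list(win, agg, dose, cov))

  # combined window over years 1..k_max
  comb <- out[, .(window = paste0("y1_", k_max),
                  start_day = 0,
                  end_day = max(end_day),
                  window_days = sum(window_days),
                  any_gc = any(any_gc, na.rm = TRUE),
                  any_hcq = any(any_hcq, na.rm = TRUE),
                  any_is = any(any_is, na.rm = TRUE),
                  gc_cum_dose_mg = sum(gc_cum_dose_mg, na.rm = TRUE),
                  hcq_days_covered = sum(hcq_days_covered, na.rm = TRUE)),
              by = .(person_id, diagnosis_date, fu_days)]
  out <- rbind(out, comb, use.names = TRUE)

  for (col in c("any_gc", "any_hcq", "any_is"))
    out[is.na(get(col)), (col) := FALSE]
  out[is.na(gc_cum_dose_mg), gc_cum_dose_mg := 0]
  out[is.na(hcq_days_covered), hcq_days_covered := 0]

  out[, gc_avg_daily_dose_mg := gc_cum_dose_mg / window_days]
  out[, gc_dose_cat := avg_daily_dose_category(gc_cum_dose_mg, window_days)]
  out[, hcq_pdc := pmin(1, hcq_days_covered / window_days)]
  out[, hcq_pdc_cat := hcq_pdc_category(hcq_pdc)]
  out[, combination := combination_state(any_gc, any_hcq, any_is)]
  out[, c("diagnosis_date", "fu_days") := NULL]
  setorder(out, person_id, window)
  out[]
}
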