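# Table- and figure-shaped data products: baseline characteristics,
# any-use by calendar cohort, yearly state-transition tables (the data
# behind alluvial plots), and GC-dose x HCQ-PDC cross-tabulations.

#' Published Swedish incident-SLE cohort counts
#'
#' Cell counts (numerator, stratum denominator and the percentage as
#' printed, half-up rounded to one decimal) from the published register
#' study of incident SLE in Sweden 2005--2021 (n = 3891): baseline
#' characteristics by calendar cohort, and any glucocorticoid /
#' hydroxychloroquine use during the first and fifth year after
#' diagnosis.  Used to calibrate the synthetic-register generator and to
#' validate the package's percentage arithmetic against printed values.
#'
#' @return `data.table` with columns `table` (`"characteristics"` or
#'   `"anyuse"`), `variable`, `level`, `cohort` (calendar cohort or
#'   `"total"`), `numerator`, `denominator`, `printed_pct`.
#' @export
reference_cohort_counts <- function() {
  cohorts <- c(COHORT_LABELS, "total")
  denom_all <- c(835L, 995L, 967L, 1094L, 3891L)
  row <- function(variable, level, nums, pcts, table = "characteristics",
                  denom = denom_all, cht = cohorts) {
    data.table(table = table, variable = variable, level = level,
               cohort = cht, numerator = as.integer(nums),
               denominator = as.integer(denom), printed_pct = pcts)
  }
  ch <- rbind(
    row("sex", "female", c(699, 828, 791, 893, 3211),
        c(83.7, 83.2, 81.8, 81.6, 82.5)),
    row("sex", "male", c(136, 167, 176, 201, 680),
        c(16.3, 16.8, 18.2, 18.4, 17.5)),
    row("age_category", "18-39", c(281, 341, 330, 411, 1363),
        c(33.7, 34.3, 34.1, 37.6, 35.0)),
    row("age_category", "40-59", c(304, 343, 310, 328, 1285),
        c(36.4, 34.5, 32.1, 30.0, 33.0)),
    row("age_category", ">=60", c(250, 311, 327, 355, 1243),
        c(29.9, 31.3, 33.8, 32.4, 31.9)),
    row("birth_region", "Nordic", c(733, 846, 778, 876, 3233),
        c(87.8, 85.0, 80.5, 80.1, 83.1)),
    row("birth_region", "non-Nordic", c(90, 139, 171, 205, 605),
        c(10.8, 14.0, 17.7, 18.7, 15.5)),
    row("birth_region", "missing", c(12, 10, 18, 13, 53),
        c(1.4, 1.0, 1.9, 1.2, 1.4)),
    row("diagnosis_hospital", "university", c(415, 491, 492, 505, 1903),
        c(49.7, 49.3, 50.9, 46.2, 48.9)),
    row("diagnosis_hospital", "other", c(420, 504, 475, 589, 1988),
        c(50.3, 50.7, 49.1, 53.8, 51.1)),
    row("education", "0-9y", c(221, 245, 205, 185, 856),
        c(26.5, 24.6, 21.2, 16.9, 22.0)),
    row("education", "10-12y", c(368, 431, 426, 472, 1697),
        c(44.1, 43.3, 44.1, 43.1, 43.6)),
    row("education", ">=13y", c(245, 313, 327, 427, 1312),
        c(29.3, 31.5, 33.8, 39.0, 33.7)),
    row("education", "missing", c(1, 6, 9, 10, 26),
        c(0.1, 0.6, 0.9, 0.9, 0.7)),
    row("prior_hospital_cat", "0", c(523, 612, 582, 746, 2463),
        c(62.6, 61.5, 60.2, 68.2, 63.3)),
    row("prior_hospital_cat", "1-7", c(165, 205, 208, 191, 769),
        c(19.8, 20.6, 21.5, 17.5, 19.8)),
    row("prior_hospital_cat", ">7", c(147, 178, 177, 157, 659),
        c(17.6, 17.9, 18.3, 14.4, 16.9)),
    row("prior_outpatient_cat", "0-2", c(370, 389, 331, 373, 1463),
        c(44.3, 39.1, 34.2, 34.1, 37.6)),
    row("prior_outpatient_cat", "3-6", c(280, 346, 341, 384, 1351),
        c(33.5, 34.8, 35.3, 35.1, 34.7)),
    row("prior_outpatient_cat", ">6", c(185, 260, 295, 337, 1077),
        c(22.2, 26.1, 30.5, 30.8, 27.7)))
  au <- rbind(
    row("any_gc_y1", "user", c(568, 727, 707, 747),
        c(68.0, 73.1, 73.1, 68.3), table = "anyuse",
        denom = denom_all[1:4], cht = COHORT_LABELS),
    row("any_hcq_y1", "user", c(369, 636, 706, 877),
        c(44.2, 63.9, 73.0, 80.2), table = "anyuse",
        denom = denom_all[1:4], cht = COHORT_LABELS),
    row("any_gc_y5", "user", c(417, 457, 415),
        c(54.1, 49.6, 46.3), table = "anyuse",
        denom = c(771L, 922L, 897L), cht = COHORT_LABELS[1:3]),
    row("any_hcq_y5", "user", c(314, 472, 539),
        c(40.7, 51.2, 60.1), table = "anyuse",
        denom = c(771L, 922L, 897L), cht = COHORT_LABELS[1:3]))
  rbind(ch, au)
}

#' Baseline characteristics table
#'
#' Per-calendar-cohort and total columns for the categorical cohort
#' covariates (count and percentage of the stratum denominator, half-up
#' rounded to one decimal) plus age summaries (mean, SD, median, min,
#' max).
#'
#' @param cohort completed cohort table (from [build_cohort()]).
#' @return list with `categorical` (`data.table`: `variable`, `level`,
#'   `cohort`, `n`, `pct`) and `age` (`data.table` of age summaries per
#'   stratum).
#' @export
table_characteristics <- function(cohort) {
  cohort <- as.data.table(cohort)
  if (nrow(cohort) == 0L) stop("cohort must be non-empty")
  vars <- c("sex", "age_category", "birth_region", "diagnosis_hospital",
            "education", "prior_hospital_cat", "prior_outpatient_cat")
  strata <- c(as.character(unique(cohort$calendar_cohort)), "total")

  one_stratum <- function(sub, label) {
    denom <- nrow(sub)
    cat_tab <- rbindlist(lapply(vars, function(v) {
      tab <- table(sub[[v]])
      data.table(variable = v, level = names(tab), cohort = label,
                 n = as.integer(tab),
                 pct = round_half_up(100 * as.integer(tab) / denom, 1))
    }))
    age_tab <- data.table(cohort = label, n = denom,
                          age_mean = mean(sub$age_at_diagnosis),
                          age_sd = sd(sub$age_at_diagnosis),
                          age_median = median(sub$age_at_diagnosis),
                          age_min = min(sub$age_at_diagnosis),
                          age_max = max(sub$age_at_diagnosis))
    list(cat_tab, age_tab)
  }
  parts <- lapply(strata, function(s) {
    sub <- if (s == "total") cohort else cohort[calendar_cohort == s]
    one_stratum(sub, s)
  })
  list(categorical = rbindlist(lapply(parts, `[[`, 1L)),
       age = rbindlist(lapply(parts, `[[`, 2L)))
}

#' Any-use by calendar cohort with trend odds ratios
#'
#' Year-1 rows use persons with at least 1 year of follow-up; year-5
#' rows use persons with at least 5 years of follow-up and diagnosis in
#' the first three calendar cohorts (the 2017--2021 cohort is excluded
#' from 5-year analyses by design).  Counts and percentages come
#' from the exposure table; odds ratios from [fit_logistic_anyuse()] are
#' joined when estimates are supplied.
#'
#' @param exposures exposure table from [derive_exposures()].
#' @param cohort cohort table.
#' @param estimates optional named list of estimate tables, e.g.
#'   `list(gc_y1 = ..., hcq_y1 = ..., gc_y5 = ..., hcq_y5 = ...)`.
#' @return `data.table` with `drug`, `year`, `cohort`, `n`, `n_users`,
#'   `pct` and (when estimates are given) `or`, `ci_low`, `ci_high`,
#'   `p`.
#' @export
table_anyuse_trend <- function(exposures, cohort, estimates = NULL) {
  exposures <- as.data.table(exposures)
  cohort <- as.data.table(cohort)
  blocks <- rbindlist(lapply(c(1L, 5L), function(yr) {
    eligible <- cohort[follow_up_years >= yr]
    if (yr == 5L)
      eligible <- eligible[calendar_cohort %in% COHORT_LABELS[1:3]]
    sub <- merge(exposures[window == paste0("y", yr)],
                 eligible[, .(person_id, calendar_cohort)],
                 by = "person_id")
    rbindlist(lapply(c("gc", "hcq"), function(drug) {
      flag <- paste0("any_", drug)
      sub[, .(drug = drug, year = yr, n = .N,
              n_users = sum(get(flag)),
              pct = round_half_up(100 * sum(get(flag)) / .N, 1)),
          by = .(cohort = calendar_cohort)]
    }))
  }))
  setorder(blocks, year, drug, cohort)
  if (!is.null(estimates)) {
    ors <- rbindlist(lapply(names(estimates), function(nm) {
      est <- as.data.table(estimates[[nm]])
      est <- est[term == "calendar_cohort"]
      parts <- strsplit(nm, "_")[[1]]
      data.table(drug = parts[1],
                 year = as.integer(sub("y", "", parts[2])),
                 cohort = est$level, or = est$or, ci_low = est$ci_low,
                 ci_high = est$ci_high, p = est$p)
    }))
    blocks <- merge(blocks, ors, by = c("drug", "year", "cohort"),
                    all.x = TRUE)
  }
  blocks[]
}

#' Year-to-year exposure state-transition tables
#'
#' For each drug and calendar cohort, counts transitions between
#' exposure categories from year `k` to year `k+1` (the data underlying
#' alluvial plots).  Persons without an observed year-`k+1` window are
#' routed to an explicit `"censored"` state, so every table conserves
#' persons.
#'
#' @param exposures exposure table from [derive_exposures()].
#' @param cohort cohort table (for the calendar cohort).
#' @param drug `"gc"` (average-daily-dose category) or `"hcq"` (PDC
#'   category).
#' @param k_max last from-year.
#' @return `data.table` with `cohort`, `from_year`, `to_year`,
#'   `from_state`, `to_state`, `count`, `proportion` (of the from-state
#'   row among persons observed in year `k`).
#' @export
transition_tables <- function(exposures, cohort, drug = c("gc", "hcq"),
                              k_max = 5L) {
  drug <- match.arg(drug)
  state_col <- if (drug == "gc") "gc_dose_cat" else "hcq_pdc_cat"
  levels_all <- c(if (drug == "gc") GC_DOSE_CATEGORIES else
                    HCQ_PDC_CATEGORIES, "censored")
  exposures <- as.data.table(exposures)
  cohort <- as.data.table(cohort)

  wide <- merge(exposures[window %in% paste0("y", seq_len(k_max)),
                          .(person_id, window, state = as.character(get(state_col)))],
                cohort[, .(person_id, calendar_cohort)], by = "person_id")
  out <- rbindlist(lapply(seq_len(k_max - 1L), function(k) {
    a <- wide[window == paste0("y", k),
              .(person_id, calendar_cohort, from_state = state)]
    b <- wide[window == paste0("y", k + 1L), .(person_id, to_state = state)]
    m <- merge(a, b, by = "person_id", all.x = TRUE)
    m[is.na(to_state), to_state := "censored"]
    m[, `:=`(from_year = k, to_year = k + 1L)]
    m[, .(count = .N),
      by = .(cohort = calendar_cohort, from_year, to_year,
             from_state, to_state)]
  }))
  out[, proportion := count / sum(count),
      by = .(cohort, from_year, from_state)]
  out[, from_state := factor(from_state, levels_all)]
  out[, to_state := factor(to_state, levels_all)]
  setorder(out, cohort, from_year, from_state, to_state)
  out[]
}

#' Cross-tabulation of 5-year GC dose category by HCQ PDC category
#'
#' Per calendar cohort, the contingency table of the 5-year average
#' daily GC dose category against the 5-year HCQ PDC category, with a
#' chi-square independence statistic as a numeric summary of
#' association (`NA` when the table is degenerate).
#'
#' @param exposures exposure table from [derive_exposures()].
#' @param cohort cohort table; only persons with at least 5 years of
#'   follow-up and diagnosis in the first three calendar cohorts enter.
#' @return list with `counts` (`data.table`: `cohort`, `gc_dose_cat`,
#'   `hcq_pdc_cat`, `count`) and `tests` (`data.table`: `cohort`,
#'   `statistic`, `df`, `p`).
#' @export
crosstab_gc_hcq <- function(exposures, cohort) {
  exposures <- as.data.table(exposures)
  cohort <- as.data.table(cohort)
  sub <- merge(exposures[window == "y1_5"],
               cohort[follow_up_years >= 5 &
                        calendar_cohort %in% COHORT_LABELS[1:3],
                      .(person_id, calendar_cohort)], by = "person_id")
  counts <- sub[, .(count = .N),
                by = .(cohort = calendar_cohort, gc_dose_cat, hcq_pdc_cat)]
  tests <- sub[, {
    tab <- table(droplevels(gc_dose_cat), droplevels(hcq_pdc_cat))
    if (nrow(tab) < 2L || ncol(tab) < 2L)
      .(statistic = NA_real_, df = NA_real_, p = NA_real_)
    else {
      ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
      .(statistic = unname(ct$statistic), df = unname(ct$parameter),
        p = ct$p.value)
    }
  }, by = .(cohort = calendar_cohort)]
  setorder(counts, cohort, gc_dose_cat, hcq_pdc_cat)
  list(counts = counts[], tests = tests[])
}
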