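library(data.table)

mk_visits <- function(...) {
  v <- rbindlist(list(...), fill = TRUE)
  if (!"icd_codes" %in% names(v)) v[, icd_codes := "M32.9"]
  if (!"department" %in% names(v)) v[, department := "rheumatology"]
  if (!"hospital_type" %in% names(v)) v[, hospital_type := "university"]
  if (!"inpatient" %in% names(v)) v[, inpatient := FALSE]
  if (!"discharge_date" %in% names(v)) v[, discharge_date := as.Date(NA)]
  v[is.na(inpatient), inpatient := FALSE]
  v
}

mk_person <- function(id = "A", birth = "1970-01-01",
                      residency = birth, reg_end = "2024-01-31",
                      sex = "female") {
  data.table(person_id = id, sex = sex,
             birth_date = as.Date(birth),
             birth_region = "Nordic", education = "10-12y",
             residency_start = as.Date(residency),
             registration_end = as.Date(reg_end))
}

test_that("case candidacy needs two SLE visits within a year and a specialist", {
  # qualifying pair, second visit at a non-specialist department
  v <- mk_visits(
    data.table(person_id = "A",
               visit_date = as.Date(c("2010-03-01", "2010-09-01")),
               icd_codes = "M32.9",
               department = c("rheumatology", "other")))
  cand <- find_case_candidates(v)
  expect_equal(cand$person_id, "A")
  expect_equal(cand$candidate_date, as.Date("2010-03-01"))

  # pair more than 365 days apart does not qualify
  v2 <- mk_visits(
    data.table(person_id = "B",
               visit_date = as.Date(c("2010-03-01", "2011-06-01"))))
  expect_equal(nrow(find_case_candidates(v2)), 0L)

  # a single SLE-coded visit does not qualify
  v3 <- mk_visits(data.table(person_id = "C",
                             visit_date = as.Date("2010-03-01"),
                             icd_codes = "M32.1"))
  expect_equal(nrow(find_case_candidates(v3)), 0L)

  # specialist requirement spans all of the person's SLE-coded visits
  v4 <- mk_visits(
    data.table(person_id = "D",
               visit_date = as.Date(c("2010-03-01", "2010-05-01")),
               department = "other"))
  expect_equal(nrow(find_case_candidates(v4)), 0L)
  v5 <- rbind(v4, mk_visits(data.table(person_id = "D",
                                       visit_date = as.Date("2012-01-01"),
                                       department = "rheumatology")))
  expect_equal(nrow(find_case_candidates(v5)), 1L)

  # gap of exactly 365 days qualifies; malformed codes warn and are ignored
  v6 <- mk_visits(
    data.table(person_id = "E",
               visit_date = as.Date(c("2010-01-01", "2011-01-01"))))
  expect_equal(nrow(find_case_candidates(v6)), 1L)
  v7 <- rbind(v6, mk_visits(data.table(person_id = "E",
                                       visit_date = as.Date("2009-01-01"),
                                       icd_codes = "not_a_code")))
  expect_warning(cand7 <- find_case_candidates(v7), "malformed")
  expect_equal(cand7$candidate_date, as.Date("2010-01-01"))
})

test_that("incidence filters apply in order with a complete exclusion log", {
  persons <- rbind(
    mk_person("late"),                                  # first visit after window
    mk_person("prev"),                                  # SLE-coded care before window
    mk_person("newcomer", residency = "2010-06-01"),    # < 2 years residency
    mk_person("minor", birth = "1995-01-01"),           # 17.9 at diagnosis
    mk_person("shortfu", reg_end = "2011-03-01"),       # < 1 year follow-up
    mk_person("ok"))
  pair <- function(id, d1, d2) data.table(
    person_id = id, visit_date = as.Date(c(d1, d2)))
  visits <- mk_visits(
    pair("late", "2021-10-01", "2021-11-01"),
    pair("prev", "2004-05-01", "2004-07-01"),
    pair("prev", "2010-11-01", "2010-12-01"),
    pair("newcomer", "2010-11-01", "2010-12-01"),
    pair("minor", "2012-11-01", "2012-12-01"),
    pair("shortfu", "2010-11-01", "2010-12-01"),
    pair("ok", "2010-11-01", "2010-12-01"))
  res <- apply_incidence_filters(find_case_candidates(visits), persons)
  excl <- res$exclusions
  expect_equal(excl[reason == "first_sle_visit_after_window", n], 1L)
  expect_equal(excl[reason == "prevalent_case_washout", n], 1L)
  expect_equal(excl[reason == "residency_under_2_years", n], 1L)
  expect_equal(excl[reason == "age_under_18", n], 1L)
  expect_equal(excl[reason == "followup_under_1_year", n], 1L)
  expect_equal(res$cohort$person_id, "ok")
  expect_equal(sum(excl$n), 6L)           # log sums to candidate count
  expect_equal(as.character(res$cohort$calendar_cohort), "2009-2012")
  expect_gte(res$cohort$follow_up_years, 1)

  # visit for a person absent from the population table is a hard error
  ghost <- mk_visits(pair("ghost", "2010-01-01", "2010-02-01"))
  expect_error(
    apply_incidence_filters(find_case_candidates(rbind(visits, ghost)),
                            persons),
    "ghost")
})

test_that("pre-diagnosis utilization covariates clip and categorize correctly", {
  persons <- mk_person("A")
  sle <- mk_visits(data.table(
    person_id = "A", visit_date = as.Date(c("2010-01-02", "2010-03-01"))))
  # stay running past the diagnosis: 2009-12-20 .. 2010-01-05 clipped at
  # 2010-01-02 -> 13 days -> ">7"
  stay <- mk_visits(data.table(
    person_id = "A", visit_date = as.Date("2009-12-20"),
    icd_codes = "I10", department = "internal_medicine",
    inpatient = TRUE, discharge_date = as.Date("2010-01-05")))
  # exactly 7 specialist outpatient visits in the prior year -> ">6"
  outp <- mk_visits(data.table(
    person_id = "A",
    visit_date = as.Date("2010-01-01") - seq(10, 310, by = 50),
    icd_codes = "I10", department = "nephrology"))
  visits <- rbind(sle, stay, outp)
  built <- build_cohort(persons, visits)
  entry <- built$cohort
  expect_equal(entry$prior_hospital_days, 13)
  expect_equal(as.character(entry$prior_hospital_cat), ">7")
  expect_equal(entry$prior_outpatient_visits, 7L)
  expect_equal(as.character(entry$prior_outpatient_cat), ">6")
  expect_equal(as.character(entry$diagnosis_hospital), "university")

  # no prior-year contact -> lowest categories
  built0 <- build_cohort(persons, sle)
  expect_equal(as.character(built0$cohort$prior_hospital_cat), "0")
  expect_equal(as.character(built0$cohort$prior_outpatient_cat), "0-2")
})

test_that("builder decisions agree with generator ground-truth flags", {
  cfg <- sim_config(n_persons = 3000, seed = 21)
  sim <- simulate_registers(cfg)
  built <- build_cohort(sim$population, sim$visits)
  gt <- sim$ground_truth
  expect_setequal(built$cohort$person_id, gt$person_id[gt$eligible])
  # washout invariant: no retained person has SLE-coded care before diagnosis
  v <- as.data.table(sim$visits)
  sle <- v[grepl("M32\\.[189]", icd_codes),
           .(first_sle = min(visit_date)), by = person_id]
  m <- merge(built$cohort, sle, by = "person_id")
  expect_true(all(m$first_sle == m$diagnosis_date))
  # every candidate is accounted for
  expect_equal(sum(built$exclusions$n), nrow(built$candidates))
  # covariate categories are exhaustive
  expect_false(anyNA(built$cohort$age_category))
  expect_false(anyNA(built$cohort$prior_hospital_cat))
  expect_false(anyNA(built$cohort$prior_outpatient_cat))
  expect_false(anyNA(built$cohort$calendar_cohort))
})
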