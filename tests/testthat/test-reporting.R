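library(data.table)

test_that("percentages round half-up to one decimal", {
  expect_equal(round_half_up(c(82.45, 14.351, 0.05, -0.05), 1),
               c(82.5, 14.4, 0.1, -0.1))
  expect_equal(round_half_up(2.5, 0), 3)
  expect_equal(format_count_pct(568, 835), "568 (68.0)")
  expect_equal(format_count_pct(0, 10), "0 (0.0)")
})

test_that("characteristics table closes over every variable and stratum", {
  cfg <- sim_config(n_persons = 1200, seed = 41)
  sim <- simulate_registers(cfg)
  built <- build_cohort(sim$population, sim$visits)
  tab <- table_characteristics(built$cohort)
  n_by_stratum <- tab$age[, setNames(n, cohort)]
  sums <- tab$categorical[, .(tot = sum(n)), by = .(variable, cohort)]
  expect_true(all(sums$tot == n_by_stratum[sums$cohort]))
  # percentages recompute from counts under half-up rounding
  chk <- merge(tab$categorical, tab$age[, .(cohort, denom = n)],
               by = "cohort")
  expect_equal(chk$pct, round_half_up(100 * chk$n / chk$denom, 1))
  # a single-person cohort has only 0.0 or 100.0 cells
  one <- table_characteristics(built$cohort[1])
  expect_true(all(one$categorical$pct %in% c(0, 100)))
})

test_that("any-use table blocks respect follow-up and cohort restrictions", {
  cfg <- sim_config(n_persons = 2500, seed = 42)
  sim <- simulate_registers(cfg)
  built <- build_cohort(sim$population, sim$visits)
  expo <- derive_exposures(built$cohort, sim$dispensations)
  tab <- table_anyuse_trend(expo, built$cohort)
  expect_setequal(unique(tab$year), c(1L, 5L))
  # the most recent calendar cohort never enters the year-5 block
  expect_false("2017-2021" %in% as.character(tab[year == 5L, cohort]))
  expect_equal(tab$pct, round_half_up(100 * tab$n_users / tab$n, 1))
  # denominators: year-1 counts equal cohort sizes (everyone has >= 1y)
  sizes <- built$cohort[, .N, by = .(cohort = calendar_cohort)]
  m <- merge(tab[year == 1L & drug == "gc"], sizes, by = "cohort")
  expect_equal(m$n, m$N)
})

test_that("transition tables conserve persons through the censored state", {
  cfg <- sim_config(n_persons = 1500, seed = 43)
  sim <- simulate_registers(cfg)
  built <- build_cohort(sim$population, sim$visits)
  expo <- derive_exposures(built$cohort, sim$dispensations)
  for (drug in c("gc", "hcq")) {
    tr <- transition_tables(expo, built$cohort, drug)
    # flows out of year k equal the persons observed in year k
    outflow <- tr[, .(n = sum(count)), by = .(cohort, from_year)]
    persons_k <- merge(expo[window %in% paste0("y", 1:4),
                            .(person_id, window)],
                       built$cohort[, .(person_id,
                                        cohort = calendar_cohort)],
                       by = "person_id")[
      , .(n = .N), by = .(cohort, from_year = as.integer(sub("y", "", window)))]
    m <- merge(outflow, persons_k, by = c("cohort", "from_year"))
    expect_equal(m$n.x, m$n.y)
    # proportions sum to one within each from-state row
    props <- tr[, .(s = sum(proportion)), by = .(cohort, from_year, from_state)]
    expect_equal(props$s, rep(1, nrow(props)))
  }
})

test_that("GC x HCQ cross-tabulation margins and degenerate tables behave", {
  cfg <- sim_config(n_persons = 2000, seed = 44)
  sim <- simulate_registers(cfg)
  built <- build_cohort(sim$population, sim$visits)
  expo <- derive_exposures(built$cohort, sim$dispensations)
  ct <- crosstab_gc_hcq(expo, built$cohort)
  # margins reproduce the 5-year category counts
  five <- merge(expo[window == "y1_5"],
                built$cohort[follow_up_years >= 5 &
                               calendar_cohort != "2017-2021",
                             .(person_id, calendar_cohort)],
                by = "person_id")
  marg <- five[, .(n = .N), by = .(cohort = calendar_cohort, gc_dose_cat)]
  got <- ct$counts[, .(n = sum(count)), by = .(cohort, gc_dose_cat)]
  m <- merge(marg[n > 0], got, by = c("cohort", "gc_dose_cat"))
  expect_equal(m$n.x, m$n.y)
  expect_true(all(is.finite(ct$tests$statistic)))
  # an all-one-cell table yields NA rather than a chi-square value
  ids <- built$cohort[follow_up_years >= 5 &
                        calendar_cohort != "2017-2021", person_id][1:10]
  fake_expo <- expo[window == "y1_5" & person_id %in% ids]
  fake_expo[, `:=`(gc_dose_cat = factor("none", levels(gc_dose_cat)),
                   hcq_pdc_cat = factor("0", levels(hcq_pdc_cat)))]
  fake_cohort <- built$cohort[person_id %in% ids]
  ct2 <- crosstab_gc_hcq(fake_expo, fake_cohort)
  expect_true(all(is.na(ct2$tests$statistic)))
})
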