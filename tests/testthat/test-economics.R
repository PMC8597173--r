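test_that("discount factors follow the compound annual rate", {
  expect_equal(discount_factor(0, 0.03), 1)
  expect_equal(discount_factor(17.3, 0), 1)
  expect_equal(discount_factor(1, 0.03), 1 / 1.03)
  expect_equal(discount_factor(2, 0.03), 1 / 1.03^2)
  expect_equal(discount_factor(0.5, 0.03), 1.03^-0.5)  # fractional years
  expect_error(discount_factor(-1, 0.03), "non-negative")
  expect_error(discount_factor(1, -0.01), ">= 0")
})

test_that("treatment cost doubles in bilateral states and vanishes in blindness", {
  dex <- default_strategies()$dexamethasone
  expect_equal(cycle_drug_cost(c(1, 0, 0, 0, 0), dex, 1), 1165)   # 1075 + 90
  expect_equal(cycle_drug_cost(c(0, 1, 0, 0, 0), dex, 1), 2330)   # both eyes
  expect_equal(cycle_drug_cost(c(0, 0, 1, 0, 0), dex, 1), 2330)
  expect_equal(cycle_drug_cost(c(0, 0, 0, 0, 1000), dex, 1), 0)   # endpoint
  expect_equal(cycle_drug_cost(c(1, 0, 0, 0, 0), dex, 0.8), 1165 * 0.8)
  # state-5 treatment switch restores bilateral dosing there
  te <- health_states(state5_treatment = TRUE)$treated_eyes
  expect_equal(cycle_drug_cost(c(0, 0, 0, 0, 1), dex, 1, treated_eyes = te), 2330)
})

test_that("recurring adverse events accrue per cycle on the treated population", {
  s <- treatment_strategy("x", 0, 0, 4, adverse_events = data.frame(
    name = "Endophthalmitis", unit_cost = 3101,
    incidence_per_cycle = 0.0025, once_only = FALSE
  ))
  out <- cycle_adverse_event_cost(c(1000, 0, 0, 0, 0), s, numeric(0), 1)
  expect_equal(out$cost, 7752.50)
  # state 5 population is untreated and at no risk
  out5 <- cycle_adverse_event_cost(c(0, 0, 0, 0, 1000), s, numeric(0), 1)
  expect_equal(out5$cost, 0)
})

test_that("once-only adverse events saturate through the cohort-fraction ledger", {
  s <- treatment_strategy("x", 0, 0, 4, adverse_events = data.frame(
    name = "Cataract", unit_cost = 1373,
    incidence_per_cycle = 0.1, once_only = TRUE
  ))
  occ <- c(1000, 0, 0, 0, 0)
  out1 <- cycle_adverse_event_cost(occ, s, c(Cataract = 0), 1)
  expect_equal(out1$cost, 1000 * 0.1 * 1373)
  expect_equal(unname(out1$ledger), 0.1)
  out2 <- cycle_adverse_event_cost(occ, s, out1$ledger, 1)
  expect_equal(out2$cost, 900 * 0.1 * 1373)  # only the not-yet-affected
  expect_equal(unname(out2$ledger), 0.19)
  # saturated ledger contributes nothing
  out3 <- cycle_adverse_event_cost(occ, s, c(Cataract = 1), 1)
  expect_equal(out3$cost, 0)
  expect_equal(unname(out3$ledger), 1)
  # zero incidence leaves cost and ledger untouched
  s0 <- treatment_strategy("x", 0, 0, 4, adverse_events = data.frame(
    name = "Cataract", unit_cost = 1373,
    incidence_per_cycle = 0, once_only = TRUE
  ))
  out0 <- cycle_adverse_event_cost(occ, s0, c(Cataract = 0.2), 1)
  expect_equal(out0$cost, 0)
  expect_equal(unname(out0$ledger), 0.2)
})

test_that("lump-sum mode charges the whole once-only incidence in the first cycle", {
  s <- treatment_strategy("x", 0, 0, 4, adverse_events = data.frame(
    name = "Cataract", unit_cost = 1373,
    incidence_per_cycle = 0.1, once_only = TRUE
  ))
  occ <- c(1000, 0, 0, 0, 0)
  out1 <- cycle_adverse_event_cost(occ, s, c(Cataract = 0), 1,
                                   mode = "lump_sum", first_cycle = TRUE)
  expect_equal(out1$cost, 1000 * 0.1 * 1373)
  out2 <- cycle_adverse_event_cost(occ, s, out1$ledger, 1,
                                   mode = "lump_sum", first_cycle = FALSE)
  expect_equal(out2$cost, 0)
})

test_that("follow-up accrues in monitored states and rehabilitation in impaired states", {
  fu <- default_followup()
  rh <- default_rehab()
  # one person in state 1 followed for 12 months (3 cycles of 4 months)
  per_cycle <- cycle_followup_and_rehab_cost(c(1, 0, 0, 0, 0), fu, rh, 4, 1)
  expect_equal(3 * per_cycle$followup, 1755)
  expect_equal(per_cycle$rehab, 0)
  # one person in state 5 for 12 months: rehab only
  per_cycle5 <- cycle_followup_and_rehab_cost(c(0, 0, 0, 0, 1), fu, rh, 4, 1)
  expect_equal(3 * per_cycle5$rehab, 7320)
  expect_equal(per_cycle5$followup, 0)
  # state 4 accrues both
  per_cycle4 <- cycle_followup_and_rehab_cost(c(0, 0, 0, 1, 0), fu, rh, 4, 1)
  expect_equal(3 * per_cycle4$followup, 1755)
  expect_equal(3 * per_cycle4$rehab, 7320)
  # empty schedules cost nothing
  none <- cycle_followup_and_rehab_cost(c(1, 1, 1, 1, 1), NULL, NULL, 4, 1)
  expect_equal(none$followup + none$rehab, 0)
})

test_that("a fixed cohort accrues utility-weighted person-time as QALYs", {
  s <- plain_strategy(cycle = 4, drug = 0, admin = 0)
  tr <- run_trace(s, identity_matrix_set(), horizon_years = 1, cohort_size = 1)
  out <- accrue_outcomes(tr, s, followup = NULL, rehab = NULL, annual_rate = 0)
  expect_equal(out$total_qalys, 0.97)

  # the same person pinned in state 5 (blindness utility)
  tr5 <- tr
  tr5$occupancy[, 1] <- 0
  tr5$occupancy[, 5] <- 1
  out5 <- accrue_outcomes(tr5, s, followup = NULL, rehab = NULL, annual_rate = 0)
  expect_equal(out5$total_qalys, 0.40)

  # zero-length horizon accrues nothing
  tr0 <- run_trace(s, identity_matrix_set(), horizon_years = 0)
  out0 <- accrue_outcomes(tr0, s, annual_rate = 0)
  expect_equal(out0$total_cost, 0)
  expect_equal(out0$total_qalys, 0)
})

test_that("annual cost summaries reproduce the per-year cost table exactly", {
  strategies <- default_strategies()
  dex <- annual_cost_summary(strategies$dexamethasone)
  ta <- annual_cost_summary(strategies$triamcinolone)
  expect_equal(dex$cost_per_year[dex$item == "Medication"], 2580)
  expect_equal(ta$cost_per_year[ta$item == "Medication"], 621)
  expect_equal(dex$cost_per_year[dex$item == "Administration"], 216)
  expect_equal(ta$cost_per_year[ta$item == "Administration"], 228)
  for (tab in list(dex, ta)) {
    expect_equal(tab$cost_per_year[tab$item == "OCT + medical visit"], 690)
    expect_equal(tab$cost_per_year[tab$item == "IOP measurement"], 988)
    expect_equal(tab$cost_per_year[tab$item == "FAG"], 77)
  }
  expect_equal(sum(dex$cost_per_year[3:5]), 1755)
})

test_that("zero-rate discounting is the identity and totals are additive and linear", {
  mats <- generate_matrices(matrix_gen_spec(seed = 5))
  s <- default_strategies()$dexamethasone
  tr <- run_trace(s, mats$dexamethasone, horizon_years = 2)
  out0 <- accrue_outcomes(tr, s, annual_rate = 0)
  expect_equal(out0$total_cost, out0$total_cost_undiscounted)
  expect_equal(out0$total_qalys, out0$total_qalys_undiscounted)

  out3 <- accrue_outcomes(tr, s, annual_rate = 0.03)
  # cost components sum to the total
  expect_equal(sum(out3$cost_components), out3$total_cost, tolerance = 1e-12)
  # discounting strictly reduces totals with positive accrual after time 0
  expect_lt(out3$total_cost, out0$total_cost)
  expect_lt(out3$total_qalys, out0$total_qalys)
  out6 <- accrue_outcomes(tr, s, annual_rate = 0.06)
  expect_lt(out6$total_cost, out3$total_cost)

  # doubling the cohort doubles everything
  tr2 <- run_trace(s, mats$dexamethasone, horizon_years = 2, cohort_size = 2000)
  out2x <- accrue_outcomes(tr2, s, annual_rate = 0.03)
  expect_equal(out2x$total_cost, 2 * out3$total_cost, tolerance = 1e-9)
  expect_equal(out2x$total_qalys, 2 * out3$total_qalys, tolerance = 1e-9)
})

test_that("final-cycle accounting modes split a non-integer horizon as documented", {
  s <- plain_strategy(cycle = 5, drug = 0, admin = 0)
  # 24 months on a 5-month grid: 5 cycles; extend accrues all 25 months,
  # fractional weights the last cycle by 0.8 so accrual equals the horizon
  ext <- run_trace(s, identity_matrix_set(), 2, cohort_size = 1,
                   final_cycle = "extend")
  frac <- run_trace(s, identity_matrix_set(), 2, cohort_size = 1,
                    final_cycle = "fractional")
  expect_equal(ext$cycle_fractions, rep(1, 5))
  expect_equal(frac$cycle_fractions, c(1, 1, 1, 1, 0.8))
  expect_equal(ext$times_months[6], 25)
  expect_equal(frac$times_months[6], 24)
  o_ext <- accrue_outcomes(ext, s, followup = NULL, rehab = NULL, annual_rate = 0)
  o_frac <- accrue_outcomes(frac, s, followup = NULL, rehab = NULL, annual_rate = 0)
  expect_equal(o_ext$total_qalys, 0.97 * 25 / 12)
  expect_equal(o_frac$total_qalys, 0.97 * 2)
})

test_that("a one-cycle toy configuration matches hand-computed accrual", {
  # 1 cycle of 4 months, 10 persons in state 1, drug 100 + admin 10,
  # follow-up 1755/yr, no AEs, rate 0
  s <- plain_strategy(cycle = 4, drug = 100, admin = 10)
  tr <- run_trace(s, identity_matrix_set(), horizon_years = 4 / 12,
                  cohort_size = 10)
  out <- accrue_outcomes(tr, s, annual_rate = 0)
  expect_equal(out$total_cost, 10 * 110 + 10 * 1755 / 3)
  expect_equal(out$total_qalys, 10 * 0.97 / 3)
})
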