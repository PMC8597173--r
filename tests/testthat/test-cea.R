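test_that("the ICER is the cost difference per QALY difference", {
  # the published per-strategy expected values, supplied directly
  dex0 <- economic_outcome("dexamethasone", 9810196, 2016.28, 2, 0)
  ta0 <- economic_outcome("triamcinolone", 5562866, 1936.28, 2, 0)
  r0 <- compute_icer(dex0, ta0)
  expect_equal(r0$delta_cost, 4247330)
  expect_equal(r0$delta_qalys, 80.00)
  expect_equal(r0$icer, 4247330 / 80, tolerance = 1e-12)  # 53091.6...
  expect_equal(r0$dominance, "none")

  dex3 <- economic_outcome("dexamethasone", 9454583, 1943.48, 2, 0.03)
  ta3 <- economic_outcome("triamcinolone", 5374726, 1870.94, 2, 0.03)
  r3 <- compute_icer(dex3, ta3)
  expect_equal(r3$delta_cost, 4079857)
  expect_equal(r3$delta_qalys, 72.54)
  expect_equal(r3$icer, 4079857 / 72.54, tolerance = 1e-12)

  expect_error(compute_icer(dex0, ta3), "different horizons or discount rates")
})

test_that("dominance classification follows the sign pattern of the differences", {
  mk <- function(cost, q) economic_outcome("ref", cost, q, 2, 0)
  cmp <- economic_outcome("cmp", 100, 10, 2, 0)

  same <- compute_icer(economic_outcome("ref", 100, 10, 2, 0), cmp)
  expect_true(is.na(same$icer))
  expect_equal(same$dominance, "none")

  dom_ref <- compute_icer(mk(90, 11), cmp)  # cheaper and more effective
  expect_equal(dom_ref$dominance, "reference_dominant")
  expect_true(is.na(dom_ref$icer))

  dom_cmp <- compute_icer(mk(110, 9), cmp)  # costs more, yields less
  expect_equal(dom_cmp$dominance, "comparator_dominant")
  expect_true(is.na(dom_cmp$icer))
  expect_equal(dom_cmp$icer_signed, 10 / -1)

  # exactly one consistent description for random sign patterns
  set.seed(11)
  for (i in 1:50) {
    r <- compute_icer(mk(100 + rnorm(1, 0, 20), 10 + rnorm(1, 0, 2)), cmp)
    states <- c(defined = !is.na(r$icer) && r$delta_qalys > 0,
                undefined = is.na(r$icer) && r$dominance == "none",
                dominated = r$dominance != "none")
    expect_equal(sum(states), 1L)
  }
})

test_that("willingness-to-pay decisions are monotone in the threshold", {
  dex <- economic_outcome("dexamethasone", 9454583, 1943.48, 2, 0.03)
  ta <- economic_outcome("triamcinolone", 5374726, 1870.94, 2, 0.03)
  r <- compute_icer(dex, ta)  # icer ~ 56,245
  expect_false(decide(r, 30000)$accept_reference)
  expect_false(decide(r, 55000)$accept_reference)
  expect_true(decide(r, 57000)$accept_reference)
  thresholds <- seq(0, 2e5, by = 5000)
  accepts <- vapply(thresholds, function(th) decide(r, th)$accept_reference,
                    logical(1))
  expect_true(all(diff(accepts) >= 0))

  dom <- compute_icer(economic_outcome("a", 110, 9, 2, 0),
                      economic_outcome("b", 100, 10, 2, 0))
  expect_false(decide(dom, 1e9)$accept_reference)  # dominated: never accept
  rd <- compute_icer(economic_outcome("a", 90, 11, 2, 0),
                     economic_outcome("b", 100, 10, 2, 0))
  expect_true(decide(rd, 0)$accept_reference)      # dominant: always accept
  expect_error(decide(r, -1), "non-negative")
})

test_that("identical strategies produce zero incremental difference", {
  cfg <- default_config(seed = 2)
  cfg$strategies$triamcinolone <- cfg$strategies$dexamethasone
  cfg$strategies$triamcinolone$id <- "triamcinolone"
  cfg$matrices$triamcinolone <- lapply(cfg$matrices$dexamethasone, function(m) {
    attr(m, "strategy_id") <- "triamcinolone"
    m
  })
  res <- run_scenario(cfg)
  expect_true(all(abs(res$results$delta_cost) < 1e-6))
  expect_true(all(abs(res$results$delta_qalys) < 1e-9))
})

test_that("a one-cycle toy scenario matches a hand-computed ledger", {
  cfg <- default_config(seed = 1)
  cfg$horizons_years <- 4 / 12
  cfg$discount_rates <- 0
  cfg$strategies <- list(
    dexamethasone = plain_strategy("dexamethasone", cycle = 4, drug = 1000, admin = 0),
    triamcinolone = plain_strategy("triamcinolone", cycle = 4, drug = 100, admin = 0)
  )
  cfg$matrices <- list(dexamethasone = identity_matrix_set("dexamethasone"),
                       triamcinolone = identity_matrix_set("triamcinolone"))
  res <- run_scenario(cfg)
  # same occupancy path, so QALYs cancel; costs differ by drug price alone
  expect_equal(res$results$delta_qalys, 0)
  expect_equal(res$results$delta_cost, 1000 * (1000 - 100))
})

test_that("sensitivity scenarios modify a copy and leave the base config intact", {
  cfg <- default_config(seed = 3)
  before <- config_to_digest(cfg)
  sens <- run_sensitivity(cfg)
  expect_identical(config_to_digest(cfg), before)
  expect_equal(sort(unique(sens$scenario_id)),
               sort(c("ta_cycle_3m", "dex_price_cut", "alt_utilities")))
  # one row per scenario per (horizon, rate)
  expect_equal(nrow(sens), 3 * length(cfg$horizons_years) * length(cfg$discount_rates))
  expect_equal(nrow(run_sensitivity(cfg, list())), 0L)
})

test_that("cutting the dexamethasone price strictly lowers the ICER", {
  cfg <- default_config(seed = 4)
  base <- run_scenario(cfg)$results
  sens <- run_sensitivity(cfg)
  for (h in cfg$horizons_years) {
    for (r in cfg$discount_rates) {
      b <- base[base$horizon_years == h & base$discount_rate == r, ]
      s <- sens[sens$scenario_id == "dex_price_cut" &
                sens$horizon_years == h & sens$discount_rate == r, ]
      expect_lt(s$delta_cost, b$delta_cost)
      if (b$delta_qalys > 0) expect_lt(s$icer_signed, b$icer_signed)
    }
  }
})
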