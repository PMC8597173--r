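#' Discount factor at an annual rate
#'
#' Costs and QALYs are discounted to present value at the cycle start
#' time, compounding the annual rate continuously over fractional
#' years: `(1 + rate)^(-time_years)`.
#'
#' @param time_years non-negative time in years (fractional allowed).
#' @param annual_rate discount rate per annum, >= 0 (0 and 0.03 in the
#'   base case).
#' @return A value in (0, 1].
#' @examples
#' discount_factor(1, 0.03)  # 1/1.03
#' @export
discount_factor <- function(time_years, annual_rate) {
  if (any(time_years < 0)) stop("'time_years' must be non-negative", call. = FALSE)
  if (any(annual_rate < 0)) stop("'annual_rate' must be >= 0", call. = FALSE)
  (1 + annual_rate)^(-time_years)
}

#' Per-cycle treatment (drug + administration) cost
#'
#' Each treated eye receives one dose per cycle. With bilateral disease
#' (states 2-4) both eyes are treated, doubling the drug and
#' administration cost; state 1 treats one eye; state 5 none by
#' default. The cost is weighted by the cycle fraction (a truncated
#' final cycle accrues proportionally).
#'
#' @param occupancy 5-vector of person counts.
#' @param strategy a [treatment_strategy()].
#' @param cycle_fraction accrual weight in (0, 1].
#' @param treated_eyes integer vector of eyes treated per state
#'   (default `c(1, 2, 2, 2, 0)` from [health_states()]).
#' @return Cost in EUR.
#' @examples
#' cycle_drug_cost(c(1, 0, 0, 0, 0), default_strategies()$dexamethasone, 1)
#' @export
cycle_drug_cost <- function(occupancy, strategy, cycle_fraction = 1,
                            treated_eyes = health_states()$treated_eyes) {
  stopifnot(length(occupancy) == 5L, length(treated_eyes) == 5L)
  per_dose <- strategy$drug_unit_cost + strategy$administration_unit_cost
  sum(occupancy * treated_eyes) * per_dose * cycle_fraction
}

#' Per-cycle adverse-event cost with once-only bookkeeping
#'
#' Adverse events are treatment-caused, so incidences apply to the
#' population in drug-treated states. Recurring events (IOP medication,
#' endophthalmitis, retinal detachment) contribute
#' `treated_population * incidence * unit_cost` every cycle; once-only
#' events (cataract surgery, laser, vitrectomy) contribute only for the
#' cohort fraction not yet affected, and the ledger accumulates that
#' fraction until it saturates. An alternative `"lump_sum"` mode
#' charges the full incidence once in the first cycle.
#'
#' @param occupancy 5-vector of person counts.
#' @param strategy a [treatment_strategy()].
#' @param ledger named numeric vector of cohort fractions already
#'   affected, one entry per once-only event (in the order they appear
#'   in the strategy's adverse-event table).
#' @param cycle_fraction accrual weight in (0, 1].
#' @param cohort_size total cohort size (defaults to `sum(occupancy)`,
#'   exact under the no-exit model).
#' @param treated_states logical vector: which states are under
#'   treatment (default states 1-4).
#' @param mode `"saturating"` or `"lump_sum"`.
#' @param first_cycle logical; only used by `"lump_sum"`.
#' @return List with `cost` (EUR) and the updated `ledger`.
#' @export
cycle_adverse_event_cost <- function(occupancy, strategy, ledger,
                                     cycle_fraction = 1,
                                     cohort_size = sum(occupancy),
                                     treated_states = c(TRUE, TRUE, TRUE, TRUE, FALSE),
                                     mode = c("saturating", "lump_sum"),
                                     first_cycle = FALSE) {
  mode <- match.arg(mode)
  if (any(ledger < 0) || any(ledger > 1)) {
    stop("'ledger' fractions must lie in [0, 1]", call. = FALSE)
  }
  ae <- strategy$adverse_events
  treated_pop <- sum(occupancy[treated_states])
  cost <- 0
  once_idx <- which(ae$once_only)
  if (length(once_idx) != length(ledger)) {
    stop("'ledger' must have one entry per once-only adverse event",
         call. = FALSE)
  }
  for (i in seq_len(nrow(ae))) {
    if (ae$once_only[i]) {
      j <- match(i, once_idx)
      step <- onceonly_step(treated_pop, ledger[j], ae$incidence_per_cycle[i],
                            cohort_size, cycle_fraction, mode = mode,
                            first_cycle = first_cycle)
      cost <- cost + step$new_persons * ae$unit_cost[i]
      ledger[j] <- step$ledger
    } else {
      cost <- cost + treated_pop * ae$incidence_per_cycle[i] *
        ae$unit_cost[i] * cycle_fraction
    }
  }
  list(cost = cost, ledger = ledger)
}

#' Per-cycle follow-up and rehabilitation cost
#'
#' Follow-up (OCT, IOP measurement, angiography, visits) accrues pro
#' rata temporis: annual follow-up cost times the cycle length in years
#' times the cycle fraction, for persons in monitored states (1-4 by
#' default). Rehabilitation accrues the same way for persons in the
#' visually impaired states the schedule names (4 and 5).
#'
#' @param occupancy 5-vector of person counts.
#' @param followup follow-up schedule data frame (or `NULL` for none).
#' @param rehab rehabilitation schedule from [default_rehab()] (or
#'   `NULL`).
#' @param cycle_length_months cycle length.
#' @param cycle_fraction accrual weight in (0, 1].
#' @param followup_states logical 5-vector of monitored states.
#' @return List with `followup` and `rehab` costs in EUR.
#' @export
cycle_followup_and_rehab_cost <- function(occupancy, followup, rehab,
                                          cycle_length_months,
                                          cycle_fraction = 1,
                                          followup_states = c(TRUE, TRUE, TRUE, TRUE, FALSE)) {
  years <- cycle_length_months / 12 * cycle_fraction
  fu_cost <- 0
  if (!is.null(followup) && nrow(followup)) {
    annual_fu <- sum(followup$unit_cost * followup$utilization_per_year)
    fu_cost <- sum(occupancy[followup_states]) * annual_fu * years
  }
  rehab_cost <- 0
  if (!is.null(rehab) && nrow(rehab$components)) {
    annual_rehab <- sum(rehab$components$annual_cost)
    rehab_cost <- sum(occupancy[rehab$applies_to_states]) * annual_rehab * years
  }
  list(followup = fu_cost, rehab = rehab_cost)
}

#' Accrue costs and QALYs over a cohort trace
#'
#' Walks the trace cycle by cycle. Occupancy at the cycle start is used
#' for the whole cycle's accrual (no half-cycle correction). Per cycle:
#' treatment, follow-up, rehabilitation and adverse-event costs are
#' computed as in the `cycle_*` functions, QALYs are
#' `sum(occupancy * utility) * cycle_years * fraction`, and both are
#' discounted by [discount_factor()] at the cycle END time — the
#' convention implied by the published discounted-to-undiscounted
#' ratios. Totals are reported discounted and undiscounted; at rate 0
#' the two coincide.
#'
#' @param trace a [run_trace()] result.
#' @param strategy the same strategy the trace was run with.
#' @param followup,rehab cost schedules (defaults as in the base case).
#' @param utilities a [utility_set()].
#' @param annual_rate discount rate per annum.
#' @param states health-state table from [health_states()].
#' @param followup_in_state5 logical; also monitor blind patients.
#' @return An `economic_outcome`: totals (discounted and undiscounted
#'   costs and QALYs), the per-cycle component ledger, and the horizon /
#'   rate metadata needed for incremental comparison.
#' @export
accrue_outcomes <- function(trace, strategy,
                            followup = default_followup(),
                            rehab = default_rehab(),
                            utilities = default_utilities("base"),
                            annual_rate = 0,
                            states = health_states(),
                            followup_in_state5 = FALSE) {
  stopifnot(inherits(trace, "cohort_trace"), inherits(strategy, "treatment_strategy"))
  if (!identical(trace$strategy_id, strategy$id) ||
      abs(trace$cycle_length_months - strategy$cycle_length_months) > 1e-12) {
    stop("trace and strategy use different cycle grids", call. = FALSE)
  }
  n_cycles <- length(trace$cycle_fractions)
  u <- utilities$utility_by_state
  treated_eyes <- states$treated_eyes
  treated_states <- treated_eyes >= 1L
  followup_states <- c(TRUE, TRUE, TRUE, TRUE, followup_in_state5)
  cl_years <- trace$cycle_length_months / 12

  ae <- strategy$adverse_events
  ledger <- rep(0, sum(ae$once_only))

  comp <- data.frame(
    time_months = numeric(n_cycles), cycle_fraction = numeric(n_cycles),
    treatment_cost = numeric(n_cycles), followup_cost = numeric(n_cycles),
    adverse_event_cost = numeric(n_cycles), rehab_cost = numeric(n_cycles),
    qalys = numeric(n_cycles), discount = numeric(n_cycles)
  )

  for (k in seq_len(n_cycles)) {
    occ <- trace$occupancy[k, ]
    frac <- trace$cycle_fractions[k]
    # discount at the cycle's end time
    t_years <- (trace$times_months[k] + trace$cycle_length_months) / 12
    fr <- cycle_followup_and_rehab_cost(occ, followup, rehab,
                                        trace$cycle_length_months, frac,
                                        followup_states)
    aec <- cycle_adverse_event_cost(occ, strategy, ledger, frac,
                                    cohort_size = trace$cohort_size,
                                    treated_states = treated_states,
                                    mode = trace$once_only_mode,
                                    first_cycle = (k == 1L))
    ledger <- aec$ledger
    comp$time_months[k] <- trace$times_months[k]
    comp$cycle_fraction[k] <- frac
    comp$treatment_cost[k] <- cycle_drug_cost(occ, strategy, frac, treated_eyes)
    comp$followup_cost[k] <- fr$followup
    comp$adverse_event_cost[k] <- aec$cost
    comp$rehab_cost[k] <- fr$rehab
    comp$qalys[k] <- sum(occ * u) * cl_years * frac
    comp$discount[k] <- discount_factor(t_years, annual_rate)
  }

  cost_cols <- c("treatment_cost", "followup_cost", "adverse_event_cost",
                 "rehab_cost")
  cycle_cost <- rowSums(comp[cost_cols])
  structure(
    list(
      strategy_id = strategy$id,
      horizon_years = trace$horizon_years,
      discount_rate = annual_rate,
      cohort_size = trace$cohort_size,
      total_cost = sum(cycle_cost * comp$discount),
      total_qalys = sum(comp$qalys * comp$discount),
      total_cost_undiscounted = sum(cycle_cost),
      total_qalys_undiscounted = sum(comp$qalys),
      cost_components = vapply(
        comp[cost_cols], function(x) sum(x * comp$discount), numeric(1)
      ),
      per_cycle_ledger = comp,
      utility_set = utilities$name
    ),
    class = "economic_outcome"
  )
}

#' @export
print.economic_outcome <- function(x, ...) {
  cat(sprintf(
    "Economic outcome: %s | %g y | rate %g\n  cost %12.2f EUR | QALYs %10.2f (discounted)\n  cost %12.2f EUR | QALYs %10.2f (undiscounted)\n",
    x$strategy_id, x$horizon_years, x$discount_rate,
    x$total_cost, x$total_qalys,
    x$total_cost_undiscounted, x$total_qalys_undiscounted
  ))
  invisible(x)
}
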