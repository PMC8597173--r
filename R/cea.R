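#' Construct an economic outcome from totals
#'
#' Builds an `economic_outcome` directly from expected cost and QALY
#' totals, e.g. published per-strategy values, so that incremental
#' comparisons can be formed without re-running the model.
#'
#' @param strategy_id character.
#' @param total_cost expected (discounted) cost, EUR.
#' @param total_qalys expected (discounted) QALYs.
#' @param horizon_years,discount_rate comparison metadata.
#' @param cohort_size cohort the totals refer to (default 1000).
#' @return An `economic_outcome`.
#' @export
economic_outcome <- function(strategy_id, total_cost, total_qalys,
                             horizon_years, discount_rate,
                             cohort_size = 1000) {
  if (total_cost < 0 || total_qalys < 0) {
    stop("totals must be non-negative", call. = FALSE)
  }
  structure(
    list(
      strategy_id = as.character(strategy_id),
      horizon_years = horizon_years, discount_rate = discount_rate,
      cohort_size = cohort_size,
      total_cost = total_cost, total_qalys = total_qalys,
      total_cost_undiscounted = if (discount_rate == 0) total_cost else NA_real_,
      total_qalys_undiscounted = if (discount_rate == 0) total_qalys else NA_real_,
      cost_components = NULL, per_cycle_ledger = NULL, utility_set = NA_character_
    ),
    class = "economic_outcome"
  )
}

#' Incremental cost-effectiveness of one strategy over another
#'
#' Differences are reference minus comparator. When the reference
#' strategy costs more and yields more QALYs the ICER is their
#' quotient, in EUR per QALY. When one strategy costs less AND yields
#' more it dominates: the ICER is then not meaningful as a price and is
#' reported as `NA` in the primary field, with the signed quotient
#' available as `icer_signed` (a negative ICER conventionally signals
#' dominance in published tables).
#'
#' @param outcome_ref reference-strategy `economic_outcome` (here
#'   dexamethasone).
#' @param outcome_cmp comparator `economic_outcome` (here
#'   triamcinolone).
#' @return A `cea_result`: list with `delta_cost`, `delta_qalys`,
#'   `icer` (NA unless defined), `icer_signed`, `dominance` (one of
#'   `"none"`, `"reference_dominant"`, `"comparator_dominant"`), and
#'   the shared horizon / rate.
#' @examples
#' a <- economic_outcome("dex", 9810196, 2016.28, 2, 0)
#' b <- economic_outcome("ta", 5562866, 1936.28, 2, 0)
#' compute_icer(a, b)
#' @export
compute_icer <- function(outcome_ref, outcome_cmp) {
  stopifnot(inherits(outcome_ref, "economic_outcome"),
            inherits(outcome_cmp, "economic_outcome"))
  if (!isTRUE(all.equal(outcome_ref$horizon_years, outcome_cmp$horizon_years)) ||
      !isTRUE(all.equal(outcome_ref$discount_rate, outcome_cmp$discount_rate))) {
    stop("outcomes compare different horizons or discount rates", call. = FALSE)
  }
  dc <- outcome_ref$total_cost - outcome_cmp$total_cost
  dq <- outcome_ref$total_qalys - outcome_cmp$total_qalys

  dominance <- "none"
  if (dc > 0 && dq < 0) dominance <- "comparator_dominant"
  if (dc < 0 && dq > 0) dominance <- "reference_dominant"

  icer_signed <- if (abs(dq) < 1e-12) NA_real_ else dc / dq
  icer <- if (dominance == "none" && dq > 1e-12) dc / dq else NA_real_

  structure(
    list(
      reference_strategy = outcome_ref$strategy_id,
      comparator_strategy = outcome_cmp$strategy_id,
      delta_cost = dc, delta_qalys = dq,
      icer = icer, icer_signed = icer_signed,
      dominance = dominance,
      discount_rate = outcome_ref$discount_rate,
      horizon_years = outcome_ref$horizon_years
    ),
    class = "cea_result"
  )
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("CEA: %s vs %s | %g y | rate %g\n", x$reference_strategy,
              x$comparator_strategy, x$horizon_years, x$discount_rate))
  cat(sprintf("  delta cost %12.2f EUR | delta QALYs %10.4f\n",
              x$delta_cost, x$delta_qalys))
  if (x$dominance == "comparator_dominant") {
    cat("  ", x$comparator_strategy, " dominates (cheaper and more effective);",
        " signed ICER ", format(round(x$icer_signed)), " EUR/QALY\n", sep = "")
  } else if (x$dominance == "reference_dominant") {
    cat("  ", x$reference_strategy, " dominates (cheaper and more effective)\n",
        sep = "")
  } else if (is.na(x$icer)) {
    cat("  ICER undefined (no QALY difference)\n")
  } else {
    cat(sprintf("  ICER %.1f EUR/QALY\n", x$icer))
  }
  invisible(x)
}

#' Willingness-to-pay decision
#'
#' The reference strategy is accepted when it dominates, or when its
#' ICER is defined (positive QALY gain) and does not exceed the
#' decision-maker's willingness to pay per QALY.
#'
#' @param result a [compute_icer()] result.
#' @param threshold willingness-to-pay, EUR per QALY (>= 0).
#' @return A `wtp_decision`: list with `threshold` and
#'   `accept_reference`.
#' @export
decide <- function(result, threshold) {
  stopifnot(inherits(result, "cea_result"))
  if (!is.numeric(threshold) || threshold < 0) {
    stop("'threshold' must be a non-negative EUR/QALY value", call. = FALSE)
  }
  accept <- result$dominance == "reference_dominant" ||
    (!is.na(result$icer) && result$delta_qalys > 0 && result$icer <= threshold)
  structure(list(threshold = threshold, accept_reference = accept,
                 reference_strategy = result$reference_strategy),
            class = "wtp_decision")
}

#' @export
print.wtp_decision <- function(x, ...) {
  cat(sprintf("WTP %.0f EUR/QALY: %s %s\n", x$threshold,
              if (x$accept_reference) "accept" else "reject",
              x$reference_strategy))
  invisible(x)
}

#' Run the full base-case scenario
#'
#' For every (horizon, discount rate) combination in the configuration,
#' runs both strategies through the Markov engine, accrues costs and
#' QALYs, and forms the incremental comparison with the first strategy
#' (dexamethasone in the base case) as reference. Deterministic given
#' the configuration.
#'
#' @param config a scenario configuration from [default_config()] or
#'   [load_config()].
#' @return A `scenario_result`: list with `outcomes` (data frame of
#'   per-strategy expected costs/QALYs per horizon and rate), `results`
#'   (data frame of incremental comparisons), `cea` (list of
#'   `cea_result` objects keyed `"<horizon>y_<rate>"`), and the
#'   resolved `config`.
#' @export
run_scenario <- function(config) {
  config <- validate_config(config)
  strategies <- config$strategies
  matrices <- config$matrices
  states <- health_states(state5_treatment = config$switches$state5_treatment)
  utilities <- config$utilities

  outcome_rows <- list()
  result_rows <- list()
  cea <- list()
  for (h in config$horizons_years) {
    traces <- lapply(strategies, function(s) {
      run_trace(s, matrices[[s$id]], h, cohort_size = config$cohort_size,
                states = states, once_only_mode = config$switches$once_only_mode,
                final_cycle = config$switches$final_cycle)
    })
    for (r in config$discount_rates) {
      outs <- lapply(names(strategies), function(sid) {
        accrue_outcomes(traces[[sid]], strategies[[sid]],
                        followup = config$followup, rehab = config$rehab,
                        utilities = utilities, annual_rate = r,
                        states = states,
                        followup_in_state5 = config$switches$followup_in_state5)
      })
      names(outs) <- names(strategies)
      for (o in outs) {
        outcome_rows[[length(outcome_rows) + 1L]] <- data.frame(
          horizon_years = h, discount_rate = r, strategy = o$strategy_id,
          expected_cost = o$total_cost, expected_qalys = o$total_qalys,
          stringsAsFactors = FALSE
        )
      }
      res <- compute_icer(outs[[1L]], outs[[2L]])
      key <- sprintf("%gy_%g", h, r)
      cea[[key]] <- res
      result_rows[[length(result_rows) + 1L]] <- data.frame(
        horizon_years = h, discount_rate = r,
        reference = res$reference_strategy, comparator = res$comparator_strategy,
        delta_cost = res$delta_cost, delta_qalys = res$delta_qalys,
        icer = res$icer, icer_signed = res$icer_signed,
        dominance = res$dominance, stringsAsFactors = FALSE
      )
    }
  }
  structure(
    list(
      outcomes = do.call(rbind, outcome_rows),
      results = do.call(rbind, result_rows),
      cea = cea,
      config = config
    ),
    class = "scenario_result"
  )
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("Scenario results (per", format(x$config$cohort_size), "patients):\n\n")
  out <- x$outcomes
  out$expected_cost <- round(out$expected_cost)
  out$expected_qalys <- round(out$expected_qalys, 2)
  print(out, row.names = FALSE)
  cat("\nIncremental (", x$results$reference[1], " - ",
      x$results$comparator[1], "):\n", sep = "")
  res <- x$results[, c("horizon_years", "discount_rate", "delta_cost",
                       "delta_qalys", "icer_signed", "dominance")]
  res$delta_cost <- round(res$delta_cost)
  res$delta_qalys <- round(res$delta_qalys, 2)
  res$icer_signed <- round(res$icer_signed)
  print(res, row.names = FALSE)
  invisible(x)
}

#' The bundled deterministic sensitivity scenarios
#'
#' Three one-way scenarios: (1) shorten the triamcinolone cycle from 4
#' to 3 months (the same per-cycle transition matrices are reused for
#' the shorter cycle — no re-estimated matrices exist for it, so the
#' scenario isolates the cost of more frequent dosing); (2) lower the
#' dexamethasone implant price by 20%; (3) swap the utility set for the
#' alternative (Sharma) values.
#'
#' @return Named list of `sensitivity_scenario` objects, each with
#'   `name` and a `modify` function acting on a config.
#' @export
sensitivity_scenarios <- function() {
  scen <- function(name, modify) {
    structure(list(name = name, modify = modify),
              class = "sensitivity_scenario")
  }
  list(
    ta_cycle_3m = scen("3-month cycle length for triamcinolone", function(cfg) {
      cfg$strategies$triamcinolone$cycle_length_months <- 3
      cfg
    }),
    dex_price_cut = scen("Dexamethasone implant cost lowered by 20%", function(cfg) {
      cfg$strategies$dexamethasone$drug_unit_cost <-
        cfg$strategies$dexamethasone$drug_unit_cost * 0.8
      cfg
    }),
    alt_utilities = scen("Alternative (Sharma) utilities", function(cfg) {
      cfg$utilities <- default_utilities("sharma")
      cfg
    })
  )
}

#' Run deterministic sensitivity analyses
#'
#' Applies each scenario's modification to a copy of the configuration,
#' re-runs the full scenario, and collects one incremental result per
#' scenario per (horizon, rate) pair. The base configuration is left
#' untouched.
#'
#' @param config scenario configuration.
#' @param scenarios list of scenarios (default the three bundled ones
#'   from [sensitivity_scenarios()]).
#' @return Data frame: `scenario`, `horizon_years`, `discount_rate`,
#'   `delta_cost`, `delta_qalys`, `icer`, `icer_signed`, `dominance`.
#' @export
run_sensitivity <- function(config, scenarios = sensitivity_scenarios()) {
  if (length(scenarios) == 0L) {
    return(data.frame(
      scenario = character(), scenario_id = character(),
      horizon_years = numeric(), discount_rate = numeric(),
      reference = character(), comparator = character(),
      delta_cost = numeric(), delta_qalys = numeric(),
      icer = numeric(), icer_signed = numeric(), dominance = character(),
      stringsAsFactors = FALSE
    ))
  }
  rows <- list()
  for (nm in names(scenarios)) {
    sc <- scenarios[[nm]]
    modified <- sc$modify(config)
    res <- run_scenario(modified)$results
    res <- cbind(scenario = sc$name, scenario_id = nm, res,
                 stringsAsFactors = FALSE)
    rows[[nm]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
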