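#' Build the cycle grid for a strategy
#'
#' Cycle length equals the re-dosing interval and is constant over the
#' whole follow-up (5 months for the dexamethasone implant, 4 for
#' triamcinolone injections). When the horizon is not an integer
#' multiple of the cycle length the final cycle is truncated: its
#' transitions are still applied in full (a state change is a discrete
#' event tied to the dose given at the cycle start) but cost and QALY
#' accrual in it is weighted by the fraction of the cycle inside the
#' horizon. A 2-year dexamethasone run is thus 4 full 5-month cycles
#' plus a 0.8-weight fifth cycle, preserving 2.4 doses per year.
#'
#' @param cycle_length_months positive; months between doses.
#' @param horizon_years positive (or zero for an empty grid); model time
#'   horizon.
#' @return A `cycle_grid`: list with `cycle_length_months`, `boundaries`
#'   (cycle start times in months, beginning at 0), `cycle_fractions`
#'   (accrual weight of each cycle; all 1 except possibly the last), and
#'   `final_cycle_fraction`.
#' @examples
#' build_cycle_grid(5, 2)  # 5 cycles, last one weighted 0.8
#' @export
build_cycle_grid <- function(cycle_length_months, horizon_years) {
  if (!is.numeric(cycle_length_months) || length(cycle_length_months) != 1L ||
      !is.finite(cycle_length_months) || cycle_length_months <= 0) {
    stop("'cycle_length_months' must be a positive number", call. = FALSE)
  }
  if (!is.numeric(horizon_years) || length(horizon_years) != 1L ||
      !is.finite(horizon_years) || horizon_years < 0) {
    stop("'horizon_years' must be a non-negative number", call. = FALSE)
  }
  horizon_months <- horizon_years * 12
  n_full <- floor(horizon_months / cycle_length_months + 1e-12)
  remainder <- horizon_months - n_full * cycle_length_months
  if (remainder < 1e-9) {
    n_cycles <- n_full
    final_fraction <- if (n_full > 0) 1 else NA_real_
  } else {
    n_cycles <- n_full + 1L
    final_fraction <- remainder / cycle_length_months
  }
  boundaries <- cycle_length_months * seq_len(n_cycles + 1L) - cycle_length_months
  fractions <- rep(1, n_cycles)
  if (n_cycles > 0) fractions[n_cycles] <- final_fraction
  structure(
    list(
      cycle_length_months = cycle_length_months,
      boundaries = boundaries[seq_len(n_cycles)],
      cycle_fractions = fractions,
      final_cycle_fraction = final_fraction,
      horizon_years = horizon_years
    ),
    class = "cycle_grid"
  )
}

#' Select the transition matrix for a cycle
#'
#' Two matrices per strategy encode that the first doses are more
#' effective than later ones: an early matrix for follow-up under 12
#' months and a late matrix afterwards. Assignment uses the cycle START
#' time (the dose is delivered at the cycle start): a cycle beginning
#' before month 12 uses the early matrix even if it ends after month 12;
#' a cycle beginning exactly at month 12 uses the late matrix.
#'
#' @param matrices `list(early=, late=)` for one strategy.
#' @param cycle_start_months non-negative cycle start time in months.
#' @return The applicable `transition_matrix`.
#' @export
select_matrix <- function(matrices, cycle_start_months) {
  if (is.null(matrices$early) || is.null(matrices$late)) {
    stop("matrix set must contain both an 'early' and a 'late' matrix",
         call. = FALSE)
  }
  if (cycle_start_months < 0) {
    stop("'cycle_start_months' must be non-negative", call. = FALSE)
  }
  if (cycle_start_months < 12) matrices$early else matrices$late
}

#' Advance a cohort occupancy vector by one cycle
#'
#' @param occupancy numeric vector of length 5, non-negative person
#'   counts per state.
#' @param matrix a `transition_matrix` (or a plain valid 5x5 matrix).
#' @return The next occupancy vector `occupancy \%*\% p`; the total
#'   count is conserved.
#' @examples
#' p <- diag(5)
#' advance_cohort(c(1000, 0, 0, 0, 0), p)
#' @export
advance_cohort <- function(occupancy, matrix) {
  if (!is.numeric(occupancy) || length(occupancy) != 5L) {
    stop("'occupancy' must be a numeric vector of length 5", call. = FALSE)
  }
  if (any(occupancy < 0)) {
    stop("'occupancy' must be non-negative", call. = FALSE)
  }
  m <- unclass(matrix)
  if (!is.matrix(m) || !all(dim(m) == c(5L, 5L))) {
    stop("'matrix' must be 5x5", call. = FALSE)
  }
  as.numeric(occupancy %*% m)
}

#' Run a cohort trace for one strategy
#'
#' The whole cohort starts in state 1 (one eye with oedema, good
#' acuity). Each cycle the occupancy is propagated by the early or late
#' matrix chosen at the cycle's start time; the once-only adverse-event
#' ledger (cohort fraction that has already incurred cataract surgery,
#' laser, or vitrectomy) is advanced in step so the trace carries full
#' bookkeeping. No mortality or other exit exists: occupancy always
#' sums to the cohort size.
#'
#' @param strategy a [treatment_strategy()].
#' @param matrices `list(early=, late=)` transition matrices for the
#'   strategy.
#' @param horizon_years non-negative model horizon.
#' @param cohort_size positive cohort size (default 1000).
#' @param states health-state table from [health_states()]; controls
#'   which states are treated (and hence at adverse-event risk).
#' @param once_only_mode `"saturating"` (each cycle the not-yet-affected
#'   treated fraction can incur the event) or `"lump_sum"` (the whole
#'   incidence charged in the first cycle).
#' @param final_cycle how a horizon that is not a whole number of cycles
#'   is closed out. `"extend"` (the default, matching the published
#'   accrual arithmetic): the last cycle runs and accrues in full, so a
#'   2-year horizon on a 5-month cycle covers 25 months of dosing,
#'   monitoring and utility. `"fractional"`: the last cycle's
#'   transitions still apply in full but its cost/QALY accrual is
#'   weighted by the fraction of the cycle inside the horizon.
#' @return A `cohort_trace`: list with `strategy_id`, `occupancy`
#'   (matrix, one row per cycle start plus a final row at the horizon),
#'   `times_months`, `cycle_fractions`, and `cumulative_onceonly`
#'   (matrix of cohort fractions, one column per once-only event).
#' @export
run_trace <- function(strategy, matrices, horizon_years,
                      cohort_size = 1000,
                      states = health_states(),
                      once_only_mode = c("saturating", "lump_sum"),
                      final_cycle = c("extend", "fractional")) {
  once_only_mode <- match.arg(once_only_mode)
  final_cycle <- match.arg(final_cycle)
  stopifnot(inherits(strategy, "treatment_strategy"))
  if (!is.numeric(cohort_size) || cohort_size <= 0) {
    stop("'cohort_size' must be positive", call. = FALSE)
  }
  grid <- build_cycle_grid(strategy$cycle_length_months, horizon_years)
  n_cycles <- length(grid$boundaries)
  if (final_cycle == "extend" && n_cycles > 0) {
    grid$cycle_fractions[n_cycles] <- 1
  }
  end_months <- if (n_cycles > 0 && final_cycle == "extend") {
    grid$boundaries[n_cycles] + grid$cycle_length_months
  } else {
    horizon_years * 12
  }

  occ <- matrix(0, nrow = n_cycles + 1L, ncol = 5L,
                dimnames = list(NULL, paste0("s", 1:5)))
  occ[1L, 1L] <- cohort_size

  ae <- strategy$adverse_events
  once <- ae[ae$once_only, , drop = FALSE]
  ledger <- matrix(0, nrow = n_cycles + 1L, ncol = nrow(once),
                   dimnames = list(NULL, once$name))

  treated <- states$treated_eyes >= 1L
  for (k in seq_len(n_cycles)) {
    frac <- grid$cycle_fractions[k]
    treated_pop <- sum(occ[k, treated])
    ledger[k + 1L, ] <- ledger[k, ]
    if (nrow(once)) {
      for (j in seq_len(nrow(once))) {
        step <- onceonly_step(
          treated_pop, ledger[k, j], once$incidence_per_cycle[j],
          cohort_size, frac, mode = once_only_mode, first_cycle = (k == 1L)
        )
        ledger[k + 1L, j] <- step$ledger
      }
    }
    m <- select_matrix(matrices, grid$boundaries[k])
    occ[k + 1L, ] <- advance_cohort(occ[k, ], m)
  }

  structure(
    list(
      strategy_id = strategy$id,
      occupancy = occ,
      times_months = c(grid$boundaries, end_months),
      cycle_fractions = grid$cycle_fractions,
      cycle_length_months = strategy$cycle_length_months,
      horizon_years = horizon_years,
      cohort_size = cohort_size,
      cumulative_onceonly = ledger,
      once_only_mode = once_only_mode,
      final_cycle = final_cycle
    ),
    class = "cohort_trace"
  )
}

# One once-only bookkeeping step for a single event. `ledger` is the
# cohort fraction already affected; returns the new fraction and the
# number of newly affected persons this cycle.
onceonly_step <- function(treated_pop, ledger, incidence, cohort_size,
                          cycle_fraction, mode = "saturating",
                          first_cycle = FALSE) {
  if (mode == "lump_sum") {
    if (!first_cycle) return(list(ledger = ledger, new_persons = 0))
    new_persons <- treated_pop * incidence
    return(list(ledger = min(1, ledger + new_persons / cohort_size),
                new_persons = new_persons))
  }
  at_risk <- max(0, treated_pop - ledger * cohort_size)
  new_persons <- at_risk * incidence * cycle_fraction
  list(ledger = min(1, ledger + new_persons / cohort_size),
       new_persons = new_persons)
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat("Cohort trace:", x$strategy_id, "|", nrow(x$occupancy) - 1L,
      "cycles |", x$horizon_years, "years |", x$cohort_size, "persons\n")
  cat("Final occupancy:",
      paste(format(round(x$occupancy[nrow(x$occupancy), ], 2)), collapse = " "),
      "\n")
  invisible(x)
}

#' Flatten a cohort trace to a data frame
#'
#' One row per trace time point (cycle starts plus the horizon), with
#' occupancy per state and the cumulative once-only ledgers; suitable
#' for CSV export.
#'
#' @param x a `cohort_trace`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return A data frame.
#' @export
as.data.frame.cohort_trace <- function(x, row.names = NULL, optional = FALSE, ...) {
  df <- data.frame(
    strategy = x$strategy_id,
    time_months = x$times_months,
    x$occupancy,
    stringsAsFactors = FALSE
  )
  if (ncol(x$cumulative_onceonly)) {
    led <- as.data.frame(x$cumulative_onceonly)
    names(led) <- paste0("onceonly_", gsub("[^a-z0-9]+", "_",
                                           tolower(names(led))))
    df <- cbind(df, led)
  }
  df
}

#' Write a cohort trace to CSV
#'
#' @param trace a `cohort_trace`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
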