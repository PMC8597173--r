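#' Base-case scenario configuration
#'
#' Bundles everything a run needs: the two strategies (dexamethasone,
#' 5-month cycle; triamcinolone, 4-month cycle) with their unit costs
#' and adverse-event profiles, transition matrices (generated from the
#' synthetic spec unless supplied), the follow-up, rehabilitation and
#' utility schedules, horizons of 2 and 5 years, discount rates of 0%
#' and 3%, and a cohort of 1000 patients.
#'
#' @param seed integer; forwarded to the matrix generator.
#' @param matrices optional pre-built matrix sets (named list per
#'   strategy of `list(early=, late=)`); generated when `NULL`.
#' @param gen_spec optional [matrix_gen_spec()]; defaults to
#'   `matrix_gen_spec(seed = seed)`.
#' @param horizons_years,discount_rates,cohort_size base-case grid.
#' @param utilities a [utility_set()].
#' @param state5_treatment,followup_in_state5,once_only_mode model
#'   switches; see [health_states()], [accrue_outcomes()],
#'   [cycle_adverse_event_cost()].
#' @return A `scenario_config`.
#' @export
default_config <- function(seed = 1L, matrices = NULL, gen_spec = NULL,
                           horizons_years = c(2, 5),
                           discount_rates = c(0, 0.03),
                           cohort_size = 1000,
                           utilities = default_utilities("base"),
                           state5_treatment = FALSE,
                           followup_in_state5 = FALSE,
                           once_only_mode = "saturating",
                           final_cycle = "extend") {
  if (is.null(gen_spec)) gen_spec <- matrix_gen_spec(seed = seed)
  if (is.null(matrices)) matrices <- generate_matrices(gen_spec)
  structure(
    list(
      strategies = default_strategies(),
      matrices = matrices,
      gen_spec = gen_spec,
      followup = default_followup(),
      rehab = default_rehab(),
      utilities = utilities,
      horizons_years = horizons_years,
      discount_rates = discount_rates,
      cohort_size = cohort_size,
      seed = as.integer(seed),
      switches = list(
        state5_treatment = state5_treatment,
        followup_in_state5 = followup_in_state5,
        once_only_mode = once_only_mode,
        final_cycle = final_cycle
      )
    ),
    class = "scenario_config"
  )
}

#' Validate a scenario configuration
#'
#' Checks the complete configuration and reports every problem at once
#' (field paths included) rather than stopping at the first.
#'
#' @param config a `scenario_config` (or a bare list with the same
#'   fields).
#' @return The validated config, invisibly classed `scenario_config`.
#' @export
validate_config <- function(config) {
  problems <- character()
  need <- function(cond, msg) {
    if (!isTRUE(cond)) problems <<- c(problems, msg)
  }
  need(is.list(config$strategies) && length(config$strategies) == 2L,
       "strategies: exactly two treatment strategies are required")
  if (is.list(config$strategies)) {
    for (nm in names(config$strategies)) {
      s <- config$strategies[[nm]]
      need(inherits(s, "treatment_strategy"),
           paste0("strategies.", nm, ": not a treatment_strategy"))
      if (inherits(s, "treatment_strategy")) {
        need(s$cycle_length_months > 0,
             paste0("strategies.", nm, ".cycle_length_months: must be positive"))
        need(s$drug_unit_cost >= 0 && s$administration_unit_cost >= 0,
             paste0("strategies.", nm, ": unit costs must be non-negative"))
      }
    }
  }
  if (!is.null(config$matrices)) {
    rep <- validate_matrices(config$matrices)
    if (length(rep)) problems <- c(problems, paste0("matrices: ", rep))
    miss <- setdiff(names(config$strategies), names(config$matrices))
    need(length(miss) == 0,
         paste0("matrices: missing set for ", paste(miss, collapse = ", ")))
  } else {
    need(FALSE, "matrices: missing")
  }
  need(inherits(config$utilities, "utility_set"), "utilities: not a utility_set")
  need(is.numeric(config$horizons_years) && all(config$horizons_years >= 0),
       "horizons_years: must be non-negative numbers")
  need(is.numeric(config$discount_rates) && all(config$discount_rates >= 0),
       "discount_rates: must be >= 0")
  need(is.numeric(config$cohort_size) && config$cohort_size > 0,
       "cohort_size: must be positive")
  need(config$switches$once_only_mode %in% c("saturating", "lump_sum"),
       "switches.once_only_mode: must be 'saturating' or 'lump_sum'")
  need(config$switches$final_cycle %in% c("extend", "fractional"),
       "switches.final_cycle: must be 'extend' or 'fractional'")
  if (length(problems)) {
    stop("invalid scenario configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  class(config) <- "scenario_config"
  invisible(config)
}

matrix_to_rows <- function(m) lapply(1:5, function(i) as.numeric(unclass(m)[i, ]))

rows_to_matrix <- function(rows, sid, period) {
  p <- do.call(rbind, lapply(rows, as.numeric))
  transition_matrix(p, sid, period)
}

config_to_list <- function(config) {
  list(
    strategies = lapply(config$strategies, function(s) {
      list(id = s$id, drug_unit_cost = s$drug_unit_cost,
           administration_unit_cost = s$administration_unit_cost,
           cycle_length_months = s$cycle_length_months,
           adverse_events = lapply(seq_len(nrow(s$adverse_events)), function(i)
             as.list(s$adverse_events[i, ])))
    }),
    matrices = lapply(config$matrices, function(set)
      lapply(set, matrix_to_rows)),
    followup = lapply(seq_len(nrow(config$followup)), function(i)
      as.list(as.data.frame(config$followup)[i, ])),
    rehab = list(
      components = lapply(seq_len(nrow(config$rehab$components)), function(i)
        as.list(config$rehab$components[i, ])),
      applies_to_states = as.integer(config$rehab$applies_to_states)
    ),
    utilities = list(name = config$utilities$name,
                     utility_by_state = config$utilities$utility_by_state),
    horizons_years = config$horizons_years,
    discount_rates = config$discount_rates,
    cohort_size = config$cohort_size,
    seed = config$seed,
    switches = config$switches
  )
}

list_to_config <- function(x, dir = ".") {
  strategies <- lapply(x$strategies, function(s) {
    ae <- if (length(s$adverse_events)) {
      do.call(rbind, lapply(s$adverse_events, function(r)
        data.frame(name = r$name, unit_cost = r$unit_cost,
                   incidence_per_cycle = r$incidence_per_cycle,
                   once_only = r$once_only, stringsAsFactors = FALSE)))
    } else empty_adverse_events()
    treatment_strategy(s$id, s$drug_unit_cost, s$administration_unit_cost,
                       s$cycle_length_months, ae)
  })
  names(strategies) <- vapply(strategies, `[[`, character(1), "id")

  matrices <- NULL
  if (is.character(x$matrices)) {
    path <- x$matrices
    if (!file.exists(path)) path <- file.path(dir, x$matrices)
    if (!file.exists(path)) {
      stop("matrix file not found: ", x$matrices, call. = FALSE)
    }
    matrices <- read_matrices(path)
  } else if (is.list(x$matrices)) {
    matrices <- lapply(names(x$matrices), function(sid) {
      set <- x$matrices[[sid]]
      lapply(stats::setNames(names(set), names(set)), function(period)
        rows_to_matrix(set[[period]], sid, period))
    })
    names(matrices) <- names(x$matrices)
  }

  followup <- do.call(rbind, lapply(x$followup, function(r)
    data.frame(name = r$name, unit_cost = r$unit_cost,
               utilization_per_year = r$utilization_per_year,
               stringsAsFactors = FALSE)))
  class(followup) <- c("followup_schedule", "data.frame")

  rehab <- structure(
    list(
      components = do.call(rbind, lapply(x$rehab$components, function(r)
        data.frame(name = r$name, annual_cost = r$annual_cost,
                   stringsAsFactors = FALSE))),
      applies_to_states = as.integer(x$rehab$applies_to_states)
    ),
    class = "rehab_schedule"
  )

  cfg <- structure(
    list(
      strategies = strategies,
      matrices = matrices,
      gen_spec = NULL,
      followup = followup,
      rehab = rehab,
      utilities = utility_set(x$utilities$name,
                              as.numeric(x$utilities$utility_by_state)),
      horizons_years = as.numeric(x$horizons_years),
      discount_rates = as.numeric(x$discount_rates),
      cohort_size = as.numeric(x$cohort_size),
      seed = as.integer(x$seed %||% 1L),
      switches = list(
        state5_treatment = isTRUE(x$switches$state5_treatment),
        followup_in_state5 = isTRUE(x$switches$followup_in_state5),
        once_only_mode = x$switches$once_only_mode %||% "saturating",
        final_cycle = x$switches$final_cycle %||% "extend"
      )
    ),
    class = "scenario_config"
  )
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a scenario configuration to YAML or JSON
#'
#' @param config a `scenario_config`.
#' @param path destination; format chosen by extension (`.yaml`/`.yml`
#'   or `.json`).
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  x <- config_to_list(config)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(x, path, precision = 15)
  }
  invisible(path)
}

#' Load and validate a scenario configuration
#'
#' Reads a YAML or JSON configuration (matrices either inline or as a
#' CSV path resolved relative to the config file) and validates it,
#' reporting all invariant violations at once.
#'
#' @param path configuration file.
#' @return A validated `scenario_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                        simplifyMatrix = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  required <- c("strategies", "matrices", "followup", "rehab", "utilities",
                "horizons_years", "discount_rates", "cohort_size")
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    stop("config ", path, " is missing fields: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  cfg <- list_to_config(x, dir = dirname(path))
  validate_config(cfg)
  cfg
}
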