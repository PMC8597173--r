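#' Health states of the diabetic macular oedema model
#'
#' The model tracks a cohort across five health states defined by the
#' visual acuity of the better-seeing eye (Snellen decimal). State 1 is
#' unilateral disease with good acuity; states 2-4 are bilateral disease
#' with progressively worse acuity; state 5 is blindness (acuity below
#' 0.05), the absorbing endpoint. Treatment is bilateral in states 2-4
#' (both eyes receive drug, doubling treatment cost), unilateral in
#' state 1, and absent in state 5 by default (the endpoint receives no
#' further injections; see `state5_treatment` in [default_config()]).
#' Rehabilitation costs for visual impairment apply in states 4 and 5.
#'
#' @param state5_treatment logical; if `TRUE`, state 5 continues to
#'   receive bilateral treatment (and adverse-event risk) instead of
#'   none. Default `FALSE`.
#' @return A data frame with one row per state and columns `index`,
#'   `label`, `va_band`, `bilateral_dmo`, `treated_eyes`,
#'   `rehab_eligible`.
#' @examples
#' health_states()
#' @export
health_states <- function(state5_treatment = FALSE) {
  stopifnot(is.logical(state5_treatment), length(state5_treatment) == 1L)
  data.frame(
    index = 1:5,
    label = c(
      "unilateral DMO, good acuity",
      "bilateral DMO, good acuity",
      "bilateral DMO, mild visual impairment",
      "bilateral DMO, moderate to severe visual impairment",
      "bilateral DMO, blindness"
    ),
    va_band = c(">=0.5", ">=0.5", "[0.3,0.5)", "[0.05,0.3)", "<0.05"),
    bilateral_dmo = c(FALSE, TRUE, TRUE, TRUE, TRUE),
    treated_eyes = c(1L, 2L, 2L, 2L, if (state5_treatment) 2L else 0L),
    rehab_eligible = c(FALSE, FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Health-state utility sets
#'
#' Utilities weight time in each state when accruing QALYs. The base set
#' comes from time-tradeoff studies of macular disease; the alternative
#' set (`"sharma"`) averages published ranges for eye disease in general
#' and is used in the third sensitivity analysis.
#'
#' @param name `"base"` or `"sharma"`.
#' @return An object of class `utility_set`: a list with `name` and
#'   `utility_by_state` (numeric vector of length 5).
#' @examples
#' default_utilities("base")$utility_by_state
#' @export
default_utilities <- function(name = c("base", "sharma")) {
  name <- match.arg(name)
  u <- switch(name,
    base = c(0.97, 0.89, 0.81, 0.55, 0.40),
    sharma = c(0.93, 0.85, 0.66, 0.58, 0.53)
  )
  utility_set(name, u)
}

#' Construct a utility set
#'
#' @param name character label.
#' @param utility_by_state numeric vector of length 5, each in \[0, 1\].
#' @return An object of class `utility_set`.
#' @export
utility_set <- function(name, utility_by_state) {
  if (!is.numeric(utility_by_state) || length(utility_by_state) != 5L) {
    stop("'utility_by_state' must be a numeric vector of length 5", call. = FALSE)
  }
  if (any(utility_by_state < 0) || any(utility_by_state > 1)) {
    stop("utilities must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(name = as.character(name), utility_by_state = as.numeric(utility_by_state)),
    class = "utility_set"
  )
}

#' @export
print.utility_set <- function(x, ...) {
  cat("Utility set '", x$name, "': ",
      paste(format(x$utility_by_state), collapse = ", "), "\n", sep = "")
  invisible(x)
}
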