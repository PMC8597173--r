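#' Construct a per-cycle transition matrix
#'
#' A transition matrix gives, for each origin state (row), the
#' probability of occupying each destination state (column) after one
#' cycle. Structural rules of the disease model: rows are stochastic;
#' nobody returns to state 1 (treatment, once started, continues and the
#' fellow eye never recovers to healthy); state 5 (blindness) is
#' absorbing.
#'
#' @param p 5x5 numeric matrix of per-cycle transition probabilities.
#' @param strategy_id character; which treatment strategy the matrix
#'   belongs to.
#' @param period `"early"` (cycles starting before month 12) or
#'   `"late"`.
#' @param validate logical; check the structural invariants (default
#'   `TRUE`).
#' @return A `transition_matrix`: the matrix with `strategy_id` and
#'   `period` attributes.
#' @export
transition_matrix <- function(p, strategy_id, period = c("early", "late"),
                              validate = TRUE) {
  period <- match.arg(period)
  p <- as.matrix(p)
  if (!is.numeric(p) || !all(dim(p) == c(5L, 5L))) {
    stop("'p' must be a numeric 5x5 matrix", call. = FALSE)
  }
  dimnames(p) <- list(paste0("s", 1:5), paste0("s", 1:5))
  out <- structure(p,
    strategy_id = as.character(strategy_id), period = period,
    class = c("transition_matrix", "matrix", "array")
  )
  if (validate) {
    problems <- check_matrix(out)
    if (length(problems)) {
      stop("invalid transition matrix (", attr(out, "strategy_id"), "/",
           period, "): ", paste(problems, collapse = "; "), call. = FALSE)
    }
  }
  out
}

# Structural checks for a single 5x5 matrix; returns character vector of
# violations (empty if valid).
check_matrix <- function(p, tol = 1e-9) {
  problems <- character()
  if (any(p < -tol) || any(p > 1 + tol)) {
    bad <- which(p < -tol | p > 1 + tol, arr.ind = TRUE)
    problems <- c(problems, sprintf(
      "entries outside [0,1] at (%s)",
      paste(apply(bad, 1L, paste, collapse = ","), collapse = "), (")
    ))
  }
  rs <- rowSums(p)
  off <- which(abs(rs - 1) > tol)
  if (length(off)) {
    problems <- c(problems, sprintf(
      "row %d sums to %.12g (deficit %.3g)", off, rs[off], 1 - rs[off]
    ))
  }
  inflow <- which(p[2:5, 1] != 0)
  if (length(inflow)) {
    problems <- c(problems, sprintf(
      "return to state 1 from state %d violates the no-return rule", inflow + 1L
    ))
  }
  if (any(p[5, ] != c(0, 0, 0, 0, 1))) {
    problems <- c(problems, "row 5 must be (0,0,0,0,1): state 5 is absorbing")
  }
  problems
}

#' Validate transition-matrix sets
#'
#' Checks every matrix in a set (or a single matrix) against the
#' structural invariants: row sums of 1, entries in \[0, 1\], no inflow
#' to state 1, absorbing state 5. Optionally checks that late-period
#' improvement probabilities do not exceed early-period ones (the first
#' doses are the most effective).
#'
#' @param matrices a `transition_matrix`, a list with `early` and `late`
#'   matrices for one strategy, or a named list of such per-strategy
#'   lists (as returned by [generate_matrices()]).
#' @param check_early_late logical; also require elementwise
#'   early >= late on the improvement (sub-diagonal, non-state-1)
#'   entries.
#' @return A character vector of violations, each prefixed with the
#'   strategy/period it concerns. Empty (length 0) means the set is
#'   valid.
#' @export
validate_matrices <- function(matrices, check_early_late = FALSE) {
  report <- character()
  if (inherits(matrices, "transition_matrix")) {
    pr <- check_matrix(matrices)
    if (length(pr)) {
      report <- paste0(attr(matrices, "strategy_id"), "/",
                       attr(matrices, "period"), ": ", pr)
    }
    return(report)
  }
  sets <- matrices
  if (!is.null(sets$early) || !is.null(sets$late)) sets <- list(strategy = sets)
  for (sid in names(sets)) {
    set <- sets[[sid]]
    for (period in c("early", "late")) {
      m <- set[[period]]
      if (is.null(m)) {
        report <- c(report, sprintf("%s: missing %s matrix", sid, period))
        next
      }
      pr <- check_matrix(m)
      if (length(pr)) report <- c(report, paste0(sid, "/", period, ": ", pr))
    }
    if (check_early_late && !is.null(set$early) && !is.null(set$late)) {
      imp <- improvement_entries()
      worse <- imp[set$late[imp] > set$early[imp] + 1e-12, , drop = FALSE]
      if (nrow(worse)) {
        report <- c(report, sprintf(
          "%s: late improvement exceeds early at (%s)",
          sid, paste(apply(worse, 1L, paste, collapse = ","), collapse = "), (")
        ))
      }
    }
  }
  report
}

# (row, col) indices of improvement entries: moves to a better state,
# excluding the forbidden column 1.
improvement_entries <- function() {
  idx <- which(row(diag(5)) > col(diag(5)) & col(diag(5)) > 1, arr.ind = TRUE)
  idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
}

#' Write transition-matrix sets to CSV
#'
#' Long-ish layout: one row per origin state, with `strategy` and
#' `period` columns followed by the five destination probabilities
#' (`s1`..`s5`). The file written by this function is read back
#' losslessly by [read_matrices()].
#'
#' @param matrices named list of per-strategy `list(early=, late=)`
#'   matrix sets.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_matrices <- function(matrices, path) {
  rows <- list()
  for (sid in names(matrices)) {
    for (period in c("early", "late")) {
      m <- matrices[[sid]][[period]]
      rows[[length(rows) + 1L]] <- data.frame(
        strategy = sid, period = period, from_state = 1:5,
        s1 = m[, 1], s2 = m[, 2], s3 = m[, 3], s4 = m[, 4], s5 = m[, 5],
        stringsAsFactors = FALSE
      )
    }
  }
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read transition-matrix sets from CSV
#'
#' @param path file written by [write_matrices()] (or hand-authored in
#'   the same layout).
#' @param validate logical; reject structurally invalid matrices.
#' @return Named list of per-strategy `list(early=, late=)` sets.
#' @export
read_matrices <- function(path, validate = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("strategy", "period", "from_state", paste0("s", 1:5))
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("matrix file ", path, " lacks columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- list()
  for (sid in unique(df$strategy)) {
    out[[sid]] <- list()
    for (period in unique(df$period[df$strategy == sid])) {
      sub <- df[df$strategy == sid & df$period == period, ]
      sub <- sub[order(sub$from_state), ]
      if (!identical(sub$from_state, 1:5) && !identical(as.integer(sub$from_state), 1:5)) {
        stop("matrix ", sid, "/", period, " must have origin states 1..5",
             call. = FALSE)
      }
      p <- as.matrix(sub[, paste0("s", 1:5)])
      out[[sid]][[period]] <- transition_matrix(p, sid, period, validate = validate)
    }
  }
  if (validate) {
    report <- validate_matrices(out)
    if (length(report)) {
      stop("invalid matrices in ", path, ": ",
           paste(report, collapse = "; "), call. = FALSE)
    }
  }
  out
}
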