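# Shared fixtures built in code.

# A hand-set, structurally valid matrix pair (early favours staying put).
toy_matrix <- function(strategy_id = "toy", period = "early",
                       row1 = c(0.7, 0.2, 0.08, 0.02, 0)) {
  p <- diag(5)
  p[1, ] <- row1
  p[2, ] <- c(0, 0.8, 0.15, 0.05, 0)
  p[3, ] <- c(0, 0.1, 0.7, 0.15, 0.05)
  p[4, ] <- c(0, 0, 0.2, 0.7, 0.1)
  transition_matrix(p, strategy_id, period)
}

toy_matrix_set <- function(strategy_id = "toy") {
  early <- toy_matrix(strategy_id, "early")
  late_p <- unclass(early)
  late_p[3, ] <- c(0, 0.05, 0.75, 0.15, 0.05)  # weaker improvement late
  late_p[4, ] <- c(0, 0, 0.1, 0.8, 0.1)
  list(early = early,
       late = transition_matrix(late_p, strategy_id, "late"))
}

identity_matrix_set <- function(strategy_id = "toy") {
  list(early = transition_matrix(diag(5), strategy_id, "early"),
       late = transition_matrix(diag(5), strategy_id, "late"))
}

# Byte snapshot of a config, for isolation checks.
config_to_digest <- function(cfg) serialize(cfg, NULL, version = 3)

# A strategy with no adverse events, for clean cost arithmetic.
plain_strategy <- function(id = "toy", cycle = 4, drug = 100, admin = 10) {
  treatment_strategy(id, drug, admin, cycle)
}
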