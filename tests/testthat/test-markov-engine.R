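test_that("cycle grids cover the horizon exactly, with a fractional last cycle", {
  g <- build_cycle_grid(4, 2)
  expect_equal(length(g$boundaries), 6L)
  expect_equal(g$final_cycle_fraction, 1)
  expect_equal(g$boundaries, seq(0, 20, by = 4))

  g <- build_cycle_grid(5, 2)
  expect_equal(g$boundaries, c(0, 5, 10, 15, 20))
  expect_equal(g$final_cycle_fraction, 0.8)
  expect_equal(g$cycle_fractions, c(1, 1, 1, 1, 0.8))
  # durations weighted by fraction reconstruct the horizon
  expect_equal(sum(5 * g$cycle_fractions), 24)

  g <- build_cycle_grid(5, 5)
  expect_equal(length(g$boundaries), 12L)
  expect_equal(g$final_cycle_fraction, 1)

  expect_error(build_cycle_grid(0, 2), "positive")
  expect_error(build_cycle_grid(4, -1), "non-negative")
})

test_that("matrix selection switches from early to late at the cycle start month", {
  set <- toy_matrix_set()
  expect_identical(select_matrix(set, 0), set$early)
  expect_identical(select_matrix(set, 10), set$early)   # 3rd 5-month cycle
  expect_identical(select_matrix(set, 11.999), set$early)
  expect_identical(select_matrix(set, 12), set$late)
  expect_identical(select_matrix(set, 40), set$late)
  expect_error(select_matrix(list(early = set$early), 0), "late")
})

test_that("advancing a cohort is the occupancy-matrix product and conserves persons", {
  occ <- c(100, 200, 300, 250, 150)
  expect_equal(advance_cohort(occ, diag(5)), occ)
  expect_equal(advance_cohort(c(0, 0, 0, 0, 1000), toy_matrix()),
               c(0, 0, 0, 0, 1000))
  expect_equal(advance_cohort(c(1000, 0, 0, 0, 0), toy_matrix()),
               c(700, 200, 80, 20, 0))
  out <- advance_cohort(occ, toy_matrix())
  expect_equal(sum(out), sum(occ))
  expect_error(advance_cohort(c(-1, 0, 0, 0, 1), toy_matrix()), "non-negative")
})

test_that("a trace starts with everyone in state 1 and matches repeated products", {
  s <- plain_strategy(cycle = 5)
  set <- toy_matrix_set()
  tr <- run_trace(s, set, horizon_years = 10 / 12, cohort_size = 1000)
  expect_equal(tr$occupancy[1, ], c(s1 = 1000, s2 = 0, s3 = 0, s4 = 0, s5 = 0))
  step1 <- advance_cohort(c(1000, 0, 0, 0, 0), set$early)
  step2 <- advance_cohort(step1, set$early)
  expect_equal(unname(tr$occupancy[2, ]), step1)
  expect_equal(unname(tr$occupancy[3, ]), step2)
})

test_that("degenerate traces behave: zero horizon and identity matrices", {
  s <- plain_strategy()
  tr <- run_trace(s, identity_matrix_set(), horizon_years = 0)
  expect_equal(nrow(tr$occupancy), 1L)
  expect_equal(unname(tr$occupancy[1, ]), c(1000, 0, 0, 0, 0))

  tr <- run_trace(s, identity_matrix_set(), horizon_years = 3)
  expect_true(all(tr$occupancy[, 1] == 1000))
  expect_true(all(tr$occupancy[, 2:5] == 0))
})

test_that("short traces match brute-force path enumeration", {
  s <- plain_strategy(cycle = 5)
  set <- toy_matrix_set()
  for (n_cycles in 1:3) {
    h <- n_cycles * 5 / 12
    tr <- run_trace(s, set, horizon_years = h, cohort_size = 1000)
    mats <- lapply(tr$times_months[seq_len(n_cycles)],
                   function(t) select_matrix(set, t))
    oracle <- enumerate_paths(c(1000, 0, 0, 0, 0), mats)
    expect_equal(unname(tr$occupancy), oracle, tolerance = 1e-9)
  }
})

test_that("conservation and monotone absorption hold for generated matrix sets", {
  for (seed in c(1, 7, 23)) {
    mats <- generate_matrices(matrix_gen_spec(seed = seed))
    strategies <- default_strategies()
    for (sid in names(strategies)) {
      tr <- run_trace(strategies[[sid]], mats[[sid]], horizon_years = 5)
      expect_true(all(abs(rowSums(tr$occupancy) - 1000) < 1e-6))
      expect_true(all(diff(tr$occupancy[, 1]) <= 1e-9))  # no return to state 1
      expect_true(all(diff(tr$occupancy[, 5]) >= -1e-9)) # absorbing endpoint
      expect_true(all(tr$cumulative_onceonly >= 0 & tr$cumulative_onceonly <= 1))
      expect_true(all(apply(tr$cumulative_onceonly, 2, function(x) all(diff(x) >= 0))))
    }
  }
})

test_that("traces diverge exactly at the first cycle starting at or after month 12", {
  s <- plain_strategy(cycle = 5)
  set <- toy_matrix_set()
  early_only <- list(early = set$early, late = set$early)
  tr_both <- run_trace(s, set, horizon_years = 2)
  tr_early <- run_trace(s, early_only, horizon_years = 2)
  # cycle starts: 0, 5, 10, 15, 20; the cycle at 15 is the first late one,
  # so occupancies agree up to and including the row at month 15
  same <- tr_both$times_months < 15 + 1e-9
  expect_equal(tr_both$occupancy[same, ], tr_early$occupancy[same, ])
  after <- which(!same)
  expect_false(isTRUE(all.equal(tr_both$occupancy[after, , drop = FALSE],
                                tr_early$occupancy[after, , drop = FALSE])))
})

test_that("traces round-trip through their data-frame export", {
  s <- default_strategies()$triamcinolone
  mats <- generate_matrices(matrix_gen_spec(seed = 3))
  tr <- run_trace(s, mats$triamcinolone, horizon_years = 1)
  df <- as.data.frame(tr)
  expect_equal(nrow(df), nrow(tr$occupancy))
  expect_equal(df$time_months, tr$times_months)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, path)
  back <- read.csv(path)
  expect_equal(as.matrix(back[paste0("s", 1:5)]),
               tr$occupancy, ignore_attr = TRUE)
})
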