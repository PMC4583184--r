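test_that("transition rows are stochastic and respect the state topology", {
  spec <- baseline_spec()
  for (age in c(3, 8, 9, 15, 17, 18, 25, 49)) {
    for (strat in spec$strategies) {
      M <- build_transition_matrix(age, strat, spec)
      expect_equal(rowSums(M), setNames(rep(1, 5), health_states()),
                   tolerance = 1e-12)
      # hearing loss exits only to death; death absorbing
      expect_equal(M["HearingLoss", c("HealthyEnrolled", "HealthyDischarged",
                                      "EarProblem")],
                   setNames(rep(0, 3), c("HealthyEnrolled",
                                         "HealthyDischarged", "EarProblem")))
      expect_equal(M["Dead", "Dead"], 1)
    }
  }
  expect_error(build_transition_matrix(2, "MTESS", spec), "outside")
  expect_error(build_transition_matrix(51, "MTESS", spec), "outside")
  expect_error(collapse_decision_tree("Purgatory", 10, "MTESS", spec),
               "unknown state")
})

test_that("hearing loss is permanent apart from death", {
  spec <- baseline_spec()
  for (age in c(5, 20, 45)) {
    row <- collapse_decision_tree("HearingLoss", age, "MTESS", spec)$probs
    q <- spec$transitions$mortality_by_age$q[
      spec$transitions$mortality_by_age$age == age]
    expect_equal(row[["HearingLoss"]], 1 - q)
    expect_equal(row[["Dead"]], q)
  }
})

test_that("with no detection pathway ear problems progress at the untreated rate", {
  spec <- baseline_spec()
  spec$transitions$p_screen[] <- 0
  spec$transitions$p_gp_detection <- 0
  age <- 10
  q <- spec$transitions$mortality_by_age$q[
    spec$transitions$mortality_by_age$age == age]
  row <- collapse_decision_tree("EarProblem", age, "DeadlyEars", spec)$probs
  expect_equal(row[["HearingLoss"]],
               spec$transitions$p_progress_untreated * (1 - q))
  expect_equal(row[["HealthyEnrolled"]], 0)
})

test_that("the ear-problem row matches exhaustive tree-leaf enumeration", {
  spec <- baseline_spec()
  for (age in c(4, 9, 17, 30)) {
    for (strat in spec$strategies) {
      engine <- collapse_decision_tree("EarProblem", age, strat, spec)$probs
      oracle <- ep_row_leaf_oracle(age, strat, spec)
      expect_equal(engine, oracle, tolerance = 1e-12,
                   info = paste(strat, "age", age))
    }
  }
  # and on a randomly generated parameter set
  rs <- generate_model_spec(synthetic_config(seed = 11))
  engine <- collapse_decision_tree("EarProblem", 12, "MTESS", rs)$probs
  expect_equal(engine, ep_row_leaf_oracle(12, "MTESS", rs),
               tolerance = 1e-12)
})

test_that("adult matrices are strategy independent", {
  spec <- baseline_spec()
  for (age in 18:25) {
    expect_equal(build_transition_matrix(age, "DeadlyEars", spec),
                 build_transition_matrix(age, "MTESS", spec))
  }
})

test_that("an immortal disease-free enrolled cohort stays put", {
  spec <- baseline_spec()
  spec$transitions$p_ear_by_age$p[] <- 0
  spec$transitions$mortality_by_age$q[] <- 0
  M <- build_transition_matrix(5, "MTESS", spec)  # before discharge age
  expect_equal(M["HealthyEnrolled", "HealthyEnrolled"], 1)
})

test_that("discharge routes screen-negative healthy children out of the program", {
  spec <- baseline_spec()
  s <- spec$transitions$p_screen[["MTESS"]]
  pe <- spec$transitions$p_ear_by_age$p[1]
  q8 <- earcea:::mort_at(spec, 8)
  q9 <- earcea:::mort_at(spec, 9)
  M8 <- build_transition_matrix(8, "MTESS", spec)
  M9 <- build_transition_matrix(9, "MTESS", spec)
  expect_equal(M8["HealthyEnrolled", "HealthyDischarged"], 0)
  expect_equal(M9["HealthyEnrolled", "HealthyDischarged"],
               (1 - pe) * s * spec$transitions$p_true_negative * (1 - q9))
  # discharged healthy carry no screening cost
  expect_equal(collapse_decision_tree("HealthyDischarged", 9, "MTESS",
                                      spec)$cost, 0)
  expect_gt(collapse_decision_tree("HealthyEnrolled", 9, "MTESS",
                                   spec)$cost, 0)
})

test_that("discounting with half-cycle correction matches closed forms", {
  # constant stream at zero rate: trapezoid of a constant
  expect_equal(discount_and_correct(rep(3, 11), 0), 3 * 10)
  # single cycle: boundary half-weight
  expect_equal(discount_and_correct(7, 0.035), 3.5)
  expect_error(discount_and_correct(numeric(0), 0.05), "empty")
  # arbitrary stream equals independent trapezoid-rule quadrature of the
  # discounted stepwise stream
  set.seed(99)
  stream <- rnorm(25, 100, 30)
  r <- 0.06
  disc <- stream * (1 + r)^(-(0:24))
  expect_equal(discount_and_correct(stream, r), pracma::trapz(0:24, disc),
               tolerance = 1e-12)
})

test_that("a disease-free immortal cohort accrues the annuity of one QALY per year", {
  spec <- baseline_spec()
  spec$transitions$p_ear_by_age$p[] <- 0
  spec$transitions$mortality_by_age$q[] <- 0
  spec$utilities <- list(u_healthy_child = 1, u_healthy_adult = 1,
                         u_hearing_loss = 1, u_ear_child = 1, u_ear_adult = 1)
  spec$costs$screen_cost[] <- 0
  spec$costs$medical_child <- 0  # removes the false-positive work-up cost
  tr <- run_cohort(spec, "MTESS")
  n <- length(tr$ages)
  annuity <- discount_and_correct(rep(1, n), spec$discount_rate)
  expect_equal(tr$total_qaly, annuity, tolerance = 1e-12)
  expect_equal(tr$total_cost, 0)
})

test_that("the engine agrees with the matrix-product reference path", {
  for (sp in list(baseline_spec(),
                  generate_model_spec(synthetic_config(seed = 4)))) {
    for (strat in sp$strategies) {
      tr <- run_cohort(sp, strat)
      ref <- reference_trace(sp, strat)
      expect_equal(tr$occupancy, ref$occupancy, tolerance = 1e-12)
      expect_equal(tr$cost_stream, ref$cost, tolerance = 1e-12)
      expect_equal(tr$qaly_stream, ref$qaly, tolerance = 1e-12)
    }
  }
})

test_that("occupancy conserves mass and death is nondecreasing", {
  for (seed in 1:25) {
    sp <- generate_model_spec(synthetic_config(seed = seed))
    tr <- run_cohort(sp, sample(sp$strategies, 1))
    expect_true(all(abs(rowSums(tr$occupancy) - 1) < 1e-12))
    expect_true(all(diff(tr$occupancy[, "Dead"]) >= -1e-15))
    expect_true(all(is.finite(tr$cost_stream)))
    expect_true(all(is.finite(tr$qaly_stream)))
  }
})

test_that("raising the screening probability never hurts", {
  for (seed in c(2, 13, 21)) {
    sp <- generate_model_spec(synthetic_config(seed = seed))
    sp$transitions$p_screen[] <- c(0.3, 0.3)
    lo <- run_cohort(sp, "MTESS")
    sp2 <- sp
    sp2$transitions$p_screen[] <- c(0.7, 0.7)
    hi <- run_cohort(sp2, "MTESS")
    expect_gte(hi$total_qaly, lo$total_qaly - 1e-12)
    expect_true(all(hi$occupancy[, "HearingLoss"] <=
                      lo$occupancy[, "HearingLoss"] + 1e-12))
  }
})

test_that("strategies with equal screening parameters produce identical traces", {
  spec <- baseline_spec()
  spec$transitions$p_screen[] <- 0.5
  spec$costs$screen_cost[] <- 100
  a <- run_cohort(spec, "DeadlyEars")
  b <- run_cohort(spec, "MTESS")
  expect_equal(a$occupancy, b$occupancy)
  expect_equal(a$total_cost, b$total_cost)
  expect_equal(a$total_qaly, b$total_qaly)
})

test_that("trace CSV export round-trips", {
  tr <- run_cohort(baseline_spec(), "MTESS")
  path <- file.path(tempdir(), "trace.csv")
  df <- write_trace_csv(tr, path)
  back <- utils::read.csv(path)
  expect_equal(back, df, tolerance = 1e-12)
  expect_equal(sum(back$disc_cost), tr$total_cost, tolerance = 1e-9)
  expect_equal(sum(back$disc_qaly), tr$total_qaly, tolerance = 1e-9)
})
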