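test_that("the base case carries every published parameter", {
  spec <- baseline_spec()
  # symbol -> printed base value (transition probabilities, costs,
  # utilities); completeness over the published tables
  expected <- c(
    p_screen_DeadlyEars = 0.39, p_screen_MTESS = 0.80,
    p_false_negative = 0.05, p_true_negative = 0.90,
    p_treat_if_detected = 0.86, p_medical_vs_surgical = 0.80,
    p_treat_failure = 0.10, p_progress_untreated = 0.10,
    p_aid_child = 0.05, p_aid_adult = 0.35, p_gp_detection = 0.219,
    screen_cost_DeadlyEars = 88, screen_cost_MTESS = 117,
    medical_child = 82, medical_adult = 91,
    surgical_child = 2369, surgical_adult = 6021,
    hearing_aid_annual = 1606, cochlear_annual = 3152,
    education_annual = 7116, income_loss_annual = 6681,
    u_healthy_child = 1.000, u_healthy_adult = 0.900,
    u_hearing_loss = 0.677)
  for (id in names(expected)) {
    expect_equal(get_param(spec, id), expected[[id]], info = id)
  }
  # every addressable id resolves
  for (id in param_ids(spec)) {
    expect_true(is.numeric(get_param(spec, id)), info = id)
  }
  expect_equal(spec$discount_rate, 0.05)
  expect_equal(spec$ages$start_age, 3L)
  expect_equal(spec$ages$terminal_age, 50L)
})

test_that("ear-problem utilities are unweighted means of healthy and deaf", {
  expect_equal(derive_ear_utility(1.000, 0.677), 0.839)
  expect_equal(derive_ear_utility(0.900, 0.677), 0.789)
  expect_equal(derive_ear_utility(0.62, 0.62), 0.62)
  expect_error(derive_ear_utility(1.2, 0.5), "\\[0, 1\\]")
  spec <- baseline_spec()
  expect_equal(spec$utilities$u_ear_child, 0.839)
  expect_equal(spec$utilities$u_ear_adult, 0.789)
})

test_that("validation rejects out-of-range probabilities and negative costs", {
  spec <- baseline_spec()
  bad <- spec
  bad$transitions$p_treat_failure <- 1.3
  expect_error(validate_model_spec(bad), "p_treat_failure")
  bad <- spec
  bad$costs$medical_child <- -5
  expect_error(validate_model_spec(bad), "medical_child")
  bad <- spec
  bad$utilities$u_hearing_loss <- 0.95  # above the ear-problem utility
  expect_error(validate_model_spec(bad), "ordering")
  bad <- spec
  bad$transitions$p_ear_by_age$age_to[1] <- 10L  # gap before band 2
  expect_error(validate_model_spec(bad), "gaps")
  expect_error(set_param(spec, "no_such_parameter", 1), "unknown parameter")
})

test_that("specification files round-trip through YAML and JSON", {
  spec <- baseline_spec()
  for (ext in c("yaml", "json")) {
    path <- file.path(tempdir(), paste0("spec_roundtrip.", ext))
    save_model_spec(spec, path)
    expect_equal(load_model_spec(path), spec, tolerance = 1e-10)
  }
  expect_error(load_model_spec(file.path(tempdir(), "nope.yaml")),
               "no such file")
})

test_that("the packaged fixtures load, validate and match the base case", {
  base <- load_model_spec(system.file("extdata", "base_case.yaml",
                                      package = "earcea"))
  expect_equal(base, baseline_spec(), tolerance = 1e-9)
  expect_equal(base$transitions$p_screen[["MTESS"]], 0.80)
  expect_equal(base$transitions$p_screen[["DeadlyEars"]], 0.39)
  a4 <- load_model_spec(system.file("extdata", "age4_start.yaml",
                                    package = "earcea"))
  expect_equal(a4$ages$start_age, 4L)
  ns <- load_model_spec(system.file("extdata", "no_screening.yaml",
                                    package = "earcea"))
  expect_true(all(ns$transitions$p_screen == 0))
})

test_that("a file with an out-of-range probability is rejected with the field name", {
  spec <- baseline_spec()
  path <- file.path(tempdir(), "bad_spec.yaml")
  x <- earcea:::spec_to_list(spec)
  x$transitions$p_treat_failure <- 1.3
  yaml::write_yaml(x, path)
  expect_error(load_model_spec(path), "p_treat_failure")
})

test_that("the no-screening scenario removes the strategy difference", {
  ns <- no_screening_spec()
  expect_true(all(ns$transitions$p_screen == 0))
  expect_equal(ns$transitions$p_gp_detection, 0.219)
  a <- run_cohort(ns, "DeadlyEars")
  b <- run_cohort(ns, "MTESS")
  expect_equal(a$occupancy, b$occupancy)
  expect_equal(a$total_cost, b$total_cost)
  expect_equal(a$total_qaly, b$total_qaly)
})

test_that("set_param re-derives the ear-problem utilities", {
  spec <- baseline_spec()
  sp <- set_param(spec, "u_hearing_loss", 0.5)
  expect_equal(sp$utilities$u_ear_child, derive_ear_utility(1.0, 0.5))
  expect_equal(sp$utilities$u_ear_adult, derive_ear_utility(0.9, 0.5))
  sp <- set_param(spec, "p_ear_band1", 0.12)
  expect_equal(sp$transitions$p_ear_by_age$p[1], 0.12)
})
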