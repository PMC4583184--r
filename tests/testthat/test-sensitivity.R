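test_that("method-of-moments fits recover the stated algebra", {
  # gamma with SE = 20% of the mean: shape 25, scale mean/25
  ds <- dist_spec("gamma", mean = 2369, se = 0.2 * 2369)
  expect_equal((ds$mean / ds$se)^2, 25)
  expect_equal(ds$se^2 / ds$mean, 2369 / 25)
  # beta mean .5, SE .1: alpha = beta = 12
  m <- 0.5; s <- 0.1
  nu <- m * (1 - m) / s^2 - 1
  expect_equal(m * nu, 12)
  expect_equal((1 - m) * nu, 12)
  expect_error(dist_spec("beta", mean = 0.5, se = 0.6), "infeasible")
  expect_error(dist_spec("triangular", min = 1, mode = 0.5, max = 2),
               "min <= mode <= max")
})

test_that("samplers recover their stated moments within Monte-Carlo error", {
  n <- 1e5
  specs <- list(
    beta = dist_spec("beta", mean = 0.39, se = 0.2 * 0.39),
    gamma = dist_spec("gamma", mean = 1606, se = 0.2 * 1606),
    triangular = dist_spec("triangular", min = 0.02, mode = 0.05,
                           max = 0.20))
  set.seed(123)
  for (nm in names(specs)) {
    mom <- dist_moments(specs[[nm]])
    x <- fit_distribution(specs[[nm]])(n)
    se_mean <- mom[["sd"]] / sqrt(n)
    expect_lt(abs(mean(x) - mom[["mean"]]), 3 * se_mean)
    # SE of the sample SD, normal approximation
    expect_lt(abs(sd(x) - mom[["sd"]]), 3 * mom[["sd"]] / sqrt(2 * n))
  }
})

test_that("zero spread collapses samplers to the base value", {
  expect_equal(fit_distribution(dist_spec("beta", mean = 0.3, se = 0))(5),
               rep(0.3, 5))
  expect_equal(fit_distribution(dist_spec("gamma", mean = 82, se = 0))(3),
               rep(82, 3))
  expect_equal(fit_distribution(dist_spec("triangular", min = 0.8,
                                          mode = 0.8, max = 0.8))(4),
               rep(0.8, 4))
})

test_that("the default one-way analysis covers the published table", {
  rng <- dsa_ranges()
  expect_equal(nrow(rng), 23)
  expect_equal(sum(grepl("^p_", rng$id)), 10)
  expect_equal(sum(grepl("^u_", rng$id)), 3)
  spec <- baseline_spec()
  for (id in rng$id) expect_true(is.numeric(get_param(spec, id)), info = id)
})

test_that("one-way analysis at the base value reproduces the base verdict", {
  spec <- baseline_spec()
  base <- run_comparison(spec)
  for (id in c("p_treat_failure", "u_hearing_loss", "surgical_child")) {
    v <- get_param(spec, id)
    row <- one_way_dsa(spec, id, v, v)
    expect_equal(row$verdict_low, base$verdict, info = id)
    expect_equal(row$verdict_high, base$verdict, info = id)
    if (base$verdict == "ICER") {
      expect_equal(row$icer_low, base$icer, info = id)
      expect_equal(row$icer_high, base$icer, info = id)
    }
  }
})

test_that("an empty range list yields an empty report", {
  empty <- run_dsa(baseline_spec(), dsa_ranges()[0, ])
  expect_equal(nrow(empty), 0)
  expect_true(all(c("parameter", "verdict_low", "verdict_high") %in%
                    names(empty)))
})

test_that("one-way bounds move the verdict in a sensible direction", {
  spec <- baseline_spec()
  row <- one_way_dsa(spec, "p_screen_DeadlyEars", 0.3, 0.6)
  # widening the reference program's screening erodes the comparator's
  # advantage: the QALY gain shrinks toward the high bound
  hi <- run_comparison(set_param(spec, "p_screen_DeadlyEars", 0.6))
  lo <- run_comparison(set_param(spec, "p_screen_DeadlyEars", 0.3))
  expect_gt(lo$delta_qaly, hi$delta_qaly)
})

test_that("the PSA is reproducible and varies every declared parameter", {
  spec <- baseline_spec()
  a <- run_psa(spec, n_draws = 40, seed = 9, thresholds = c(0, 50000))
  b <- run_psa(spec, n_draws = 40, seed = 9, thresholds = c(0, 50000))
  expect_identical(a$draws, b$draws)
  expect_identical(a$ceac, b$ceac)
  expect_equal(nrow(a$draws), 40)
  c2 <- run_psa(spec, n_draws = 40, seed = 10, thresholds = c(0, 50000))
  expect_false(identical(a$draws$delta_cost, c2$draws$delta_cost))
  # declared distribution set: every sampled id is addressable and the
  # count matches the published tables (23 scalar rows + incidence bands)
  dists <- psa_distributions(spec)
  expect_equal(length(dists),
               23 + nrow(spec$transitions$p_ear_by_age))
  for (id in names(dists)) {
    expect_true(is.numeric(get_param(spec, id)), info = id)
  }
})

test_that("zero-spread PSA reproduces the base-case increments exactly", {
  spec <- baseline_spec()
  base <- run_comparison(spec)
  psa0 <- run_psa(spec, n_draws = 5, seed = 3, thresholds = 50000,
                  se_scale = 0)
  expect_equal(psa0$draws$delta_cost, rep(base$delta_cost, 5),
               tolerance = 1e-9)
  expect_equal(psa0$draws$delta_qaly, rep(base$delta_qaly, 5),
               tolerance = 1e-9)
})

test_that("the acceptability curve at threshold zero counts cost-saving draws", {
  psa <- run_psa(baseline_spec(), n_draws = 60, seed = 5,
                 thresholds = c(0, 20000))
  expect_equal(psa$ceac$probability[psa$ceac$threshold == 0],
               mean(psa$draws$delta_cost <= 0))
})
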