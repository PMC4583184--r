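#' Describe the sampling distribution of one uncertain parameter
#'
#' Probabilities and utilities with symmetric uncertainty follow a beta
#' distribution and costs a gamma distribution, both parameterised from
#' the base-case mean and a standard error (20% of the mean in the
#' published analysis); expert-elicited parameters follow a triangular
#' distribution over their stated range with the base case as mode.
#'
#' @param kind One of `"beta"`, `"gamma"`, `"triangular"`, `"fixed"`.
#' @param mean Mean (beta/gamma/fixed).
#' @param se Standard error (beta/gamma).
#' @param min,mode,max Triangular support and mode.
#' @return A `dist_spec` object.
#' @export
dist_spec <- function(kind = c("beta", "gamma", "triangular", "fixed"),
                      mean = NULL, se = NULL, min = NULL, mode = NULL,
                      max = NULL) {
  kind <- match.arg(kind)
  if (kind %in% c("beta", "gamma")) {
    stopifnot(is.numeric(mean), is.numeric(se), se >= 0)
    if (kind == "beta" && (mean <= 0 || mean >= 1)) {
      stop("beta mean must lie in (0, 1)")
    }
    if (kind == "gamma" && mean <= 0) stop("gamma mean must be > 0")
    if (kind == "beta" && se > 0 && se^2 >= mean * (1 - mean)) {
      stop("infeasible beta moments: se^2 must be < mean * (1 - mean)")
    }
  } else if (kind == "triangular") {
    stopifnot(is.numeric(min), is.numeric(mode), is.numeric(max))
    if (!(min <= mode && mode <= max)) stop("need min <= mode <= max")
  } else {
    stopifnot(is.numeric(mean))
  }
  structure(list(kind = kind, mean = mean, se = se, min = min, mode = mode,
                 max = max), class = "dist_spec")
}

#' Build a sampler from a distribution spec
#'
#' Beta parameters are obtained by the method of moments from the mean
#' and standard error (`nu = m(1-m)/se^2 - 1`, `alpha = m nu`,
#' `beta = (1-m) nu`); the gamma uses `shape = (m/se)^2`,
#' `scale = se^2/m`; the triangular is sampled by inverse CDF. A zero
#' standard error (or a degenerate triangular support) yields a
#' degenerate sampler returning the base value.
#'
#' @param ds A [dist_spec()].
#' @return `function(n)` drawing `n` values from the fitted distribution
#'   using the current RNG stream.
#' @export
fit_distribution <- function(ds) {
  stopifnot(inherits(ds, "dist_spec"))
  switch(ds$kind,
    fixed = function(n) rep(ds$mean, n),
    beta = {
      if (ds$se == 0) return(function(n) rep(ds$mean, n))
      nu <- ds$mean * (1 - ds$mean) / ds$se^2 - 1
      if (nu <= 0) stop("infeasible beta moments")
      a <- ds$mean * nu
      b <- (1 - ds$mean) * nu
      function(n) stats::rbeta(n, a, b)
    },
    gamma = {
      if (ds$se == 0) return(function(n) rep(ds$mean, n))
      shape <- (ds$mean / ds$se)^2
      scale <- ds$se^2 / ds$mean
      function(n) stats::rgamma(n, shape = shape, scale = scale)
    },
    triangular = {
      a <- ds$min; cc <- ds$mode; b <- ds$max
      if (a == b) return(function(n) rep(cc, n))
      function(n) {
        u <- stats::runif(n)
        fc <- (cc - a) / (b - a)
        ifelse(u < fc,
               a + sqrt(u * (b - a) * (cc - a)),
               b - sqrt((1 - u) * (b - a) * (b - cc)))
      }
    })
}

#' Moments of a fitted distribution spec
#'
#' @param ds A [dist_spec()].
#' @return c(mean, sd) implied by the spec (triangular moments from the
#'   closed form).
#' @export
dist_moments <- function(ds) {
  stopifnot(inherits(ds, "dist_spec"))
  switch(ds$kind,
    fixed = c(mean = ds$mean, sd = 0),
    beta = c(mean = ds$mean, sd = ds$se),
    gamma = c(mean = ds$mean, sd = ds$se),
    triangular = {
      m <- (ds$min + ds$mode + ds$max) / 3
      v <- (ds$min^2 + ds$mode^2 + ds$max^2 - ds$min * ds$mode -
              ds$min * ds$max - ds$mode * ds$max) / 18
      c(mean = m, sd = sqrt(v))
    })
}

#' Published one-way sensitivity ranges
#'
#' The 23 parameters varied one at a time in the deterministic
#' sensitivity analysis, with their published ranges: ten transition
#' probabilities, ten costs (base +/- 20%) and three utilities.
#'
#' @return data.frame with columns `id`, `low`, `high`.
#' @export
dsa_ranges <- function() {
  data.frame(
    id = c("p_screen_DeadlyEars", "p_screen_MTESS", "p_false_negative",
           "p_true_negative", "p_treat_if_detected",
           "p_medical_vs_surgical", "p_treat_failure",
           "p_progress_untreated", "p_aid_child", "p_aid_adult",
           "screen_cost_DeadlyEars", "screen_cost_MTESS", "medical_child",
           "medical_adult", "surgical_child", "surgical_adult",
           "hearing_aid_annual", "cochlear_annual", "education_annual",
           "income_loss_annual",
           "u_healthy_child", "u_healthy_adult", "u_hearing_loss"),
    low = c(0.3, 0.7, 0.02, 0.80, 0.60, 0.70, 0.05, 0.05, 0.02, 0.10,
            70, 93, 66, 73, 1895, 4817, 1286, 2525, 5693, 5345,
            0.85, 0.85, 0.50),
    high = c(0.6, 0.9, 0.20, 0.95, 0.95, 0.90, 0.35, 0.35, 0.15, 0.50,
             106, 140, 98, 109, 2843, 7225, 1930, 3787, 8539, 8018,
             1.00, 1.00, 0.85)
  )
}

#' One-way deterministic sensitivity analysis for one parameter
#'
#' Re-runs the two-strategy comparison with the parameter set to each
#' bound (all other parameters at base) and records the verdict at each
#' end: an ICER value, `Dominant` or `Dominated`.
#'
#' @param spec Base-case `ear_spec`.
#' @param parameter Parameter id (see [param_ids()]).
#' @param low,high Bounds to evaluate.
#' @return One-row data.frame: `parameter`, `low`, `high`, `verdict_low`,
#'   `icer_low`, `verdict_high`, `icer_high`.
#' @export
one_way_dsa <- function(spec, parameter, low, high) {
  ends <- lapply(c(low, high), function(v) {
    res <- run_comparison(set_param(spec, parameter, v))
    list(verdict = res$verdict, icer = res$icer)
  })
  data.frame(parameter = parameter, low = low, high = high,
             verdict_low = ends[[1]]$verdict, icer_low = ends[[1]]$icer,
             verdict_high = ends[[2]]$verdict, icer_high = ends[[2]]$icer)
}

#' Run the full one-way sensitivity analysis
#'
#' @param spec Base-case `ear_spec`.
#' @param ranges data.frame `id`, `low`, `high` (default [dsa_ranges()]).
#' @return data.frame with one row per parameter (tornado table).
#' @export
run_dsa <- function(spec, ranges = dsa_ranges()) {
  if (nrow(ranges) == 0) {
    return(data.frame(parameter = character(), low = numeric(),
                      high = numeric(), verdict_low = character(),
                      icer_low = numeric(), verdict_high = character(),
                      icer_high = numeric()))
  }
  do.call(rbind, lapply(seq_len(nrow(ranges)), function(i) {
    one_way_dsa(spec, ranges$id[i], ranges$low[i], ranges$high[i])
  }))
}

#' Distributions varied in the probabilistic sensitivity analysis
#'
#' Every parameter carrying a distribution in the published tables:
#' probabilities with symmetric uncertainty and the incidence bands as
#' beta (SE = 20% of base), expert-elicited probabilities and the three
#' utilities as triangular over their printed ranges (mode = base), and
#' all costs as gamma (SE = 20% of base). Structural ages, the discount
#' rate and the GP detection probability vary only via scenarios.
#'
#' @param spec An `ear_spec`.
#' @param se_scale Multiplier on all standard errors and triangular
#'   half-ranges (0 collapses every distribution to its base value).
#' @return Named list of [dist_spec()] objects in fixed declaration
#'   order (the PSA sampling order).
#' @export
psa_distributions <- function(spec, se_scale = 1) {
  tr <- spec$transitions
  cs <- spec$costs
  ut <- spec$utilities
  bt <- function(m) dist_spec("beta", mean = m, se = se_scale * 0.2 * m)
  gm <- function(m) {
    if (m == 0) dist_spec("fixed", mean = 0)
    else dist_spec("gamma", mean = m, se = se_scale * 0.2 * m)
  }
  tri <- function(lo, mode, hi) {
    # published ranges anchor the support; a mode outside them (possible
    # for generated parameter sets) degrades gracefully to a one-sided
    # triangle
    lo <- min(lo, mode)
    hi <- max(hi, mode)
    dist_spec("triangular", min = mode - se_scale * (mode - lo),
              mode = mode, max = mode + se_scale * (hi - mode))
  }
  out <- list()
  for (i in seq_len(nrow(tr$p_ear_by_age))) {
    out[[paste0("p_ear_band", i)]] <- bt(tr$p_ear_by_age$p[i])
  }
  out$p_screen_DeadlyEars <- bt(tr$p_screen[["DeadlyEars"]])
  out$p_screen_MTESS <- bt(tr$p_screen[["MTESS"]])
  out$p_false_negative <- tri(0.02, tr$p_false_negative, 0.20)
  out$p_true_negative <- tri(0.80, tr$p_true_negative, 0.95)
  out$p_treat_if_detected <- bt(tr$p_treat_if_detected)
  out$p_medical_vs_surgical <- tri(0.70, tr$p_medical_vs_surgical, 0.90)
  out$p_treat_failure <- bt(tr$p_treat_failure)
  out$p_progress_untreated <- bt(tr$p_progress_untreated)
  out$p_aid_child <- tri(0.02, tr$p_aid_child, 0.15)
  out$p_aid_adult <- tri(0.10, tr$p_aid_adult, 0.50)
  out$screen_cost_DeadlyEars <- gm(cs$screen_cost[["DeadlyEars"]])
  out$screen_cost_MTESS <- gm(cs$screen_cost[["MTESS"]])
  out$medical_child <- gm(cs$medical_child)
  out$medical_adult <- gm(cs$medical_adult)
  out$surgical_child <- gm(cs$surgical_child)
  out$surgical_adult <- gm(cs$surgical_adult)
  out$hearing_aid_annual <- gm(cs$hearing_aid_annual)
  out$cochlear_annual <- gm(cs$cochlear_annual)
  out$education_annual <- gm(cs$education_annual)
  out$income_loss_annual <- gm(cs$income_loss_annual)
  out$u_healthy_child <- tri(0.85, ut$u_healthy_child, 1.00)
  out$u_healthy_adult <- tri(0.85, ut$u_healthy_adult, 1.00)
  out$u_hearing_loss <- tri(0.50, ut$u_hearing_loss, 0.85)
  out
}

#' Probabilistic sensitivity analysis
#'
#' Second-order Monte Carlo: per draw, every uncertain parameter is
#' sampled from its distribution ([psa_distributions()]), both
#' strategies are run, and the incremental cost and QALYs are recorded.
#' All parameters are sampled up-front in a fixed declaration order from
#' a single seeded generator, so a given seed reproduces the analysis
#' bit for bit. Probability draws from triangular distributions whose
#' range would leave `[0, 1]` are clipped (none do at base settings).
#'
#' @param spec Base-case `ear_spec`.
#' @param n_draws Number of Monte Carlo draws (>= 1).
#' @param seed Integer RNG seed.
#' @param thresholds Threshold grid for the acceptability curve.
#' @param se_scale Multiplier on every distribution's spread (see
#'   [psa_distributions()]).
#' @return A `psa_result`: `draws` (per-draw totals and increments),
#'   `quadrant_table`, `ceac`, `seed`, `n_draws`.
#' @export
run_psa <- function(spec, n_draws = 10000, seed = 1,
                    thresholds = seq(0, 100000, by = 1000), se_scale = 1) {
  stopifnot(n_draws >= 1)
  dists <- psa_distributions(spec, se_scale = se_scale)
  set.seed(seed)
  samples <- vector("list", length(dists))
  names(samples) <- names(dists)
  for (nm in names(dists)) {
    sampler <- tryCatch(fit_distribution(dists[[nm]]),
                        error = function(e) {
                          stop("parameter ", nm, ": ", conditionMessage(e))
                        })
    x <- sampler(n_draws)
    if (grepl("^(p_|u_)", nm)) x <- pmin(1, pmax(0, x))
    samples[[nm]] <- x
  }
  draws <- data.frame(draw = seq_len(n_draws),
                      cost_ref = NA_real_, cost_new = NA_real_,
                      qaly_ref = NA_real_, qaly_new = NA_real_)
  for (k in seq_len(n_draws)) {
    sp <- spec
    for (nm in names(samples)) {
      sp <- set_param(sp, nm, samples[[nm]][k], validate = FALSE)
    }
    tr <- run_cohort(sp, spec$strategies[1])
    tn <- run_cohort(sp, spec$strategies[2])
    draws$cost_ref[k] <- tr$total_cost
    draws$cost_new[k] <- tn$total_cost
    draws$qaly_ref[k] <- tr$total_qaly
    draws$qaly_new[k] <- tn$total_qaly
  }
  draws$delta_cost <- draws$cost_new - draws$cost_ref
  draws$delta_qaly <- draws$qaly_new - draws$qaly_ref
  structure(list(
    draws = draws,
    quadrant_table = quadrant_table(draws),
    ceac = acceptability_curve(draws, thresholds),
    seed = seed, n_draws = n_draws
  ), class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat("<psa_result>", x$n_draws, "draws, seed", x$seed, "\n")
  cat(sprintf("  dominant (comparator cheaper & more effective): %.1f%%\n",
              100 * mean(x$draws$delta_cost <= 0 & x$draws$delta_qaly > 0)))
  for (l in c(10000, 50000)) {
    cat(sprintf("  acceptable at %d/QALY: %.1f%%\n", l,
                100 * mean(l * x$draws$delta_qaly - x$draws$delta_cost >= 0)))
  }
  invisible(x)
}

#' Write PSA draws to CSV
#'
#' @param psa A `psa_result`.
#' @param path Output CSV path.
#' @return The draws data.frame, invisibly.
#' @export
write_psa_csv <- function(psa, path) {
  utils::write.csv(psa$draws, path, row.names = FALSE)
  invisible(psa$draws)
}
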