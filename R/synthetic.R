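#' Configuration for random model generation
#'
#' @param seed Integer seed (identical seed, identical spec).
#' @param terminal_age Horizon end (years).
#' @param prob_max Upper bound for randomly drawn probabilities.
#' @param cost_max Upper bound for randomly drawn costs.
#' @param no_death Zero mortality everywhere.
#' @param no_disease Zero ear-disease incidence (and start everyone
#'   healthy).
#' @param two_state Reduce to a healthy/dead model: no disease, constant
#'   mortality `q_const`, unit utilities and zero costs, so the engine
#'   output is checkable against the closed-form survival annuity.
#' @param q_const Constant annual death probability for `two_state`.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1, terminal_age = 50, prob_max = 0.95,
                             cost_max = 10000, no_death = FALSE,
                             no_disease = FALSE, two_state = FALSE,
                             q_const = 0.02) {
  stopifnot(terminal_age > 19)
  structure(list(seed = as.integer(seed), terminal_age = terminal_age,
                 prob_max = prob_max, cost_max = cost_max,
                 no_death = no_death, no_disease = no_disease,
                 two_state = two_state, q_const = q_const),
            class = "synthetic_config")
}

#' Generate a random valid model specification
#'
#' Draws every probability, cost and utility uniformly from valid
#' ranges (utilities respecting the hearing loss <= ear problem <=
#' healthy ordering via the derived mean), producing a spec that passes
#' all parameter invariants. Degenerate modes zero out parameters rather
#' than switching engine code paths, so oracle tests exercise the
#' production engine.
#'
#' @param config A [synthetic_config()].
#' @return A validated `ear_spec`.
#' @export
generate_model_spec <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  ru <- function(lo, hi) stats::runif(1, lo, hi)
  spec <- baseline_spec()
  spec$meta$name <- paste0("synthetic_seed", config$seed)
  spec$ages$terminal_age <- as.integer(config$terminal_age)
  spec$discount_rate <- ru(0, 0.1)
  tr <- spec$transitions
  tr$p_screen[] <- stats::runif(length(tr$p_screen), 0, config$prob_max)
  tr$p_false_negative <- ru(0, 0.5)
  tr$p_true_negative <- ru(0.5, config$prob_max)
  tr$p_treat_if_detected <- ru(0, config$prob_max)
  tr$p_medical_vs_surgical <- ru(0, 1)
  tr$p_treat_failure <- ru(0, 0.5)
  tr$p_progress_untreated <- ru(0, 0.5)
  tr$p_aid_child <- ru(0, 0.5)
  tr$p_aid_adult <- ru(0, 0.5)
  tr$p_gp_detection <- ru(0, 0.5)
  tr$p_ear_by_age$age_to[nrow(tr$p_ear_by_age)] <- spec$ages$terminal_age
  tr$p_ear_by_age$p <- stats::runif(nrow(tr$p_ear_by_age), 0, 0.2)
  ages <- spec$ages$start_age:spec$ages$terminal_age
  tr$mortality_by_age <- data.frame(
    age = ages, q = stats::runif(length(ages), 0, 0.05))
  spec$transitions <- tr
  cs <- spec$costs
  for (nm in setdiff(names(cs), "screen_cost")) {
    cs[[nm]] <- ru(0, config$cost_max)
  }
  cs$screen_cost[] <- stats::runif(length(cs$screen_cost), 0, 500)
  spec$costs <- cs
  u_hl <- ru(0.2, 0.9)
  u_hc <- ru(u_hl, 1)
  u_ha <- ru(u_hl, 1)
  spec$utilities <- list(
    u_healthy_child = u_hc, u_healthy_adult = u_ha, u_hearing_loss = u_hl,
    u_ear_child = derive_ear_utility(u_hc, u_hl),
    u_ear_adult = derive_ear_utility(u_ha, u_hl))

  if (config$no_disease || config$two_state) {
    spec$transitions$p_ear_by_age$p[] <- 0
  }
  if (config$no_death) {
    spec$transitions$mortality_by_age$q[] <- 0
  }
  if (config$two_state) {
    spec$transitions$mortality_by_age$q[] <- config$q_const
    spec$utilities <- list(u_healthy_child = 1, u_healthy_adult = 1,
                           u_hearing_loss = 1, u_ear_child = 1,
                           u_ear_adult = 1)
    for (nm in setdiff(names(spec$costs), "screen_cost")) {
      spec$costs[[nm]] <- 0
    }
    spec$costs$screen_cost[] <- 0
  }
  validate_model_spec(spec)
}

#' Closed-form present value of a two-state survival annuity
#'
#' Direct summation oracle for the engine on healthy/dead reductions:
#' half-cycle-corrected sum of `reward * (1 - p_die)^t * (1 + rate)^-t`
#' over `cycles` annual cycles.
#'
#' @param p_die Constant annual death probability in `[0, 1]`.
#' @param reward Per-year reward while alive.
#' @param rate Annual discount rate.
#' @param cycles Number of cycles (reward points).
#' @return Present value (scalar).
#' @export
closed_form_two_state <- function(p_die, reward, rate, cycles) {
  stopifnot(p_die >= 0, p_die <= 1, cycles >= 1)
  t <- 0:(cycles - 1)
  w <- if (cycles == 1) 0.5 else c(0.5, rep(1, cycles - 2), 0.5)
  sum(w * reward * (1 - p_die)^t * (1 + rate)^(-t))
}

#' Calibrate the age-dependent incidence schedule
#'
#' Finds a piecewise-constant annual incidence schedule (one band per
#' target age) such that, in the unscreened scenario (detection only via
#' GP visits), hearing-loss prevalence among survivors matches each
#' target at its age. Band `i` spans from the previous target age (or
#' the start age) up to target age `i` minus one; the last band extends
#' to the terminal age. Because prevalence at a target age depends only
#' on earlier bands, bands are solved sequentially by scalar
#' root-finding (bisection via `uniroot`) on the bracket `[0, 0.5]`.
#'
#' @param targets Named numeric vector: names are target ages, values
#'   the hearing-loss prevalences (fractions in `[0, 1)`, increasing
#'   with age).
#' @param base Spec providing all other parameters (default the
#'   packaged base case).
#' @param bracket Incidence bracket searched per band.
#' @param tol Absolute tolerance on achieved prevalence.
#' @return An `ear_spec` equal to `base` with the calibrated
#'   `p_ear_by_age` schedule (also used as the unscreened validation
#'   scenario's schedule).
#' @export
calibrate_incidence <- function(targets, base = baseline_spec(),
                                bracket = c(0, 0.5), tol = 0.005) {
  ages <- as.integer(names(targets))
  if (is.unsorted(ages) || any(duplicated(ages))) {
    stop("target ages must be strictly increasing")
  }
  if (any(targets < 0 | targets >= 1)) stop("targets must lie in [0, 1)")
  if (any(diff(targets) < 0)) stop("targets must be nondecreasing in age")
  ag <- base$ages
  stopifnot(all(ages > ag$start_age), all(ages <= ag$terminal_age))
  from <- c(ag$start_age, ages[-length(ages)])
  to <- c(ages[-length(ages)] - 1L, ag$terminal_age)
  spec <- base
  spec$transitions$p_ear_by_age <- data.frame(age_from = as.integer(from),
                                              age_to = as.integer(to),
                                              p = 0)
  ns <- no_screening_spec(spec)
  prev_at <- function(s, age) {
    hl_prevalence(run_cohort(s, s$strategies[1]), age)
  }
  for (i in seq_along(ages)) {
    f <- function(p) {
      ns$transitions$p_ear_by_age$p[i] <- p
      prev_at(ns, ages[i]) - targets[i]
    }
    if (targets[i] == 0 || f(bracket[1]) >= 0) {
      # a zero band already meets (or exceeds) the target
      if (abs(f(bracket[1])) > tol) {
        stop("target at age ", ages[i], " not bracketed from below")
      }
      p_i <- bracket[1]
    } else {
      if (f(bracket[2]) < 0) {
        stop("target at age ", ages[i], " not attainable within bracket [",
             bracket[1], ", ", bracket[2], "]")
      }
      p_i <- stats::uniroot(f, interval = bracket, tol = 1e-8)$root
    }
    ns$transitions$p_ear_by_age$p[i] <- p_i
  }
  achieved <- vapply(ages, function(a) prev_at(ns, a), numeric(1))
  if (any(abs(achieved - targets) > tol)) {
    stop("calibration failed to reach targets within tolerance")
  }
  spec$transitions$p_ear_by_age <- ns$transitions$p_ear_by_age
  validate_model_spec(spec)
}
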