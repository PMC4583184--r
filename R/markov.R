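#' Health states of the cohort model
#'
#' Five states: healthy children enrolled in the screening program,
#' healthy individuals discharged from it (screen-negative at or after
#' the discharge age, or past the screening stop age), prevalent ear
#' problem, permanent hearing loss, and dead. Hearing loss exits only to
#' death; death is absorbing.
#'
#' @return Character vector of state names, in matrix order.
#' @export
health_states <- function() {
  c("HealthyEnrolled", "HealthyDischarged", "EarProblem", "HearingLoss",
    "Dead")
}

.S <- list(HE = 1L, HD = 2L, EP = 3L, HL = 4L, DE = 5L)

# Collapsed one-cycle parameters for one (age, strategy): 5x5 transition
# matrix plus per-occupant expected cycle cost and utility by state.
cycle_components <- function(age, strategy, spec) {
  tr <- spec$transitions
  ag <- spec$ages
  cs <- spec$costs
  ut <- spec$utilities
  q <- mort_at(spec, age)
  pe <- p_ear_at(spec, age)
  child <- age < ag$adult_age
  screening_on <- age < ag$screening_stop_age
  s <- if (screening_on) tr$p_screen[[strategy]] else 0

  c_med <- if (child) cs$medical_child else cs$medical_adult
  c_surg <- if (child) cs$surgical_child else cs$surgical_adult
  treat_cost <- tr$p_medical_vs_surgical * c_med +
    (1 - tr$p_medical_vs_surgical) * c_surg
  scr_cost <- if (screening_on) s * cs$screen_cost[[strategy]] else 0

  M <- matrix(0, 5, 5)
  cost <- numeric(5)

  # Healthy, enrolled: screened while the program runs; a negative screen
  # at or after the discharge age moves the child out of the program; a
  # false positive incurs a medical work-up but leaves the state healthy.
  if (!screening_on) {
    M[.S$HE, .S$HD] <- 1 - pe
    M[.S$HE, .S$EP] <- pe
  } else {
    to_disch <- if (age >= ag$discharge_age) s * tr$p_true_negative else 0
    M[.S$HE, .S$HE] <- (1 - pe) * (1 - to_disch)
    M[.S$HE, .S$HD] <- (1 - pe) * to_disch
    M[.S$HE, .S$EP] <- pe
    cost[.S$HE] <- scr_cost +
      s * (1 - tr$p_true_negative) * tr$p_treat_if_detected * c_med
  }

  # Healthy, discharged: no screening; re-entry to care only through the
  # ear-problem state (GP detection).
  M[.S$HD, .S$HD] <- 1 - pe
  M[.S$HD, .S$EP] <- pe

  # Ear problem: detected by screening (true positive) or, if unscreened,
  # by a GP visit; detected cases are treated (medical or surgical) and a
  # successful treatment restores health. Failed or undetected disease
  # may progress to permanent hearing loss.
  d <- if (screening_on) {
    s * (1 - tr$p_false_negative) + (1 - s) * tr$p_gp_detection
  } else {
    tr$p_gp_detection
  }
  cure <- d * tr$p_treat_if_detected * (1 - tr$p_treat_failure)
  healthy_dest <- if (screening_on) .S$HE else .S$HD
  M[.S$EP, healthy_dest] <- cure
  M[.S$EP, .S$HL] <- (1 - cure) * tr$p_progress_untreated
  M[.S$EP, .S$EP] <- (1 - cure) * (1 - tr$p_progress_untreated)
  cost[.S$EP] <- scr_cost + d * tr$p_treat_if_detected * treat_cost

  # Hearing loss: permanent; annual support costs while alive.
  M[.S$HL, .S$HL] <- 1
  split <- if (child) spec$aid_split$child else spec$aid_split$adult
  aid_cost <- split[["non_cochlear"]] * cs$hearing_aid_annual +
    split[["cochlear"]] * cs$cochlear_annual
  p_aid <- if (child) tr$p_aid_child else tr$p_aid_adult
  cost[.S$HL] <- p_aid * aid_cost +
    (if (age >= ag$education_start_age && child) cs$education_annual else 0) +
    (if (age >= ag$income_loss_start_age) cs$income_loss_annual else 0)

  # Mortality as a competing final split on every living state.
  M[1:4, ] <- M[1:4, ] * (1 - q)
  M[1:4, .S$DE] <- M[1:4, .S$DE] + q
  M[.S$DE, .S$DE] <- 1

  u_h <- if (child) ut$u_healthy_child else ut$u_healthy_adult
  u_e <- if (child) ut$u_ear_child else ut$u_ear_adult
  utility <- c(u_h, u_h, u_e, ut$u_hearing_loss, 0)

  list(M = M, cost = cost, utility = utility)
}

#' Collapse the per-cycle screening/treatment tree for one state
#'
#' Enumerates the mutually exclusive screening, detection, treatment and
#' outcome paths open to an occupant of `state` at the given age under
#' the given strategy, and returns the resulting one-cycle destination
#' probabilities together with the expected per-occupant cycle cost.
#' Mortality is applied as a competing final split.
#'
#' @param state A state name from [health_states()].
#' @param age Age in years (within the modelled range).
#' @param strategy Strategy id (e.g. `"DeadlyEars"` or `"MTESS"`).
#' @param spec An `ear_spec`.
#' @return List with `probs` (named length-5 probability vector summing
#'   to 1) and `cost` (expected cycle cost for an occupant of `state`).
#' @export
collapse_decision_tree <- function(state, age, strategy, spec) {
  states <- health_states()
  i <- match(state, states)
  if (is.na(i)) stop("unknown state: ", state)
  cc <- cycle_components(age, strategy, spec)
  probs <- cc$M[i, ]
  names(probs) <- states
  list(probs = probs, cost = cc$cost[i])
}

#' Build the one-cycle transition matrix
#'
#' @param age Age in years; must lie in `[start_age, terminal_age]`.
#' @param strategy Strategy id.
#' @param spec An `ear_spec`.
#' @return A 5x5 row-stochastic matrix over [health_states()].
#' @export
build_transition_matrix <- function(age, strategy, spec) {
  if (age < spec$ages$start_age || age > spec$ages$terminal_age) {
    stop("age ", age, " outside modelled range [", spec$ages$start_age,
         ", ", spec$ages$terminal_age, "]")
  }
  M <- cycle_components(age, strategy, spec)$M
  dimnames(M) <- list(health_states(), health_states())
  M
}

#' Discount a per-cycle stream with half-cycle correction
#'
#' Applies the life-table half-cycle convention (half weight on the first
#' and the terminal cycle) and discounts cycle `t` (0-based) at
#' `(1 + rate)^-t`, returning the present-value sum.
#'
#' @param stream Numeric vector of per-cycle (annual) values.
#' @param rate Annual discount rate (fraction).
#' @return Present value (scalar).
#' @export
discount_and_correct <- function(stream, rate) {
  n <- length(stream)
  if (n == 0) stop("empty stream")
  w <- if (n == 1) 0.5 else c(0.5, rep(1, n - 2), 0.5)
  t <- seq_len(n) - 1
  sum(w * stream * (1 + rate)^(-t))
}

#' Run the cohort simulation for one strategy
#'
#' Iterates annual cycles from the start age to the terminal age. The
#' cohort enters split between healthy (enrolled) and ear problem at the
#' start-age incidence; nobody starts with hearing loss. Per-cycle costs
#' (screening of the enrolled and symptomatic, expected treatment costs,
#' false-positive work-ups, and hearing-loss consequence costs) and
#' QALYs (occupancy times the age-appropriate utility) are accrued on
#' start-of-cycle occupancy; the dead contribute nothing. Totals are
#' discounted with half-cycle correction.
#'
#' @param spec An `ear_spec`.
#' @param strategy Strategy id; must appear in `spec$strategies`.
#' @return A `cohort_trace` object: per-cycle occupancy, cost and QALY
#'   streams, and discounted totals (`total_cost`, `total_qaly`).
#' @export
run_cohort <- function(spec, strategy) {
  if (!strategy %in% spec$strategies) {
    stop("unknown strategy: ", strategy)
  }
  tr <- spec$transitions
  ag <- spec$ages
  cs <- spec$costs
  ut <- spec$utilities
  ages <- ag$start_age:ag$terminal_age
  n <- length(ages)

  # precomputed per-age ingredients (same arithmetic as
  # cycle_components(), unrolled for speed; a regression test checks the
  # two paths agree)
  q <- mort_at(spec, ages)
  pe <- p_ear_at(spec, ages)
  child <- ages < ag$adult_age
  scr_on <- ages < ag$screening_stop_age
  s <- ifelse(scr_on, tr$p_screen[[strategy]], 0)
  to_disch <- ifelse(scr_on & ages >= ag$discharge_age,
                     s * tr$p_true_negative, 0)
  d <- ifelse(scr_on,
              s * (1 - tr$p_false_negative) + (1 - s) * tr$p_gp_detection,
              tr$p_gp_detection)
  cure <- d * tr$p_treat_if_detected * (1 - tr$p_treat_failure)
  pp <- tr$p_progress_untreated
  c_med <- ifelse(child, cs$medical_child, cs$medical_adult)
  c_surg <- ifelse(child, cs$surgical_child, cs$surgical_adult)
  treat_cost <- tr$p_medical_vs_surgical * c_med +
    (1 - tr$p_medical_vs_surgical) * c_surg
  scr_cost <- ifelse(scr_on, s * cs$screen_cost[[strategy]], 0)
  cost_he <- scr_cost + ifelse(scr_on,
    s * (1 - tr$p_true_negative) * tr$p_treat_if_detected * c_med, 0)
  cost_ep <- scr_cost + d * tr$p_treat_if_detected * treat_cost
  aid_cost <- ifelse(child,
    spec$aid_split$child[["non_cochlear"]] * cs$hearing_aid_annual +
      spec$aid_split$child[["cochlear"]] * cs$cochlear_annual,
    spec$aid_split$adult[["non_cochlear"]] * cs$hearing_aid_annual +
      spec$aid_split$adult[["cochlear"]] * cs$cochlear_annual)
  p_aid <- ifelse(child, tr$p_aid_child, tr$p_aid_adult)
  cost_hl <- p_aid * aid_cost +
    ifelse(ages >= ag$education_start_age & child, cs$education_annual, 0) +
    ifelse(ages >= ag$income_loss_start_age, cs$income_loss_annual, 0)
  u_h <- ifelse(child, ut$u_healthy_child, ut$u_healthy_adult)
  u_e <- ifelse(child, ut$u_ear_child, ut$u_ear_adult)

  occ <- matrix(0, n, 5, dimnames = list(NULL, health_states()))
  he <- 1 - pe[1]; hd <- 0; ep <- pe[1]; hl <- 0; de <- 0
  occ[1, ] <- c(he, hd, ep, hl, de)
  cost <- numeric(n)
  qaly <- numeric(n)
  for (t in seq_len(n)) {
    cost[t] <- he * cost_he[t] + ep * cost_ep[t] + hl * cost_hl[t]
    qaly[t] <- (he + hd) * u_h[t] + ep * u_e[t] + hl * ut$u_hearing_loss
    if (t < n) {
      sv <- 1 - q[t]
      if (scr_on[t]) {
        he2 <- (he * (1 - pe[t]) * (1 - to_disch[t]) + ep * cure[t]) * sv
        hd2 <- (he * (1 - pe[t]) * to_disch[t] + hd * (1 - pe[t])) * sv
      } else {
        he2 <- 0
        hd2 <- ((he + hd) * (1 - pe[t]) + ep * cure[t]) * sv
      }
      ep2 <- ((he + hd) * pe[t] + ep * (1 - cure[t]) * (1 - pp)) * sv
      hl2 <- (ep * (1 - cure[t]) * pp + hl) * sv
      de2 <- de + (he + hd + ep + hl) * q[t]
      he <- he2; hd <- hd2; ep <- ep2; hl <- hl2; de <- de2
      occ[t + 1, ] <- c(he, hd, ep, hl, de)
    }
  }
  structure(list(
    strategy = strategy,
    spec_name = spec$meta$name,
    discount_rate = spec$discount_rate,
    ages = ages,
    occupancy = occ,
    cost_stream = cost,
    qaly_stream = qaly,
    total_cost = discount_and_correct(cost, spec$discount_rate),
    total_qaly = discount_and_correct(qaly, spec$discount_rate)
  ), class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat("<cohort_trace>", x$strategy, "| ages", min(x$ages), "-", max(x$ages),
      "| discount", x$discount_rate, "\n")
  cat(sprintf("  total discounted cost: %.2f\n", x$total_cost))
  cat(sprintf("  total discounted QALYs: %.4f\n", x$total_qaly))
  invisible(x)
}

#' @export
as.data.frame.cohort_trace <- function(x, ...) {
  t <- seq_along(x$ages) - 1
  w <- if (length(t) == 1) 0.5 else c(0.5, rep(1, length(t) - 2), 0.5)
  df <- (1 + x$discount_rate)^(-t)
  data.frame(age = x$ages, as.data.frame(x$occupancy),
             cost = x$cost_stream, qaly = x$qaly_stream,
             disc_cost = w * x$cost_stream * df,
             disc_qaly = w * x$qaly_stream * df)
}

#' Write a cohort trace to CSV
#'
#' One row per cycle: age, state occupancy, undiscounted and discounted
#' (half-cycle-weighted) cost and QALY contributions.
#'
#' @param trace A `cohort_trace`.
#' @param path Output CSV path.
#' @return The trace data.frame, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  df <- as.data.frame(trace)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Hearing-loss prevalence at a given age
#'
#' State occupancy of the hearing-loss state at `age`, by default among
#' survivors (occupancy renormalised over living states).
#'
#' @param trace A `cohort_trace`.
#' @param age Age in years (must be a modelled cycle age).
#' @param among_survivors Divide by the living fraction (default TRUE)?
#' @return Prevalence as a fraction.
#' @export
hl_prevalence <- function(trace, age, among_survivors = TRUE) {
  i <- match(age, trace$ages)
  if (is.na(i)) stop("age ", age, " not a modelled cycle age")
  hl <- unname(trace$occupancy[i, .S$HL])
  if (among_survivors) hl / (1 - unname(trace$occupancy[i, .S$DE])) else hl
}
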