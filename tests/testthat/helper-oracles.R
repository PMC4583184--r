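# Independent brute-force enumeration of the one-cycle screening ->
# detection -> treatment -> outcome tree for an ear-problem occupant.
# Written against the model description only (not the engine internals):
# every mutually exclusive leaf is listed with its probability and
# destination, then aggregated and subjected to the competing mortality
# split. Used as the oracle for collapse_decision_tree().
ep_row_leaf_oracle <- function(age, strategy, spec) {
  tr <- spec$transitions
  scr_on <- age < spec$ages$screening_stop_age
  s <- if (scr_on) tr$p_screen[[strategy]] else 0
  healthy_dest <- if (scr_on) "HealthyEnrolled" else "HealthyDischarged"
  leaves <- data.frame(p = numeric(0), dest = character(0))
  add <- function(p, dest) {
    leaves <<- rbind(leaves, data.frame(p = p, dest = dest))
  }
  progress_split <- function(p) {
    add(p * tr$p_progress_untreated, "HearingLoss")
    add(p * (1 - tr$p_progress_untreated), "EarProblem")
  }
  for (screened in c(TRUE, FALSE)) {
    p1 <- if (screened) s else 1 - s
    if (p1 == 0) next
    p_det <- if (screened) 1 - tr$p_false_negative else tr$p_gp_detection
    for (detected in c(TRUE, FALSE)) {
      p2 <- p1 * (if (detected) p_det else 1 - p_det)
      if (p2 == 0) next
      if (!detected) {
        progress_split(p2)
      } else {
        # treated (medical or surgical arm) with success/failure, or
        # no treatment obtained
        for (arm_medical in c(TRUE, FALSE)) {
          p_arm <- p2 * tr$p_treat_if_detected *
            (if (arm_medical) tr$p_medical_vs_surgical
             else 1 - tr$p_medical_vs_surgical)
          add(p_arm * (1 - tr$p_treat_failure), healthy_dest)
          progress_split(p_arm * tr$p_treat_failure)
        }
        progress_split(p2 * (1 - tr$p_treat_if_detected))
      }
    }
  }
  states <- health_states()
  row <- vapply(states, function(st) sum(leaves$p[leaves$dest == st]),
                numeric(1))
  q <- spec$transitions$mortality_by_age$q[
    match(age, spec$transitions$mortality_by_age$age)]
  row <- row * (1 - q)
  row["Dead"] <- row["Dead"] + q
  row
}

# Matrix-product reference path for the cohort engine: iterates the
# exported per-age transition matrices and per-state rewards, for
# comparison with the unrolled recursion inside run_cohort().
reference_trace <- function(spec, strategy) {
  ages <- spec$ages$start_age:spec$ages$terminal_age
  n <- length(ages)
  occ <- matrix(0, n, 5, dimnames = list(NULL, health_states()))
  p0 <- spec$transitions$p_ear_by_age$p[1]
  occ[1, "HealthyEnrolled"] <- 1 - p0
  occ[1, "EarProblem"] <- p0
  cost <- numeric(n)
  qaly <- numeric(n)
  ut <- spec$utilities
  for (t in seq_len(n)) {
    a <- ages[t]
    child <- a < spec$ages$adult_age
    u <- c(rep(if (child) ut$u_healthy_child else ut$u_healthy_adult, 2),
           if (child) ut$u_ear_child else ut$u_ear_adult,
           ut$u_hearing_loss, 0)
    cvec <- vapply(health_states(), function(st) {
      collapse_decision_tree(st, a, strategy, spec)$cost
    }, numeric(1))
    cost[t] <- sum(occ[t, ] * cvec)
    qaly[t] <- sum(occ[t, ] * u)
    if (t < n) {
      occ[t + 1, ] <- as.numeric(occ[t, ] %*%
                                   build_transition_matrix(a, strategy, spec))
    }
  }
  list(occupancy = occ, cost = cost, qaly = qaly)
}
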