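#' Compare two strategies (incremental cost-effectiveness)
#'
#' Computes incremental cost and QALYs of the new strategy over the
#' reference and classifies the result: `Dominant` (cheaper and more
#' effective), `Dominated` (costlier and less effective), `Indifferent`
#' (identical), or an incremental cost-effectiveness ratio (ICER,
#' incremental cost per QALY gained). When the QALY increment is exactly
#' zero with a non-zero cost increment, the verdict follows the cost sign
#' and the ICER is undefined (`NA`).
#'
#' @param trace_ref Reference-strategy `cohort_trace`.
#' @param trace_new Comparator `cohort_trace` (increments are new - ref).
#' @return A `ce_result`: per-strategy totals, increments, `icer`,
#'   `verdict`.
#' @export
compare_strategies <- function(trace_ref, trace_new) {
  stopifnot(inherits(trace_ref, "cohort_trace"),
            inherits(trace_new, "cohort_trace"))
  if (!identical(trace_ref$ages, trace_new$ages) ||
        trace_ref$discount_rate != trace_new$discount_rate) {
    stop("traces were not produced under the same horizon and discount rate")
  }
  dc <- trace_new$total_cost - trace_ref$total_cost
  dq <- trace_new$total_qaly - trace_ref$total_qaly
  if (dc == 0 && dq == 0) {
    verdict <- "Indifferent"; icer <- NA_real_
  } else if (dc < 0 && dq > 0) {
    verdict <- "Dominant"; icer <- NA_real_
  } else if (dc > 0 && dq < 0) {
    verdict <- "Dominated"; icer <- NA_real_
  } else if (dq == 0) {
    verdict <- if (dc > 0) "Dominated" else "Dominant"; icer <- NA_real_
  } else {
    verdict <- "ICER"; icer <- dc / dq
  }
  structure(list(
    reference = trace_ref$strategy, comparator = trace_new$strategy,
    cost_ref = trace_ref$total_cost, cost_new = trace_new$total_cost,
    qaly_ref = trace_ref$total_qaly, qaly_new = trace_new$total_qaly,
    delta_cost = dc, delta_qaly = dq, icer = icer, verdict = verdict
  ), class = "ce_result")
}

#' Run both strategies and compare them
#'
#' Convenience wrapper: runs the cohort for the reference (first) and
#' comparator (second) strategy of the spec and compares them.
#'
#' @param spec An `ear_spec`.
#' @param reference Reference strategy (default the spec's first).
#' @param comparator Comparator strategy (default the spec's second).
#' @return A `ce_result` with the traces attached as `trace_ref`,
#'   `trace_new`.
#' @export
run_comparison <- function(spec, reference = spec$strategies[1],
                           comparator = spec$strategies[2]) {
  tr <- run_cohort(spec, reference)
  tn <- run_cohort(spec, comparator)
  res <- compare_strategies(tr, tn)
  res$trace_ref <- tr
  res$trace_new <- tn
  res
}

#' @export
print.ce_result <- function(x, ...) {
  cat("<ce_result>", x$comparator, "vs", x$reference, "\n")
  cat(sprintf("  cost:  %s %.0f | %s %.0f | delta %+.2f\n", x$reference,
              x$cost_ref, x$comparator, x$cost_new, x$delta_cost))
  cat(sprintf("  QALYs: %s %.3f | %s %.3f | delta %+.4f\n", x$reference,
              x$qaly_ref, x$comparator, x$qaly_new, x$delta_qaly))
  if (x$verdict == "ICER") {
    cat(sprintf("  ICER: %.0f per QALY\n", x$icer))
  } else {
    cat("  verdict:", x$verdict, "\n")
  }
  invisible(x)
}

#' Summarise a comparison as a results table
#'
#' @param res A `ce_result`.
#' @return A data.frame shaped like a published cost-effectiveness
#'   results table (totals, increments, cost/QALY, ICER or verdict).
#' @export
ce_table <- function(res) {
  stopifnot(inherits(res, "ce_result"))
  data.frame(
    quantity = c("Total cost", "Incremental cost", "Total QALYs",
                 "Incremental QALYs", "Cost/QALY", "ICER or verdict"),
    reference = c(round(res$cost_ref), NA, round(res$qaly_ref, 3), NA,
                  round(res$cost_ref / res$qaly_ref), NA),
    comparator = c(round(res$cost_new), round(res$delta_cost),
                   round(res$qaly_new, 3), round(res$delta_qaly, 3),
                   round(res$cost_new / res$qaly_new),
                   if (res$verdict == "ICER") round(res$icer) else NA),
    verdict = c(NA, NA, NA, NA, NA,
                if (res$verdict == "ICER") "ICER" else res$verdict)
  )
}

#' Classify a point on the cost-effectiveness plane
#'
#' Quadrants follow the published convention for a comparator versus a
#' reference: I more costly & more effective, II more costly & less
#' effective, III less costly & less effective, IV less costly & more
#' effective. A point is acceptable at willingness-to-pay `threshold`
#' when its net monetary benefit `threshold * delta_qaly - delta_cost`
#' is non-negative (inclusive at the boundary).
#'
#' @param delta_cost Incremental cost.
#' @param delta_qaly Incremental QALYs.
#' @param thresholds Numeric vector of willingness-to-pay thresholds.
#' @return List with `quadrant` (`"I"`..`"IV"`), `dominant`, `dominated`,
#'   and `acceptable_at` (named logical per threshold).
#' @export
classify_point <- function(delta_cost, delta_qaly, thresholds = 50000) {
  stopifnot(is.finite(delta_cost), is.finite(delta_qaly))
  more_costly <- delta_cost > 0
  more_effective <- delta_qaly > 0
  quadrant <- if (more_costly && more_effective) "I"
  else if (more_costly && !more_effective) "II"
  else if (!more_costly && !more_effective) "III"
  else "IV"
  acc <- thresholds * delta_qaly - delta_cost >= 0
  names(acc) <- thresholds
  list(quadrant = quadrant,
       dominant = !more_costly && more_effective,
       dominated = more_costly && delta_qaly < 0,
       acceptable_at = acc)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold, the fraction of (delta cost,
#' delta QALY) points with non-negative net monetary benefit.
#'
#' @param draws data.frame with columns `delta_cost`, `delta_qaly`.
#' @param thresholds Threshold grid (default 0 to 100,000 by 1,000).
#' @return data.frame with columns `threshold`, `probability`.
#' @export
acceptability_curve <- function(draws,
                                thresholds = seq(0, 100000, by = 1000)) {
  stopifnot(nrow(draws) > 0,
            all(c("delta_cost", "delta_qaly") %in% names(draws)))
  prob <- vapply(thresholds, function(l) {
    mean(l * draws$delta_qaly - draws$delta_cost >= 0)
  }, numeric(1))
  data.frame(threshold = thresholds, probability = prob)
}

#' Quadrant table for PSA draws
#'
#' Tabulates the distribution of PSA points on the cost-effectiveness
#' plane at each threshold, with quadrants I and III split at the
#' threshold and dominance reported separately — six rows per threshold,
#' mirroring the published summary layout.
#'
#' @param draws data.frame with columns `delta_cost`, `delta_qaly`.
#' @param thresholds Thresholds at which to split quadrants I and III.
#' @return data.frame with columns `quadrant`, `classification` and one
#'   fraction column per threshold.
#' @export
quadrant_table <- function(draws, thresholds = c(10000, 30000, 50000)) {
  stopifnot(nrow(draws) > 0)
  dc <- draws$delta_cost
  dq <- draws$delta_qaly
  q1 <- dc > 0 & dq > 0
  q2 <- dc > 0 & dq <= 0
  q3 <- dc <= 0 & dq <= 0
  q4 <- dc <= 0 & dq > 0
  out <- data.frame(
    quadrant = c("I", "I", "II", "III", "III", "IV"),
    classification = c("Below threshold", "Above threshold", "Dominated",
                       "Below threshold", "Above threshold", "Dominant"))
  for (l in thresholds) {
    nmb <- l * dq - dc
    out[[paste0("wtp_", l)]] <- c(
      mean(q1 & nmb >= 0), mean(q1 & nmb < 0), mean(q2),
      mean(q3 & nmb < 0), mean(q3 & nmb >= 0), mean(q4))
  }
  out
}
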