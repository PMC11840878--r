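# Vectorized penalty kernel: days overdue (floored at zero) times the
# priority weight; unscheduled (NA day) surgeries contribute zero.
penalty_vec <- function(day, deadline, weight) {
  p <- pmax(0, day - deadline) * weight
  p[is.na(day)] <- 0
  p
}

#' Penalty earned by a single surgery
#'
#' The penalty is the number of days the surgery is scheduled past its
#' guaranteed-maximum-response-time deadline, multiplied by the weight of its
#' priority level; a surgery on or before its deadline earns zero. An
#' unscheduled surgery earns zero as well -- unscheduled cases are counted in
#' their own report column, not folded into the penalty score.
#'
#' @param surgery one waiting-list entry: a list or one-row data.frame with
#'   at least \code{deadline_day} and \code{priority}.
#' @param scheduled_day integer day, or NA for unscheduled.
#' @param weights named numeric vector mapping priority level to weight.
#' @return non-negative scalar penalty.
#' @export
surgery_penalty <- function(surgery, scheduled_day, weights) {
  pr <- as.character(surgery$priority)
  if (!pr %in% names(weights)) {
    stopf("no weight configured for priority level %s", pr)
  }
  penalty_vec(scheduled_day, surgery$deadline_day, weights[[pr]])
}

#' Total penalty and schedule metrics
#'
#' Sums the per-surgery penalties into the total penalty score \code{pt} and
#' tallies the three count metrics reported alongside it: surgeries without
#' penalty, surgeries with penalty, and unscheduled surgeries. The solvers
#' minimize \code{objective = total + unscheduled_cost * n_unscheduled};
#' with the default \code{unscheduled_cost = 0} the objective equals the
#' penalty score itself.
#'
#' An infeasible schedule is still scored, but the report's
#' \code{infeasible} flag is set; solvers treat that flag as a rejection
#' signal and never emit such schedules.
#'
#' @param schedule an [ssp_schedule()].
#' @param instance an [ssp_instance()].
#' @param unscheduled_cost fixed extra cost charged per unscheduled surgery
#'   in the \code{objective} (not in \code{total}).
#' @param check if FALSE, skip the feasibility check (used in inner loops
#'   where feasibility is maintained by construction).
#' @return object of class \code{ssp_penalty_report}: a list with
#'   \code{per_surgery} (named numeric), \code{total}, \code{objective},
#'   \code{counts} (\code{n_without_penalty}, \code{n_with_penalty},
#'   \code{n_unscheduled}), \code{unscheduled_cost} and \code{infeasible}.
#' @export
total_penalty <- function(schedule, instance, unscheduled_cost = 0,
                          check = TRUE) {
  sur <- instance$surgeries
  day <- scheduled_days(schedule, instance)
  w <- instance$priority_weights[as.character(sur$priority)]
  if (anyNA(w)) {
    bad <- unique(sur$priority[is.na(w)])
    stopf("no weight configured for priority level(s): %s",
          paste(bad, collapse = ", "))
  }
  p <- penalty_vec(day[sur$id], sur$deadline_day, unname(w))
  names(p) <- sur$id
  n_unsched <- sum(is.na(day[sur$id]))
  counts <- c(n_without_penalty = sum(!is.na(day[sur$id]) & p == 0),
              n_with_penalty = sum(p > 0),
              n_unscheduled = n_unsched)
  infeasible <- if (check) nrow(check_feasibility(schedule, instance)) > 0 else FALSE
  structure(
    list(per_surgery = p,
         total = sum(p),
         objective = sum(p) + unscheduled_cost * n_unsched,
         counts = counts,
         unscheduled_cost = unscheduled_cost,
         infeasible = infeasible),
    class = "ssp_penalty_report"
  )
}

#' @export
print.ssp_penalty_report <- function(x, ...) {
  cat(sprintf("penalty score (pt): %g%s\n", x$total,
              if (x$infeasible) "  [INFEASIBLE SCHEDULE]" else ""))
  if (x$unscheduled_cost > 0) {
    cat(sprintf("objective (pt + %g per unscheduled): %g\n",
                x$unscheduled_cost, x$objective))
  }
  cat(sprintf("  without penalty: %d   with penalty: %d   unscheduled: %d\n",
              x$counts[["n_without_penalty"]], x$counts[["n_with_penalty"]],
              x$counts[["n_unscheduled"]]))
  invisible(x)
}

#' Per-surgery day shift between two schedules
#'
#' For every surgery scheduled in both schedules, reports
#' \code{day_a - day_b}: negative values mean schedule \code{a} books the
#' surgery earlier. Surgeries unscheduled on either side are listed in a
#' separate bucket rather than given a delta.
#'
#' @param schedule_a,schedule_b two [ssp_schedule()]s over \code{instance}.
#' @param instance an [ssp_instance()].
#' @return list of class \code{ssp_schedule_delta}: \code{deltas}
#'   (data.frame surgery_id, day_a, day_b, delta), \code{unmatched}
#'   (surgeries unscheduled in either schedule, with a side marker), and
#'   \code{summary} (counts earlier/same/later and the mean shift).
#' @export
schedule_delta <- function(schedule_a, schedule_b, instance) {
  da <- scheduled_days(schedule_a, instance)
  db <- scheduled_days(schedule_b, instance)
  ids <- instance$surgeries$id
  both <- ids[!is.na(da[ids]) & !is.na(db[ids])]
  deltas <- data.frame(surgery_id = both,
                       day_a = unname(da[both]),
                       day_b = unname(db[both]),
                       delta = unname(da[both] - db[both]),
                       stringsAsFactors = FALSE)
  miss <- ids[is.na(da[ids]) | is.na(db[ids])]
  unmatched <- data.frame(
    surgery_id = miss,
    unscheduled_in = ifelse(is.na(da[miss]) & is.na(db[miss]), "both",
                            ifelse(is.na(da[miss]), "a", "b")),
    stringsAsFactors = FALSE)
  structure(
    list(deltas = deltas, unmatched = unmatched,
         summary = c(n_earlier = sum(deltas$delta < 0),
                     n_same = sum(deltas$delta == 0),
                     n_later = sum(deltas$delta > 0),
                     mean_shift = if (nrow(deltas)) mean(deltas$delta) else NA_real_)),
    class = "ssp_schedule_delta"
  )
}

#' @export
print.ssp_schedule_delta <- function(x, ...) {
  s <- x$summary
  cat(sprintf("schedule delta over %d surgeries scheduled in both:\n",
              nrow(x$deltas)))
  cat(sprintf("  earlier in a: %d   same day: %d   later in a: %d   mean shift: %s\n",
              s[["n_earlier"]], s[["n_same"]], s[["n_later"]],
              format(s[["mean_shift"]], digits = 3)))
  if (nrow(x$unmatched)) {
    cat(sprintf("  %d surgeries unscheduled in at least one schedule\n",
                nrow(x$unmatched)))
  }
  invisible(x)
}
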