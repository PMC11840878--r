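#' Construct a surgical scheduling instance
#'
#' Bundles a surgical waiting list and the bookable operating-room (OR)
#' shifts ("slots") of one scheduling period into a single instance object,
#' the input to every solver and report in the package.
#'
#' A waiting-list entry carries the estimated procedure duration plus the
#' turnover time needed to clean and prepare the room afterwards, the day the
#' patient entered the list, the guaranteed-maximum-response-time deadline,
#' and an ordinal priority level. A slot is one shift of one OR on one day,
#' reserved for a single specialty, with a capacity in minutes and an
#' optional cap on the number of surgeries it may host. Days are 0-based
#' integers over the half-open horizon \code{[0, horizon_days)}; waiting-list
#' entry days (and hence deadlines) may be negative, meaning the patient
#' joined the list before the period under study.
#'
#' @param surgeries data.frame with columns \code{id}, \code{specialty},
#'   \code{duration_min}, \code{turnover_min}, \code{entry_day},
#'   \code{deadline_day}, \code{priority}.
#' @param slots data.frame with columns \code{id}, \code{day}, \code{room},
#'   \code{specialty}, \code{start_min}, \code{length_min},
#'   \code{max_surgeries} (NA = unbounded).
#' @param horizon_days length of the planning horizon in days.
#' @param priority_weights named numeric vector mapping priority level to a
#'   positive penalty weight, e.g. \code{c("1" = 1, "2" = 2, "3" = 4, "4" = 8)}.
#' @param specialty_rooms optional named list mapping each specialty to the
#'   rooms it may use; derived from \code{slots} when omitted (a specialty
#'   appearing only in \code{surgeries} gets zero permitted rooms, which is a
#'   legal state: such surgeries can never be scheduled).
#' @param rooms optional character vector of room identifiers; derived from
#'   \code{slots} when omitted.
#' @return An object of class \code{ssp_instance}.
#' @seealso [validate_instance()], [check_feasibility()], [generate_instance()]
#' @export
ssp_instance <- function(surgeries, slots, horizon_days,
                         priority_weights = c("1" = 1, "2" = 2, "3" = 4, "4" = 8),
                         specialty_rooms = NULL, rooms = NULL) {
  surgeries <- as.data.frame(surgeries, stringsAsFactors = FALSE)
  slots <- as.data.frame(slots, stringsAsFactors = FALSE)
  need_sur <- c("id", "specialty", "duration_min", "turnover_min",
                "entry_day", "deadline_day", "priority")
  need_slo <- c("id", "day", "room", "specialty", "start_min", "length_min")
  miss <- setdiff(need_sur, names(surgeries))
  if (length(miss)) stopf("surgeries is missing column(s): %s",
                          paste(miss, collapse = ", "))
  miss <- setdiff(need_slo, names(slots))
  if (length(miss)) stopf("slots is missing column(s): %s",
                          paste(miss, collapse = ", "))
  if (!"max_surgeries" %in% names(slots)) slots$max_surgeries <- NA_real_
  surgeries$id <- as.character(surgeries$id)
  slots$id <- as.character(slots$id)
  slots$room <- as.character(slots$room)

  if (is.null(rooms)) rooms <- sort(unique(slots$room))
  if (is.null(specialty_rooms)) {
    specs <- sort(unique(c(surgeries$specialty, slots$specialty)))
    specialty_rooms <- lapply(specs, function(s) {
      sort(unique(slots$room[slots$specialty == s]))
    })
    names(specialty_rooms) <- specs
  }
  structure(
    list(surgeries = surgeries, slots = slots,
         horizon_days = as.integer(horizon_days),
         rooms = rooms,
         priority_weights = priority_weights,
         specialty_rooms = specialty_rooms),
    class = "ssp_instance"
  )
}

#' @export
print.ssp_instance <- function(x, ...) {
  cat(sprintf("ssp_instance: %d surgeries, %d slots, horizon %d days, %d room(s)\n",
              nrow(x$surgeries), nrow(x$slots), x$horizon_days, length(x$rooms)))
  tab <- table(x$surgeries$specialty)
  stab <- table(x$slots$specialty)
  for (s in union(names(tab), names(stab))) {
    cat(sprintf("  %-28s %4d surgeries / %4d slots\n", s,
                if (s %in% names(tab)) tab[[s]] else 0L,
                if (s %in% names(stab)) stab[[s]] else 0L))
  }
  invisible(x)
}

#' Structural validation of an instance
#'
#' Checks every type invariant of an instance -- positive durations,
#' non-negative turnovers, deadlines no earlier than entry days, priorities
#' covered by the weight map, unique identifiers, slot days inside the
#' horizon, positive slot lengths -- and returns the violations as data
#' rather than raising errors. Demand exceeding slot capacity is \emph{not} a
#' violation: an overloaded waiting list is the normal state of the problem.
#'
#' @param instance an [ssp_instance()].
#' @return data.frame with columns \code{entity}, \code{rule},
#'   \code{message}; zero rows iff the instance is valid.
#' @export
validate_instance <- function(instance) {
  stopifnot(inherits(instance, "ssp_instance"))
  sur <- instance$surgeries
  slo <- instance$slots
  v <- list()
  add <- function(entity, rule, message) {
    v[[length(v) + 1L]] <<- violation_frame(entity, rule, message)
  }
  for (i in seq_len(nrow(sur))) {
    s <- sur[i, ]
    if (!is.finite(s$duration_min) || s$duration_min <= 0) {
      add(s$id, "duration_positive",
          sprintf("surgery %s has non-positive duration %s", s$id, s$duration_min))
    }
    if (!is.finite(s$turnover_min) || s$turnover_min < 0) {
      add(s$id, "turnover_nonnegative",
          sprintf("surgery %s has negative turnover %s", s$id, s$turnover_min))
    }
    if (s$deadline_day < s$entry_day) {
      add(s$id, "deadline_after_entry",
          sprintf("surgery %s deadline day %d precedes entry day %d",
                  s$id, s$deadline_day, s$entry_day))
    }
    if (!as.character(s$priority) %in% names(instance$priority_weights)) {
      add(s$id, "priority_known",
          sprintf("surgery %s priority %s has no configured weight",
                  s$id, s$priority))
    }
    if (!s$specialty %in% names(instance$specialty_rooms)) {
      add(s$id, "specialty_known",
          sprintf("surgery %s specialty '%s' is not in specialty_rooms",
                  s$id, s$specialty))
    }
  }
  dup <- sur$id[duplicated(sur$id)]
  for (d in unique(dup)) {
    add(d, "surgery_id_unique",
        sprintf("surgery id %s appears more than once", d))
  }
  for (i in seq_len(nrow(slo))) {
    k <- slo[i, ]
    if (!is.finite(k$length_min) || k$length_min <= 0) {
      add(k$id, "slot_length_positive",
          sprintf("slot %s has non-positive length %s", k$id, k$length_min))
    }
    if (k$day < 0 || k$day >= instance$horizon_days) {
      add(k$id, "slot_day_in_horizon",
          sprintf("slot %s day %d outside [0, %d)", k$id, k$day,
                  instance$horizon_days))
    }
    if (!is.na(k$max_surgeries) && k$max_surgeries < 1) {
      add(k$id, "max_surgeries_at_least_one",
          sprintf("slot %s max_surgeries %s < 1", k$id, k$max_surgeries))
    }
    if (!k$room %in% instance$rooms) {
      add(k$id, "room_known",
          sprintf("slot %s room '%s' not in the instance room set", k$id, k$room))
    }
  }
  dup <- slo$id[duplicated(slo$id)]
  for (d in unique(dup)) {
    add(d, "slot_id_unique", sprintf("slot id %s appears more than once", d))
  }
  if (length(v)) do.call(rbind, v) else violation_frame()
}
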