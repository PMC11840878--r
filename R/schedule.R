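#' Construct a schedule
#'
#' A schedule assigns each surgery of an instance either to one slot, with a
#' 0-based position in that slot's running order, or to the "unscheduled"
#' state (slot NA). The solvers optimize only the day a surgery lands on;
#' positions record the within-slot sequence but carry no cost.
#'
#' @param assignments data.frame with columns \code{surgery_id},
#'   \code{slot_id} (NA = unscheduled) and optionally \code{position};
#'   missing positions are filled 0,1,2,... in row order per slot.
#' @return object of class \code{ssp_schedule} (a data.frame).
#' @export
ssp_schedule <- function(assignments) {
  a <- as.data.frame(assignments, stringsAsFactors = FALSE)
  stopifnot(all(c("surgery_id", "slot_id") %in% names(a)))
  a$surgery_id <- as.character(a$surgery_id)
  a$slot_id <- as.character(a$slot_id)
  if (!"position" %in% names(a)) a$position <- NA_integer_
  a$position <- as.integer(a$position)
  need <- !is.na(a$slot_id) & is.na(a$position)
  if (any(need)) {
    for (k in unique(a$slot_id[need])) {
      idx <- which(!is.na(a$slot_id) & a$slot_id == k)
      a$position[idx] <- seq_along(idx) - 1L
    }
  }
  a$position[is.na(a$slot_id)] <- NA_integer_
  a <- a[, c("surgery_id", "slot_id", "position")]
  class(a) <- c("ssp_schedule", "data.frame")
  a
}

#' All-unscheduled schedule for an instance
#' @param instance an [ssp_instance()].
#' @return an empty \code{ssp_schedule} covering every surgery.
#' @export
empty_schedule <- function(instance) {
  ssp_schedule(data.frame(surgery_id = instance$surgeries$id,
                          slot_id = NA_character_,
                          position = NA_integer_,
                          stringsAsFactors = FALSE))
}

#' Day on which each surgery is scheduled
#'
#' @param schedule an [ssp_schedule()].
#' @param instance the instance the schedule refers to.
#' @return named integer vector over the instance's surgeries; NA for
#'   unscheduled surgeries.
#' @export
scheduled_days <- function(schedule, instance) {
  slot_day <- instance$slots$day[match(schedule$slot_id, instance$slots$id)]
  out <- rep(NA_integer_, nrow(instance$surgeries))
  names(out) <- instance$surgeries$id
  out[schedule$surgery_id] <- as.integer(slot_day)
  out
}

#' @export
print.ssp_schedule <- function(x, ...) {
  n <- nrow(x)
  ns <- sum(!is.na(x$slot_id))
  cat(sprintf("ssp_schedule: %d/%d surgeries scheduled (%d unscheduled)\n",
              ns, n, n - ns))
  invisible(x)
}

#' Hard-constraint check of a schedule
#'
#' Lists every violation of the hard constraints: per-slot capacity in
#' minutes (each surgery charges duration + turnover), the optional per-slot
#' cap on the number of surgeries, the slot/surgery specialty match, duplicate
#' surgery assignments, and non-contiguous within-slot positions. An empty
#' report means the schedule is feasible; leaving surgeries unscheduled is
#' always feasible.
#'
#' @param schedule an [ssp_schedule()].
#' @param instance an [ssp_instance()]; the schedule may reference only ids
#'   present in it (unknown ids are an error, not a violation).
#' @return data.frame with columns \code{entity}, \code{rule},
#'   \code{message}; zero rows iff feasible.
#' @export
check_feasibility <- function(schedule, instance) {
  stopifnot(inherits(instance, "ssp_instance"))
  sur <- instance$surgeries
  slo <- instance$slots
  unknown <- setdiff(schedule$surgery_id, sur$id)
  if (length(unknown)) stopf("schedule references unknown surgery id(s): %s",
                             paste(unknown, collapse = ", "))
  unknown <- setdiff(schedule$slot_id[!is.na(schedule$slot_id)], slo$id)
  if (length(unknown)) stopf("schedule references unknown slot id(s): %s",
                             paste(unknown, collapse = ", "))
  v <- list()
  add <- function(entity, rule, message) {
    v[[length(v) + 1L]] <<- violation_frame(entity, rule, message)
  }
  dup <- schedule$surgery_id[duplicated(schedule$surgery_id)]
  for (d in unique(dup)) {
    add(d, "surgery_assigned_once",
        sprintf("surgery %s appears more than once in the schedule", d))
  }
  placed <- schedule[!is.na(schedule$slot_id), , drop = FALSE]
  if (nrow(placed)) {
    si <- match(placed$surgery_id, sur$id)
    ki <- match(placed$slot_id, slo$id)
    mism <- which(sur$specialty[si] != slo$specialty[ki])
    for (i in mism) {
      add(placed$surgery_id[i], "specialty_match",
          sprintf("surgery %s (%s) assigned to slot %s reserved for %s",
                  placed$surgery_id[i], sur$specialty[si[i]],
                  placed$slot_id[i], slo$specialty[ki[i]]))
    }
    load <- tapply(sur$duration_min[si] + sur$turnover_min[si],
                   placed$slot_id, sum)
    cnt <- tapply(rep(1L, nrow(placed)), placed$slot_id, sum)
    for (k in names(load)) {
      cap <- slo$length_min[slo$id == k]
      if (load[[k]] > cap) {
        add(k, "slot_capacity",
            sprintf("slot %s overloaded by %g min (%g assigned, %g capacity)",
                    k, load[[k]] - cap, load[[k]], cap))
      }
      maxn <- slo$max_surgeries[slo$id == k]
      if (!is.na(maxn) && cnt[[k]] > maxn) {
        add(k, "slot_count",
            sprintf("slot %s holds %d surgeries, cap is %g", k, cnt[[k]], maxn))
      }
      pos <- sort(placed$position[placed$slot_id == k])
      if (!identical(as.integer(pos), seq_along(pos) - 1L)) {
        add(k, "positions_contiguous",
            sprintf("slot %s positions are not a contiguous 0-based sequence", k))
      }
    }
  }
  if (length(v)) do.call(rbind, v) else violation_frame()
}
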