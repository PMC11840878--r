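#' Order the waiting list by priority and waiting-list longevity
#'
#' Produces the scheduling order the first-fit constructor consumes: a
#' stable sort by priority (descending -- higher levels are more urgent),
#' then waiting-list entry day (ascending -- longest waiters first), then
#' surgery id (ascending) as the final deterministic tie-break.
#'
#' @param instance an [ssp_instance()].
#' @return object of class \code{ssp_waiting_order}: a data.frame with
#'   columns \code{surgery_id}, \code{priority}, \code{entry_day} in
#'   scheduling order.
#' @export
order_waiting_list <- function(instance) {
  sur <- instance$surgeries
  o <- order(-sur$priority, sur$entry_day, sur$id)
  out <- data.frame(surgery_id = sur$id[o],
                    priority = sur$priority[o],
                    entry_day = sur$entry_day[o],
                    stringsAsFactors = FALSE)
  class(out) <- c("ssp_waiting_order", "data.frame")
  out
}

# Day-major slot ordering: day, then room, then id. All scanning and
# encoding in the package uses this single ordering.
slot_order <- function(slots) order(slots$day, slots$room, slots$id)

#' First-fit construction of an initial schedule
#'
#' Takes surgeries in waiting-list order and places each into the first slot
#' that (a) is reserved for the surgery's specialty and (b) still has room
#' for its duration plus turnover, both in minutes and in the optional
#' surgery-count cap. In \code{sequential} mode slots are scanned day-major
#' (day, then room, then id), so each surgery lands on the earliest day that
#' can take it; in \code{random} mode the scan order is a freshly seeded
#' shuffle re-drawn for every surgery. Surgeries that fit no slot -- for
#' instance because their duration exceeds every shift length -- are left
#' unscheduled; that is a recorded outcome, not an error.
#'
#' @param instance an [ssp_instance()].
#' @param order an [order_waiting_list()] result (or any permutation of the
#'   surgery ids as a character vector).
#' @param mode \code{"sequential"} (default, deterministic) or
#'   \code{"random"}.
#' @param seed integer seed used in random mode.
#' @return a feasible [ssp_schedule()].
#' @export
first_fit_assign <- function(instance, order = order_waiting_list(instance),
                             mode = c("sequential", "random"), seed = 1L) {
  mode <- match.arg(mode)
  ids <- if (is.data.frame(order)) order$surgery_id else as.character(order)
  sur <- instance$surgeries
  if (!setequal(ids, sur$id) || length(ids) != nrow(sur)) {
    stopf("order must be a permutation of the instance's surgery ids")
  }
  slo <- instance$slots[slot_order(instance$slots), , drop = FALSE]
  K <- nrow(slo)
  remaining <- slo$length_min
  remaining_n <- ifelse(is.na(slo$max_surgeries), Inf, slo$max_surgeries)
  si <- match(ids, sur$id)
  dur <- sur$duration_min[si] + sur$turnover_min[si]
  spec <- sur$specialty[si]
  assign_slot <- rep(NA_character_, length(ids))
  assign_pos <- rep(NA_integer_, length(ids))
  filled <- integer(K)

  place <- function() {
    for (i in seq_along(ids)) {
      scan <- if (mode == "sequential") seq_len(K) else sample.int(K)
      for (k in scan) {
        if (slo$specialty[k] == spec[i] &&
            remaining[k] >= dur[i] && remaining_n[k] >= 1) {
          remaining[k] <<- remaining[k] - dur[i]
          remaining_n[k] <<- remaining_n[k] - 1
          assign_slot[i] <<- slo$id[k]
          assign_pos[i] <<- filled[k]
          filled[k] <<- filled[k] + 1L
          break
        }
      }
    }
  }
  if (mode == "random") with_seed(seed, place()) else place()

  ssp_schedule(data.frame(surgery_id = ids, slot_id = assign_slot,
                          position = assign_pos, stringsAsFactors = FALSE))
}
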