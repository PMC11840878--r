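# Independent oracles: deliberately naive re-implementations used to
# cross-check the package. They share no code with the package internals.

# Sum-over-loop penalty: days overdue times priority weight, zero for
# on-time and unscheduled surgeries; plus a per-unscheduled charge for the
# solver objective.
oracle_objective <- function(schedule, instance, unscheduled_cost = 0) {
  total <- 0
  for (i in seq_len(nrow(instance$surgeries))) {
    s <- instance$surgeries[i, ]
    row <- schedule[schedule$surgery_id == s$id, ]
    if (nrow(row) == 0 || is.na(row$slot_id[1])) {
      total <- total + unscheduled_cost
    } else {
      day <- instance$slots$day[instance$slots$id == row$slot_id[1]]
      over <- day - s$deadline_day
      if (over > 0) {
        total <- total + over * instance$priority_weights[[as.character(s$priority)]]
      }
    }
  }
  total
}

# Brute-force constraint check of an assignment vector (slot id per surgery,
# NA = unscheduled), independent of check_feasibility().
oracle_is_feasible <- function(slot_assign, instance) {
  sur <- instance$surgeries
  slo <- instance$slots
  for (k in unique(stats::na.omit(slot_assign))) {
    idx <- which(!is.na(slot_assign) & slot_assign == k)
    srow <- slo[slo$id == k, ]
    if (sum(sur$duration_min[idx] + sur$turnover_min[idx]) > srow$length_min) {
      return(FALSE)
    }
    if (!is.na(srow$max_surgeries) && length(idx) > srow$max_surgeries) {
      return(FALSE)
    }
    if (any(sur$specialty[idx] != srow$specialty)) return(FALSE)
  }
  TRUE
}

# Exhaustive enumeration of all feasible assignments (each surgery goes to
# one slot or stays unscheduled); returns the minimum objective. Only viable
# for a handful of surgeries and slots.
oracle_optimum <- function(instance, unscheduled_cost) {
  sur <- instance$surgeries
  slo <- instance$slots
  n <- nrow(sur)
  options <- c(slo$id, NA_character_)
  best <- Inf
  idx <- rep(1L, n)
  m <- length(options)
  repeat {
    assign <- options[idx]
    if (oracle_is_feasible(assign, instance)) {
      sched <- ssp_schedule(data.frame(surgery_id = sur$id, slot_id = assign,
                                       stringsAsFactors = FALSE))
      obj <- oracle_objective(sched, instance, unscheduled_cost)
      if (obj < best) best <- obj
    }
    j <- n
    while (j >= 1L && idx[j] == m) {
      idx[j] <- 1L
      j <- j - 1L
    }
    if (j == 0L) break
    idx[j] <- idx[j] + 1L
  }
  best
}

# Reference first-fit: surgeries in the given order, slots scanned by
# ascending day then room then id.
oracle_first_fit <- function(instance, order_ids) {
  slo <- instance$slots
  slo <- slo[order(slo$day, slo$room, slo$id), ]
  remaining <- slo$length_min
  remaining_n <- ifelse(is.na(slo$max_surgeries), Inf, slo$max_surgeries)
  out <- data.frame(surgery_id = order_ids, slot_id = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(order_ids)) {
    s <- instance$surgeries[instance$surgeries$id == order_ids[i], ]
    need <- s$duration_min + s$turnover_min
    for (k in seq_len(nrow(slo))) {
      if (slo$specialty[k] == s$specialty && remaining[k] >= need &&
          remaining_n[k] >= 1) {
        out$slot_id[i] <- slo$id[k]
        remaining[k] <- remaining[k] - need
        remaining_n[k] <- remaining_n[k] - 1
        break
      }
    }
  }
  out
}

# Three-key reference sort for the waiting list.
oracle_waiting_order <- function(instance) {
  sur <- instance$surgeries
  key <- data.frame(p = -sur$priority, e = sur$entry_day, id = sur$id)
  sur$id[do.call(order, key)]
}
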