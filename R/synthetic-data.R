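#' Specification for the synthetic instance generator
#'
#' Describes the statistical shape of a generated hospital workload. The
#' defaults emulate an overloaded three-specialty surgical centre at the
#' scale of the motivating case study: 198 obesity surgeries competing for
#' 122 slots, 133 urology surgeries for 89 slots, and 98 pediatric plastic
#' surgeries for 45 slots -- total demand (429) well above total capacity
#' (256 slots), so some surgeries necessarily stay unscheduled or run past
#' their deadlines.
#'
#' Surgery durations are drawn from a log-normal (configurable median and
#' log-scale dispersion) truncated to \code{duration_range} minutes by
#' resampling. Deadlines derive from priority via guaranteed-maximum-
#' response-time windows (defaults: level 4 urgent = 14 days down to level 1
#' routine = 270 days); entry days place patients on the list before the
#' planning horizon starts, so part of the backlog is already near or past
#' its deadline -- the regime in which scheduling order matters.
#'
#' @param specialties character vector of specialty names.
#' @param n_surgeries,n_slots integer vectors parallel to
#'   \code{specialties}.
#' @param horizon_days planning horizon H; each specialty receives
#'   \code{ceiling(n_slots / horizon_days)} dedicated rooms, filled
#'   day-major.
#' @param slot_length_min shift capacity in minutes.
#' @param slot_start_min shift start, minutes from midnight.
#' @param max_surgeries optional per-slot cap on surgeries (NA = unbounded).
#' @param duration_median,duration_sdlog median (minutes) and log-sd of the
#'   log-normal surgery-duration distribution.
#' @param duration_range truncation interval in minutes.
#' @param turnover_min constant room-turnover minutes charged per surgery.
#' @param priority_levels,priority_probs ordinal priority levels (higher =
#'   more urgent) and their sampling probabilities.
#' @param priority_weights named penalty weight per level.
#' @param response_windows named vector: days allowed between entry and
#'   deadline per priority level.
#' @param entry_day_range integer range (usually negative: before the
#'   horizon) from which waiting-list entry days are drawn uniformly.
#' @param deadline_slack integer range of extra days added to the planted
#'   day when building planted-feasible instances.
#' @return object of class \code{ssp_generator_spec}.
#' @export
generator_spec <- function(specialties = c("obesity", "urology",
                                           "pediatric_plastic"),
                           n_surgeries = c(198L, 133L, 98L),
                           n_slots = c(122L, 89L, 45L),
                           horizon_days = 130L,
                           slot_length_min = 480,
                           slot_start_min = 480,
                           max_surgeries = NA_real_,
                           duration_median = 120,
                           duration_sdlog = 0.45,
                           duration_range = c(30, 480),
                           turnover_min = 15,
                           priority_levels = 1:4,
                           priority_probs = c(0.35, 0.35, 0.2, 0.1),
                           priority_weights = c("1" = 1, "2" = 2,
                                                "3" = 4, "4" = 8),
                           response_windows = c("1" = 270, "2" = 180,
                                                "3" = 60, "4" = 14),
                           entry_day_range = c(-180L, -1L),
                           deadline_slack = c(0L, 14L)) {
  if (length(n_surgeries) != length(specialties) ||
      length(n_slots) != length(specialties)) {
    stopf("n_surgeries and n_slots must be parallel to specialties")
  }
  if (any(n_surgeries < 0) || any(n_slots < 0)) {
    stopf("surgery and slot counts must be >= 0")
  }
  if (horizon_days < 1) stopf("horizon_days must be >= 1")
  if (duration_sdlog <= 0 || duration_median <= 0) {
    stopf("duration distribution parameters must be positive")
  }
  if (duration_range[1] <= 0 || duration_range[2] < duration_range[1]) {
    stopf("invalid duration_range")
  }
  if (abs(sum(priority_probs) - 1) > 1e-8 || any(priority_probs < 0)) {
    stopf("priority_probs must be a probability vector")
  }
  if (!all(as.character(priority_levels) %in% names(priority_weights)) ||
      !all(as.character(priority_levels) %in% names(response_windows))) {
    stopf("priority_weights and response_windows must cover every level")
  }
  structure(
    list(specialties = specialties, n_surgeries = as.integer(n_surgeries),
         n_slots = as.integer(n_slots),
         horizon_days = as.integer(horizon_days),
         slot_length_min = slot_length_min, slot_start_min = slot_start_min,
         max_surgeries = max_surgeries,
         duration_median = duration_median, duration_sdlog = duration_sdlog,
         duration_range = duration_range, turnover_min = turnover_min,
         priority_levels = priority_levels, priority_probs = priority_probs,
         priority_weights = priority_weights,
         response_windows = response_windows,
         entry_day_range = as.integer(entry_day_range),
         deadline_slack = as.integer(deadline_slack)),
    class = "ssp_generator_spec"
  )
}

# Truncated log-normal durations by resampling.
draw_durations <- function(n, spec) {
  if (n == 0) return(numeric(0))
  lo <- spec$duration_range[1]
  hi <- spec$duration_range[2]
  out <- numeric(0)
  while (length(out) < n) {
    d <- stats::rlnorm(2L * (n - length(out)) + 8L,
                       meanlog = log(spec$duration_median),
                       sdlog = spec$duration_sdlog)
    out <- c(out, d[d >= lo & d <= hi])
  }
  round(out[seq_len(n)])
}

# Day-major slot table: each specialty owns ceiling(n_slots/H) rooms and its
# slots fill the (day, room) grid day by day.
build_slots <- function(spec) {
  rows <- list()
  for (j in seq_along(spec$specialties)) {
    ns <- spec$n_slots[j]
    if (ns == 0) next
    s <- spec$specialties[j]
    n_rooms <- ceiling(ns / spec$horizon_days)
    day <- (seq_len(ns) - 1L) %/% n_rooms
    room <- (seq_len(ns) - 1L) %% n_rooms + 1L
    rows[[j]] <- data.frame(
      id = sprintf("slot_%s_%03d", substr(s, 1, 3), seq_len(ns)),
      day = as.integer(day),
      room = sprintf("OR_%s_%d", substr(s, 1, 3), room),
      specialty = s,
      start_min = spec$slot_start_min,
      length_min = spec$slot_length_min,
      max_surgeries = spec$max_surgeries,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(id = character(), day = integer(), room = character(),
                      specialty = character(), start_min = numeric(),
                      length_min = numeric(), max_surgeries = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Generate a synthetic scheduling instance
#'
#' Draws a reproducible waiting list and slot table from a
#' [generator_spec()]. With the default spec the per-specialty surgery and
#' slot counts are exactly 198/122, 133/89 and 98/45, so total demand
#' exceeds capacity and the instance behaves like a real overloaded
#' scheduling period.
#'
#' @param spec a [generator_spec()].
#' @param seed integer seed; the instance is a pure function of
#'   (spec, seed).
#' @return an [ssp_instance()] that passes [validate_instance()].
#' @export
generate_instance <- function(spec = generator_spec(), seed = 1L) {
  stopifnot(inherits(spec, "ssp_generator_spec"))
  with_seed(seed, {
    rows <- list()
    for (j in seq_along(spec$specialties)) {
      n <- spec$n_surgeries[j]
      if (n == 0) next
      s <- spec$specialties[j]
      pr <- sample(spec$priority_levels, n, replace = TRUE,
                   prob = spec$priority_probs)
      entry <- sample(seq(spec$entry_day_range[1], spec$entry_day_range[2]),
                      n, replace = TRUE)
      window <- spec$response_windows[as.character(pr)]
      rows[[j]] <- data.frame(
        id = sprintf("%s_%03d", substr(s, 1, 3), seq_len(n)),
        specialty = s,
        duration_min = draw_durations(n, spec),
        turnover_min = spec$turnover_min,
        entry_day = as.integer(entry),
        deadline_day = as.integer(entry + unname(window)),
        priority = as.integer(pr),
        stringsAsFactors = FALSE)
    }
    surgeries <- if (length(rows)) do.call(rbind, rows) else
      data.frame(id = character(), specialty = character(),
                 duration_min = numeric(), turnover_min = numeric(),
                 entry_day = integer(), deadline_day = integer(),
                 priority = integer(), stringsAsFactors = FALSE)
    ssp_instance(surgeries, build_slots(spec), spec$horizon_days,
                 priority_weights = spec$priority_weights)
  })
}

#' Generate a planted-feasible instance with a known zero-penalty optimum
#'
#' Builds the slot table first, then packs surgeries into it day-major while
#' drawing their durations, so by construction every surgery fits. Each
#' surgery's deadline is its planted day plus a slack drawn from
#' \code{spec$deadline_slack}, hence the planted schedule has total penalty
#' 0 and -- penalties being non-negative -- the instance's optimal penalty
#' score is exactly 0 with every surgery scheduled. The returned surgery
#' table is shuffled so the plant is not recoverable from row order.
#'
#' @param spec a [generator_spec()]; the total surgery count must fit the
#'   total slot capacity (generation retries the draw a few times, then
#'   fails).
#' @param seed integer seed.
#' @param max_retries attempts to pack a drawn surgery before giving up.
#' @return list with elements \code{instance} (an [ssp_instance()]) and
#'   \code{schedule} (the planted zero-penalty [ssp_schedule()]).
#' @export
generate_planted_instance <- function(spec = generator_spec(), seed = 1L,
                                      max_retries = 50L) {
  stopifnot(inherits(spec, "ssp_generator_spec"))
  slots <- build_slots(spec)
  with_seed(seed, {
    rows <- list()
    planted <- list()
    for (j in seq_along(spec$specialties)) {
      n <- spec$n_surgeries[j]
      if (n == 0) next
      s <- spec$specialties[j]
      sl <- slots[slots$specialty == s, , drop = FALSE]
      sl <- sl[order(sl$day, sl$room, sl$id), , drop = FALSE]
      remaining <- sl$length_min
      remaining_n <- ifelse(is.na(sl$max_surgeries), Inf, sl$max_surgeries)
      slot_id <- character(n)
      planted_day <- integer(n)
      dur <- numeric(n)
      for (i in seq_len(n)) {
        ok <- FALSE
        for (r in seq_len(max_retries)) {
          d <- draw_durations(1L, spec) + spec$turnover_min
          k <- which(remaining >= d & remaining_n >= 1)[1]
          if (!is.na(k)) {
            remaining[k] <- remaining[k] - d
            remaining_n[k] <- remaining_n[k] - 1
            slot_id[i] <- sl$id[k]
            planted_day[i] <- sl$day[k]
            dur[i] <- d - spec$turnover_min
            ok <- TRUE
            break
          }
        }
        if (!ok) {
          stopf("could not pack surgery %d of specialty %s into the slots; %s",
                i, s, "reduce n_surgeries or enlarge the slots")
        }
      }
      pr <- sample(spec$priority_levels, n, replace = TRUE,
                   prob = spec$priority_probs)
      slack <- sample(seq(spec$deadline_slack[1], spec$deadline_slack[2]),
                      n, replace = TRUE)
      deadline <- planted_day + slack
      window <- unname(spec$response_windows[as.character(pr)])
      rows[[j]] <- data.frame(
        id = sprintf("%s_%03d", substr(s, 1, 3), seq_len(n)),
        specialty = s, duration_min = dur, turnover_min = spec$turnover_min,
        entry_day = as.integer(deadline - window),
        deadline_day = as.integer(deadline),
        priority = as.integer(pr), stringsAsFactors = FALSE)
      planted[[j]] <- data.frame(surgery_id = rows[[j]]$id, slot_id = slot_id,
                                 stringsAsFactors = FALSE)
    }
    surgeries <- do.call(rbind, rows)
    planted <- do.call(rbind, planted)
    perm <- sample.int(nrow(surgeries))
    surgeries <- surgeries[perm, , drop = FALSE]
    rownames(surgeries) <- NULL
    instance <- ssp_instance(surgeries, slots, spec$horizon_days,
                             priority_weights = spec$priority_weights)
    sched <- ssp_schedule(planted[match(surgeries$id, planted$surgery_id), ,
                                  drop = FALSE])
    list(instance = instance, schedule = sched)
  })
}

#' Emulate a manual-scheduling baseline
#'
#' Produces the kind of schedule a comparison report needs as its "manual
#' management" row: first-fit under a deliberately suboptimal ordering
#' (waiting-list entry day only, ignoring priority), after which a
#' \code{disruption} fraction of the scheduled surgeries is displaced to a
#' random later slot that still has room. The output is always feasible and
#' on an overloaded instance typically carries a positive penalty score.
#'
#' @param instance an [ssp_instance()].
#' @param disruption fraction in [0, 1] of scheduled surgeries to displace.
#' @param seed integer seed.
#' @return a feasible [ssp_schedule()].
#' @export
generate_manual_baseline <- function(instance, disruption = 0.3, seed = 1L) {
  stopifnot(disruption >= 0, disruption <= 1)
  sur <- instance$surgeries
  ord <- sur$id[order(sur$entry_day, sur$id)]
  sched <- first_fit_assign(instance, order = ord, mode = "sequential")
  if (disruption == 0) return(sched)
  with_seed(seed + 104729L, {
    st <- build_state(instance, sched, unscheduled_cost = 0)
    scheduled <- which(!is.na(st$slot_of))
    n_move <- round(disruption * length(scheduled))
    if (n_move > 0) {
      for (i in sample(scheduled, n_move)) {
        a <- st$slot_of[i]
        later <- st$cands[[st$spec_s[i]]]
        later <- later[st$day[later] > st$day[a] &
                         st$load[later] + st$dur[i] <= st$cap[later] &
                         st$cnt[later] + 1 <= st$maxn[later]]
        if (length(later)) {
          k <- later[sample.int(length(later), 1L)]
          apply_move(st, list(type = "relocate", i = i, k = k, a = a,
                              delta = p_at(st, i, k) - st$p[i]))
        }
      }
    }
    state_schedule(st)
  })
}
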