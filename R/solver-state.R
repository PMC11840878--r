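# Internal mutable solver state.
#
# The solvers run tens of thousands of candidate evaluations, so the
# schedule is held as flat vectors in an environment: slot assignment per
# surgery, load and count per slot, and the per-surgery penalty. All moves
# are O(1) to test and apply; the ssp_schedule data.frame is only
# materialized at the end of a run. Slots are indexed day-major so index
# order equals scan order everywhere (first-fit, PSO encoding, repair).

build_state <- function(instance, schedule, unscheduled_cost) {
  sur <- instance$surgeries
  slo <- instance$slots[slot_order(instance$slots), , drop = FALSE]
  specs <- sort(unique(c(sur$specialty, slo$specialty)))
  st <- new.env(parent = emptyenv())
  st$N <- nrow(sur)
  st$K <- nrow(slo)
  st$sur_ids <- sur$id
  st$slot_ids <- slo$id
  st$dur <- sur$duration_min + sur$turnover_min
  st$deadline <- sur$deadline_day
  w <- instance$priority_weights[as.character(sur$priority)]
  if (anyNA(w)) stopf("no weight configured for some priority levels")
  st$w <- unname(w)
  st$spec_s <- match(sur$specialty, specs)
  st$spec_k <- match(slo$specialty, specs)
  st$day <- slo$day
  st$cap <- slo$length_min
  st$maxn <- ifelse(is.na(slo$max_surgeries), Inf, slo$max_surgeries)
  st$cands <- lapply(seq_along(specs), function(s) which(st$spec_k == s))
  # slots sharing a day and a specialty, for PSO same-day repair
  st$same_day_spec <- lapply(seq_len(st$K), function(k) {
    which(st$day == st$day[k] & st$spec_k == st$spec_k[k])
  })
  st$U <- unscheduled_cost

  st$slot_of <- rep(NA_integer_, st$N)
  if (!is.null(schedule)) {
    idx <- match(schedule$surgery_id, sur$id)
    st$slot_of[idx] <- match(schedule$slot_id, slo$id)
  }
  st$load <- numeric(st$K)
  st$cnt <- integer(st$K)
  for (i in which(!is.na(st$slot_of))) {
    k <- st$slot_of[i]
    st$load[k] <- st$load[k] + st$dur[i]
    st$cnt[k] <- st$cnt[k] + 1L
  }
  st$members <- lapply(seq_len(st$K), function(k) which(st$slot_of == k))
  st$p <- state_penalties(st, st$slot_of)
  st$obj <- sum(st$p) + st$U * sum(is.na(st$slot_of))
  st
}

state_penalties <- function(st, slot_of) {
  d <- st$day[slot_of]
  p <- pmax(0, d - st$deadline) * st$w
  p[is.na(slot_of)] <- 0
  p
}

p_at <- function(st, i, k) max(0, st$day[k] - st$deadline[i]) * st$w[i]

state_objective <- function(st, slot_of) {
  sum(state_penalties(st, slot_of)) + st$U * sum(is.na(slot_of))
}

state_schedule <- function(st, slot_of = st$slot_of) {
  ord <- order(slot_of, seq_along(slot_of), na.last = TRUE)
  slot_chr <- st$slot_ids[slot_of]
  ssp_schedule(data.frame(surgery_id = st$sur_ids[ord],
                          slot_id = slot_chr[ord],
                          position = NA_integer_,
                          stringsAsFactors = FALSE))
}

# Propose one feasible move: with equal probability a swap of two surgeries
# between different slots, or a relocation of one surgery (scheduled or
# unscheduled) into a different slot with room for it. The swap generalizes
# to an ejection (the displaced surgery lands in a third slot) or, for an
# unscheduled mover, a count-neutral exchange with a slot occupant. Returns
# NULL when no feasible candidate is found within `retries` draws. Moves
# never reduce the number of scheduled surgeries. Uses the current RNG
# stream.
#
# Proposals are guided: half the time the moved surgery is drawn among
# those currently paying a penalty (or unscheduled), and relocation targets
# of a penalized surgery are biased toward slots earlier than its current
# day. Guidance reshapes the proposal distribution only -- the neighbourhood
# (one swap or one relocation) and the acceptance rules are untouched.
propose_move <- function(st, retries = 25L) {
  if (st$N == 0L) return(NULL)
  pick_surgery <- function(pool_biased) {
    if (length(pool_biased) && stats::runif(1) < 0.5) {
      pool_biased[sample.int(length(pool_biased), 1L)]
    } else {
      sample.int(st$N, 1L)
    }
  }
  for (r in seq_len(retries)) {
    if (stats::runif(1) < 0.5) {
      i <- pick_surgery(which(st$p > 0 | is.na(st$slot_of)))
      a <- st$slot_of[i]
      cand <- st$cands[[st$spec_s[i]]]
      if (!is.na(a)) {
        if (st$p[i] > 0 && stats::runif(1) < 0.75) {
          cand <- cand[st$day[cand] < st$day[a]]
        }
        cand <- cand[cand != a]
      }
      if (!length(cand)) next
      b <- cand[sample.int(length(cand), 1L)]
      mem <- st$members[[b]]
      if (!length(mem)) next
      j <- mem[sample.int(length(mem), 1L)]
      if (st$load[b] - st$dur[j] + st$dur[i] > st$cap[b]) next
      p_i_new <- p_at(st, i, b) - if (is.na(a)) st$U else st$p[i]
      # direct exchange: j takes i's old slot
      if (!is.na(a) && st$load[a] - st$dur[i] + st$dur[j] <= st$cap[a]) {
        delta <- p_i_new + p_at(st, j, a) - st$p[j]
        return(list(type = "swap", i = i, j = j, a = a, b = b, delta = delta))
      }
      # ejection: j is displaced into any third slot with room for it
      pool <- st$cands[[st$spec_s[j]]]
      room <- st$load[pool] + st$dur[j] <= st$cap[pool] &
        st$cnt[pool] + 1L <= st$maxn[pool]
      if (!is.na(a)) {
        room[pool == a] <- st$load[a] - st$dur[i] + st$dur[j] <= st$cap[a]
      }
      pool <- pool[room & pool != b]
      if (!length(pool)) {
        if (is.na(a)) {
          # count-neutral exchange: unscheduled i takes j's place, j joins
          # the unscheduled pool (the per-unscheduled charges cancel)
          return(list(type = "swapout", i = i, j = j, b = b,
                      delta = p_at(st, i, b) - st$p[j]))
        }
        next
      }
      cc <- pool[sample.int(length(pool), 1L)]
      delta <- p_i_new + p_at(st, j, cc) - st$p[j]
      return(list(type = "eject", i = i, j = j, a = a, b = b, cc = cc,
                  delta = delta))
    } else {
      lagging <- which(st$p > 0 | is.na(st$slot_of))
      if (length(lagging) && stats::runif(1) < 0.5) {
        # drain variant: free capacity in a slot that a lagging surgery
        # would need, by relocating one of its current occupants elsewhere
        # (without worsening that occupant) -- still a single relocation.
        i0 <- lagging[sample.int(length(lagging), 1L)]
        a0 <- st$slot_of[i0]
        cand0 <- st$cands[[st$spec_s[i0]]]
        if (!is.na(a0)) cand0 <- cand0[st$day[cand0] < st$day[a0]]
        if (!length(cand0)) next
        b <- cand0[sample.int(length(cand0), 1L)]
        mem <- st$members[[b]]
        if (!length(mem)) next
        i <- mem[sample.int(length(mem), 1L)]
        pool <- st$cands[[st$spec_s[i]]]
        room <- st$load[pool] + st$dur[i] <= st$cap[pool] &
          st$cnt[pool] + 1L <= st$maxn[pool] & pool != b
        pool <- pool[room]
        pool <- pool[pmax(0, st$day[pool] - st$deadline[i]) * st$w[i] <= st$p[i]]
        if (!length(pool)) next
        k <- pool[sample.int(length(pool), 1L)]
        return(list(type = "relocate", i = i, k = k, a = b,
                    delta = p_at(st, i, k) - st$p[i]))
      }
      i <- pick_surgery(lagging)
      cand <- st$cands[[st$spec_s[i]]]
      if (!length(cand)) next
      a <- st$slot_of[i]
      open <- cand[st$load[cand] + st$dur[i] <= st$cap[cand] &
                     st$cnt[cand] + 1L <= st$maxn[cand]]
      if (!is.na(a)) {
        open <- open[open != a]
        if (st$p[i] > 0) {
          earlier <- open[st$day[open] < st$day[a]]
          if (length(earlier)) open <- earlier
        }
      }
      if (!length(open)) next
      k <- open[sample.int(length(open), 1L)]
      delta <- if (is.na(a)) p_at(st, i, k) - st$U else p_at(st, i, k) - st$p[i]
      return(list(type = "relocate", i = i, k = k, a = a, delta = delta))
    }
  }
  NULL
}

apply_move <- function(st, mv) {
  if (mv$type == "swap") {
    i <- mv$i; j <- mv$j; a <- mv$a; b <- mv$b
    st$load[a] <- st$load[a] - st$dur[i] + st$dur[j]
    st$load[b] <- st$load[b] - st$dur[j] + st$dur[i]
    st$slot_of[i] <- b
    st$slot_of[j] <- a
    st$members[[a]] <- c(st$members[[a]][st$members[[a]] != i], j)
    st$members[[b]] <- c(st$members[[b]][st$members[[b]] != j], i)
    st$p[i] <- p_at(st, i, b)
    st$p[j] <- p_at(st, j, a)
  } else if (mv$type == "swapout") {
    i <- mv$i; j <- mv$j; b <- mv$b
    st$load[b] <- st$load[b] + st$dur[i] - st$dur[j]
    st$members[[b]] <- c(st$members[[b]][st$members[[b]] != j], i)
    st$slot_of[i] <- b
    st$slot_of[j] <- NA_integer_
    st$p[i] <- p_at(st, i, b)
    st$p[j] <- 0
  } else if (mv$type == "eject") {
    i <- mv$i; j <- mv$j; a <- mv$a; b <- mv$b; cc <- mv$cc
    if (!is.na(a)) {
      st$load[a] <- st$load[a] - st$dur[i]
      st$cnt[a] <- st$cnt[a] - 1L
      st$members[[a]] <- st$members[[a]][st$members[[a]] != i]
    }
    st$load[b] <- st$load[b] + st$dur[i] - st$dur[j]  # i in, j out: count unchanged
    st$members[[b]] <- c(st$members[[b]][st$members[[b]] != j], i)
    st$load[cc] <- st$load[cc] + st$dur[j]
    st$cnt[cc] <- st$cnt[cc] + 1L
    st$members[[cc]] <- c(st$members[[cc]], j)
    st$slot_of[i] <- b
    st$slot_of[j] <- cc
    st$p[i] <- p_at(st, i, b)
    st$p[j] <- p_at(st, j, cc)
  } else {
    i <- mv$i; k <- mv$k; a <- mv$a
    if (!is.na(a)) {
      st$load[a] <- st$load[a] - st$dur[i]
      st$cnt[a] <- st$cnt[a] - 1L
      st$members[[a]] <- st$members[[a]][st$members[[a]] != i]
    }
    st$load[k] <- st$load[k] + st$dur[i]
    st$cnt[k] <- st$cnt[k] + 1L
    st$members[[k]] <- c(st$members[[k]], i)
    st$slot_of[i] <- k
    st$p[i] <- p_at(st, i, k)
  }
  st$obj <- st$obj + mv$delta
  invisible(st)
}

#' Propose one feasible neighbourhood move
#'
#' The local-search neighbourhood shared by hill climbing and simulated
#' annealing: with equal probability either swap two surgeries between
#' different slots (generalized, when the direct exchange does not fit, to
#' displacing the partner into a third slot or -- for an unscheduled mover
#' -- trading places with a slot occupant), or relocate one surgery
#' (scheduled or unscheduled) into a different slot that still has room for
#' it. Candidates are drawn at random and checked against the hard
#' constraints; after a bounded number of infeasible draws the input
#' schedule is returned unchanged. Moves never reduce the number of
#' scheduled surgeries.
#'
#' @param schedule a feasible [ssp_schedule()].
#' @param instance an [ssp_instance()].
#' @param seed optional integer; when given, the draw is a pure function of
#'   (schedule, instance, seed), otherwise the current RNG stream is used.
#' @param retries maximum number of candidate draws.
#' @return a feasible [ssp_schedule()] differing from the input in at most
#'   two assignments (possibly identical to the input).
#' @export
neighborhood_move <- function(schedule, instance, seed = NULL, retries = 25L) {
  st <- build_state(instance, schedule, unscheduled_cost = 0)
  draw <- function() propose_move(st, retries)
  mv <- if (is.null(seed)) draw() else with_seed(seed, draw())
  if (!is.null(mv)) apply_move(st, mv)
  state_schedule(st)
}

default_unscheduled_cost <- function(instance) {
  instance$horizon_days * max(instance$priority_weights)
}
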