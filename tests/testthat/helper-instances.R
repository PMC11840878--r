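# Hand-built and randomly sampled fixture instances.

# A small two-specialty instance with known structure.
tiny_instance <- function() {
  surgeries <- data.frame(
    id = c("s1", "s2", "s3", "s4", "s5"),
    specialty = c("uro", "uro", "uro", "ped", "ped"),
    duration_min = c(60, 120, 90, 45, 500),
    turnover_min = c(10, 10, 10, 5, 10),
    entry_day = c(-30, -10, 0, -5, -1),
    deadline_day = c(2, 0, 5, 1, 10),
    priority = c(2L, 3L, 1L, 2L, 1L),
    stringsAsFactors = FALSE)
  slots <- data.frame(
    id = c("k1", "k2", "k3"),
    day = c(0L, 1L, 3L),
    room = c("OR1", "OR1", "OR2"),
    specialty = c("uro", "uro", "ped"),
    start_min = 480,
    length_min = c(180, 240, 120),
    max_surgeries = c(NA, 2, NA),
    stringsAsFactors = FALSE)
  ssp_instance(surgeries, slots, horizon_days = 5L)
}

# Random instances small enough for exhaustive enumeration: at most 6
# surgeries and 3 slots, coarse durations, deadlines inside the horizon.
random_tiny_instance <- function(seed) {
  set.seed(seed)
  n_sur <- sample(2:6, 1)
  n_slot <- sample(1:3, 1)
  specs <- if (stats::runif(1) < 0.6) "gen" else c("gen", "uro")
  H <- 5L
  surgeries <- data.frame(
    id = sprintf("s%d", seq_len(n_sur)),
    specialty = sample(specs, n_sur, replace = TRUE),
    duration_min = sample(c(60, 90, 120, 180), n_sur, replace = TRUE),
    turnover_min = 15,
    entry_day = sample(-20:0, n_sur, replace = TRUE),
    deadline_day = sample(0:(H - 1), n_sur, replace = TRUE),
    priority = sample(1:4, n_sur, replace = TRUE),
    stringsAsFactors = FALSE)
  slots <- data.frame(
    id = sprintf("k%d", seq_len(n_slot)),
    day = sort(sample(0:(H - 1), n_slot, replace = TRUE)),
    room = "OR1",
    specialty = sample(specs, n_slot, replace = TRUE),
    start_min = 480,
    length_min = sample(c(240, 480), n_slot, replace = TRUE),
    max_surgeries = ifelse(stats::runif(n_slot) < 0.3, 2, NA),
    stringsAsFactors = FALSE)
  slots$room <- sprintf("OR%d", seq_len(n_slot))
  ssp_instance(surgeries, slots, horizon_days = H)
}

# Random feasible schedule on an instance: greedy placement of a random
# subset in random order.
random_schedule <- function(instance, seed) {
  set.seed(seed)
  ids <- sample(instance$surgeries$id)
  keep <- stats::runif(length(ids)) < 0.8
  slo <- instance$slots
  remaining <- slo$length_min
  remaining_n <- ifelse(is.na(slo$max_surgeries), Inf, slo$max_surgeries)
  assign <- stats::setNames(rep(NA_character_, length(ids)), ids)
  for (id in ids[keep]) {
    s <- instance$surgeries[instance$surgeries$id == id, ]
    need <- s$duration_min + s$turnover_min
    ks <- sample(nrow(slo))
    for (k in ks) {
      if (slo$specialty[k] == s$specialty && remaining[k] >= need &&
          remaining_n[k] >= 1) {
        assign[id] <- slo$id[k]
        remaining[k] <- remaining[k] - need
        remaining_n[k] <- remaining_n[k] - 1
        break
      }
    }
  }
  ssp_schedule(data.frame(surgery_id = names(assign), slot_id = unname(assign),
                          stringsAsFactors = FALSE))
}

# Shared generator settings for planted solver tests: 100 surgeries in 40
# full-day slots over a 40-day horizon.
planted_test_spec <- function() {
  generator_spec(specialties = "general", n_surgeries = 100L, n_slots = 40L,
                 horizon_days = 40L)
}
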