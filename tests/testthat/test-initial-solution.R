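test_that("waiting list orders by priority, then entry day, then id", {
  base <- data.frame(
    id = c("a", "b"), specialty = "uro", duration_min = 60,
    turnover_min = 0, entry_day = c(7L, 3L), deadline_day = 30L,
    priority = 2L, stringsAsFactors = FALSE)
  slots <- data.frame(id = "k1", day = 0L, room = "OR1", specialty = "uro",
                      start_min = 480, length_min = 480,
                      max_surgeries = NA, stringsAsFactors = FALSE)
  inst <- ssp_instance(base, slots, 5L)
  expect_equal(order_waiting_list(inst)$surgery_id, c("b", "a"))

  # equal priority and entry day: lexicographic id order breaks the tie
  base$entry_day <- 3L
  inst <- ssp_instance(base, slots, 5L)
  expect_equal(order_waiting_list(inst)$surgery_id, c("a", "b"))

  # higher priority goes first regardless of entry day
  base$priority <- c(1L, 4L)
  base$entry_day <- c(0L, 10L)
  inst <- ssp_instance(base, slots, 5L)
  expect_equal(order_waiting_list(inst)$surgery_id, c("b", "a"))
})

test_that("waiting-list order equals an independently coded three-key sort", {
  for (s in 1:10) {
    set.seed(s)
    n <- 20L
    sur <- data.frame(
      id = sprintf("s%02d", sample(n)), specialty = "gen",
      duration_min = 60, turnover_min = 0,
      entry_day = sample(-30:0, n, replace = TRUE),
      deadline_day = 50L,
      priority = sample(1:4, n, replace = TRUE), stringsAsFactors = FALSE)
    slots <- data.frame(id = "k1", day = 0L, room = "OR1", specialty = "gen",
                        start_min = 480, length_min = 480,
                        max_surgeries = NA, stringsAsFactors = FALSE)
    inst <- ssp_instance(sur, slots, 5L)
    expect_equal(order_waiting_list(inst)$surgery_id,
                 oracle_waiting_order(inst))
  }
})

test_that("first fit places a fitting surgery and strands an oversized one", {
  sur <- data.frame(id = c("small", "huge"), specialty = "uro",
                    duration_min = c(60, 500), turnover_min = 0,
                    entry_day = 0L, deadline_day = 10L, priority = 2L,
                    stringsAsFactors = FALSE)
  slots <- data.frame(id = "k1", day = 0L, room = "OR1", specialty = "uro",
                      start_min = 480, length_min = 120, max_surgeries = NA,
                      stringsAsFactors = FALSE)
  inst <- ssp_instance(sur, slots, 3L)
  sched <- first_fit_assign(inst)
  expect_equal(sched$slot_id[sched$surgery_id == "small"], "k1")
  expect_equal(sched$position[sched$surgery_id == "small"], 0L)
  # 500 min exceeds every shift length: recorded as unscheduled, no error
  expect_true(is.na(sched$slot_id[sched$surgery_id == "huge"]))
  expect_equal(nrow(check_feasibility(sched, inst)), 0L)
})

test_that("sequential first fit matches the reference implementation", {
  for (s in 1:15) {
    inst <- random_tiny_instance(s)
    ord <- order_waiting_list(inst)
    got <- first_fit_assign(inst, ord, mode = "sequential")
    want <- oracle_first_fit(inst, ord$surgery_id)
    m <- match(want$surgery_id, got$surgery_id)
    expect_equal(got$slot_id[m], want$slot_id, info = paste("seed", s))
  }
})

test_that("first fit is deterministic: sequential ignores the seed, random obeys it", {
  inst <- random_tiny_instance(4)
  expect_identical(first_fit_assign(inst, mode = "sequential", seed = 1),
                   first_fit_assign(inst, mode = "sequential", seed = 999))
  r1 <- first_fit_assign(inst, mode = "random", seed = 5)
  r2 <- first_fit_assign(inst, mode = "random", seed = 5)
  expect_identical(r1, r2)
  expect_equal(nrow(check_feasibility(r1, inst)), 0L)
})

test_that("first fit output is always feasible", {
  for (s in 1:15) {
    inst <- random_tiny_instance(s)
    for (mode in c("sequential", "random")) {
      sched <- first_fit_assign(inst, mode = mode, seed = s)
      expect_equal(nrow(check_feasibility(sched, inst)), 0L,
                   info = paste(mode, s))
    }
  }
})

test_that("first fit is no worse than scheduling nothing", {
  for (s in 1:10) {
    inst <- random_tiny_instance(s)
    U <- inst$horizon_days * max(inst$priority_weights)
    ff <- total_penalty(first_fit_assign(inst), inst, unscheduled_cost = U)
    none <- total_penalty(empty_schedule(inst), inst, unscheduled_cost = U)
    expect_lte(ff$objective, none$objective)
  }
})

test_that("first fit recovers a zero-penalty plan when the plant follows priority order", {
  # three slots packed in a known order; deadlines equal the planted day,
  # entry days follow the packing order, priorities all equal -- so the
  # waiting-list order equals the planted order
  sur <- data.frame(
    id = sprintf("s%d", 1:6), specialty = "gen",
    duration_min = c(200, 200, 150, 150, 100, 100), turnover_min = 20,
    entry_day = -(6:1), deadline_day = c(0L, 0L, 1L, 1L, 2L, 2L),
    priority = 2L, stringsAsFactors = FALSE)
  slots <- data.frame(id = c("k1", "k2", "k3"), day = 0:2, room = "OR1",
                      specialty = "gen", start_min = 480, length_min = 480,
                      max_surgeries = NA, stringsAsFactors = FALSE)
  inst <- ssp_instance(sur, slots, 3L)
  sched <- first_fit_assign(inst)
  expect_equal(total_penalty(sched, inst)$total, 0)
  expect_equal(total_penalty(sched, inst)$counts[["n_unscheduled"]], 0L)
})
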