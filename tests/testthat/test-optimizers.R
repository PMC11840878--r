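# number of surgeries whose assignment differs between two schedules
n_changed <- function(a, b, instance) {
  da <- stats::setNames(a$slot_id, a$surgery_id)[instance$surgeries$id]
  db <- stats::setNames(b$slot_id, b$surgery_id)[instance$surgeries$id]
  sum(!(is.na(da) & is.na(db)) & (is.na(da) != is.na(db) |
                                    (!is.na(da) & !is.na(db) & da != db)))
}

test_that("neighbourhood move returns the input when no alternative exists", {
  sur <- data.frame(id = "s1", specialty = "gen", duration_min = 60,
                    turnover_min = 0, entry_day = 0L, deadline_day = 5L,
                    priority = 1L, stringsAsFactors = FALSE)
  slots <- data.frame(id = "k1", day = 0L, room = "OR1", specialty = "gen",
                      start_min = 480, length_min = 480, max_surgeries = NA,
                      stringsAsFactors = FALSE)
  inst <- ssp_instance(sur, slots, 3L)
  sched <- first_fit_assign(inst)
  moved <- neighborhood_move(sched, inst, seed = 3)
  expect_equal(n_changed(sched, moved, inst), 0L)
})

test_that("exact-capacity swaps of equal-duration surgeries are feasible", {
  sur <- data.frame(id = c("s1", "s2"), specialty = "gen",
                    duration_min = 100, turnover_min = 20,
                    entry_day = 0L, deadline_day = c(0L, 5L), priority = 2L,
                    stringsAsFactors = FALSE)
  slots <- data.frame(id = c("k1", "k2"), day = 0:1, room = "OR1",
                      specialty = "gen", start_min = 480, length_min = 120,
                      max_surgeries = NA, stringsAsFactors = FALSE)
  inst <- ssp_instance(sur, slots, 2L)
  sched <- ssp_schedule(data.frame(surgery_id = c("s1", "s2"),
                                   slot_id = c("k2", "k1")))
  # the only non-identity neighbour is the swap; drawing until it appears
  found <- FALSE
  for (s in 1:50) {
    moved <- neighborhood_move(sched, inst, seed = s)
    expect_equal(nrow(check_feasibility(moved, inst)), 0L)
    if (n_changed(sched, moved, inst) == 2L) found <- TRUE
  }
  expect_true(found)
})

test_that("emitted candidates are feasible and differ in at most 2 assignments", {
  inst <- random_tiny_instance(17)
  sched <- first_fit_assign(inst)
  for (s in 1:1000) {
    cand <- neighborhood_move(sched, inst, seed = s)
    expect_lte(n_changed(sched, cand, inst), 2L)
    expect_equal(nrow(check_feasibility(cand, inst)), 0L)
  }
})

test_that("moves never reduce the number of scheduled surgeries", {
  inst <- random_tiny_instance(21)
  sched <- first_fit_assign(inst)
  for (s in 1:200) {
    cand <- neighborhood_move(sched, inst, seed = s)
    expect_gte(sum(!is.na(cand$slot_id)), sum(!is.na(sched$slot_id)))
    sched <- cand
  }
})

test_that("SA acceptance implements the Metropolis rule", {
  expect_true(sa_acceptance(-5, 0.01, u = 0.999999))  # improving: always
  expect_true(sa_acceptance(0, 1e-9, u = 0.999999))   # equal: always
  # delta == T: accept iff u < exp(-1)
  expect_true(sa_acceptance(2, 2, u = exp(-1) - 1e-9))
  expect_false(sa_acceptance(2, 2, u = exp(-1) + 1e-9))
  expect_error(sa_acceptance(1, 0), "temperature")
  expect_error(sa_acceptance(1, -2), "temperature")
})

test_that("empirical SA acceptance frequency matches exp(-delta/T)", {
  n <- 1e5
  set.seed(2024)
  acc <- sum(vapply(seq_len(n), function(i) sa_acceptance(2, 1), logical(1)))
  p <- exp(-2)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(acc / n - p), 3 * se)
})

test_that("hill climbing cannot leave a zero-penalty optimum", {
  gen <- generate_planted_instance(
    generator_spec(specialties = "gen", n_surgeries = 12L, n_slots = 5L,
                   horizon_days = 5L), seed = 2)
  inst <- gen$instance
  res <- hill_climb(inst, gen$schedule, solver_control(max_iters = 20, seed = 1))
  expect_equal(res$best_penalty, 0)
  expect_true(all(res$trace$best_penalty == 0))
})

test_that("hill climbing trace is monotone and the result reproducible", {
  inst <- random_tiny_instance(8)
  init <- first_fit_assign(inst)
  ctl <- solver_control(max_iters = 30, seed = 11)
  r1 <- hill_climb(inst, init, ctl)
  r2 <- hill_climb(inst, init, ctl)
  expect_identical(r1$best_schedule, r2$best_schedule)
  expect_identical(r1$trace, r2$trace)
  expect_true(all(diff(r1$trace$best_penalty) <= 0))
  expect_true(all(diff(r1$trace$current_penalty) <= 0))
  expect_equal(nrow(check_feasibility(r1$best_schedule, inst)), 0L)
  # reported score consistent with re-evaluating the returned schedule
  expect_equal(r1$best_penalty, total_penalty(r1$best_schedule, inst)$total)
})

test_that("solvers reject an infeasible initial schedule", {
  inst <- tiny_instance()
  inst$surgeries$duration_min[1:3] <- 150
  inst$surgeries$turnover_min[1:3] <- 0
  bad <- ssp_schedule(data.frame(surgery_id = c("s1", "s2", "s3"),
                                 slot_id = c("k1", "k1", "k1")))
  expect_error(hill_climb(inst, bad, solver_control(max_iters = 2)),
               "infeasible")
  expect_error(simulated_annealing(inst, bad, solver_control(max_iters = 2)),
               "infeasible")
})

test_that("simulated annealing tracks the best-ever schedule", {
  gen <- generate_planted_instance(
    generator_spec(specialties = "gen", n_surgeries = 12L, n_slots = 5L,
                   horizon_days = 5L), seed = 5)
  inst <- gen$instance
  # start at the optimum: excursions cannot worsen the reported best
  res <- simulated_annealing(inst, gen$schedule,
                             solver_control(max_iters = 30, seed = 3,
                                            sa_T0 = 50))
  expect_equal(res$best_penalty, 0)
  expect_true(all(diff(res$trace$best_penalty) <= 0))
  expect_true(all(diff(res$trace$temperature[-1]) <= 0))
  expect_equal(nrow(check_feasibility(res$best_schedule, inst)), 0L)
})

test_that("near-zero temperature SA behaves as pure descent", {
  inst <- random_tiny_instance(13)
  init <- first_fit_assign(inst)
  res <- simulated_annealing(inst, init,
                             solver_control(max_iters = 30, seed = 4,
                                            sa_T0 = 1e-9, sa_Tmin = 1e-12))
  expect_true(all(diff(res$trace$current_penalty) <= 0))
  U <- inst$horizon_days * max(inst$priority_weights)
  expect_lte(res$best_objective,
             total_penalty(init, inst, unscheduled_cost = U)$objective)
})

test_that("PSO encode/decode round-trips feasible schedules", {
  for (s in c(2, 9, 14)) {
    inst <- random_tiny_instance(s)
    sched <- first_fit_assign(inst)
    x <- pso_encode(sched, inst)
    expect_length(x, nrow(inst$surgeries))
    back <- pso_decode(x, inst)
    expect_identical(scheduled_days(back, inst), scheduled_days(sched, inst))
  }
  expect_error(pso_decode(c(0, 1), random_tiny_instance(2)), "length")
})

test_that("PSO decode clamps out-of-range coordinates and repairs to feasibility", {
  inst <- random_tiny_instance(6)
  n <- nrow(inst$surgeries)
  # a strongly negative coordinate is clamped to the earliest slot index
  x <- rep(-3.7, n)
  sched <- pso_decode(x, inst)
  expect_equal(nrow(check_feasibility(sched, inst)), 0L)
  set.seed(31)
  K <- nrow(inst$slots)
  for (r in 1:200) {
    x <- stats::runif(n, -2, K + 2)
    sched <- pso_decode(x, inst)
    expect_equal(nrow(check_feasibility(sched, inst)), 0L)
  }
})

test_that("a swarm seeded at a zero-penalty schedule keeps it", {
  gen <- generate_planted_instance(
    generator_spec(specialties = "gen", n_surgeries = 10L, n_slots = 4L,
                   horizon_days = 4L), seed = 3)
  inst <- gen$instance
  ctl <- solver_control(max_iters = 10, seed = 2, pso_swarm_size = 8,
                        pso_init = gen$schedule)
  res <- particle_swarm(inst, ctl)
  expect_equal(res$best_penalty, 0)
  expect_equal(res$best_objective, 0)
  expect_true(all(diff(res$trace$best_penalty) <= 0))
  expect_equal(nrow(check_feasibility(res$best_schedule, inst)), 0L)
})

test_that("local solvers with restarts find the exhaustive optimum on small instances", {
  for (s in c(3, 7, 19)) {
    inst <- random_tiny_instance(s)
    U <- inst$horizon_days * max(inst$priority_weights)
    opt <- oracle_optimum(inst, U)
    hc <- hill_climb_restarts(inst, solver_control(max_iters = 15, seed = s),
                              restarts = 10)
    expect_equal(hc$best_objective, opt, info = paste("seed", s))
    # PSO is bounded between the optimum and nothing-scheduled
    ps <- particle_swarm(inst, solver_control(max_iters = 30, seed = s,
                                              pso_swarm_size = 10))
    expect_gte(ps$best_objective, opt)
    expect_lte(ps$best_objective,
               total_penalty(empty_schedule(inst), inst,
                             unscheduled_cost = U)$objective)
  }
})
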