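test_that("per-surgery penalty is days overdue times the priority weight", {
  weights <- c("1" = 1, "2" = 3, "3" = 4)
  s <- list(deadline_day = 10L, priority = 2L)
  expect_equal(surgery_penalty(s, 8L, weights), 0)    # before deadline
  expect_equal(surgery_penalty(s, 10L, weights), 0)   # exactly at deadline
  expect_equal(surgery_penalty(s, 15L, weights), 15)  # 5 days x weight 3
  expect_equal(surgery_penalty(s, NA, weights), 0)    # unscheduled
  expect_error(surgery_penalty(list(deadline_day = 1, priority = 9), 2, weights),
               "priority")
})

test_that("total penalty sums per-surgery penalties and counts partition N", {
  inst <- tiny_instance()
  # everything scheduled on or before its deadline -> zero total
  on_time <- ssp_schedule(data.frame(surgery_id = c("s2", "s1", "s3"),
                                     slot_id = c("k1", "k2", "k2")))
  rep <- total_penalty(on_time, inst)
  expect_equal(rep$total, 0)
  expect_equal(rep$counts[["n_with_penalty"]], 0L)

  # s2 (deadline 0, weight 4) on day 1: penalty 4
  # s4 (deadline 1, weight 2) on day 3: penalty 4
  late <- ssp_schedule(data.frame(surgery_id = c("s2", "s4"),
                                  slot_id = c("k2", "k3")))
  rep <- total_penalty(late, inst)
  expect_equal(unname(rep$per_surgery["s2"]), 4)
  expect_equal(unname(rep$per_surgery["s4"]), 4)
  expect_equal(rep$total, sum(rep$per_surgery))
  expect_equal(sum(rep$counts), nrow(inst$surgeries))
  expect_equal(rep$counts[["n_unscheduled"]], 3L)
})

test_that("total penalty matches an independent sum-over-loop oracle", {
  for (s in 1:20) {
    inst <- random_tiny_instance(s)
    sched <- random_schedule(inst, seed = s + 500)
    for (U in c(0, 40)) {
      expect_equal(total_penalty(sched, inst, unscheduled_cost = U)$objective,
                   oracle_objective(sched, inst, unscheduled_cost = U),
                   info = paste("seed", s, "U", U))
    }
  }
})

test_that("an infeasible schedule is scored but flagged", {
  inst <- tiny_instance()
  inst$surgeries$duration_min[1:3] <- 120
  inst$surgeries$turnover_min[1:3] <- 0
  bad <- ssp_schedule(data.frame(surgery_id = c("s1", "s2", "s3"),
                                 slot_id = c("k1", "k1", "k1")))
  rep <- total_penalty(bad, inst)
  expect_true(rep$infeasible)
  expect_true(is.finite(rep$total))
})

test_that("penalty is monotone in scheduled day and deadline", {
  weights <- c("1" = 1, "2" = 2, "3" = 4, "4" = 8)
  set.seed(42)
  for (r in 1:200) {
    deadline <- sample(-30:30, 1)
    pr <- sample(1:4, 1)
    s <- list(deadline_day = deadline, priority = pr)
    d1 <- sample(0:40, 1)
    d2 <- d1 + sample(1:10, 1)
    expect_gte(surgery_penalty(s, d2, weights), surgery_penalty(s, d1, weights))
    tighter <- list(deadline_day = deadline - sample(1:10, 1), priority = pr)
    expect_gte(surgery_penalty(tighter, d1, weights),
               surgery_penalty(s, d1, weights))
  }
})

test_that("scaling all priority weights scales the total penalty exactly", {
  inst <- random_tiny_instance(3)
  sched <- random_schedule(inst, seed = 99)
  base <- total_penalty(sched, inst)$total
  for (c in c(0.5, 2, 7.25)) {
    inst2 <- inst
    inst2$priority_weights <- inst$priority_weights * c
    expect_equal(total_penalty(sched, inst2)$total, c * base)
  }
})

test_that("total is zero iff every scheduled surgery meets its deadline", {
  for (s in 1:15) {
    inst <- random_tiny_instance(s)
    sched <- random_schedule(inst, seed = s)
    rep <- total_penalty(sched, inst)
    day <- scheduled_days(sched, inst)
    ids <- inst$surgeries$id
    all_on_time <- all(is.na(day[ids]) |
                         day[ids] <= inst$surgeries$deadline_day)
    expect_equal(rep$total == 0, all_on_time, info = paste("seed", s))
  }
})

test_that("schedule delta is zero against itself and tracks uniform shifts", {
  inst <- tiny_instance()
  a <- ssp_schedule(data.frame(surgery_id = c("s1", "s2"),
                               slot_id = c("k1", "k1")))
  d <- schedule_delta(a, a, inst)
  expect_true(all(d$deltas$delta == 0))
  expect_equal(unname(d$summary["n_same"]), 2)

  # b books every surgery one day later than a (k1 day 0 -> k2 day 1)
  b <- ssp_schedule(data.frame(surgery_id = c("s1", "s2"),
                               slot_id = c("k2", "k2")))
  d <- schedule_delta(a, b, inst)
  expect_true(all(d$deltas$delta == -1))
  expect_equal(unname(d$summary["mean_shift"]), -1)
})

test_that("schedule delta agrees with direct per-id subtraction", {
  for (s in 1:10) {
    inst <- random_tiny_instance(s)
    a <- random_schedule(inst, seed = s + 1)
    b <- random_schedule(inst, seed = s + 2)
    d <- schedule_delta(a, b, inst)
    da <- scheduled_days(a, inst)
    db <- scheduled_days(b, inst)
    for (i in seq_len(nrow(d$deltas))) {
      id <- d$deltas$surgery_id[i]
      expect_equal(d$deltas$delta[i], unname(da[id] - db[id]))
    }
    expect_equal(nrow(d$deltas) + nrow(d$unmatched), nrow(inst$surgeries))
    both_na <- sum(is.na(da) & is.na(db))
    expect_equal(sum(d$unmatched$unscheduled_in == "both"), both_na)
  }
})
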