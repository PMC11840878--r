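#' Solver control parameters
#'
#' One control object is shared by all three solvers; each reads the fields
#' it needs. One "iteration" of hill climbing and simulated annealing is a
#' sweep of N candidate proposals (N = number of surgeries), so traces are
#' comparable across instance sizes; for particle swarm an iteration is one
#' velocity/position update of the whole swarm.
#'
#' @param max_iters number of sweep-iterations (>= 1).
#' @param seed integer seed; every stochastic choice of a solver run flows
#'   from it, so identical (instance, init, control) give identical results.
#' @param trace record the per-iteration incumbent and best penalties.
#' @param unscheduled_cost per-unscheduled-surgery charge added to the
#'   objective the solvers minimize; \code{NULL} (default) uses
#'   \code{horizon_days * max(priority_weights)}, which makes scheduling a
#'   surgery -- even overdue -- always preferable to leaving it off the
#'   table. Reported penalty scores always remain the plain \code{pt}.
#' @param sa_T0 initial temperature; \code{NULL} (default) calibrates it to
#'   the move scale by sampling candidate moves from the initial solution
#'   and choosing T0 so the mean worsening delta is accepted with
#'   probability about 0.8 (the classic initial-acceptance-ratio rule), so
#'   early sweeps explore and the geometric schedule cools to near-greedy
#'   within about 100 sweeps.
#' @param sa_step geometric cooling factor in (0, 1) applied once per sweep.
#' @param sa_Tmin floor temperature.
#' @param pso_swarm_size number of particles (>= 2).
#' @param pso_lower,pso_upper per-dimension bounds on the encoded positions;
#'   \code{NULL} uses 0 and K (K = number of slots; coordinate K is the
#'   unscheduled sentinel).
#' @param pso_init optional [ssp_schedule()] used to seed one particle.
#' @param move_retries bounded draws per neighbourhood proposal.
#' @return object of class \code{ssp_solver_control}.
#' @export
solver_control <- function(max_iters = 100L, seed = 1L, trace = TRUE,
                           unscheduled_cost = NULL,
                           sa_T0 = NULL, sa_step = 0.95, sa_Tmin = 1e-6,
                           pso_swarm_size = 20L, pso_lower = NULL,
                           pso_upper = NULL, pso_init = NULL,
                           move_retries = 25L) {
  if (max_iters < 1) stopf("max_iters must be >= 1")
  if (!(sa_step > 0 && sa_step < 1)) stopf("sa_step must be in (0, 1)")
  if (!is.null(sa_T0) && sa_T0 <= 0) stopf("sa_T0 must be > 0")
  if (pso_swarm_size < 2) stopf("pso_swarm_size must be >= 2")
  if (!is.null(pso_lower) && !is.null(pso_upper) &&
      any(pso_lower > pso_upper)) {
    stopf("pso_lower must be <= pso_upper elementwise")
  }
  structure(
    list(max_iters = as.integer(max_iters), seed = as.integer(seed),
         trace = isTRUE(trace), unscheduled_cost = unscheduled_cost,
         sa_T0 = sa_T0, sa_step = sa_step, sa_Tmin = sa_Tmin,
         pso_swarm_size = as.integer(pso_swarm_size),
         pso_lower = pso_lower, pso_upper = pso_upper, pso_init = pso_init,
         move_retries = as.integer(move_retries)),
    class = "ssp_solver_control"
  )
}

solver_result <- function(algorithm, instance, st, best_slot_of, trace_df,
                          control) {
  best_schedule <- state_schedule(st, best_slot_of)
  rep <- total_penalty(best_schedule, instance,
                       unscheduled_cost = st$U, check = FALSE)
  final_best <- trace_df$best_penalty[nrow(trace_df)]
  stab <- trace_df$iteration[which(trace_df$best_penalty <= final_best)[1]]
  structure(
    list(algorithm = algorithm,
         best_schedule = best_schedule,
         best_penalty = rep$total,
         best_objective = rep$objective,
         trace = trace_df,
         iters_to_stabilize = stab,
         control = control),
    class = "ssp_solver_result"
  )
}

#' @export
print.ssp_solver_result <- function(x, ...) {
  cat(sprintf("%s solver result: penalty score %g (objective %g)\n",
              x$algorithm, x$best_penalty, x$best_objective))
  cat(sprintf("  stabilized after %d sweep-iteration(s) of %d\n",
              x$iters_to_stabilize, max(x$trace$iteration)))
  print(x$best_schedule)
  invisible(x)
}

check_init <- function(init, instance) {
  viol <- check_feasibility(init, instance)
  if (nrow(viol)) {
    stopf("initial schedule is infeasible (%d violation(s), first: %s)",
          nrow(viol), viol$message[1])
  }
}

#' Hill-climbing solver
#'
#' Greedy local search over the swap/relocate neighbourhood: in each of
#' \code{max_iters} sweeps, N candidate moves are proposed and a candidate
#' is adopted only if it does not worsen the objective. Accepting equal-cost
#' candidates lets the search walk across plateaus -- rearranging on-time
#' surgeries at no cost until capacity opens up for an overdue one -- and is
#' exactly the zero-temperature limit of [simulated_annealing()], which the
#' two solvers' acceptance rules share. The trace is monotone
#' non-increasing.
#'
#' @param instance an [ssp_instance()].
#' @param init a feasible starting [ssp_schedule()], typically from
#'   [first_fit_assign()].
#' @param control an [solver_control()].
#' @return object of class \code{ssp_solver_result} with the best schedule,
#'   its penalty score and objective, the per-sweep trace and
#'   \code{iters_to_stabilize} (first sweep after which the incumbent never
#'   improves).
#' @export
hill_climb <- function(instance, init, control = solver_control()) {
  check_init(init, instance)
  U <- control$unscheduled_cost %||% default_unscheduled_cost(instance)
  st <- build_state(instance, init, U)
  n_iter <- control$max_iters
  cur_tr <- best_tr <- numeric(n_iter + 1L)
  cur_tr[1] <- best_tr[1] <- st$obj
  with_seed(control$seed, {
    for (it in seq_len(n_iter)) {
      for (s in seq_len(max(st$N, 1L))) {
        mv <- propose_move(st, control$move_retries)
        if (!is.null(mv) && mv$delta <= 0) apply_move(st, mv)
      }
      cur_tr[it + 1L] <- best_tr[it + 1L] <- st$obj
    }
  })
  trace_df <- data.frame(iteration = 0:n_iter, current_penalty = cur_tr,
                         best_penalty = best_tr, temperature = NA_real_)
  solver_result("hc", instance, st, st$slot_of,
                if (control$trace) trace_df else trace_df[nrow(trace_df), ],
                control)
}

#' Hill climbing with random restarts
#'
#' Runs [hill_climb()] from several diversified starting points: restart r
#' builds its initial schedule by first-fit over a seeded random permutation
#' of the waiting list with randomized slot scanning, and the best result
#' across restarts is returned (the first restart uses the deterministic
#' priority-ordered sequential first-fit).
#'
#' @inheritParams hill_climb
#' @param restarts number of starts.
#' @return the best \code{ssp_solver_result} across restarts.
#' @export
hill_climb_restarts <- function(instance, control = solver_control(),
                                restarts = 20L) {
  best <- NULL
  for (r in seq_len(restarts)) {
    init <- if (r == 1L) {
      first_fit_assign(instance, mode = "sequential")
    } else {
      ord <- with_seed(control$seed + 7919L * r,
                       sample(instance$surgeries$id))
      first_fit_assign(instance, order = ord, mode = "random",
                       seed = control$seed + r)
    }
    ctl <- control
    ctl$seed <- control$seed + r
    res <- hill_climb(instance, init, ctl)
    if (is.null(best) || res$best_objective < best$best_objective) best <- res
  }
  best
}

#' Simulated-annealing acceptance rule
#'
#' An improving or equal candidate (difference in objective values
#' \code{delta <= 0}) is always accepted; a worsening one is accepted with
#' probability \code{exp(-delta / temperature)}.
#'
#' @param delta objective difference f(candidate) - f(current).
#' @param temperature current temperature, must be > 0.
#' @param u uniform(0,1) draw; defaults to a fresh draw from the current
#'   RNG stream.
#' @return logical: accept the candidate?
#' @export
sa_acceptance <- function(delta, temperature, u = stats::runif(1)) {
  if (temperature <= 0) stopf("temperature must be > 0")
  delta <= 0 || u < exp(-delta / temperature)
}

# Temperature matched to the scale of the landscape: the classic
# initial-acceptance-ratio calibration -- T0 such that the mean worsening
# delta among sampled candidate moves is accepted with probability ~0.8,
# i.e. T0 = mean(delta+) / ln(1/0.8); at least 1. Sampling does not touch
# the state.
calibrate_T0 <- function(st, retries, accept0 = 0.8) {
  deltas <- numeric(0)
  for (r in 1:50) {
    mv <- propose_move(st, retries)
    if (!is.null(mv) && mv$delta > 0) deltas <- c(deltas, mv$delta)
  }
  if (length(deltas)) max(1, mean(deltas) / log(1 / accept0)) else 1
}

#' Simulated-annealing solver
#'
#' Local search with the same swap/relocate neighbourhood as
#' [hill_climb()], but worsening moves are accepted with probability
#' \code{exp(-delta/T)} under a geometric cooling schedule
#' \code{T <- sa_step * T} applied once per sweep, starting from
#' \code{sa_T0} and floored at \code{sa_Tmin}. The best schedule ever
#' visited is tracked separately from the current one and is what the
#' solver returns, so excursions can never worsen the reported result.
#'
#' @inheritParams hill_climb
#' @return object of class \code{ssp_solver_result}.
#' @export
simulated_annealing <- function(instance, init, control = solver_control()) {
  check_init(init, instance)
  U <- control$unscheduled_cost %||% default_unscheduled_cost(instance)
  st <- build_state(instance, init, U)
  n_iter <- control$max_iters
  temp <- control$sa_T0 %||%
    with_seed(control$seed + 65537L, calibrate_T0(st, control$move_retries))
  cur_tr <- best_tr <- temp_tr <- numeric(n_iter + 1L)
  cur_tr[1] <- best_tr[1] <- st$obj
  temp_tr[1] <- temp
  best_obj <- st$obj
  best_slot_of <- st$slot_of
  with_seed(control$seed, {
    for (it in seq_len(n_iter)) {
      for (s in seq_len(max(st$N, 1L))) {
        mv <- propose_move(st, control$move_retries)
        if (is.null(mv)) next
        if (mv$delta < 0 || stats::runif(1) < exp(-mv$delta / temp)) {
          apply_move(st, mv)
          if (st$obj < best_obj) {
            best_obj <- st$obj
            best_slot_of <- st$slot_of
          }
        }
      }
      temp <- max(control$sa_Tmin, control$sa_step * temp)
      cur_tr[it + 1L] <- st$obj
      best_tr[it + 1L] <- best_obj
      temp_tr[it + 1L] <- temp
    }
  })
  trace_df <- data.frame(iteration = 0:n_iter, current_penalty = cur_tr,
                         best_penalty = best_tr, temperature = temp_tr)
  solver_result("sa", instance, st, best_slot_of,
                if (control$trace) trace_df else trace_df[nrow(trace_df), ],
                control)
}

# --- particle swarm ---------------------------------------------------------

# Internal decode on the flat state: positions are real coordinates, one per
# surgery, over [0, K]; coordinate K is the unscheduled sentinel. Each
# coordinate is rounded and clamped, then repaired to feasibility by first
# fit among the slots sharing the target slot's day and specialty;
# unplaceable surgeries stay unscheduled.
decode_positions <- function(st, x, lower = 0, upper = st$K) {
  t0 <- pmin(pmax(round(x), lower), upper)
  slot_of <- rep(NA_integer_, st$N)
  load <- numeric(st$K)
  cnt <- integer(st$K)
  for (i in seq_len(st$N)) {
    if (t0[i] >= st$K) next
    k0 <- t0[i] + 1L
    placed <- FALSE
    if (st$spec_k[k0] == st$spec_s[i] &&
        load[k0] + st$dur[i] <= st$cap[k0] && cnt[k0] + 1L <= st$maxn[k0]) {
      k <- k0
      placed <- TRUE
    } else {
      for (k in st$same_day_spec[[k0]]) {
        if (st$spec_k[k] == st$spec_s[i] &&
            load[k] + st$dur[i] <= st$cap[k] && cnt[k] + 1L <= st$maxn[k]) {
          placed <- TRUE
          break
        }
      }
    }
    if (placed) {
      slot_of[i] <- k
      load[k] <- load[k] + st$dur[i]
      cnt[k] <- cnt[k] + 1L
    }
  }
  slot_of
}

#' Encode a schedule as a particle position / decode a position back
#'
#' The particle-swarm solver searches a continuous space with one coordinate
#' per surgery: the day-major index of its slot, from 0 (earliest shift) to
#' K - 1 (latest shift), with K acting as the "unscheduled" sentinel.
#' \code{pso_decode} rounds each coordinate, clamps it into \code{[lower,
#' upper]}, and repairs to feasibility by first fit among the slots sharing
#' the targeted slot's day and specialty; surgeries that still fit nowhere
#' are left unscheduled. For any feasible schedule,
#' \code{pso_decode(pso_encode(s))} reproduces the scheduled day of every
#' surgery.
#'
#' @param schedule a feasible [ssp_schedule()].
#' @param instance an [ssp_instance()].
#' @return \code{pso_encode}: numeric vector of length N (one coordinate per
#'   surgery, in the instance's surgery order).
#' @export
pso_encode <- function(schedule, instance) {
  st <- build_state(instance, schedule, unscheduled_cost = 0)
  x <- st$slot_of - 1
  x[is.na(x)] <- st$K
  as.numeric(x)
}

#' @rdname pso_encode
#' @param x numeric vector of length N of encoded coordinates.
#' @param lower,upper clamping bounds (defaults 0 and K).
#' @return \code{pso_decode}: a feasible [ssp_schedule()].
#' @export
pso_decode <- function(x, instance, lower = 0, upper = NULL) {
  st <- build_state(instance, NULL, unscheduled_cost = 0)
  if (length(x) != st$N) {
    stopf("encoded vector has length %d, expected %d", length(x), st$N)
  }
  upper <- upper %||% st$K
  state_schedule(st, decode_positions(st, x, lower, upper))
}

#' Particle-swarm solver
#'
#' Canonical global-best particle swarm over the encoded slot-index space
#' (constriction-equivalent constants: inertia 0.7298, cognitive and social
#' coefficients 1.4961). Particle fitness is the objective of the decoded
#' schedule, so every evaluated -- and hence the returned -- schedule is
#' feasible by repair. Unlike the local-search solvers, the swarm is
#' initialized at random positions rather than from a constructed initial
#' solution (one particle can be seeded through \code{control$pso_init}).
#'
#' @param instance an [ssp_instance()].
#' @param control an [solver_control()].
#' @return object of class \code{ssp_solver_result}.
#' @export
particle_swarm <- function(instance, control = solver_control()) {
  U <- control$unscheduled_cost %||% default_unscheduled_cost(instance)
  st <- build_state(instance, NULL, U)
  N <- st$N
  K <- st$K
  lower <- control$pso_lower %||% 0
  upper <- control$pso_upper %||% K
  M <- control$pso_swarm_size
  n_iter <- control$max_iters
  w <- 0.7298
  c1 <- 1.4961
  c2 <- 1.4961
  fitness <- function(x) {
    so <- decode_positions(st, x, lower, upper)
    sum(state_penalties(st, so)) + U * sum(is.na(so))
  }
  cur_tr <- best_tr <- numeric(n_iter + 1L)
  res_env <- new.env(parent = emptyenv())
  with_seed(control$seed, {
    X <- matrix(stats::runif(M * N, lower, upper), nrow = M)
    if (!is.null(control$pso_init)) {
      X[1, ] <- pso_encode(control$pso_init, instance)
    }
    V <- matrix(0, nrow = M, ncol = N)
    fit <- apply(X, 1, fitness)
    Pbest <- X
    pfit <- fit
    g <- which.min(fit)
    G <- X[g, ]
    gfit <- fit[g]
    cur_tr[1] <- min(fit)
    best_tr[1] <- gfit
    for (it in seq_len(n_iter)) {
      r1 <- matrix(stats::runif(M * N), nrow = M)
      r2 <- matrix(stats::runif(M * N), nrow = M)
      V <- w * V + c1 * r1 * (Pbest - X) +
        c2 * r2 * (matrix(G, nrow = M, ncol = N, byrow = TRUE) - X)
      X <- pmin(pmax(X + V, lower), upper)
      fit <- apply(X, 1, fitness)
      better <- fit < pfit
      Pbest[better, ] <- X[better, , drop = FALSE]
      pfit[better] <- fit[better]
      if (min(pfit) < gfit) {
        g <- which.min(pfit)
        G <- Pbest[g, ]
        gfit <- pfit[g]
      }
      cur_tr[it + 1L] <- min(fit)
      best_tr[it + 1L] <- gfit
    }
    res_env$G <- G
  })
  best_slot_of <- decode_positions(st, res_env$G, lower, upper)
  trace_df <- data.frame(iteration = 0:n_iter, current_penalty = cur_tr,
                         best_penalty = best_tr, temperature = NA_real_)
  solver_result("pso", instance, st, best_slot_of,
                if (control$trace) trace_df else trace_df[nrow(trace_df), ],
                control)
}

#' Run a solver by name
#'
#' @param algorithm one of \code{"hc"}, \code{"sa"}, \code{"pso"}.
#' @param instance an [ssp_instance()].
#' @param init feasible initial schedule (ignored by \code{"pso"});
#'   \code{NULL} builds the sequential first-fit solution.
#' @param control an [solver_control()].
#' @return an \code{ssp_solver_result}.
#' @export
solve_instance <- function(algorithm = c("hc", "sa", "pso"), instance,
                           init = NULL, control = solver_control()) {
  algorithm <- match.arg(algorithm)
  if (is.null(init) && algorithm != "pso") {
    init <- first_fit_assign(instance, mode = "sequential")
  }
  switch(algorithm,
         hc = hill_climb(instance, init, control),
         sa = simulated_annealing(instance, init, control),
         pso = particle_swarm(instance, control))
}
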