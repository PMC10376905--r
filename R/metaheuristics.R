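# Four bounded-box maximization metaheuristics with a shared contract:
# objective(position) -> scalar to maximize, positions kept inside the box by
# projection, a single seeded RNG stream per run, and a best-so-far trace.

#' Define a box-constrained search space
#'
#' @param name character vector of dimension names (unique).
#' @param lower,upper numeric bounds, `lower < upper` per dimension.
#' @param integer logical vector marking dimensions that are rounded to
#'   integers when decoded into model hyperparameters (the search itself
#'   stays continuous).
#' @return a `search_space` data.frame.
#' @export
search_space <- function(name, lower, upper, integer = FALSE) {
  n <- length(name)
  integer <- rep_len(integer, n)
  if (length(lower) != n || length(upper) != n) {
    stop("name, lower and upper must have equal length", call. = FALSE)
  }
  if (anyDuplicated(name)) {
    stop("dimension names must be unique", call. = FALSE)
  }
  if (any(!is.finite(lower)) || any(!is.finite(upper)) || any(lower >= upper)) {
    stop("bounds must be finite with lower < upper", call. = FALSE)
  }
  structure(data.frame(name = name, lower = lower, upper = upper,
                       integer = integer, stringsAsFactors = FALSE),
            class = c("search_space", "data.frame"))
}

#' Clip a position into the search box
#'
#' @param position numeric vector, one coordinate per dimension.
#' @param space a [search_space()].
#' @return the coordinate-wise projection onto the box.
#' @export
project_to_bounds <- function(position, space) {
  if (length(position) != nrow(space)) {
    stop("position length does not match the search space", call. = FALSE)
  }
  if (any(!is.finite(position))) {
    stop("position contains non-finite coordinates", call. = FALSE)
  }
  pmin(pmax(position, space$lower), space$upper)
}

random_position <- function(space) {
  stats::runif(nrow(space), space$lower, space$upper)
}

init_population <- function(n, space) {
  pop <- matrix(NA_real_, n, nrow(space))
  for (i in seq_len(n)) {
    pop[i, ] <- random_position(space)
  }
  pop
}

new_optimizer_result <- function(method, best_position, best_fitness, trace,
                                 evaluations, runtime, space) {
  names(best_position) <- space$name
  structure(list(method = method,
                 best_position = best_position,
                 best_fitness = best_fitness,
                 trace = trace,
                 evaluations = evaluations,
                 runtime = runtime),
            class = "optimizer_result")
}

#' @export
print.optimizer_result <- function(x, ...) {
  cat(sprintf("<optimizer_result: %s>\n", x$method))
  cat(sprintf("  best fitness : %.6f\n", x$best_fitness))
  cat(sprintf("  evaluations  : %d\n", x$evaluations))
  cat(sprintf("  runtime      : %.2f s\n", x$runtime))
  cat("  best position:\n")
  print(round(x$best_position, 4))
  invisible(x)
}

check_objective_value <- function(value, position) {
  if (length(value) != 1L || !is.finite(value)) {
    stop(sprintf("objective returned a non-finite value at position (%s)",
                 paste(signif(position, 4), collapse = ", ")), call. = FALSE)
  }
  as.numeric(value)
}

#' Differential evolution control parameters
#'
#' Defaults are the settings used for hyperparameter tuning: mutation factor
#' F = 0.5, crossover probability CR = 0.9, population 10, 10 generations,
#' with the classic rand/1/bin strategy.
#'
#' @param np population size (>= 4 so three distinct partners exist).
#' @param generations iteration budget.
#' @param f mutation scaling factor (> 0).
#' @param cr crossover probability in \[0,1\].
#' @param seed RNG seed for the run.
#' @export
de_control <- function(np = 10, generations = 10, f = 0.5, cr = 0.9,
                       seed = 1) {
  stopifnot(np >= 4, generations >= 1, f > 0, cr >= 0, cr <= 1)
  list(np = as.integer(np), generations = as.integer(generations),
       f = f, cr = cr, seed = seed)
}

#' Maximize an objective with differential evolution (rand/1/bin)
#'
#' Each generation builds, for every population member i, a mutant
#' v = x_r1 + F (x_r2 - x_r3) from three distinct partners, crosses it with
#' x_i binomially (one coordinate guaranteed from the mutant), projects the
#' trial into the box, and keeps the trial if its fitness is higher; ties are
#' broken by a fair coin.
#'
#' @param objective function(position) -> scalar fitness (maximized).
#' @param space a [search_space()].
#' @param control a [de_control()].
#' @return an `optimizer_result` (best candidate, non-decreasing best-so-far
#'   trace of length generations + 1, evaluation count, runtime).
#' @export
de_optimize <- function(objective, space, control = de_control()) {
  set.seed(control$seed)
  t0 <- Sys.time()
  d <- nrow(space)
  np <- control$np
  pop <- init_population(np, space)
  fit <- apply(pop, 1, function(p) check_objective_value(objective(p), p))
  evals <- np
  trace <- numeric(control$generations + 1L)
  trace[1L] <- max(fit)
  fit_history <- matrix(NA_real_, np, control$generations + 1L)
  fit_history[, 1L] <- fit
  for (g in seq_len(control$generations)) {
    for (i in seq_len(np)) {
      partners <- sample(setdiff(seq_len(np), i), 3L)
      mutant <- pop[partners[1L], ] +
        control$f * (pop[partners[2L], ] - pop[partners[3L], ])
      jrand <- sample.int(d, 1L)
      cross <- stats::runif(d) < control$cr
      cross[jrand] <- TRUE
      trial <- ifelse(cross, mutant, pop[i, ])
      trial <- project_to_bounds(trial, space)
      ftrial <- check_objective_value(objective(trial), trial)
      evals <- evals + 1L
      replace <- if (ftrial > fit[i]) TRUE
        else if (ftrial < fit[i]) FALSE
        else stats::runif(1) < 0.5
      if (replace) {
        pop[i, ] <- trial
        fit[i] <- ftrial
      }
    }
    trace[g + 1L] <- max(trace[g], max(fit))
    fit_history[, g + 1L] <- fit
  }
  best <- which.max(fit)
  out <- new_optimizer_result("de", pop[best, ], trace[length(trace)], trace,
                              evals,
                              as.numeric(difftime(Sys.time(), t0,
                                                  units = "secs")),
                              space)
  out$fitness_history <- fit_history  # per-member fitness per generation
  out
}

#' Particle swarm control parameters
#'
#' Defaults: inertia weight 0.5, cognitive and social coefficients 2.05,
#' swarm of 10, 10 iterations.
#'
#' @param swarm number of particles.
#' @param iterations iteration budget.
#' @param omega inertia weight (>= 0).
#' @param c1,c2 cognitive and social acceleration coefficients (>= 0).
#' @param seed RNG seed.
#' @export
pso_control <- function(swarm = 10, iterations = 10, omega = 0.5,
                        c1 = 2.05, c2 = 2.05, seed = 1) {
  stopifnot(swarm >= 1, iterations >= 1, omega >= 0, c1 >= 0, c2 >= 0)
  list(swarm = as.integer(swarm), iterations = as.integer(iterations),
       omega = omega, c1 = c1, c2 = c2, seed = seed)
}

#' Maximize an objective with particle swarm optimization
#'
#' Velocity update v <- omega v + c1 r1 (pbest - x) + c2 r2 (gbest - x) with
#' fresh uniform r per component per term, then x <- x + v projected into the
#' box.
#'
#' @inheritParams de_optimize
#' @param control a [pso_control()].
#' @return an `optimizer_result` with trace length iterations + 1.
#' @export
pso_optimize <- function(objective, space, control = pso_control()) {
  set.seed(control$seed)
  t0 <- Sys.time()
  d <- nrow(space)
  n <- control$swarm
  range <- space$upper - space$lower
  pos <- init_population(n, space)
  vel <- 0.1 * matrix(stats::runif(n * d, -range, range), n, d,
                      byrow = TRUE)
  fit <- apply(pos, 1, function(p) check_objective_value(objective(p), p))
  evals <- n
  pbest <- pos
  pbest_fit <- fit
  gbest_i <- which.max(fit)
  gbest <- pos[gbest_i, ]
  gbest_fit <- fit[gbest_i]
  trace <- numeric(control$iterations + 1L)
  trace[1L] <- gbest_fit
  for (it in seq_len(control$iterations)) {
    for (i in seq_len(n)) {
      r1 <- stats::runif(d)
      r2 <- stats::runif(d)
      vel[i, ] <- control$omega * vel[i, ] +
        control$c1 * r1 * (pbest[i, ] - pos[i, ]) +
        control$c2 * r2 * (gbest - pos[i, ])
      pos[i, ] <- project_to_bounds(pos[i, ] + vel[i, ], space)
      f <- check_objective_value(objective(pos[i, ]), pos[i, ])
      evals <- evals + 1L
      if (f > pbest_fit[i]) {
        pbest[i, ] <- pos[i, ]
        pbest_fit[i] <- f
      }
      if (f > gbest_fit) {
        gbest <- pos[i, ]
        gbest_fit <- f
      }
    }
    trace[it + 1L] <- gbest_fit
  }
  new_optimizer_result("pso", gbest, gbest_fit, trace, evals,
                       as.numeric(difftime(Sys.time(), t0, units = "secs")),
                       space)
}

#' Genetic algorithm control parameters
#'
#' Defaults are the tuning settings: population 10, 10 generations, elitism
#' fraction 0.3, random-selection fraction 0.1, per-gene mutation rate 0.5.
#'
#' @param pop_size population size (>= 2).
#' @param generations iteration budget.
#' @param elitism fraction of top-ranked individuals copied unchanged.
#' @param random_selection fraction admitted uniformly at random (keeps
#'   diversity); `elitism + random_selection <= 1`.
#' @param mutation_rate per-gene probability of resampling uniformly within
#'   bounds.
#' @param seed RNG seed.
#' @export
ga_control <- function(pop_size = 10, generations = 10, elitism = 0.3,
                       random_selection = 0.1, mutation_rate = 0.5,
                       seed = 1) {
  stopifnot(pop_size >= 2, generations >= 1,
            elitism >= 0, elitism <= 1,
            random_selection >= 0, random_selection <= 1,
            elitism + random_selection <= 1,
            mutation_rate >= 0, mutation_rate <= 1)
  list(pop_size = as.integer(pop_size), generations = as.integer(generations),
       elitism = elitism, random_selection = random_selection,
       mutation_rate = mutation_rate, seed = seed)
}

#' Maximize an objective with a genetic algorithm
#'
#' Real-coded chromosomes (one gene per search dimension). Each generation:
#' the top `elitism` fraction survives unchanged, a `random_selection`
#' fraction of the current population is admitted uniformly at random, and
#' the remainder are children of rank-weighted parents combined by one-point
#' crossover; every non-elite gene then mutates with probability
#' `mutation_rate` by uniform resampling within its bounds. Population size
#' is invariant; elites keep their cached fitness.
#'
#' @inheritParams de_optimize
#' @param control a [ga_control()].
#' @return an `optimizer_result` with trace length generations + 1.
#' @export
ga_optimize <- function(objective, space, control = ga_control()) {
  set.seed(control$seed)
  t0 <- Sys.time()
  d <- nrow(space)
  np <- control$pop_size
  n_elite <- floor(control$elitism * np + 1e-9)
  n_rand <- floor(control$random_selection * np + 1e-9)
  n_child <- np - n_elite - n_rand
  pop <- init_population(np, space)
  fit <- apply(pop, 1, function(p) check_objective_value(objective(p), p))
  evals <- np
  trace <- numeric(control$generations + 1L)
  trace[1L] <- max(fit)
  fit_history <- matrix(NA_real_, np, control$generations + 1L)
  fit_history[, 1L] <- fit
  for (g in seq_len(control$generations)) {
    ord <- order(fit, decreasing = TRUE)
    pop <- pop[ord, , drop = FALSE]
    fit <- fit[ord]
    # rank weighting: rank 1 (best) gets weight np, worst gets 1
    weights <- rev(seq_len(np))
    pick_parent <- function() sample.int(np, 1L, prob = weights)
    newpop <- matrix(NA_real_, np, d)
    newfit <- rep(NA_real_, np)
    if (n_elite > 0L) {
      newpop[seq_len(n_elite), ] <- pop[seq_len(n_elite), , drop = FALSE]
      newfit[seq_len(n_elite)] <- fit[seq_len(n_elite)]
    }
    slot <- n_elite
    if (n_rand > 0L) {
      idx <- sample.int(np, n_rand, replace = TRUE)
      newpop[slot + seq_len(n_rand), ] <- pop[idx, , drop = FALSE]
      slot <- slot + n_rand
    }
    if (n_child > 0L) {
      for (k in seq_len(n_child)) {
        p1 <- pop[pick_parent(), ]
        p2 <- pop[pick_parent(), ]
        cut <- if (d > 1L) sample.int(d - 1L, 1L) else 1L
        child <- if (cut >= d) p1 else
          c(p1[seq_len(cut)], p2[seq.int(cut + 1L, d)])
        newpop[slot + k, ] <- child
      }
      slot <- slot + n_child
    }
    # mutate non-elites gene-wise by uniform resampling within bounds
    if (np > n_elite && control$mutation_rate > 0) {
      for (i in seq.int(n_elite + 1L, np)) {
        hit <- stats::runif(d) < control$mutation_rate
        if (any(hit)) {
          newpop[i, hit] <- stats::runif(sum(hit), space$lower[hit],
                                         space$upper[hit])
        }
      }
    }
    if (np > n_elite) {
      for (i in seq.int(n_elite + 1L, np)) {
        newfit[i] <- check_objective_value(objective(newpop[i, ]), newpop[i, ])
        evals <- evals + 1L
      }
    }
    pop <- newpop
    fit <- newfit
    trace[g + 1L] <- max(trace[g], max(fit))
    fit_history[, g + 1L] <- fit
  }
  best <- which.max(fit)
  out <- new_optimizer_result("ga", pop[best, ], trace[length(trace)], trace,
                              evals,
                              as.numeric(difftime(Sys.time(), t0,
                                                  units = "secs")),
                              space)
  out$fitness_history <- fit_history
  out
}

#' Simulated annealing control parameters
#'
#' Defaults: 100 iterations (the tuning budget), initial temperature 1,
#' geometric cooling with factor 0.95, perturbation magnitude 0.1 expressed
#' as a fraction of each dimension's box range.
#'
#' @param iterations chain length (>= 1).
#' @param t0 initial temperature (> 0).
#' @param cooling geometric cooling factor in (0,1).
#' @param delta perturbation magnitude as a fraction of each dimension's
#'   range; the step in dimension k is `delta * (upper_k - lower_k) * r`,
#'   r uniform on \[-1,1\].
#' @param seed RNG seed.
#' @export
sa_control <- function(iterations = 100, t0 = 1, cooling = 0.95,
                       delta = 0.1, seed = 1) {
  stopifnot(iterations >= 1, t0 > 0, cooling > 0, cooling < 1, delta > 0)
  list(iterations = as.integer(iterations), t0 = t0, cooling = cooling,
       delta = delta, seed = seed)
}

#' Maximize an objective with simulated annealing
#'
#' Single chain with Metropolis acceptance in maximization form: a
#' perturbed candidate (uniform step per coordinate, projected into the box)
#' is always accepted when it improves the fitness, and accepted with
#' probability exp(delta_f / T) otherwise; the temperature is multiplied by
#' the cooling factor every iteration. The best-ever state is returned, not
#' the final one.
#'
#' @inheritParams de_optimize
#' @param control an [sa_control()].
#' @return an `optimizer_result` with trace length iterations + 1.
#' @export
sa_optimize <- function(objective, space, control = sa_control()) {
  set.seed(control$seed)
  t0 <- Sys.time()
  d <- nrow(space)
  step <- control$delta * (space$upper - space$lower)
  x <- random_position(space)
  fx <- check_objective_value(objective(x), x)
  evals <- 1L
  best_x <- x
  best_f <- fx
  temp <- control$t0
  trace <- numeric(control$iterations + 1L)
  trace[1L] <- best_f
  accepted <- logical(control$iterations)
  deltas <- numeric(control$iterations)
  for (it in seq_len(control$iterations)) {
    cand <- project_to_bounds(x + step * stats::runif(d, -1, 1), space)
    fc <- check_objective_value(objective(cand), cand)
    evals <- evals + 1L
    dfit <- fc - fx
    accept <- dfit > 0 || stats::runif(1) < exp(dfit / temp)
    accepted[it] <- accept
    deltas[it] <- dfit
    if (accept) {
      x <- cand
      fx <- fc
    }
    if (fx > best_f) {
      best_x <- x
      best_f <- fx
    }
    temp <- temp * control$cooling
    trace[it + 1L] <- best_f
  }
  out <- new_optimizer_result("sa", best_x, best_f, trace, evals,
                              as.numeric(difftime(Sys.time(), t0,
                                                  units = "secs")),
                              space)
  out$accepted <- accepted  # per-iteration acceptance log
  out$deltas <- deltas      # fitness change proposed at each iteration
  out
}
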