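#' Box bounds for the swarm optimizer
#'
#' Lower and upper limits of the continuous search box, one pair per
#' dimension.
#'
#' @param lower Numeric vector of lower limits.
#' @param upper Numeric vector of upper limits, same length as `lower`,
#'   strictly above it in every dimension.
#' @return An object of class `cho_bounds`.
#' @examples
#' cho_bounds(rep(-5, 5), rep(5, 5))
#' @export
cho_bounds <- function(lower, upper) {
  lower <- as.numeric(lower)
  upper <- as.numeric(upper)
  if (length(lower) < 1L || length(lower) != length(upper))
    stopf("bounds must have equal length >= 1")
  if (any(!is.finite(lower)) || any(!is.finite(upper)))
    stopf("bounds must be finite")
  if (any(lower >= upper))
    stopf("every lower bound must be strictly below its upper bound")
  structure(list(lower = lower, upper = upper, dim = length(lower)),
            class = "cho_bounds")
}

#' Configuration of the cnidaria-herd optimizer
#'
#' The optimizer combines a jellyfish-style time-control schedule, which
#' decides per iteration whether a member forages with the ocean current
#' (exploration) or moves inside the swarm (exploitation, krill-style
#' induced movement), with diffusion-based boundary repair. All moves are
#' maximization moves; wrap a minimization objective by negation.
#'
#' @param pop_size Number of swarm members (>= 2).
#' @param t_max Iteration budget (>= 1).
#' @param foraging_speed Foraging speed factor applied to the differential
#'   fitness during exploration.
#' @param trial_factor_scale Scale of the trial factor `a`; each exploration
#'   move draws `a = trial_factor_scale * U(0,1)`.
#' @param sensitive_factor Sensitivity of the induced random walk during
#'   exploitation, as a fraction of the box width.
#' @param recursive_range Range of the recursive factor `r3`, a subset of
#'   (0, 1].
#' @param diffusion_max Maximum diffusion speed added during boundary repair.
#' @param epsilon Small positive constant guarding the normalized
#'   displacement denominators.
#' @param inertia Length-2 vector: the adaptive weight is annealed linearly
#'   from `inertia[1]` at the first iteration to `inertia[2]` at the last.
#'   Because the weight multiplies the position directly in the exploration
#'   move (total position coefficient `inertia + 1/2`), values below 1/2
#'   keep the per-move map contractive; see the methods vignette.
#' @param target_effect How the target-direction component of the induced
#'   movement is formed: `"best"` (normalized attraction toward the global
#'   best, mirroring the krill target effect) or `"none"`.
#' @param seed Integer seed; the whole trajectory is reproducible from it.
#' @return An object of class `cho_config`.
#' @export
cho_config <- function(pop_size = 30L, t_max = 200L,
                       foraging_speed = 0.02, trial_factor_scale = 3,
                       sensitive_factor = 0.1, recursive_range = c(0.1, 1),
                       diffusion_max = 0.005, epsilon = 1e-10,
                       inertia = c(0.45, 0.05),
                       target_effect = c("best", "none"), seed = 1L) {
  pop_size <- as.integer(pop_size)
  t_max <- as.integer(t_max)
  if (pop_size < 2L) stopf("pop_size must be >= 2")
  if (t_max < 1L) stopf("t_max must be >= 1")
  assert_scalar_num(epsilon, "epsilon", lower = .Machine$double.xmin)
  assert_scalar_num(diffusion_max, "diffusion_max", lower = 0)
  assert_scalar_num(foraging_speed, "foraging_speed")
  assert_scalar_num(sensitive_factor, "sensitive_factor", lower = 0)
  assert_scalar_num(trial_factor_scale, "trial_factor_scale", lower = 0)
  if (length(recursive_range) != 2L || recursive_range[1] <= 0 ||
      recursive_range[2] > 1 || recursive_range[1] > recursive_range[2])
    stopf("recursive_range must lie within (0, 1]")
  if (length(inertia) != 2L || any(!is.finite(inertia)))
    stopf("inertia must be two finite numbers")
  structure(list(pop_size = pop_size, t_max = t_max,
                 foraging_speed = foraging_speed,
                 trial_factor_scale = trial_factor_scale,
                 sensitive_factor = sensitive_factor,
                 recursive_range = as.numeric(recursive_range),
                 diffusion_max = diffusion_max, epsilon = epsilon,
                 inertia = as.numeric(inertia),
                 target_effect = match.arg(target_effect),
                 seed = as.integer(seed)),
            class = "cho_config")
}

# Linear anneal of the adaptive weight over the iteration budget.
cho_inertia <- function(config, t) {
  if (config$t_max == 1L) return(config$inertia[1])
  w <- config$inertia
  w[1] + (w[2] - w[1]) * (t - 1) / (config$t_max - 1)
}

#' Initialize the swarm
#'
#' Draws `pop_size` positions uniformly inside the bounds, evaluates the
#' objective at each, and sets up the elitist best / current worst
#' bookkeeping. The previous-position memory starts equal to the initial
#' positions (zero initial velocity).
#'
#' @param bounds A [cho_bounds()] object.
#' @param config A [cho_config()] object.
#' @param objective Function mapping a position vector to a finite scalar
#'   fitness; higher is better.
#' @return An object of class `cho_swarm`: positions, previous positions,
#'   fitnesses, previous fitnesses, elitist best position/fitness, current
#'   worst fitness, and the iteration counter.
#' @export
init_swarm <- function(bounds, config, objective) {
  stopifnot(inherits(bounds, "cho_bounds"), inherits(config, "cho_config"))
  n <- config$pop_size
  d <- bounds$dim
  pos <- matrix(runif(n * d), n, d)
  pos <- sweep(sweep(pos, 2, bounds$upper - bounds$lower, "*"),
               2, bounds$lower, "+")
  fit <- apply(pos, 1L, objective)
  if (any(!is.finite(fit)))
    stopf("invalid objective: non-finite fitness at an initial position")
  b <- which.max(fit)
  structure(list(positions = pos, previous_positions = pos,
                 fitnesses = fit, previous_fitnesses = fit,
                 best_position = pos[b, ], best_fitness = fit[b],
                 worst_fitness = min(fit), t = 0L, bounds = bounds),
            class = "cho_swarm")
}

#' Jellyfish time-control function
#'
#' Draws the stochastic schedule value
#' `zeta(t) = |(1 - t/t_max) * (2 r2 - 1)|` with `r2 ~ U(0,1)`. A swarm
#' member explores when a fresh uniform draw exceeds `1 - zeta(t)` and
#' exploits otherwise, so exploration fades as the budget is consumed;
#' `zeta(t_max) = 0` exactly.
#'
#' @param t Current iteration, `1 <= t <= t_max`.
#' @param t_max Iteration budget.
#' @return A value in \[0, 1\].
#' @export
time_control <- function(t, t_max) {
  if (t > t_max) stopf("iteration overflow: t = %d exceeds t_max = %d", t, t_max)
  if (t < 1) stopf("t must be >= 1")
  abs((1 - t / t_max) * (2 * runif(1) - 1))
}

#' Differential fitness factor
#'
#' Signed fitness gap between a member and the elitist global best,
#' `F(B_t) - F(B_G)`; never positive under elitist bookkeeping because the
#' recorded best is the maximum fitness ever observed.
#'
#' @param f_current Fitness of the member.
#' @param f_best Elitist best fitness.
#' @return A scalar `<= 0` whenever `f_best` dominates.
#' @export
differential_fitness <- function(f_current, f_best) {
  if (!is.finite(f_current) || !is.finite(f_best))
    stopf("fitness values must be finite")
  f_current - f_best
}

#' Exploration move (ocean-current foraging)
#'
#' Proposes
#' `B' = VF * alpha_i + w_F * B_t + (B_t + r3 * (B_G - a * mu)) / 2`
#' where `alpha_i` is the differential fitness, `w_F` the annealed adaptive
#' weight, `r3 ~ U(recursive_range)`, `a = trial_factor_scale * U(0,1)` and
#' `mu` the swarm mean position. The result may leave the box; it is the
#' caller's job to repair it with [boundary_step()].
#'
#' @param state A `cho_swarm`.
#' @param i Member index.
#' @param config A [cho_config()].
#' @param t Iteration the move belongs to (defaults to the swarm's next).
#' @return Proposed position vector.
#' @export
exploration_step <- function(state, i, config, t = state$t + 1L) {
  mu <- colMeans(state$positions)
  r3 <- runif(1, config$recursive_range[1], config$recursive_range[2])
  a <- config$trial_factor_scale * runif(1)
  alpha <- differential_fitness(state$fitnesses[i], state$best_fitness)
  wf <- cho_inertia(config, t)
  b <- state$positions[i, ]
  config$foraging_speed * alpha + wf * b +
    (b + r3 * (state$best_position - a * mu)) / 2
}

#' Local induced-movement effect of the swarm neighbours
#'
#' Sums, over every swarm member, the product of its normalized fitness
#' change `(F(B_t) - F(B_{t-1})) / (F(B_worst) - F(B_G))` with its
#' normalized displacement
#' `(B_{t-1} - B_t) / (||B_{t-1}|| + ||B_t|| + eps)`. A flat swarm
#' (`F(B_worst) = F(B_G)`) carries no gradient information and returns the
#' zero vector.
#'
#' @inheritParams exploration_step
#' @return Numeric vector of length `dim`.
#' @export
local_effect <- function(state, config) {
  d <- ncol(state$positions)
  den <- state$worst_fitness - state$best_fitness
  if (den == 0) return(numeric(d))
  fhat <- (state$fitnesses - state$previous_fitnesses) / den
  disp <- state$previous_positions - state$positions
  nrm <- sqrt(rowSums(state$previous_positions^2)) +
    sqrt(rowSums(state$positions^2)) + config$epsilon
  colSums((fhat / nrm) * disp)
}

# Target-direction effect: the same normalized construction with the global
# best standing in for the neighbour.
target_effect <- function(state, i, config) {
  d <- ncol(state$positions)
  if (config$target_effect == "none") return(numeric(d))
  den <- state$worst_fitness - state$best_fitness
  if (den == 0) return(numeric(d))
  fhat <- (state$fitnesses[i] - state$best_fitness) / den
  b <- state$positions[i, ]
  nrm <- sqrt(sum(state$best_position^2)) + sqrt(sum(b^2)) + config$epsilon
  fhat * (state$best_position - b) / nrm
}

#' Exploitation move (krill-style induced movement)
#'
#' Proposes
#' `B' = B_t + gamma * r4 * (U_up - U_low) * (1 - t/t_max)^2
#'       + (B_G * phi_B + w_n * (B_t - B_{t-1})) / 2`
#' with `r4 ~ U(0,1)` drawn per dimension and
#' `phi_B = phi_local + phi_target`. The random-walk amplitude is annealed
#' quadratically with the remaining budget — faster than the exploration
#' rate decays, so the drift accumulated between exploration events
#' vanishes — and the adaptive weight rides on the difference velocity;
#' late-stage exploitation therefore degenerates into local refinement.
#' See the methods vignette for the reasoning.
#'
#' @inheritParams exploration_step
#' @return Proposed position vector.
#' @export
exploitation_step <- function(state, i, config, t = state$t + 1L) {
  b <- state$positions[i, ]
  bounds <- state$bounds
  d <- length(b)
  r4 <- runif(d)
  anneal <- (1 - t / config$t_max)^2
  phi <- local_effect(state, config) + target_effect(state, i, config)
  wn <- cho_inertia(config, t)
  vel <- b - state$previous_positions[i, ]
  b + config$sensitive_factor * r4 * (bounds$upper - bounds$lower) * anneal +
    (state$best_position * phi + wn * vel) / 2
}

#' Diffusion-based boundary repair
#'
#' Out-of-bounds coordinates are wrapped to the opposite face with a small
#' diffusion perturbation: above the box, `B' = (B - U_up) + U_low +
#' D_max * delta`; below it, `B' = (B - U_low) + U_up + D_max * delta`,
#' with `delta ~ U(-1, 1)` per offending coordinate. A final clamp
#' guarantees containment even for proposals more than one box-width out.
#'
#' @param position Numeric position vector.
#' @param bounds A [cho_bounds()].
#' @param config A [cho_config()].
#' @return A position inside the bounds.
#' @export
boundary_step <- function(position, bounds, config) {
  p <- position
  hi <- p > bounds$upper
  lo <- p < bounds$lower
  if (any(hi))
    p[hi] <- (p[hi] - bounds$upper[hi]) + bounds$lower[hi] +
      config$diffusion_max * runif(sum(hi), -1, 1)
  if (any(lo))
    p[lo] <- (p[lo] - bounds$lower[lo]) + bounds$upper[lo] +
      config$diffusion_max * runif(sum(lo), -1, 1)
  pmin(pmax(p, bounds$lower), bounds$upper)
}

#' Run the cnidaria-herd optimizer
#'
#' Maximizes `objective` over the box for `t_max` iterations. Each
#' iteration draws the time-control value once, then moves every member by
#' exploration or exploitation according to its own phase draw, repairs the
#' proposal with [boundary_step()], and evaluates it. A proposal with
#' non-finite fitness is rejected (the member keeps its position) with a
#' warning. The global best is elitist: it is never replaced by a worse
#' candidate, so the best-fitness history is monotone non-decreasing.
#'
#' @param objective Fitness function (higher is better).
#' @param bounds A [cho_bounds()].
#' @param config A [cho_config()]; `config$seed` fixes the full trajectory.
#' @return An object of class `cho_result` with elements `best_position`,
#'   `best_fitness`, `history` (tibble: iteration, best_fitness,
#'   mean_fitness, zeta), `evaluations`, and the `config`/`bounds` used.
#' @examples
#' sphere <- function(b) -sum(b^2)
#' res <- cho_optimize(sphere, cho_bounds(rep(-5, 2), rep(5, 2)),
#'                     cho_config(pop_size = 10, t_max = 25, seed = 1))
#' res$best_fitness
#' @export
cho_optimize <- function(objective, bounds, config = cho_config()) {
  stopifnot(inherits(bounds, "cho_bounds"), inherits(config, "cho_config"))
  with_seed(config$seed, {
    state <- init_swarm(bounds, config, objective)
    n <- config$pop_size
    hist_best <- hist_mean <- hist_zeta <- numeric(config$t_max)
    for (t in seq_len(config$t_max)) {
      zeta <- time_control(t, config$t_max)
      new_pos <- state$positions
      new_fit <- state$fitnesses
      for (i in seq_len(n)) {
        explore <- runif(1) > 1 - zeta
        cand <- if (explore) exploration_step(state, i, config, t)
                else exploitation_step(state, i, config, t)
        cand <- boundary_step(cand, bounds, config)
        f <- objective(cand)
        if (!is.finite(f)) {
          warnf("non-finite fitness at iteration %d; candidate rejected", t)
        } else {
          new_pos[i, ] <- cand
          new_fit[i] <- f
        }
      }
      state$previous_positions <- state$positions
      state$previous_fitnesses <- state$fitnesses
      state$positions <- new_pos
      state$fitnesses <- new_fit
      state$worst_fitness <- min(new_fit)
      b <- which.max(new_fit)
      if (new_fit[b] > state$best_fitness) {
        state$best_fitness <- new_fit[b]
        state$best_position <- new_pos[b, ]
      }
      state$t <- t
      hist_best[t] <- state$best_fitness
      hist_mean[t] <- mean(new_fit)
      hist_zeta[t] <- zeta
    }
    structure(list(best_position = state$best_position,
                   best_fitness = state$best_fitness,
                   history = tibble::tibble(iteration = seq_len(config$t_max),
                                            best_fitness = hist_best,
                                            mean_fitness = hist_mean,
                                            zeta = hist_zeta),
                   evaluations = n * (config$t_max + 1L),
                   config = config, bounds = bounds,
                   final_state = state),
              class = "cho_result")
  })
}

#' @export
print.cho_result <- function(x, ...) {
  cat("<cho_result>\n")
  cat(sprintf("  dimensions : %d\n", x$bounds$dim))
  cat(sprintf("  iterations : %d (pop %d, %d evaluations)\n",
              x$config$t_max, x$config$pop_size, x$evaluations))
  cat(sprintf("  best fitness: %.6g\n", x$best_fitness))
  invisible(x)
}

#' Write an optimizer trace to CSV
#'
#' @param result A `cho_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cho_trace <- function(result, path) {
  stopifnot(inherits(result, "cho_result"))
  write.csv(result$history[, c("iteration", "best_fitness", "mean_fitness")],
            path, row.names = FALSE)
  invisible(path)
}
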