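sphere <- function(b) -sum(b^2)

test_that("swarm initialization respects bounds, evaluates fitness, and is seeded", {
  b <- cho_bounds(rep(0, 3), rep(1, 3))
  cfg <- cho_config(pop_size = 5, t_max = 10, seed = 42)
  st <- nodulekit:::with_seed(42, init_swarm(b, cfg, sphere))
  expect_equal(dim(st$positions), c(5L, 3L))
  expect_true(all(st$positions >= 0 & st$positions <= 1))
  expect_identical(st$previous_positions, st$positions)

  b2 <- cho_bounds(c(-1, -1), c(1, 1))
  st2 <- nodulekit:::with_seed(1, init_swarm(b2, cfg, sphere))
  expect_lte(st2$best_fitness, 0)
  expect_gte(st2$best_fitness, -2)
  expect_equal(st2$best_fitness, max(st2$fitnesses))
  expect_equal(st2$worst_fitness, min(st2$fitnesses))

  st3a <- nodulekit:::with_seed(7, init_swarm(b, cfg, sphere))
  st3b <- nodulekit:::with_seed(7, init_swarm(b, cfg, sphere))
  expect_identical(st3a$positions, st3b$positions)

  expect_error(init_swarm(b, cfg, function(x) NA_real_), "invalid objective")
})

test_that("time control decays to zero, stays in [0,1], and overflows past the budget", {
  expect_equal(nodulekit:::with_seed(1, time_control(100, 100)), 0)
  draws <- nodulekit:::with_seed(2, replicate(1e4, time_control(1, 1e9)))
  expect_true(all(draws >= 0 & draws <= 1))
  half <- nodulekit:::with_seed(3, replicate(1e4, time_control(50, 100)))
  expect_true(all(half >= 0 & half <= 0.5))
  expect_error(time_control(101, 100), "iteration overflow")
})

test_that("differential fitness is the signed gap and never positive under elitism", {
  expect_equal(differential_fitness(0.4, 0.4), 0)
  expect_equal(differential_fitness(0.8, 0.9), -0.1)
  st <- nodulekit:::with_seed(5, init_swarm(cho_bounds(rep(-2, 4), rep(2, 4)),
                                            cho_config(pop_size = 12, t_max = 5),
                                            sphere))
  alphas <- vapply(st$fitnesses, differential_fitness,
                   f_best = st$best_fitness, numeric(1))
  expect_true(all(alphas <= 0))
})

test_that("exploration move matches the hand-expanded update on a collapsed swarm", {
  # swarm at a single point P: mu = BG = B = P and alpha = 0; with weight 1,
  # trial factor 0 and fixed r3 = r the move is P * (3 + r) / 2
  p <- c(0.3, -0.2, 0.5)
  r <- 0.4
  cfg <- cho_config(pop_size = 3, t_max = 10, inertia = c(1, 1),
                    trial_factor_scale = 0, recursive_range = c(r, r))
  st <- structure(list(positions = rbind(p, p, p),
                       previous_positions = rbind(p, p, p),
                       fitnesses = rep(1, 3), previous_fitnesses = rep(1, 3),
                       best_position = p, best_fitness = 1,
                       worst_fitness = 1, t = 0L,
                       bounds = cho_bounds(rep(-5, 3), rep(5, 3))),
                  class = "cho_swarm")
  out <- nodulekit:::with_seed(1, exploration_step(st, 1, cfg, t = 1))
  expect_equal(out, p * (3 + r) / 2, tolerance = 1e-12, ignore_attr = TRUE)

  # zeroed coefficients leave only B/2
  cfg0 <- cho_config(pop_size = 3, t_max = 10, inertia = c(0, 0),
                     foraging_speed = 0, trial_factor_scale = 0,
                     recursive_range = c(1e-9, 1e-9))
  st$fitnesses <- c(0.2, 0.9, 0.5)
  st$best_fitness <- 0.9
  out0 <- nodulekit:::with_seed(1, exploration_step(st, 1, cfg0, t = 1))
  expect_equal(out0, p / 2, tolerance = 1e-6, ignore_attr = TRUE)

  # determinism under a fixed seed
  a <- nodulekit:::with_seed(9, exploration_step(st, 2, cfg, t = 3))
  b <- nodulekit:::with_seed(9, exploration_step(st, 2, cfg, t = 3))
  expect_identical(a, b)
})

test_that("local effect sums normalized neighbour contributions and degrades to zero", {
  cfg <- cho_config(pop_size = 3, t_max = 5, epsilon = 1e-10)
  pos <- rbind(c(1, 0), c(0, 1), c(1, 1))
  prev <- rbind(c(0.5, 0), c(0, 2), c(1, 1))
  fit <- c(0.9, 0.4, 0.6)
  pfit <- c(0.8, 0.5, 0.6)
  st <- list(positions = pos, previous_positions = prev,
             fitnesses = fit, previous_fitnesses = pfit,
             best_fitness = 0.9, worst_fitness = 0.4)
  # hand-summed: sum_j (F_j - F_j_prev)/(F_worst - F_best) *
  #              (B_prev_j - B_j)/(|B_prev_j| + |B_j| + eps)
  den <- 0.4 - 0.9
  expected <- colSums(do.call(rbind, lapply(1:3, function(j) {
    ((fit[j] - pfit[j]) / den) * (prev[j, ] - pos[j, ]) /
      (sqrt(sum(prev[j, ]^2)) + sqrt(sum(pos[j, ]^2)) + 1e-10)
  })))
  expect_equal(local_effect(st, cfg), expected, tolerance = 1e-12)

  # stationary members contribute nothing
  st_stat <- st
  st_stat$previous_positions <- pos
  st_stat$previous_fitnesses <- fit
  expect_equal(local_effect(st_stat, cfg), c(0, 0))

  # flat swarm: no gradient information, no division by zero
  st_flat <- st
  st_flat$fitnesses <- st_flat$previous_fitnesses <- rep(0.5, 3)
  st_flat$best_fitness <- st_flat$worst_fitness <- 0.5
  expect_equal(local_effect(st_flat, cfg), c(0, 0))
})

test_that("exploitation move reduces to identity and obeys its coefficient algebra", {
  p <- c(0.4, -0.1)
  prev <- c(0.1, 0.3)
  bounds <- cho_bounds(c(-5, -5), c(5, 5))
  st <- list(positions = rbind(p, p + 1), previous_positions = rbind(prev, p),
             fitnesses = c(0.5, 0.5), previous_fitnesses = c(0.5, 0.5),
             best_position = p, best_fitness = 0.5, worst_fitness = 0.5,
             t = 0L, bounds = bounds)
  # flat swarm makes phi_B = 0; gamma = 0 and zero weight leave B_t
  cfg <- cho_config(pop_size = 2, t_max = 10, sensitive_factor = 0,
                    inertia = c(0, 0))
  expect_equal(nodulekit:::with_seed(1, exploitation_step(st, 1, cfg, t = 1)),
               p, ignore_attr = TRUE)
  # weight 2 on the difference velocity adds (B_t - B_{t-1})
  cfg2 <- cho_config(pop_size = 2, t_max = 10, sensitive_factor = 0,
                     inertia = c(2, 2))
  expect_equal(nodulekit:::with_seed(1, exploitation_step(st, 1, cfg2, t = 1)),
               p + (p - prev), ignore_attr = TRUE)
})

test_that("boundary repair wraps out-of-bounds coordinates and always lands inside", {
  b <- cho_bounds(c(0, 0), c(1, 1))
  cfg <- cho_config(pop_size = 2, t_max = 2, diffusion_max = 0)
  expect_equal(boundary_step(c(0.3, 0.7), b, cfg), c(0.3, 0.7))
  expect_equal(boundary_step(c(1.2, 0.5), b, cfg)[1], 0.2, tolerance = 1e-12)
  expect_equal(boundary_step(c(0.5, -0.3), b, cfg)[2], 0.7, tolerance = 1e-12)

  cfg_d <- cho_config(pop_size = 2, t_max = 2, diffusion_max = 0.005)
  bad <- nodulekit:::with_seed(4, matrix(runif(2e4, -3, 4), ncol = 2))
  out <- nodulekit:::with_seed(5, t(apply(bad, 1, boundary_step, bounds = b,
                                          config = cfg_d)))
  expect_true(all(out >= 0 & out <= 1))
})

test_that("the optimizer is elitist, bounded, deterministic, and handles edge budgets", {
  b <- cho_bounds(rep(-5, 3), rep(5, 3))
  seen_out_of_bounds <- FALSE
  watched <- function(x) {
    if (any(x < -5 | x > 5)) seen_out_of_bounds <<- TRUE
    -sum(x^2)
  }
  res <- cho_optimize(watched, b, cho_config(pop_size = 8, t_max = 30, seed = 3))
  expect_false(seen_out_of_bounds)
  expect_true(all(diff(res$history$best_fitness) >= 0))

  res2 <- cho_optimize(sphere, b, cho_config(pop_size = 8, t_max = 30, seed = 3))
  expect_identical(res$history$best_fitness, res2$history$best_fitness)
  expect_identical(res$best_position, res2$best_position)

  res1 <- cho_optimize(sphere, b, cho_config(pop_size = 6, t_max = 1, seed = 1))
  expect_equal(nrow(res1$history), 1L)

  flat <- cho_optimize(function(x) 3.5, b,
                       cho_config(pop_size = 5, t_max = 5, seed = 2))
  expect_equal(flat$best_fitness, 3.5)
})

test_that("non-finite candidates are rejected with the previous position kept", {
  b <- cho_bounds(c(0, 0), c(1, 1))
  hostile <- local({
    calls <- 0
    function(x) {
      calls <<- calls + 1
      if (calls > 6 && calls %% 5 == 0) return(NaN)
      -sum(x^2)
    }
  })
  ws <- capture_warnings(
    res <- cho_optimize(hostile, b, cho_config(pop_size = 6, t_max = 4, seed = 1)))
  expect_true(all(grepl("non-finite", ws)))
  expect_gt(length(ws), 0)
  expect_true(is.finite(res$best_fitness))
  expect_true(all(is.finite(res$final_state$fitnesses)))
})

test_that("tidiers and the trace writer expose the optimization history", {
  res <- cho_optimize(sphere, cho_bounds(c(-1, -1), c(1, 1)),
                      cho_config(pop_size = 5, t_max = 8, seed = 1))
  expect_identical(tidy(res), res$history)
  g <- glance(res)
  expect_equal(g$best_fitness, res$best_fitness)
  expect_equal(g$evaluations, 5 * 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cho_trace(res, path)
  tr <- read.csv(path)
  expect_equal(nrow(tr), 8)
  expect_equal(tr$best_fitness, res$history$best_fitness)
  expect_s3_class(autoplot(res), "ggplot")
})
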