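test_that("e_score follows the scoring formula", {
  expect_equal(e_score(energy_pair(-10, -5), energy_pair(-10, -5),
                       score_config(alpha = 0)), 0)
  expect_equal(e_score(energy_pair(-50, -30), energy_pair(-60, -40),
                       score_config(alpha = 2)), 180)
  for (a in c(0, 1, 2, 5))
    expect_equal(e_score(energy_pair(0, 0), energy_pair(-10, -5),
                         score_config(alpha = a)), 15)
  # with alpha = 0 the score is exactly the energy difference
  expect_equal(e_score(energy_pair(-3, 1), energy_pair(2, 4),
                       score_config(alpha = 0)), -8)
  # current = previous leaves only the magnitude term
  expect_equal(e_score(energy_pair(-7, -1), energy_pair(-7, -1),
                       score_config(alpha = 2)), 16)
})

test_that("sample_population stays in the ball, is seed-reproducible, and
           has the uniform-ball mean norm", {
  cfg <- de_config(population_size = 1e5, seed = NULL)
  set.seed(11)
  v <- sample_population(cfg)
  nrm <- sqrt(rowSums(v^2))
  expect_true(all(nrm <= cfg$max_vector_length + 1e-12))
  # E||v|| = 3R/4 for the uniform ball; sd of the mean = sd(nrm)/sqrt(n)
  expect_lt(abs(mean(nrm) - 0.75 * cfg$max_vector_length),
            3 * stats::sd(nrm) / sqrt(length(nrm)))

  set.seed(7)
  a <- sample_population(de_config(population_size = 50))
  set.seed(7)
  b <- sample_population(de_config(population_size = 50))
  expect_identical(a, b)
})

test_that("de_minimize recovers interior and boundary quadratic minima", {
  vstar <- c(0.2, -0.1, 0.3)
  cfg <- de_config(population_size = 50, iterations = 100)
  for (seed in 1:10) {
    cfg$seed <- seed
    res <- de_minimize(function(v) sum((v - vstar)^2), cfg)
    expect_lt(sqrt(sum((res$vector - vstar)^2)), 1e-3)
  }
  # minimizer outside the ball -> projection onto the boundary
  w <- c(0.9, 0.4, -0.2)
  wproj <- w / sqrt(sum(w^2)) * cfg$max_vector_length
  for (seed in 1:10) {
    cfg$seed <- seed
    res <- de_minimize(function(v) sum((v - w)^2), cfg)
    expect_lt(sqrt(sum((res$vector - wproj)^2)), 1e-3)
  }
})

test_that("de_minimize is monotone, feasible, and treats non-finite values
           as +Inf", {
  cfg <- de_config(population_size = 30, iterations = 50, seed = 2)
  res <- de_minimize(function(v) sum(v^2) + sin(10 * v[1]), cfg)
  expect_true(all(diff(res$trace) <= 1e-12))
  expect_lte(sqrt(sum(res$vector^2)), cfg$max_vector_length + 1e-12)

  # constant objective: best value is that constant, vector feasible
  res <- de_minimize(function(v) 4.2, de_config(20, iterations = 5,
                                                seed = 1))
  expect_equal(res$value, 4.2)
  expect_lte(sqrt(sum(res$vector^2)), 0.7 + 1e-12)

  # NaN region never wins
  res <- de_minimize(function(v) if (v[1] > 0) NaN else sum(v^2),
                     de_config(40, iterations = 60, seed = 3))
  expect_true(is.finite(res$value))
  expect_lte(res$vector[1], 0)
})

test_that("vectorized and scalar objectives agree", {
  vstar <- c(-0.1, 0.2, 0)
  cfg <- de_config(population_size = 40, iterations = 50, seed = 5)
  a <- de_minimize(function(v) sum((v - vstar)^2), cfg)
  b <- de_minimize(function(V) rowSums(sweep(V, 2, vstar)^2), cfg,
                   vectorized = TRUE)
  expect_identical(a$vector, b$vector)
  expect_identical(a$trace, b$trace)
})

# grid oracle: best direction by exhaustive scoring of ~1e4 probe points
grid_best_direction <- function(system, prev, alpha = 2,
                                energy_cfg = energy_config(), rmax = 0.7) {
  dirs <- depull:::fibonacci_sphere(2500, 1)
  best <- NULL
  best_s <- Inf
  for (r in rmax * c(0.35, 0.65, 0.86, 1)) {
    em <- depull:::nb_energy_translations(system, dirs * r, energy_cfg)
    s <- depull:::e_score_batch(em, energy_total(prev), alpha)
    if (min(s) < best_s) {
      best_s <- min(s)
      best <- dirs[which.min(s), ]
    }
  }
  best
}

test_that("find_direction points away from a strongly repulsive contact", {
  # pure Coulomb repulsion 0.4 nm away; the probe ball is kept at 0.5 nm so
  # every probe stays within the cutoff and the score is monotone in the
  # separation - the minimum is the straight-away direction
  lig <- atom_table(2, "L", 0, 0, 0, charge = 1, role = "ligand")
  rec <- atom_table(1, "R", -0.4, 0, 0, charge = 1)
  sys <- molecular_system(rec, lig, pulled_atom_id = 2)
  prev <- compute_nonbonded(sys)
  away <- c(1, 0, 0)
  set.seed(1)
  res <- find_direction(sys, prev,
                        de_config(100, max_vector_length = 0.5,
                                  iterations = 60))
  expect_false(res$degenerate)
  expect_gte(sum(res$direction * away), 0.9)
  # exhaustive grid oracle agrees
  g <- grid_best_direction(sys, prev, rmax = 0.5)
  expect_gte(sum(g * away), 0.9)
})

test_that("zero field within the probe ball raises the degenerate flag", {
  lig <- atom_table(2, "L", 0, 0, 0, sigma = 0.3, epsilon = 1,
                    role = "ligand")
  rec <- atom_table(1, "R", 10, 0, 0, sigma = 0.3, epsilon = 1)
  sys <- molecular_system(rec, lig, pulled_atom_id = 2)
  set.seed(1)
  res <- find_direction(sys, compute_nonbonded(sys),
                        de_config(30, iterations = 10))
  expect_true(res$degenerate)
  expect_null(res$direction)
})

test_that("with alpha = 0 the search dives into a displaced attractive
           well", {
  lig <- atom_table(2, "L", 0, 0, 0, sigma = 0.25, epsilon = 1,
                    role = "ligand")
  rec <- atom_table(1, "R", 0.55, 0, 0, sigma = 0.35, epsilon = 4)
  sys <- molecular_system(rec, lig, pulled_atom_id = 2)
  prev <- compute_nonbonded(sys)
  set.seed(2)
  res <- find_direction(sys, prev, de_config(100, iterations = 60),
                        score_config(alpha = 0))
  # the minimum set is the LJ-minimum shell around the attractive atom:
  # the best probe sits at the well bottom, on the well's side of the box
  expect_gte(res$direction[1], 0.5)
  sij <- (0.25 + 0.35) / 2
  eij <- sqrt(1 * 4)
  d_best <- sqrt(sum((res$best_vector - c(0.55, 0, 0))^2))
  expect_equal(d_best, 2^(1 / 6) * sij, tolerance = 0.02)
  expect_equal(energy_total(res$best_energy), -eij, tolerance = 0.01)
  g <- grid_best_direction(sys, prev, alpha = 0)
  expect_gte(g[1], 0.5)
})

test_that("find_direction is reproducible given the seed", {
  sys <- random_system(3, 20, seed = 4)
  sys$pulled_atom_id <- sys$ligand$atom_id[1]
  prev <- compute_nonbonded(sys)
  cfg <- de_config(40, iterations = 20, seed = 99)
  a <- find_direction(sys, prev, cfg)
  b <- find_direction(sys, prev, cfg)
  expect_identical(a$best_vector, b$best_vector)
  expect_identical(a$best_score, b$best_score)
})
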