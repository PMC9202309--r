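#' Scoring configuration for the direction search
#'
#' The per-interval objective is
#' `E_score = (E_elec + E_vdw)_current - (E_elec + E_vdw)_previous +
#'  alpha * |(E_elec + E_vdw)_current|`.
#' The alpha term keeps the search from parking in a deep local energy
#' minimum (pure energy *decrease* would reward staying put) and penalizes
#' receptor overlap; alpha = 2 balances capturing rare paths against the
#' ligand getting stuck.
#'
#' @param alpha dimensionless weight (>= 0), default 2.
#' @export
score_config <- function(alpha = 2) {
  stopifnot(alpha >= 0)
  structure(list(alpha = alpha), class = "score_config")
}

#' Differential evolution configuration
#'
#' Defaults follow the protocol's recommended parameter set: 3000 candidate
#' translation vectors of length at most 0.7 nm (7 Angstrom), 100
#' generations, crossover probability 0.9 and differential weight 0.5
#' (the classic Storn-Price values).
#'
#' @param population_size number of candidate vectors (>= 4).
#' @param max_vector_length feasible ball radius, nm.
#' @param iterations DE generations per interval.
#' @param crossover_prob CR in `[0, 1]`.
#' @param diff_weight F (> 0).
#' @param seed optional integer; when non-NULL the search seeds R's RNG.
#' @export
de_config <- function(population_size = 3000, max_vector_length = 0.7,
                      iterations = 100, crossover_prob = 0.9,
                      diff_weight = 0.5, seed = NULL) {
  stopifnot(population_size >= 4, max_vector_length > 0, iterations >= 1,
            crossover_prob >= 0, crossover_prob <= 1, diff_weight > 0)
  structure(list(population_size = as.integer(population_size),
                 max_vector_length = max_vector_length,
                 iterations = as.integer(iterations),
                 crossover_prob = crossover_prob, diff_weight = diff_weight,
                 seed = seed),
            class = "de_config")
}

#' Direction-search score
#'
#' @param current,previous `energy_pair`s for the probe pose and for the
#'   pose at the end of the last pulling interval.
#' @param cfg a [score_config()].
#' @return score in kJ/mol (non-finite energies map to +Inf).
#' @export
e_score <- function(current, previous, cfg = score_config()) {
  cur <- energy_total(current)
  prev <- energy_total(previous)
  s <- cur - prev + cfg$alpha * abs(cur)
  if (!is.finite(s)) Inf else s
}

# vectorized over rows of a P x 2 energy matrix
e_score_batch <- function(energy_mat, previous_total, alpha) {
  cur <- energy_mat[, 1] + energy_mat[, 2]
  s <- cur - previous_total + alpha * abs(cur)
  s[!is.finite(s)] <- Inf
  s
}

#' Sample candidate translation vectors
#'
#' Draws `population_size` vectors uniformly from the solid ball of radius
#' `max_vector_length` (uniform direction, radius ~ R * U^(1/3)).
#'
#' @param cfg a [de_config()].
#' @return population_size x 3 matrix, nm.
#' @export
sample_population <- function(cfg = de_config()) {
  n <- cfg$population_size
  g <- matrix(stats::rnorm(3 * n), n, 3)
  nrm <- sqrt(rowSums(g^2))
  nrm[nrm == 0] <- 1
  radii <- cfg$max_vector_length * stats::runif(n)^(1 / 3)
  g * (radii / nrm)
}

# rescale rows with norm > rmax onto the ball boundary
clip_to_ball <- function(v, rmax) {
  nrm <- sqrt(rowSums(v^2))
  bad <- nrm > rmax
  if (any(bad)) v[bad, ] <- v[bad, , drop = FALSE] * (rmax / nrm[bad])
  v
}

# r1, r2, r3 per row: mutually distinct and != row index
pick_partners <- function(n) {
  r <- matrix(sample.int(n, 3 * n, replace = TRUE), n, 3)
  i <- seq_len(n)
  repeat {
    bad <- r[, 1] == i | r[, 2] == i | r[, 3] == i |
      r[, 1] == r[, 2] | r[, 1] == r[, 3] | r[, 2] == r[, 3]
    if (!any(bad)) return(r)
    r[bad, ] <- sample.int(n, 3 * sum(bad), replace = TRUE)
  }
}

#' Minimize an objective over the feasible ball with DE/rand/1/bin
#'
#' Classic rand/1/bin: mutant `x_r1 + F (x_r2 - x_r3)` with r1, r2, r3
#' distinct and different from the target; binomial crossover with one
#' guaranteed mutant coordinate; greedy selection with ties keeping the
#' target. Trial vectors outside the ball are radially rescaled onto the
#' boundary. Runs exactly `iterations` generations and returns the
#' population best (lowest index on exact ties).
#'
#' @param objective either a scalar function of a 3-vector, or (with
#'   `vectorized = TRUE`) a function mapping an n x 3 matrix to n values.
#'   Non-finite objective values are treated as +Inf.
#' @param cfg a [de_config()]; `cfg$seed`, when set, seeds the RNG.
#' @param vectorized whether `objective` is batch-vectorized.
#' @return list with `vector` (best 3-vector), `value` (its objective),
#'   and `trace` (best value after each generation).
#' @export
de_minimize <- function(objective, cfg = de_config(), vectorized = FALSE) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  evalf <- if (vectorized) {
    function(v) {
      val <- objective(v)
      val[!is.finite(val)] <- Inf
      val
    }
  } else {
    function(v) {
      val <- apply(v, 1, objective)
      val[!is.finite(val)] <- Inf
      val
    }
  }
  n <- cfg$population_size
  pop <- sample_population(cfg)
  val <- evalf(pop)
  trace <- numeric(cfg$iterations)
  for (g in seq_len(cfg$iterations)) {
    r <- pick_partners(n)
    mutant <- pop[r[, 1], , drop = FALSE] +
      cfg$diff_weight * (pop[r[, 2], , drop = FALSE] -
                           pop[r[, 3], , drop = FALSE])
    cross <- matrix(stats::runif(3 * n) < cfg$crossover_prob, n, 3)
    cross[cbind(seq_len(n), sample.int(3, n, replace = TRUE))] <- TRUE
    trial <- ifelse(cross, mutant, pop)
    trial <- clip_to_ball(trial, cfg$max_vector_length)
    tval <- evalf(trial)
    sel <- tval < val  # strict: ties keep the incumbent target
    if (any(sel)) {
      pop[sel, ] <- trial[sel, , drop = FALSE]
      val[sel] <- tval[sel]
    }
    trace[g] <- min(val)
  }
  best <- which.min(val)  # which.min takes the lowest index on ties
  fin <- val[is.finite(val)]
  spread <- if (length(fin)) diff(range(fin)) else 0
  list(vector = pop[best, ], value = val[best], trace = trace,
       value_spread = spread)
}

#' Find the pulling direction for one interval
#'
#' Minimizes `e_score` over rigid ligand translations inside the probe ball
#' with differential evolution and returns the unit direction of the best
#' translation. When the best translation is (numerically) the null vector
#' the result is flagged degenerate and carries no direction; the caller
#' reuses the previous interval's direction in that case.
#'
#' @param system a `molecular_system` (receptor held fixed).
#' @param previous_energy `energy_pair` of the current (untranslated) pose.
#' @param de_cfg,score_cfg,energy_cfg configurations.
#' @return list of class `direction_result`: `direction` (unit 3-vector or
#'   NULL), `best_vector`, `best_score`, `best_energy`, `degenerate`.
#' @export
find_direction <- function(system, previous_energy, de_cfg = de_config(),
                           score_cfg = score_config(),
                           energy_cfg = energy_config()) {
  prev_total <- energy_total(previous_energy)
  objective <- function(v) {
    em <- nb_energy_translations(system, v, energy_cfg)
    e_score_batch(em, prev_total, score_cfg$alpha)
  }
  res <- de_minimize(objective, de_cfg, vectorized = TRUE)
  nrm <- vec_norm(res$vector)
  # degenerate: null best translation, or a flat score landscape (e.g. no
  # receptor atom within cutoff of any probe pose) that carries no signal
  degenerate <- nrm < 1e-6 || res$value_spread == 0
  be <- compute_nonbonded(system, lig_coords(system) +
                            matrix(res$vector, nrow(system$ligand), 3,
                                   byrow = TRUE), energy_cfg)
  structure(list(direction = if (degenerate) NULL else res$vector / nrm,
                 best_vector = res$vector, best_score = res$value,
                 best_energy = be, degenerate = degenerate,
                 trace = res$trace),
            class = "direction_result")
}
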