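#' Pathfinder configuration
#'
#' Orchestration of the N-interval loop: one DE direction search (or the
#' fixed direction in unidirectional mode) followed by one pulling interval,
#' repeated until the ligand exits, gets stuck, or `max_intervals` is
#' reached. The exit criterion is zero truncated nonbonded contact - the
#' minimum ligand-receptor atom distance exceeding `exit_min_distance`
#' (cutoff + 0.2 nm buffer by default) - sustained for `exit_consecutive`
#' consecutive interval ends; once first satisfied the direction is kept
#' unchanged for the confirmation intervals.
#'
#' @param max_intervals maximum number of intervals N (tau_sim / tau).
#' @param exit_min_distance nm; default cutoff + 0.2.
#' @param exit_consecutive consecutive interval ends beyond the distance.
#' @param stuck_min_displacement nm of ligand-CoM motion per interval below
#'   which an interval counts as stuck.
#' @param stuck_consecutive consecutive stuck intervals before giving up.
#' @param mode `"multidirectional"` (DE search each interval) or
#'   `"unidirectional"` (a user-supplied fixed direction, e.g. from an
#'   external straight-direction method).
#' @param fixed_direction unit 3-vector, required iff unidirectional.
#' @param energy_cutoff used for the default `exit_min_distance`.
#' @export
pathfinder_config <- function(max_intervals = 60, exit_min_distance = NULL,
                              exit_consecutive = 2,
                              stuck_min_displacement = 0.01,
                              stuck_consecutive = 5,
                              mode = c("multidirectional", "unidirectional"),
                              fixed_direction = NULL, energy_cutoff = 1.0) {
  mode <- match.arg(mode)
  if (is.null(exit_min_distance)) exit_min_distance <- energy_cutoff + 0.2
  stopifnot(max_intervals >= 1, exit_min_distance > 0,
            exit_consecutive >= 1, stuck_consecutive >= 1)
  if (mode == "unidirectional") {
    if (is.null(fixed_direction))
      stop("unidirectional mode requires fixed_direction")
    fixed_direction <- unit_vec(fixed_direction)
  }
  structure(list(max_intervals = as.integer(max_intervals),
                 exit_min_distance = exit_min_distance,
                 exit_consecutive = as.integer(exit_consecutive),
                 stuck_min_displacement = stuck_min_displacement,
                 stuck_consecutive = as.integer(stuck_consecutive),
                 mode = mode, fixed_direction = fixed_direction),
            class = "pathfinder_config")
}

#' Exit check on a history of interval-end contact distances
#'
#' TRUE when the last `exit_consecutive` entries of `min_dist_history` all
#' exceed `exit_min_distance` (zero truncated nonbonded contact sustained
#' over consecutive interval ends).
#'
#' @param min_dist_history numeric vector of minimum ligand-receptor atom
#'   distances at successive interval ends, nm.
#' @param cfg a [pathfinder_config()].
#' @export
exit_check <- function(min_dist_history, cfg = pathfinder_config()) {
  k <- cfg$exit_consecutive
  n <- length(min_dist_history)
  n >= k && all(min_dist_history[(n - k + 1):n] > cfg$exit_min_distance)
}

#' Find one egress path
#'
#' Runs the interval loop: compute the previous-pose energies, choose a
#' direction (DE search in multidirectional mode, the fixed direction in
#' unidirectional mode, the last direction unchanged once the exit
#' criterion is first met), pull for one interval, then apply the exit and
#' stuck checks.
#'
#' @param system a `molecular_system` with a selected pulled atom.
#' @param path_cfg a [pathfinder_config()].
#' @param de_cfg,score_cfg,energy_cfg,pull,engine remaining configurations
#'   ([de_config()], [score_config()], [energy_config()], [pull_spec()]
#'   - its direction field is overridden per interval - and
#'   [engine_config()]).
#' @param seed integer seed for the whole trajectory.
#' @param verbose print a per-interval log line.
#' @return a list of class `path_result`: `waypoints` (per-interval data
#'   frame), `directions` (intervals x 3), `profile` (concatenated
#'   `force_profile`), `energies` (per-interval `energy_pair` list),
#'   `ligand_snapshots`, `status` (`exited`, `stuck` or `max_intervals`),
#'   `intervals_used`, `seed`.
#' @export
find_path <- function(system, path_cfg = pathfinder_config(),
                      de_cfg = de_config(), score_cfg = score_config(),
                      energy_cfg = energy_config(), pull = pull_spec(),
                      engine = engine_config(), seed = 1, verbose = FALSE) {
  if (is.null(system$pulled_atom_id))
    stop("no pulled atom selected; call select_pulled_atom() first")
  set.seed(seed)
  de_cfg$seed <- NULL      # one RNG stream per trajectory
  engine$seed <- NULL
  rec_centroid <- colMeans(rec_coords(system))

  dirs <- matrix(NA_real_, 0, 3)
  waypoints <- list()
  energies <- list()
  snapshots <- list()
  segments <- list()
  min_hist <- numeric(0)
  stuck_run <- 0L
  offset <- c(0, 0)
  dummy <- NULL  # spring dummy persists across intervals
  last_dir <- NULL
  status <- "max_intervals"
  i <- 0L

  pre_exit <- min_ligand_receptor_distance(system) > path_cfg$exit_min_distance

  while (i < path_cfg$max_intervals) {
    i <- i + 1L
    prev_e <- compute_nonbonded(system, config = energy_cfg)
    exiting <- length(min_hist) > 0 &&
      min_hist[length(min_hist)] > path_cfg$exit_min_distance
    best_score <- NA_real_
    if (!is.null(last_dir) && (exiting || (pre_exit && i > 1))) {
      dir <- last_dir            # ligand has left the receptor: hold course
    } else if (path_cfg$mode == "unidirectional") {
      dir <- path_cfg$fixed_direction
    } else if (pre_exit) {
      # already unbound at start: no energy signal for DE, pull radially out
      dir <- unit_vec(ligand_com(system) - rec_centroid)
    } else {
      dres <- find_direction(system, prev_e, de_cfg, score_cfg, energy_cfg)
      best_score <- dres$best_score
      if (dres$degenerate) {
        if (is.null(last_dir))
          stop("degenerate DE result on the first interval (no energy ",
               "signal); reseed or check the starting pose")
        dir <- last_dir
      } else {
        dir <- dres$direction
      }
    }
    last_dir <- dir
    pull$direction <- dir
    ir <- tryCatch(run_interval(system, pull, engine, energy_cfg, offset,
                                dummy_start = dummy),
                   error = function(e)
                     stop("interval ", i, ": ", conditionMessage(e),
                          call. = FALSE))
    dummy <- ir$dummy_end
    system <- set_lig_coords(system, ir$final_positions)
    seg <- ir$profile_segment
    offset <- c(seg$times[length(seg$times)],
                seg$displacements[length(seg$displacements)])
    md <- min_ligand_receptor_distance(system)
    min_hist <- c(min_hist, md)
    com <- ligand_com(system)
    pulled_xyz <- as.numeric(
      system$ligand[match(system$pulled_atom_id, system$ligand$atom_id),
                    c("x", "y", "z")])
    dirs <- rbind(dirs, dir)
    segments[[i]] <- seg
    energies[[i]] <- ir$energies_end
    snapshots[[i]] <- ir$final_positions
    waypoints[[i]] <- data.frame(
      interval = i, time_ps = offset[1], com_x = com[1], com_y = com[2],
      com_z = com[3], pulled_x = pulled_xyz[1], pulled_y = pulled_xyz[2],
      pulled_z = pulled_xyz[3], dir_x = dir[1], dir_y = dir[2],
      dir_z = dir[3], e_elec = ir$energies_end[["e_elec"]],
      e_vdw = ir$energies_end[["e_vdw"]], min_dist = md,
      best_score = best_score)
    if (verbose)
      message(sprintf(
        "interval %3d  score %8.2f  dir (% .2f % .2f % .2f)  min_dist %.3f",
        i, best_score, dir[1], dir[2], dir[3], md))
    if (exit_check(min_hist, path_cfg)) {
      status <- "exited"
      break
    }
    if (ir$net_displacement < path_cfg$stuck_min_displacement) {
      stuck_run <- stuck_run + 1L
      if (stuck_run >= path_cfg$stuck_consecutive) {
        status <- "stuck"
        break
      }
    } else stuck_run <- 0L
  }

  rownames(dirs) <- NULL
  structure(list(waypoints = do.call(rbind, waypoints), directions = dirs,
                 profile = concat_profiles(segments), energies = energies,
                 ligand_snapshots = snapshots, status = status,
                 intervals_used = i, seed = seed,
                 final_system = system),
            class = "path_result")
}

#' @export
print.path_result <- function(x, ...) {
  cat("<path_result> status:", x$status, "| intervals:", x$intervals_used,
      "| seed:", x$seed, "\n")
  invisible(x)
}

#' Run an ensemble of independent egress trajectories
#'
#' Trajectory j uses seed `base_seed + j - 1`; results are order-stable and
#' independent of execution order. Individual trajectory failures are
#' recorded (as `error` entries) rather than aborting the ensemble.
#'
#' @param system a `molecular_system` with a selected pulled atom.
#' @param n_trajectories ensemble size.
#' @param base_seed first seed.
#' @inheritParams find_path
#' @return list of `path_result` (or error condition) objects.
#' @export
run_ensemble <- function(system, n_trajectories, base_seed = 1,
                         path_cfg = pathfinder_config(),
                         de_cfg = de_config(), score_cfg = score_config(),
                         energy_cfg = energy_config(), pull = pull_spec(),
                         engine = engine_config(), verbose = FALSE) {
  stopifnot(n_trajectories >= 1)
  lapply(seq_len(n_trajectories), function(j) {
    tryCatch(find_path(system, path_cfg, de_cfg, score_cfg, energy_cfg,
                       pull, engine, seed = base_seed + j - 1,
                       verbose = verbose),
             error = function(e) e)
  })
}
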