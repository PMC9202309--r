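#' Pulling (SMD spring) specification
#'
#' A dummy atom moving at speed `v` along `direction` drags the pulled
#' ligand atom through a harmonic spring of stiffness `k`; the spring force
#' is `k (v t - x)` where `x` is the pulled-atom displacement projected on
#' the direction (positive when the dummy leads the atom). `k` = 600
#' kJ/mol/nm^2 is a typical AFM-scale stiffness and `v` = 5 nm/ns the
#' speed the protocol was characterized at; the direction is changed every
#' `tau` = 20 ps.
#'
#' @param k spring stiffness, kJ/mol/nm^2.
#' @param v pulling speed, nm/ns.
#' @param tau interval length, ps.
#' @param direction unit 3-vector (checked to 1e-9).
#' @export
pull_spec <- function(k = 600, v = 5, tau = 20, direction = c(0, 0, 1)) {
  stopifnot(k > 0, v > 0, tau > 0)
  if (abs(vec_norm(direction) - 1) > 1e-9)
    stop("direction must be unit-norm")
  structure(list(k = k, v = v, tau = tau, direction = direction),
            class = "pull_spec")
}

#' Toy engine configuration
#'
#' Overdamped (Brownian) Langevin dynamics per ligand atom:
#' `dx = F/friction dt + sqrt(2 kB T dt / friction) N(0,1)`.
#' Receptor atoms are fixed.
#'
#' @param timestep ps.
#' @param friction kJ mol^-1 ps nm^-2 per atom.
#' @param temperature K (0 allowed and gives deterministic dynamics).
#' @param seed optional integer RNG seed applied by [run_interval()].
#' @export
engine_config <- function(timestep = 0.002, friction = 50,
                          temperature = 300, seed = NULL) {
  stopifnot(timestep > 0, friction > 0, temperature >= 0)
  structure(list(timestep = timestep, friction = friction,
                 temperature = temperature, seed = seed),
            class = "engine_config")
}

#' Spring force of the moving dummy atom
#'
#' Returns `k (v t - x)`: positive when the dummy leads the pulled atom.
#' (The restoring-pull sign convention; `v` is converted from nm/ns.)
#'
#' @param t time since interval start, ps (>= 0).
#' @param x projected pulled-atom displacement, nm.
#' @param spec a [pull_spec()].
#' @return force in kJ/mol/nm.
#' @export
spring_force <- function(t, x, spec = pull_spec()) {
  stopifnot(all(t >= 0))
  spec$k * (spec$v / 1000 * t - x)
}

#' Force-time/displacement profile
#'
#' @param times ps, strictly increasing.
#' @param forces spring force samples, kJ/mol/nm.
#' @param displacements cumulative projected pulled-atom displacement, nm
#'   (may backslide).
#' @return a list of class `force_profile`.
#' @export
force_profile <- function(times, forces, displacements) {
  stopifnot(length(times) == length(forces),
            length(times) == length(displacements))
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("profile times must be strictly increasing")
  structure(list(times = times, forces = forces,
                 displacements = displacements),
            class = "force_profile")
}

concat_profiles <- function(profiles) {
  force_profile(unlist(lapply(profiles, `[[`, "times")),
                unlist(lapply(profiles, `[[`, "forces")),
                unlist(lapply(profiles, `[[`, "displacements")))
}

#' Run one pulling interval of the toy engine
#'
#' Integrates overdamped Langevin dynamics for the ligand atoms under
#' ligand-receptor nonbonded forces, intra-ligand nonbonded forces (the
#' bond-free cohesion that lets a multi-atom ligand move as a deformable
#' unit), and the moving-spring force applied wholly to the pulled atom
#' along `spec$direction`. The dummy is a 3-D point advancing at speed `v`
#' along the current direction, linked to the pulled atom by a 3-D harmonic
#' spring; its position persists across intervals (pass `dummy_start`), so a
#' stalled ligand keeps loading the spring across direction changes until it
#' yields - the behaviour the trajectory-wide force law `k (vt - x)`
#' implies. For a single interval from rest along a fixed direction the
#' recorded force reduces exactly to `k (v t - x)`. The profile is sampled
#' every integrator step.
#'
#' @param system a `molecular_system` with a selected pulled atom.
#' @param spec a [pull_spec()] (direction set for this interval).
#' @param engine an [engine_config()].
#' @param energy_cfg an [energy_config()].
#' @param profile_offset `c(t0, x0)`: global time (ps) and accumulated
#'   projected displacement (nm) at interval start.
#' @param include_intra include intra-ligand nonbonded forces (default TRUE).
#' @param dummy_start 3-vector, the dummy position at interval start;
#'   default: the pulled atom's current position (fresh spring).
#' @return list of class `interval_result`: `final_positions`,
#'   `profile_segment` (a `force_profile`), `energies_end` (`energy_pair`),
#'   `net_displacement` (ligand CoM shift, nm), `dummy_end`.
#' @export
run_interval <- function(system, spec = pull_spec(),
                         engine = engine_config(),
                         energy_cfg = energy_config(),
                         profile_offset = c(0, 0), include_intra = TRUE,
                         dummy_start = NULL) {
  if (is.null(system$pulled_atom_id))
    stop("no pulled atom selected; call select_pulled_atom() first")
  if (!is.null(engine$seed)) set.seed(engine$seed)
  l <- sys_param_vectors(system$ligand)
  r <- sys_param_vectors(system$receptor)
  pulled <- match(system$pulled_atom_id, system$ligand$atom_id) - 1L
  if (is.null(dummy_start)) dummy_start <- l$xyz[pulled + 1L, ]
  com0 <- ligand_com(system)
  res <- run_interval_cpp(l$xyz, l$q, l$s, l$e, r$xyz, r$q, r$s, r$e,
                          spec$direction, pulled, spec$k, spec$v / 1000,
                          spec$tau, engine$timestep, engine$friction,
                          .KB * engine$temperature, energy_cfg$cutoff,
                          energy_cfg$coulomb_constant,
                          energy_cfg$dielectric,
                          energy_cfg$min_distance_clamp,
                          profile_offset[1], profile_offset[2],
                          include_intra, as.numeric(dummy_start))
  if (isTRUE(res$aborted))
    stop("pulling interval aborted at step ", res$abort_step,
         ": ligand-receptor overlap deeper than the distance clamp ",
         "(non-finite force)")
  sys_end <- set_lig_coords(system, res$positions)
  structure(list(final_positions = res$positions,
                 profile_segment = force_profile(res$times, res$forces,
                                                 res$displacements),
                 energies_end = compute_nonbonded(sys_end,
                                                  config = energy_cfg),
                 net_displacement = vec_norm(ligand_com(sys_end) - com0),
                 dummy_end = res$dummy),
            class = "interval_result")
}

#' Adapter file contract for an external pulling engine
#'
#' A production MD engine is driven one interval at a time: the pathfinder
#' writes a plain-text direction file (unit vector, k, v, tau) and expects
#' back a coordinate file (PDB/GRO, read with [load_system()] machinery)
#' and a force profile in the 3-column format of [read_profile()]. The toy
#' engine and an external engine satisfy the same per-interval contract.
#'
#' @param spec a [pull_spec()] with the interval's direction.
#' @param path file to write/read.
#' @return `write_pull_direction` returns the path invisibly;
#'   `read_pull_direction` returns a [pull_spec()].
#' @export
write_pull_direction <- function(spec, path) {
  writeLines(c("# direction_x direction_y direction_z k_kJ_mol_nm2 v_nm_ns tau_ps",
               sprintf("%.12f %.12f %.12f %g %g %g", spec$direction[1],
                       spec$direction[2], spec$direction[3], spec$k,
                       spec$v, spec$tau)), path)
  invisible(path)
}

#' @rdname write_pull_direction
#' @export
read_pull_direction <- function(path) {
  v <- scan(path, comment.char = "#", quiet = TRUE)
  stopifnot(length(v) == 6)
  pull_spec(k = v[4], v = v[5], tau = v[6],
            direction = v[1:3] / sqrt(sum(v[1:3]^2)))
}
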