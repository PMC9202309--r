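#' Ground-truth egress channel specification
#'
#' A channel is an atom-free clearance of `radius` nm around a polyline
#' running from the binding site to the exterior, plus a labeled gate
#' sphere on the exterior end used for ground-truth pathway classification.
#'
#' @param label channel label.
#' @param waypoints matrix of polyline vertices (rows, nm), from inside the
#'   receptor to outside it.
#' @param radius clearance radius, nm (must exceed the ligand bounding
#'   radius).
#' @param gate list with `center` (3-vector) and `radius`.
#' @export
channel_spec <- function(label, waypoints, radius, gate) {
  waypoints <- matrix(waypoints, ncol = 3)
  stopifnot(nrow(waypoints) >= 2, radius > 0, gate$radius > 0)
  structure(list(label = label, waypoints = waypoints, radius = radius,
                 gate = gate), class = "channel_spec")
}

#' Synthetic receptor-ligand system specification
#'
#' The synthetic receptor is a Fibonacci-sphere shell plus an interior
#' cubic-lattice scaffold of neutral Lennard-Jones atoms, with a spherical
#' binding-site cavity at the centre and the designed channels carved out.
#' A single attractive "site" atom placed behind the cavity (relative to
#' the first channel) realizes a binding well whose depth scales with
#' `site_epsilon` - the knob the work-affinity ranking fixture turns.
#' Optional "soft plugs" are sparse, weakly repulsive atom lattices filling
#' a cylinder: penetrable under sustained spring force, they emulate a
#' yielding obstruction (the collision obstacle of unidirectional pulling).
#'
#' Scaffold/shell spacing is kept below `2^(1/6) sigma` so the ligand
#' cannot leak between receptor atoms except through channels.
#'
#' @param shell_radius nm.
#' @param shell_spacing target inter-atom spacing on the shell, nm.
#' @param shell_sigma,shell_epsilon,shell_charge shell/scaffold atom
#'   nonbonded parameters.
#' @param scaffold_spacing cubic lattice constant, nm.
#' @param site_center binding-site cavity centre, nm.
#' @param cavity_radius binding-site cavity radius, nm.
#' @param site_epsilon binding-well depth parameter, kJ/mol.
#' @param site_sigma LJ sigma of the site atom, nm (large = soft, long
#'   ranged, so the peak restraining force stays below what the spring can
#'   deliver in one interval).
#' @param site_offset absolute position of the site atom, nm.
#' @param ligand_n 1, 2 or 3 ligand atoms (3 = rigid-ish triangle held by
#'   its own LJ cohesion).
#' @param ligand_sigma,ligand_epsilon,ligand_charge ligand atom parameters.
#' @param channels list of [channel_spec()]s.
#' @param soft_plugs list of lists with `from`, `to`, `radius`, and
#'   optionally `spacing`, `sigma`, `epsilon`.
#' @param seed integer (the construction is deterministic; kept for
#'   provenance).
#' @export
synthetic_system_spec <- function(shell_radius = 1.1, shell_spacing = 0.32,
                                  shell_sigma = 0.3, shell_epsilon = 0.02,
                                  shell_charge = 0, scaffold_spacing = 0.3,
                                  site_center = c(0, 0, 0),
                                  cavity_radius = 0.55, site_epsilon = 4,
                                  site_sigma = 1.2,
                                  site_offset = c(0, 0, -0.8),
                                  ligand_n = 3, ligand_sigma = 0.25,
                                  ligand_epsilon = 2, ligand_charge = 0,
                                  channels = list(), soft_plugs = list(),
                                  seed = 1) {
  stopifnot(shell_radius > 0, site_epsilon >= 0, ligand_n %in% 1:3)
  if (shell_spacing >= 2^(1 / 6) * shell_sigma)
    stop("shell_spacing must stay below 2^(1/6) * shell_sigma ",
         "(leak-tightness)")
  structure(as.list(environment()), class = "synthetic_system_spec")
}

# near-uniform deterministic points on a sphere
fibonacci_sphere <- function(n, radius) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  rho <- sqrt(pmax(1 - z^2, 0))
  radius * cbind(rho * cos(phi), rho * sin(phi), z)
}

# minimum distance from each point (rows) to a polyline
dist_to_polyline <- function(points, waypoints) {
  d <- rep(Inf, nrow(points))
  for (s in seq_len(nrow(waypoints) - 1)) {
    a <- waypoints[s, ]
    ab <- waypoints[s + 1, ] - a
    len2 <- sum(ab^2)
    ap <- sweep(points, 2, a)
    tt <- pmin(pmax((ap %*% ab) / len2, 0), 1)
    proj <- outer(as.numeric(tt), ab)
    d <- pmin(d, sqrt(rowSums((ap - proj)^2)))
  }
  d
}

dist_to_segment <- function(points, a, b) {
  dist_to_polyline(points, rbind(a, b))
}

cubic_lattice <- function(extent, spacing) {
  g <- seq(-extent, extent, by = spacing)
  as.matrix(expand.grid(x = g, y = g, z = g))
}

ligand_geometry <- function(n, sigma, center) {
  side <- 2^(1 / 6) * sigma
  # triangle in the xz-plane: atoms sit at staggered heights, so they peel
  # off the binding seat sequentially rather than all at once
  xz <- switch(n,
               matrix(0, 1, 2),
               rbind(c(-side / 2, 0), c(side / 2, 0)),
               side / sqrt(3) * rbind(c(cos(pi / 2), sin(pi / 2)),
                                      c(cos(7 * pi / 6), sin(7 * pi / 6)),
                                      c(cos(11 * pi / 6), sin(11 * pi / 6))))
  sweep(cbind(xz[, 1], 0, xz[, 2]), 2, center, `+`)
}

#' Build a synthetic receptor-ligand system
#'
#' Deterministic given the spec: shell and scaffold atoms are placed, every
#' atom within channel clearance of a channel centerline (or inside the
#' binding-site cavity or a soft-plug cylinder) is deleted, soft plugs are
#' filled with their sparse lattices, the site atom is added, and the
#' ligand is placed at the site centre.
#'
#' @param spec a [synthetic_system_spec()].
#' @return list with `system` (a `molecular_system`, pulled atom already
#'   selected), `channels`, and `spec`.
#' @export
make_system <- function(spec) {
  lig_xyz <- ligand_geometry(spec$ligand_n, spec$ligand_sigma,
                             spec$site_center)
  lig_bound <- max(sqrt(rowSums(
    sweep(lig_xyz, 2, spec$site_center)^2)))
  for (ch in spec$channels)
    if (ch$radius <= lig_bound)
      stop("channel '", ch$label, "' radius (", ch$radius,
           " nm) too small for the ligand (bounding radius ",
           round(lig_bound, 3), " nm)")

  n_shell <- ceiling(4 * pi * spec$shell_radius^2 / spec$shell_spacing^2)
  shell <- fibonacci_sphere(n_shell, spec$shell_radius)
  scaf <- cubic_lattice(spec$shell_radius, spec$scaffold_spacing)
  rad <- sqrt(rowSums(scaf^2))
  scaf <- scaf[rad < spec$shell_radius - 0.15, , drop = FALSE]
  pts <- rbind(shell, scaf)
  kind <- c(rep("SH", nrow(shell)), rep("SC", nrow(scaf)))

  keep <- sqrt(rowSums(sweep(pts, 2, spec$site_center)^2)) >
    spec$cavity_radius
  for (ch in spec$channels)
    keep <- keep & dist_to_polyline(pts, ch$waypoints) > ch$radius
  for (pl in spec$soft_plugs)
    keep <- keep & dist_to_segment(pts, pl$from, pl$to) > pl$radius
  pts <- pts[keep, , drop = FALSE]
  kind <- kind[keep]

  sig <- ifelse(kind == "SH", spec$shell_sigma, spec$shell_sigma)
  eps <- rep(spec$shell_epsilon, nrow(pts))
  chg <- rep(spec$shell_charge, nrow(pts))

  for (pl in spec$soft_plugs) {
    sp <- if (is.null(pl$spacing)) 0.45 else pl$spacing
    ssig <- if (is.null(pl$sigma)) 0.25 else pl$sigma
    seps <- if (is.null(pl$epsilon)) 0.05 else pl$epsilon
    grid <- cubic_lattice(max(abs(rbind(pl$from, pl$to))) + sp, sp)
    inside <- dist_to_segment(grid, pl$from, pl$to) <= pl$radius
    # keep the plug out of the open channels and the cavity
    ok <- inside &
      sqrt(rowSums(sweep(grid, 2, spec$site_center)^2)) >
        spec$cavity_radius
    for (ch in spec$channels)
      ok <- ok & dist_to_polyline(grid, ch$waypoints) > ch$radius
    plug <- grid[ok, , drop = FALSE]
    if (nrow(plug)) {
      pts <- rbind(pts, plug)
      kind <- c(kind, rep("SP", nrow(plug)))
      sig <- c(sig, rep(ssig, nrow(plug)))
      eps <- c(eps, rep(seps, nrow(plug)))
      chg <- c(chg, rep(0, nrow(plug)))
    }
  }

  # site atom: the binding well
  pts <- rbind(pts, spec$site_offset)
  kind <- c(kind, "ST")
  sig <- c(sig, spec$site_sigma)
  eps <- c(eps, spec$site_epsilon)
  chg <- c(chg, 0)

  receptor <- atom_table(atom_id = seq_len(nrow(pts)), name = kind,
                         x = pts[, 1], y = pts[, 2], z = pts[, 3],
                         charge = chg, sigma = sig, epsilon = eps,
                         role = "receptor", resname = "REC")
  ligand <- atom_table(atom_id = nrow(pts) + seq_len(spec$ligand_n),
                       name = paste0("L", seq_len(spec$ligand_n)),
                       x = lig_xyz[, 1], y = lig_xyz[, 2], z = lig_xyz[, 3],
                       charge = spec$ligand_charge,
                       sigma = spec$ligand_sigma,
                       epsilon = spec$ligand_epsilon,
                       role = "ligand", resname = "LIG")
  system <- molecular_system(receptor, ligand)
  system$pulled_atom_id <- select_pulled_atom(system)
  list(system = system, channels = spec$channels, spec = spec)
}

#' Ligand series over binding-well depths
#'
#' Identical geometry, only the site-well depth varies; the fixture for the
#' work-affinity rank-correlation property (a desk-scale analogue of a
#' congeneric ligand series with graded IC50).
#'
#' @param spec a [synthetic_system_spec()].
#' @param well_depths site epsilon values, kJ/mol (> 0).
#' @return list of [make_system()] results, one per depth.
#' @export
make_ligand_series <- function(spec, well_depths = c(2, 4, 6, 8, 10)) {
  stopifnot(all(well_depths > 0))
  lapply(well_depths, function(d) {
    spec$site_epsilon <- d
    make_system(spec)
  })
}

#' Canonical synthetic fixtures
#'
#' Four systems used across the test suite: `STRAIGHT` (one axial
#' channel), `BENT` (one L-shaped channel whose straight continuation is
#' blocked by a penetrable soft plug - the unidirectional-failure
#' demonstrator), `TWO_CHANNEL` (one wide plus one narrow channel on
#' orthogonal axes), and `CAGE` (no channel at all).
#'
#' @return named list of [synthetic_system_spec()]s.
#' @export
standard_fixtures <- function() {
  # channel centerlines start just above the binding cavity so carving
  # leaves the cavity floor (the seat around the site atom) intact
  straight <- channel_spec("axial", rbind(c(0, 0, 0.15), c(0, 0, 1.8)),
                           radius = 0.6,
                           gate = list(center = c(0, 0, 1.4),
                                       radius = 0.7))
  bent <- channel_spec("bent", rbind(c(0, 0, 0.15), c(0, 0, 0.7),
                                     c(1.8, 0, 0.7)),
                       radius = 0.6,
                       gate = list(center = c(1.4, 0, 0.7),
                                   radius = 0.7))
  wide <- channel_spec("wide", rbind(c(0, 0, 0.15), c(0, 0, 1.8)),
                       radius = 0.65,
                       gate = list(center = c(0, 0, 1.4), radius = 0.7))
  narrow <- channel_spec("narrow", rbind(c(0.15, 0, 0), c(1.8, 0, 0)),
                         radius = 0.55,
                         gate = list(center = c(1.4, 0, 0), radius = 0.7))
  list(
    STRAIGHT = synthetic_system_spec(channels = list(straight)),
    BENT = synthetic_system_spec(
      channels = list(bent),
      soft_plugs = list(list(from = c(0, 0, 0.7), to = c(0, 0, 1.8),
                             radius = 0.55, spacing = 0.35,
                             sigma = 0.25, epsilon = 0.025))),
    TWO_CHANNEL = synthetic_system_spec(
      channels = list(wide, narrow),
      site_offset = c(-0.566, 0, -0.566)),
    CAGE = synthetic_system_spec())
}

#' Gate table for [classify_pathways()]
#'
#' @param channels list of [channel_spec()]s.
#' @return data frame with `label`, `x`, `y`, `z`, `radius`.
#' @export
gates_table <- function(channels) {
  do.call(rbind, lapply(channels, function(ch)
    data.frame(label = ch$label, x = ch$gate$center[1],
               y = ch$gate$center[2], z = ch$gate$center[3],
               radius = ch$gate$radius)))
}

#' Write a fixture to disk
#'
#' Writes `receptor.pdb`, `ligand.pdb`, `params.txt` (nonbonded parameter
#' table) and, when jsonlite is available, `channels.json` with the
#' ground-truth channel geometry.
#'
#' @param spec a [synthetic_system_spec()].
#' @param dir output directory (created if needed).
#' @return invisibly, the [make_system()] result.
#' @export
write_fixture <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  made <- make_system(spec)
  sys <- made$system
  write_structure(sys$receptor, file.path(dir, "receptor.pdb"))
  write_structure(sys$ligand, file.path(dir, "ligand.pdb"))
  par <- unique(rbind(
    data.frame(name = sys$receptor$name, charge = sys$receptor$charge,
               sigma = sys$receptor$sigma,
               epsilon = sys$receptor$epsilon),
    data.frame(name = sys$ligand$name, charge = sys$ligand$charge,
               sigma = sys$ligand$sigma, epsilon = sys$ligand$epsilon)))
  write_parameter_table(parameter_table(par), file.path(dir, "params.txt"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    ch <- lapply(made$channels, function(c0)
      list(label = c0$label, waypoints = c0$waypoints,
           radius = c0$radius, gate = c0$gate))
    jsonlite::write_json(ch, file.path(dir, "channels.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(made)
}

#' Desk-scale study conditions for the synthetic fixtures
#'
#' The run configuration used by the packaged fixture studies (tests,
#' acceptance script, CLI defaults): differential evolution with a 120-vector
#' population refined for 40 generations inside the default 0.7 nm probe
#' ball (ample for a 3-dimensional search at fixture scale; the
#' production-scale defaults of [de_config()] stay at 3000 x 100), the toy
#' engine at T = 0 (deterministic dynamics; trajectory-to-trajectory
#' variability then comes from the stochastic direction search alone), and
#' the recommended pulling parameters (k = 600 kJ/mol/nm^2, v = 5 nm/ns,
#' tau = 20 ps).
#'
#' @return list with `de`, `engine`, `pull`, `energy`, `score` components.
#' @export
fixture_protocol <- function() {
  list(de = de_config(population_size = 120, iterations = 40),
       engine = engine_config(temperature = 0),
       pull = pull_spec(),
       energy = energy_config(),
       score = score_config())
}
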