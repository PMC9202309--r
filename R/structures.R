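#' Construct an atom table
#'
#' Atoms are held in a plain data frame, one row per atom, with positions in
#' nm, charges in elementary charge units, Lennard-Jones sigma in nm and
#' epsilon in kJ/mol.
#'
#' @param atom_id integer ids, unique within a system.
#' @param name short atom names.
#' @param x,y,z coordinates in nm.
#' @param charge partial charges, e.
#' @param sigma LJ diameter, nm (>= 0).
#' @param epsilon LJ well depth, kJ/mol (>= 0).
#' @param role `"receptor"` or `"ligand"`.
#' @param resname residue names (opaque labels).
#' @return a data frame of atom records.
#' @export
atom_table <- function(atom_id, name, x, y, z, charge = 0, sigma = 0,
                       epsilon = 0, role = "receptor", resname = "MOL") {
  df <- data.frame(atom_id = as.integer(atom_id), name = as.character(name),
                   resname = as.character(resname), role = as.character(role),
                   x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                   charge = as.numeric(charge), sigma = as.numeric(sigma),
                   epsilon = as.numeric(epsilon),
                   stringsAsFactors = FALSE)
  validate_atoms(df)
  df
}

validate_atoms <- function(df) {
  stopifnot(nrow(df) > 0)
  if (!all(is.finite(df$x) & is.finite(df$y) & is.finite(df$z)))
    stop("atom positions must be finite")
  if (any(df$sigma < 0) || any(df$epsilon < 0))
    stop("LJ sigma and epsilon must be non-negative")
  invisible(df)
}

#' Construct a receptor-ligand system
#'
#' The state the whole egress protocol acts on: fixed receptor atoms, mobile
#' ligand atoms, and (once selected) the id of the ligand atom the pulling
#' spring attaches to.
#'
#' @param receptor,ligand atom tables (see [atom_table()]).
#' @param pulled_atom_id optional id of a ligand atom.
#' @return an object of class `molecular_system`.
#' @export
molecular_system <- function(receptor, ligand, pulled_atom_id = NULL) {
  validate_atoms(receptor)
  validate_atoms(ligand)
  receptor$role <- "receptor"
  ligand$role <- "ligand"
  ids <- c(receptor$atom_id, ligand$atom_id)
  if (anyDuplicated(ids)) stop("atom_ids must be unique within the system")
  if (!is.null(pulled_atom_id) && !(pulled_atom_id %in% ligand$atom_id))
    stop("pulled_atom_id must refer to a ligand atom")
  structure(list(receptor = receptor, ligand = ligand,
                 pulled_atom_id = pulled_atom_id),
            class = "molecular_system")
}

#' @export
print.molecular_system <- function(x, ...) {
  cat("<molecular_system>", nrow(x$receptor), "receptor atoms,",
      nrow(x$ligand), "ligand atoms")
  if (!is.null(x$pulled_atom_id))
    cat(", pulled atom id", x$pulled_atom_id)
  cat("\n")
  invisible(x)
}

lig_coords <- function(system) {
  as.matrix(system$ligand[, c("x", "y", "z")])
}

rec_coords <- function(system) {
  as.matrix(system$receptor[, c("x", "y", "z")])
}

set_lig_coords <- function(system, xyz) {
  system$ligand[, c("x", "y", "z")] <- xyz
  system
}

#' Ligand centre of mass
#'
#' Unit masses are assumed unless `masses` is supplied; the protocol only
#' uses the CoM to choose the pulled atom and to track egress waypoints.
#'
#' @param system a `molecular_system`.
#' @param masses optional per-ligand-atom masses.
#' @return 3-vector, nm.
#' @export
ligand_com <- function(system, masses = NULL) {
  xyz <- lig_coords(system)
  if (is.null(masses)) masses <- rep(1, nrow(xyz))
  colSums(xyz * masses) / sum(masses)
}

#' Select the pulled ligand atom
#'
#' Returns the id of the ligand atom closest to the ligand centre of mass
#' (the atom the moving-spring dummy is linked to). Ties are broken by the
#' lowest atom id.
#'
#' @param system a `molecular_system`.
#' @param heavy_only drop atoms whose name starts with "H" before the scan.
#' @param masses optional per-atom masses for the CoM (default: unit mass).
#' @return integer atom id.
#' @export
select_pulled_atom <- function(system, heavy_only = FALSE, masses = NULL) {
  lig <- system$ligand
  if (nrow(lig) == 0) stop("ligand is empty")
  com <- ligand_com(system, masses)
  cand <- lig
  if (heavy_only) {
    keep <- !startsWith(toupper(cand$name), "H")
    if (any(keep)) cand <- cand[keep, , drop = FALSE]
  }
  d2 <- (cand$x - com[1])^2 + (cand$y - com[2])^2 + (cand$z - com[3])^2
  # ties: lowest atom_id
  ord <- order(d2, cand$atom_id)
  cand$atom_id[ord[1]]
}

#' Minimum ligand-receptor atom distance
#'
#' @param system a `molecular_system`.
#' @return nm.
#' @export
min_ligand_receptor_distance <- function(system) {
  lc <- lig_coords(system)
  rc <- rec_coords(system)
  dmin <- Inf
  for (i in seq_len(nrow(lc))) {
    d2 <- (rc[, 1] - lc[i, 1])^2 + (rc[, 2] - lc[i, 2])^2 +
      (rc[, 3] - lc[i, 3])^2
    dmin <- min(dmin, min(d2))
  }
  sqrt(dmin)
}
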