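#' Nonbonded energy configuration
#'
#' Plain-truncation Coulomb plus 12-6 Lennard-Jones, Lorentz-Berthelot
#' combination. The 1.0 nm cutoff matches common nonbonded settings in
#' all-atom simulations; truncation (no shift, no mesh electrostatics) is
#' deliberate because the energies only rank candidate ligand translations.
#'
#' @param cutoff nonbonded cutoff, nm.
#' @param coulomb_constant f in kJ mol^-1 nm e^-2.
#' @param dielectric relative dielectric (1 = vacuum).
#' @param min_distance_clamp nm; Coulomb distances are clamped below this to
#'   guard floating-point range for overlapping probe poses.
#' @return a list of class `energy_config`.
#' @export
energy_config <- function(cutoff = 1.0, coulomb_constant = 138.935458,
                          dielectric = 1.0, min_distance_clamp = 0.01) {
  stopifnot(cutoff > 0, dielectric > 0, min_distance_clamp > 0)
  structure(list(cutoff = cutoff, coulomb_constant = coulomb_constant,
                 dielectric = dielectric,
                 min_distance_clamp = min_distance_clamp),
            class = "energy_config")
}

#' An (E_elec, E_vdw) pair of interaction energies
#'
#' @param e_elec,e_vdw energies in kJ/mol.
#' @return named numeric vector of class `energy_pair`.
#' @export
energy_pair <- function(e_elec, e_vdw) {
  structure(c(e_elec = as.numeric(e_elec), e_vdw = as.numeric(e_vdw)),
            class = "energy_pair")
}

#' Total interaction energy of an energy pair
#' @param e an `energy_pair`.
#' @export
energy_total <- function(e) unname(e[["e_elec"]] + e[["e_vdw"]])

#' Single-pair nonbonded energy
#'
#' `e_elec = f qi qj / (dielectric * max(r, clamp))`;
#' `e_vdw = 4 eps ((sigma/r)^12 - (sigma/r)^6)`; both are exactly zero
#' beyond the cutoff (plain truncation).
#'
#' @param r pair distance, nm (> 0). May be a vector.
#' @param qi,qj charges, e.
#' @param sigma_ij combined LJ sigma, nm.
#' @param eps_ij combined LJ epsilon, kJ/mol.
#' @param config an [energy_config()].
#' @return an `energy_pair` (or a 2-column matrix for vector `r`).
#' @export
pair_energy <- function(r, qi, qj, sigma_ij, eps_ij,
                        config = energy_config()) {
  if (any(r <= 0)) stop("pair distance must be > 0")
  within <- r <= config$cutoff
  rc <- pmax(r, config$min_distance_clamp)
  ee <- ifelse(within,
               config$coulomb_constant * qi * qj / (config$dielectric * rc),
               0)
  sr6 <- (sigma_ij / r)^6
  ev <- ifelse(within, 4 * eps_ij * (sr6^2 - sr6), 0)
  if (length(r) == 1L) energy_pair(ee, ev)
  else cbind(e_elec = ee, e_vdw = ev)
}

sys_param_vectors <- function(atoms) {
  list(xyz = as.matrix(atoms[, c("x", "y", "z")]), q = atoms$charge,
       s = atoms$sigma, e = atoms$epsilon)
}

#' Ligand-receptor nonbonded interaction energy
#'
#' Sums pairwise Coulomb and Lennard-Jones energies over all
#' ligand-receptor atom pairs within the cutoff (intra-ligand and
#' intra-receptor pairs excluded), with Lorentz-Berthelot combination:
#' `sigma_ij = (sigma_i + sigma_j)/2`, `eps_ij = sqrt(eps_i eps_j)`.
#'
#' @param system a `molecular_system`.
#' @param ligand_positions optional replacement ligand coordinates (n x 3
#'   matrix, nm); defaults to the system's current ligand pose.
#' @param config an [energy_config()].
#' @return an `energy_pair`.
#' @export
compute_nonbonded <- function(system, ligand_positions = NULL,
                              config = energy_config()) {
  l <- sys_param_vectors(system$ligand)
  r <- sys_param_vectors(system$receptor)
  if (!is.null(ligand_positions)) {
    lp <- as.matrix(ligand_positions)
    if (!identical(dim(lp), dim(l$xyz)))
      stop("ligand_positions must be a ", nrow(l$xyz), " x 3 matrix")
    l$xyz <- lp
  }
  v <- nb_energy_cpp(l$xyz, l$q, l$s, l$e, r$xyz, r$q, r$s, r$e,
                     config$cutoff, config$coulomb_constant,
                     config$dielectric, config$min_distance_clamp)
  energy_pair(v[["e_elec"]], v[["e_vdw"]])
}

# energies for a batch of rigid ligand translations (P x 3) -> P x 2 matrix
nb_energy_translations <- function(system, translations,
                                   config = energy_config()) {
  l <- sys_param_vectors(system$ligand)
  r <- sys_param_vectors(system$receptor)
  nb_energy_batch_cpp(l$xyz, as.matrix(translations), l$q, l$s, l$e,
                      r$xyz, r$q, r$s, r$e, config$cutoff,
                      config$coulomb_constant, config$dielectric,
                      config$min_distance_clamp)
}
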