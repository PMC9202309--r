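#' Persist an egress path
#'
#' Writes `<out_prefix>_waypoints.csv` (interval index, time, ligand CoM,
#' direction, energies, contact distance) and `<out_prefix>_ligand.pdb`,
#' a multi-model PDB with one MODEL block per interval-end ligand snapshot.
#' The waypoint table round-trips losslessly through [read_waypoints()].
#'
#' @param path a `path_result` from [find_path()].
#' @param out_prefix output file prefix.
#' @param ligand_atoms the ligand atom table (for PDB names); defaults to
#'   the atoms stored in `path$final_system`.
#' @return invisibly, the two file paths written.
#' @export
write_path <- function(path, out_prefix, ligand_atoms = NULL) {
  stopifnot(inherits(path, "path_result"), path$intervals_used >= 1)
  if (is.null(ligand_atoms)) ligand_atoms <- path$final_system$ligand
  csv <- paste0(out_prefix, "_waypoints.csv")
  pdb <- paste0(out_prefix, "_ligand.pdb")
  utils::write.csv(path$waypoints, csv, row.names = FALSE)
  con <- file(pdb, "w")
  for (m in seq_along(path$ligand_snapshots)) {
    xyz <- path$ligand_snapshots[[m]]
    writeLines(sprintf("MODEL     %4d", m), con)
    writeLines(fmt_pdb_atom(ligand_atoms$atom_id, ligand_atoms$name,
                            ligand_atoms$resname, 1,
                            xyz[, 1], xyz[, 2], xyz[, 3]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  close(con)
  invisible(c(waypoints = csv, ligand = pdb))
}

#' @rdname write_path
#' @param file a waypoint CSV written by [write_path()].
#' @export
read_waypoints <- function(file) {
  utils::read.csv(file)
}
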