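#' Read a nonbonded parameter table
#'
#' A delimited text file with a header line and columns
#' `name[, resname], charge, sigma, epsilon` (charge in e, sigma in nm,
#' epsilon in kJ/mol). Each key (name, or name+resname when a resname column
#' is present) must map to exactly one parameter triple.
#'
#' @param path file path.
#' @return a data frame of class `parameter_table`.
#' @export
read_parameter_table <- function(path) {
  if (!file.exists(path)) stop("parameter table not found: ", path)
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  parameter_table(df)
}

#' @rdname read_parameter_table
#' @param df data frame with the columns described above.
#' @export
parameter_table <- function(df) {
  need <- c("name", "charge", "sigma", "epsilon")
  if (!all(need %in% names(df)))
    stop("parameter table needs columns: ", paste(need, collapse = ", "))
  key <- if ("resname" %in% names(df)) paste(df$name, df$resname) else df$name
  if (anyDuplicated(key))
    stop("duplicate parameter entries for: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  class(df) <- c("parameter_table", "data.frame")
  df
}

#' @rdname read_parameter_table
#' @param table a `parameter_table`.
#' @export
write_parameter_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# look up (charge, sigma, epsilon) for every atom; error listing misses
assign_parameters <- function(atoms, params) {
  by_res <- "resname" %in% names(params)
  key <- if (by_res) paste(atoms$name, atoms$resname) else atoms$name
  pkey <- if (by_res) paste(params$name, params$resname) else params$name
  idx <- match(key, pkey)
  if (anyNA(idx)) {
    miss <- unique(atoms$name[is.na(idx)])
    stop("no nonbonded parameters for atom name(s): ",
         paste(miss, collapse = ", "))
  }
  atoms$charge <- params$charge[idx]
  atoms$sigma <- params$sigma[idx]
  atoms$epsilon <- params$epsilon[idx]
  atoms
}

read_structure <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!file.exists(path)) stop("structure file not found: ", path)
  if (ext == "pdb") read_structure_pdb(path)
  else if (ext == "gro") read_structure_gro(path)
  else stop("unsupported structure format (need .pdb or .gro): ", path)
}

# PDB via bio3d; coordinates converted Angstrom -> nm
read_structure_pdb <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e)
                    stop("PDB parse error in ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  data.frame(atom_id = as.integer(at$eleno), name = trimws(at$elety),
             resname = trimws(at$resid),
             x = at$x / 10, y = at$y / 10, z = at$z / 10,
             stringsAsFactors = FALSE)
}

# GRO fixed columns: resid(5) resname(5) name(5) atomid(5) x y z (%8.3f);
# coordinates are already nm
read_structure_gro <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) stop("GRO parse error in ", path,
                              ": fewer than 3 lines")
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n)) stop("GRO parse error in ", path,
                     " at line 2: atom count not an integer")
  if (length(lines) < 2 + n)
    stop("GRO parse error in ", path, ": expected ", n, " atom lines")
  out <- vector("list", n)
  for (i in seq_len(n)) {
    ln <- lines[2 + i]
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 21, 28),
                                         substr(ln, 29, 36),
                                         substr(ln, 37, 44))))
    if (anyNA(xyz))
      stop("GRO parse error in ", path, " at line ", 2 + i,
           ": malformed coordinates")
    out[[i]] <- data.frame(atom_id = as.integer(substr(ln, 16, 20)),
                           name = trimws(substr(ln, 11, 15)),
                           resname = trimws(substr(ln, 6, 10)),
                           x = xyz[1], y = xyz[2], z = xyz[3],
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Load a receptor-ligand system from structure files
#'
#' Formats are detected by extension (`.pdb` or `.gro`). PDB coordinates are
#' converted from Angstrom to nm; GRO coordinates are already nm. Every atom
#' is assigned (charge, sigma, epsilon) from the parameter table; unknown
#' atom names raise an error listing the offending atoms.
#'
#' @param receptor_path,ligand_path structure file paths.
#' @param params a `parameter_table` (or path to one).
#' @return a `molecular_system`.
#' @export
load_system <- function(receptor_path, ligand_path, params) {
  if (is.character(params)) params <- read_parameter_table(params)
  rec <- assign_parameters(read_structure(receptor_path), params)
  lig <- assign_parameters(read_structure(ligand_path), params)
  # keep ids unique across the two files
  if (any(lig$atom_id %in% rec$atom_id))
    lig$atom_id <- lig$atom_id + max(rec$atom_id)
  rec$role <- "receptor"
  lig$role <- "ligand"
  molecular_system(rec, lig)
}

fmt_pdb_atom <- function(serial, name, resname, resid, x, y, z) {
  sprintf("ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
          serial %% 100000, substr(name, 1, 4), substr(resname, 1, 3),
          resid %% 10000, x * 10, y * 10, z * 10)
}

#' Write an atom table as PDB or GRO
#'
#' @param atoms an atom table.
#' @param path output file; format from extension (`.pdb` or `.gro`).
#' @export
write_structure <- function(atoms, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "pdb") {
    lines <- c(fmt_pdb_atom(atoms$atom_id, atoms$name, atoms$resname,
                            seq_len(nrow(atoms)), atoms$x, atoms$y, atoms$z),
               "END")
    writeLines(lines, path)
  } else if (ext == "gro") {
    body <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                    seq_len(nrow(atoms)) %% 100000,
                    substr(atoms$resname, 1, 5), substr(atoms$name, 1, 5),
                    atoms$atom_id %% 100000, atoms$x, atoms$y, atoms$z)
    writeLines(c("written by depull", sprintf("%5d", nrow(atoms)), body,
                 "   0.000   0.000   0.000"), path)
  } else stop("unsupported structure format: ", path)
  invisible(path)
}

#' Write a force profile as 3-column text
#'
#' Columns: time (ps), displacement (nm), force (kJ/mol/nm); lines starting
#' with `#` or `@` are comments (xvg-style tabular readers accept this).
#'
#' @param profile a `force_profile` (see [force_profile()]).
#' @param path output file.
#' @export
write_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# time_ps displacement_nm force_kJ_mol_nm", con)
  writeLines(sprintf("%.6f %.9f %.9f", profile$times, profile$displacements,
                     profile$forces), con)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          col.names = c("t", "x", "f"))
  force_profile(df$t, df$f, df$x)
}
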