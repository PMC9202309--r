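test_that("PDB coordinates are converted to nm and round-trip", {
  atoms <- atom_table(1:3, c("C1", "C2", "O1"),
                      x = c(0.1234, -0.5, 1.2), y = c(0, 0.25, -0.3),
                      z = c(0.05, 1.0, 0.7), resname = "LIG")
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(atoms, f)
  back <- depull:::read_structure_pdb(f)
  # PDB stores Angstrom at 3 decimals -> 1e-4 nm precision
  expect_equal(back$x, atoms$x, tolerance = 1e-12)
  expect_lt(max(abs(back$y - atoms$y)), 1e-4)
  expect_lt(max(abs(back$z - atoms$z)), 1e-4)
  expect_equal(trimws(back$name), atoms$name)
})

test_that("GRO positions are read as nm unchanged and round-trip", {
  atoms <- atom_table(1:2, c("N1", "N2"), x = c(0.111, 2.345),
                      y = c(0.222, -0.1), z = c(0.333, 0.9))
  f <- withr::local_tempfile(fileext = ".gro")
  write_structure(atoms, f)
  back <- depull:::read_structure_gro(f)
  # GRO stores nm at 3 decimals -> half-ulp 5e-4 nm
  expect_lt(max(abs(as.matrix(back[, c("x", "y", "z")]) -
                      as.matrix(atoms[, c("x", "y", "z")]))), 5.1e-4)
})

test_that("malformed GRO files raise parse errors with line numbers", {
  f <- withr::local_tempfile(fileext = ".gro")
  writeLines(c("title", "2",
               "    1LIG    L1    1   0.100   0.200   0.300",
               "    1LIG    L2    2   bad     0.200   0.300",
               "   0.0 0.0 0.0"), f)
  expect_error(depull:::read_structure_gro(f), "line 4")
})

test_that("load_system assigns parameters and reports unknown atoms", {
  params <- parameter_table(data.frame(
    name = c("R1", "L1"), charge = c(0.1, -0.2), sigma = c(0.3, 0.25),
    epsilon = c(0.5, 1.0)))
  rec <- atom_table(1:2, "R1", x = c(0, 0.2), y = 0, z = 0)
  lig <- atom_table(3, "L1", x = 1, y = 0, z = 0)
  fr <- withr::local_tempfile(fileext = ".pdb")
  fl <- withr::local_tempfile(fileext = ".pdb")
  write_structure(rec, fr)
  write_structure(lig, fl)
  sys <- load_system(fr, fl, params)
  expect_s3_class(sys, "molecular_system")
  expect_equal(nrow(sys$receptor) + nrow(sys$ligand), 3)
  expect_equal(sys$ligand$charge, -0.2)
  expect_equal(sys$receptor$sigma, c(0.3, 0.3))

  lig2 <- atom_table(3, "XX", x = 1, y = 0, z = 0)
  fl2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(lig2, fl2)
  expect_error(load_system(fr, fl2, params), "XX")
})

test_that("parameter tables reject duplicate keys", {
  expect_error(parameter_table(data.frame(
    name = c("A", "A"), charge = 0, sigma = 0.3, epsilon = 1)), "duplicate")
  tab <- parameter_table(data.frame(name = c("A", "B"), charge = 0,
                                    sigma = 0.3, epsilon = 1))
  f <- withr::local_tempfile(fileext = ".txt")
  write_parameter_table(tab, f)
  expect_equal(read_parameter_table(f)$name, c("A", "B"))
})

test_that("select_pulled_atom picks the CoM-nearest atom", {
  # symmetric linear 3-atom ligand: middle atom wins
  lig <- atom_table(11:13, c("L1", "L2", "L3"), x = c(-1, 0, 1), y = 0,
                    z = 0, role = "ligand")
  rec <- atom_table(1, "R", 5, 5, 5)
  expect_equal(select_pulled_atom(molecular_system(rec, lig)), 12L)
  # single-atom ligand
  one <- atom_table(7, "L", 0.3, 0.1, 0, role = "ligand")
  expect_equal(select_pulled_atom(molecular_system(rec, one)), 7L)
})

test_that("select_pulled_atom matches a brute-force scan and is rigid-motion
           invariant", {
  set.seed(42)
  for (rep in 1:5) {
    lig <- atom_table(1:10 + 100L, paste0("L", 1:10),
                      x = rnorm(10), y = rnorm(10), z = rnorm(10),
                      role = "ligand")
    rec <- atom_table(1, "R", 50, 50, 50)
    sys <- molecular_system(rec, lig)
    # independent oracle: full scan over ligand atoms
    com <- colMeans(as.matrix(lig[, c("x", "y", "z")]))
    d <- sqrt((lig$x - com[1])^2 + (lig$y - com[2])^2 + (lig$z - com[3])^2)
    expect_equal(select_pulled_atom(sys), lig$atom_id[which.min(d)])

    rot <- random_rotation(rep)
    moved <- as.matrix(lig[, c("x", "y", "z")]) %*% t(rot)
    moved <- sweep(moved, 2, c(1, -2, 0.5), `+`)
    lig2 <- lig
    lig2[, c("x", "y", "z")] <- moved
    expect_equal(select_pulled_atom(molecular_system(rec, lig2)),
                 select_pulled_atom(sys))
  }
})

test_that("write_path round-trips the waypoint table", {
  made <- make_system(standard_fixtures()$CAGE)
  pr <- fixture_protocol()
  p <- find_path(made$system, pathfinder_config(max_intervals = 2),
                 de_cfg = pr$de, engine = pr$engine, seed = 3)
  prefix <- file.path(withr::local_tempdir(), "run1")
  files <- write_path(p, prefix)
  back <- read_waypoints(files[["waypoints"]])
  expect_equal(back, as.data.frame(p$waypoints), tolerance = 1e-12,
               ignore_attr = TRUE)
  # direction columns unit-norm
  nrm <- sqrt(back$dir_x^2 + back$dir_y^2 + back$dir_z^2)
  expect_true(all(abs(nrm - 1) < 1e-9))
  # one MODEL block per interval
  pdb <- readLines(files[["ligand"]])
  expect_equal(sum(grepl("^MODEL", pdb)), p$intervals_used)
})

test_that("force profiles round-trip through the 3-column text format", {
  pf <- force_profile(times = seq(0.1, 2, by = 0.1),
                      forces = sin(1:20), displacements = cumsum(runif(20)))
  f <- withr::local_tempfile(fileext = ".xvg")
  write_profile(pf, f)
  back <- read_profile(f)
  expect_equal(back$forces, pf$forces, tolerance = 1e-8)
  expect_equal(back$displacements, pf$displacements, tolerance = 1e-8)
})
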