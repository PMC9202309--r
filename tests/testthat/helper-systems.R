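# small systems built in code for the unit tests

# a random ligand/receptor pair with given atom counts inside a box
random_system <- function(n_lig = 10, n_rec = 50, box = 3, seed = 1,
                          charged = TRUE) {
  set.seed(seed)
  mk <- function(n, role, id0) {
    atom_table(atom_id = id0 + seq_len(n),
               name = paste0(substr(role, 1, 1), seq_len(n)),
               x = runif(n, 0, box), y = runif(n, 0, box),
               z = runif(n, 0, box),
               charge = if (charged) runif(n, -0.5, 0.5) else 0,
               sigma = runif(n, 0.2, 0.4), epsilon = runif(n, 0.1, 1),
               role = role)
  }
  molecular_system(mk(n_rec, "receptor", 0), mk(n_lig, "ligand", n_rec))
}

# independent brute-force double loop over pair_energy (R implementation),
# no spatial tricks: the oracle for compute_nonbonded
nb_oracle <- function(system, config = energy_config()) {
  lig <- system$ligand
  rec <- system$receptor
  ee <- ev <- 0
  for (i in seq_len(nrow(lig))) {
    for (j in seq_len(nrow(rec))) {
      r <- sqrt((lig$x[i] - rec$x[j])^2 + (lig$y[i] - rec$y[j])^2 +
                  (lig$z[i] - rec$z[j])^2)
      p <- pair_energy(r, lig$charge[i], rec$charge[j],
                       (lig$sigma[i] + rec$sigma[j]) / 2,
                       sqrt(lig$epsilon[i] * rec$epsilon[j]), config)
      ee <- ee + p[["e_elec"]]
      ev <- ev + p[["e_vdw"]]
    }
  }
  energy_pair(ee, ev)
}

random_rotation <- function(seed = 1) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(9), 3, 3))) * sample(c(-1, 1), 1)
}

# minimal stand-in with just the CoM track, for classify_pathways
fake_path <- function(track) {
  structure(list(waypoints = data.frame(com_x = track[, 1],
                                        com_y = track[, 2],
                                        com_z = track[, 3])),
            class = "path_result")
}
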