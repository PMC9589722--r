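# Shared fixtures, built once per test run. Everything is generated in code;
# nothing is read from disk.

fixture_env <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = fixture_env)) {
    assign(name, builder(), envir = fixture_env)
  }
  get(name, envir = fixture_env)
}

# one-pocket two-state protein + 5-bead ligand, full topology
toy_complex <- function() {
  memo("toy_complex", function() {
    ts <- make_two_state_protein(60, hinge_angle = 60, seed = 11)
    cplx <- make_toy_ligand(ts, 5, seed = 11)
    topo <- build_topology(cplx, ts$open,
                           params = cg_params(eps_pp = 1.0, dt = 0.05))
    list(two_state = ts, closed = cplx, topology = topo)
  })
}

# the standard two-pocket study enzyme
study_system <- function(eps_nnat = 0) {
  key <- paste0("study_", eps_nnat)
  memo(key, function() toy_study_system(seed = 1, eps_nnat = eps_nnat))
}

# synthetic AMP-like heavy-atom table covering adenine, ribose and the
# alpha phosphate (coordinates arbitrary but fixed)
fake_amp_atoms <- function(shift = c(0, 0, 0)) {
  nm <- c("N9", "C8", "N7", "C5", "C4", "C6", "N6", "N1", "C2", "N3",
          "C1'", "C2'", "O2'", "C3'", "O3'", "C4'", "O4'", "C5'", "O5'",
          "P", "O1P", "O2P", "O3P")
  set.seed(402)
  xyz <- matrix(stats::rnorm(3 * length(nm), sd = 2), ncol = 3)
  data.frame(elety = nm, x = xyz[, 1] + shift[1], y = xyz[, 2] + shift[2],
             z = xyz[, 3] + shift[3])
}

fake_atp_atoms <- function() {
  amp <- fake_amp_atoms()
  amp$elety[amp$elety == "P"] <- "PA"
  amp$elety[amp$elety == "O1P"] <- "O1A"
  amp$elety[amp$elety == "O2P"] <- "O2A"
  amp$elety[amp$elety == "O3P"] <- "O3A"
  extra <- data.frame(
    elety = c("PB", "O1B", "O2B", "O3B", "PG", "O1G", "O2G", "O3G"),
    x = seq(8, 15, by = 1), y = 0, z = 0)
  rbind(amp, extra)
}

# write a minimal PDB with one CA (and optionally CB) atom per residue
write_fake_pdb <- function(file, coords, skip_ca = integer()) {
  lines <- character()
  serial <- 0L
  for (q in seq_len(nrow(coords))) {
    if (!(q %in% skip_ca)) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        serial, q, coords[q, 1], coords[q, 2], coords[q, 3]))
    }
    serial <- serial + 1L
    lines <- c(lines, sprintf(
      "ATOM  %5d  CB  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      serial, q, coords[q, 1] + 0.8, coords[q, 2], coords[q, 3]))
  }
  writeLines(c(lines, "END"), file)
  file
}

# brute-force O(N^2) native-contact oracle on bead coordinates
oracle_contacts <- function(structure, threshold = 6.5, min_seq_sep = 3) {
  X <- structure$coords
  n <- nrow(X)
  out <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      pi <- structure$role[i] == "protein"
      pj <- structure$role[j] == "protein"
      if (pi && pj &&
          abs(structure$residue_index[i] - structure$residue_index[j]) <
            min_seq_sep) next
      if (!pi && !pj) next
      if (sqrt(sum((X[i, ] - X[j, ])^2)) < threshold)
        out <- rbind(out, c(i, j))
    }
  }
  out
}
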