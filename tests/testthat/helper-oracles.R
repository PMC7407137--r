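# Independent oracles used across tests.

# Brute-force crossing replay: marches frame by frame, carrying one
# last-definite-side state per molecule, and checks every consecutive-frame
# side change. Deliberately a different code path from the package's
# per-molecule segment/run-length counter.
brute_force_crossings <- function(traj, slab, window_ps) {
  n_fr <- traj$n_frames
  n_mol <- traj$n_molecules
  half_box <- if (is.null(traj$box_z)) Inf else traj$box_z / 2
  t0 <- traj$times_ps[1]
  total_ps <- traj$times_ps[n_fr] - t0
  n_windows <- max(1L, as.integer(ceiling(total_ps / window_ps - 1e-9)))
  counts <- integer(n_windows)
  down <- 0L; up <- 0L
  side_of <- function(z) {
    s <- integer(length(z))
    s[z > slab$z_upper] <- 1L
    s[z < slab$z_lower] <- -1L
    s
  }
  last_side <- side_of(traj$z[1, ])
  for (f in 2:n_fr) {
    znew <- traj$z[f, ]
    s <- side_of(znew)
    wrapped <- abs(znew - traj$z[f - 1, ]) > half_box
    crossed <- !wrapped & s != 0L & last_side != 0L & s != last_side
    if (any(crossed)) {
      w <- min(as.integer(ceiling((traj$times_ps[f] - t0) / window_ps -
                                    1e-9)), n_windows)
      counts[w] <- counts[w] + sum(crossed)
      down <- down + sum(crossed & last_side == 1L)
      up <- up + sum(crossed & last_side == -1L)
    }
    # wraps reset; definite sides update; "inside" keeps the old state
    update <- wrapped | s != 0L
    last_side[update] <- s[update]
  }
  list(counts = counts, down = down, up = up)
}

# High-precision direct evaluation of the NegBin closed form used as an
# alternative route in a few spot checks (the main oracle is stats::dnbinom)
nb_direct <- function(y, mu, phi) {
  lgamma(y + phi) - lgamma(phi) - lgamma(y + 1) +
    phi * log(phi / (phi + mu)) + y * log(mu / (phi + mu))
}

# Hand-written multi-model PDB text fixture: waters + lipid phosphates
write_pdb_fixture <- function(path, water_z, lipid_z) {
  # water_z: frames x n_water; lipid_z: frames x n_lipid
  stopifnot(nrow(water_z) == nrow(lipid_z))
  n_fr <- nrow(water_z)
  con <- file(path, "w")
  on.exit(close(con))
  atom_line <- function(serial, name, resname, chain, resno, x, y, z) {
    sprintf("ATOM  %5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
            serial, name, resname, chain, resno, x, y, z, 1, 0)
  }
  for (f in seq_len(n_fr)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    serial <- 1L
    for (j in seq_len(ncol(water_z))) {
      writeLines(atom_line(serial, "OH2", "TIP3", "W", j, 1.0 * j, 2.0,
                           water_z[f, j]), con)
      serial <- serial + 1L
    }
    for (j in seq_len(ncol(lipid_z))) {
      writeLines(atom_line(serial, "P", "POPC", "L", j, 1.0 * j, 4.0,
                           lipid_z[f, j]), con)
      serial <- serial + 1L
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

expect_seeded_identical <- function(expr1, expr2) {
  testthat::expect_identical(expr1, expr2)
}
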