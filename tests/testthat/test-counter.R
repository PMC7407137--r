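test_that("canonical single traversal is counted in its completing window", {
  traj <- trajectory_slice(cbind(w = c(25, 10, -25)), times_ps = c(0, 10, 20))
  slab <- membrane_slab(-18, 18)
  got <- count_crossings(traj, slab, window_ps = 10)
  expect_identical(got$counts, c(0L, 1L))
  expect_identical(got$direction_totals, c(down = 1L, up = 0L))
})

test_that("re-entry into the origin side records nothing", {
  z <- cbind(w = rep(c(25, 10, 25), 4))
  traj <- trajectory_slice(z)
  got <- count_crossings(traj, membrane_slab(-18, 18), window_ps = 10)
  expect_identical(sum(got$counts), 0L)
})

test_that("boundary contact counts as inside, preserving the last side", {
  # touches the upper boundary exactly, then returns: no crossing
  traj <- trajectory_slice(cbind(w = c(25, 18, 25, 18, -25)))
  got <- count_crossings(traj, membrane_slab(-18, 18), window_ps = 10)
  expect_identical(sum(got$counts), 1L)   # only the final full traversal
})

test_that("multi-frame traversals count once, in the completing frame's window", {
  # drifts through the slab over several frames
  traj <- trajectory_slice(cbind(w = c(25, 15, 5, -5, -15, -25, -26, -27)))
  got <- count_crossings(traj, membrane_slab(-18, 18), window_ps = 10)
  expect_identical(got$counts, c(0L, 0L, 0L, 0L, 1L, 0L, 0L))
  expect_identical(got$direction_totals[["down"]], 1L)
})

test_that("periodic-image wraps are not crossings and reset the side", {
  # molecule wraps from near +box/2 to near -box/2 (box 80), then later
  # genuinely crosses upward
  z <- c(38, 38.5, -38, -30, -25, 0, 25, 26)
  traj <- trajectory_slice(cbind(w = z), box_z = 80)
  got <- count_crossings(traj, membrane_slab(-18, 18), window_ps = 10)
  expect_identical(sum(got$counts), 1L)
  expect_identical(got$direction_totals, c(down = 0L, up = 1L))
  # without box_z the same jump is (incorrectly) interpretable as movement;
  # the state machine then sees a definite side change
  traj2 <- trajectory_slice(cbind(w = z))
  got2 <- count_crossings(traj2, membrane_slab(-18, 18), window_ps = 10)
  expect_identical(sum(got2$counts), 2L)
})

test_that("window refinement conserves counts pairwise", {
  slab <- membrane_slab(-18, 18)
  sched <- random_schedule(40, 400, 25, seed = 31)
  traj <- simulate_membrane_trajectory(sched, slab, seed = 32)
  coarse <- count_crossings(traj, slab, window_ps = 20)
  fine <- count_crossings(traj, slab, window_ps = 10)
  n2 <- 2 * coarse$n_windows
  fine_padded <- c(fine$counts, integer(n2 - fine$n_windows))
  pair_sums <- fine_padded[seq(1, n2, 2)] + fine_padded[seq(2, n2, 2)]
  expect_identical(pair_sums, coarse$counts)
})

test_that("reflecting z and swapping slab bounds swaps directions, keeps Yi", {
  slab <- membrane_slab(-18, 18)
  sched <- random_schedule(30, 300, 15, seed = 41)
  traj <- simulate_membrane_trajectory(sched, slab, seed = 42)
  fwd <- count_crossings(traj, slab, window_ps = 10)
  refl <- trajectory_slice(-traj$z, times_ps = traj$times_ps,
                           molecule_ids = traj$molecule_ids,
                           box_z = traj$box_z)
  rev_ <- count_crossings(refl, membrane_slab(-18, 18), window_ps = 10)
  expect_identical(rev_$counts, fwd$counts)
  expect_identical(rev_$direction_totals[["down"]],
                   fwd$direction_totals[["up"]])
  expect_identical(rev_$direction_totals[["up"]],
                   fwd$direction_totals[["down"]])
})

test_that("time reversal preserves total crossings and swaps directions", {
  slab <- membrane_slab(-18, 18)
  sched <- random_schedule(25, 250, 12, seed = 51)
  traj <- simulate_membrane_trajectory(sched, slab, seed = 52)
  fwd <- count_crossings(traj, slab, window_ps = 10)
  tr <- trajectory_slice(traj$z[traj$n_frames:1, , drop = FALSE],
                         times_ps = traj$times_ps,
                         molecule_ids = traj$molecule_ids,
                         box_z = traj$box_z)
  bwd <- count_crossings(tr, slab, window_ps = 10)
  expect_identical(sum(bwd$counts), sum(fwd$counts))
  expect_identical(bwd$direction_totals[["down"]],
                   fwd$direction_totals[["up"]])
})

test_that("counter agrees with the brute-force replay on mixed fixtures", {
  slab <- membrane_slab(-18, 18)
  for (seed in 1:12) {
    n_mol <- 10 + (seed %% 4) * 20
    n_fr <- 150 + (seed %% 3) * 100
    sched <- random_schedule(n_mol, n_fr, n_events = 5 + seed, seed = seed)
    free <- setdiff(seq_len(n_mol), sched$events$molecule)
    wraps <- if (seed %% 2 == 0 && length(free) >= 2) {
      data.frame(molecule = free[1:2], frame = c(50L, 90L))
    } else NULL
    traj <- simulate_membrane_trajectory(sched, slab, seed = seed + 100,
                                         box_z = 80, wrap_events = wraps)
    got <- count_crossings(traj, slab, window_ps = 10)
    ref <- brute_force_crossings(traj, slab, window_ps = 10)
    expect_identical(got$counts, ref$counts)
    expect_identical(got$direction_totals[["down"]], ref$down)
    expect_identical(sum(got$counts), nrow(sched$events))
  }
})

test_that("invalid windows and degenerate inputs raise errors", {
  traj <- trajectory_slice(cbind(w = c(25, 10, -25)))
  slab <- membrane_slab(-18, 18)
  expect_error(count_crossings(traj, slab, window_ps = 7), "multiple")
  expect_error(trajectory_slice(cbind(w = c(0, NA, 1))), "finite")
  expect_error(membrane_slab(5, -5), "exceed")
})

test_that("slab inference averages leaflet reference atoms", {
  # two static atoms
  expect_equal(unclass(infer_slab(matrix(c(-18, 18), 1, 2)))[c("z_lower", "z_upper")],
               list(z_lower = -18, z_upper = 18))
  # single frame, +-20
  s1 <- infer_slab(c(-20, 20))
  expect_equal(s1$z_lower, -20)
  expect_equal(s1$z_upper, 20)
  # noisy leaflets: 100 atoms per leaflet, 100 frames, uniform +-1 noise
  set.seed(77)
  lower <- matrix(-18 + runif(100 * 100, -1, 1), 100, 100)
  upper <- matrix(18 + runif(100 * 100, -1, 1), 100, 100)
  lipid <- cbind(lower, upper)
  s <- infer_slab(lipid)
  expect_lt(abs(s$z_lower + 18), 0.2)
  expect_lt(abs(s$z_upper - 18), 0.2)
  # oracle: direct averaging of the same generated coordinates
  expect_equal(s$z_lower, mean(lower), tolerance = 1e-12)
  expect_equal(s$z_upper, mean(upper), tolerance = 1e-12)
  # degenerate leaflet
  expect_error(infer_slab(matrix(c(5, 5, 5, 5), 1, 4)), "degenerate|leaflet")
})
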