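test_that("generator validates its configuration and names the bad field", {
  expect_error(generator_config(n_windows = 1), "n_windows")
  expect_error(generator_config(sigma = -0.1), "sigma")
  expect_error(generator_config(nu = 0), "nu")
  expect_error(generator_config(phi = -1), "phi")
  expect_error(generator_config(window_ps = 0), "window_ps")
})

test_that("identical seed and config reproduce count series bit-for-bit", {
  cfg <- generator_config(n_windows = 500, seed = 99)
  a <- simulate_count_series(cfg)
  b <- simulate_count_series(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$meta$lambda, b$meta$lambda)
  c2 <- simulate_count_series(generator_config(n_windows = 500, seed = 100))
  expect_false(identical(a$counts, c2$counts))
})

test_that("constant-rate generator approaches the Poisson limit", {
  cfg <- generator_config(n_windows = 10000, rho = 1, sigma = 0,
                          lambda1 = log(5), phi = 1e8, nu = 4, seed = 3)
  y <- simulate_count_series(cfg)$counts
  # Poisson(5): mean 5, variance 5; allow 3 standard errors
  se_mean <- sqrt(5 / 10000)
  expect_lt(abs(mean(y) - 5), 3 * se_mean)
  se_var <- sqrt(2 * 5^2 / 10000 + 5 / 10000)  # approx SE of sample variance
  expect_lt(abs(var(y) - 5), 4 * se_var)
})

test_that("constant-rate NegBin matches the closed-form dispersion index", {
  mu <- 0.4; phi <- 0.5
  cfg <- generator_config(n_windows = 200000, rho = 1, sigma = 0,
                          lambda1 = log(mu), phi = phi, nu = 4, seed = 4)
  y <- simulate_count_series(cfg)$counts
  expect_lt(abs(mean(y) - mu), 3 * sqrt(mu * (1 + mu / phi) / 2e5))
  # dispersion index 1 + mu/phi = 1.8; Monte-Carlo tolerance
  expect_lt(abs(var(y) / mean(y) - 1.8), 0.05)
})

test_that("bursty generator produces a heavier-than-Poisson upper tail", {
  cfg <- generator_config(n_windows = 50000, rho = 0.9, sigma = 0.5,
                          nu = 4, phi = 0.5, lambda1 = log(0.5), seed = 5)
  y <- simulate_count_series(cfg)
  cmp <- compare_to_poisson(y)
  expect_gt(cmp$tail_mass_ratio, 1)
  expect_gt(cmp$dispersion_index, 1)
})

test_that("crossing schedules enforce spacing and direction alternation", {
  ok <- data.frame(molecule = c(1L, 1L), frame = c(5L, 9L),
                   direction = c("down", "up"))
  expect_s3_class(crossing_schedule(ok, 3, 20), "crossing_schedule")
  too_close <- data.frame(molecule = c(1L, 1L), frame = c(5L, 6L),
                          direction = c("down", "up"))
  expect_error(crossing_schedule(too_close, 3, 20), "frames apart")
  same_dir <- data.frame(molecule = c(1L, 1L), frame = c(5L, 9L),
                         direction = c("down", "down"))
  expect_error(crossing_schedule(same_dir, 3, 20), "alternate")
  out_of_range <- data.frame(molecule = 1L, frame = 25L, direction = "down")
  expect_error(crossing_schedule(out_of_range, 3, 20), "frames")
})

test_that("generated trajectories realise their schedule exactly", {
  slab <- membrane_slab(-18, 18)
  sched <- random_schedule(n_molecules = 30, n_frames = 500, n_events = 7,
                           seed = 21)
  traj <- simulate_membrane_trajectory(sched, slab, seed = 22)
  got <- count_crossings(traj, slab, window_ps = 10)
  expect_identical(sum(got$counts), 7L)
  # per-direction totals match the schedule
  expect_identical(got$direction_totals[["down"]],
                   sum(sched$events$direction == "down"))
  expect_identical(got$direction_totals[["up"]],
                   sum(sched$events$direction == "up"))
  # event windows match: completing frame f at time (f-1)*10 ps
  want <- integer(got$n_windows)
  for (f in sched$events$frame) {
    w <- min(ceiling((f - 1) * 10 / 10), got$n_windows)
    want[w] <- want[w] + 1L
  }
  expect_identical(got$counts, want)
})

test_that("empty schedules and image wraps give zero crossings", {
  slab <- membrane_slab(-18, 18)
  empty <- crossing_schedule(NULL, 50, 100)
  traj <- simulate_membrane_trajectory(empty, slab, seed = 2)
  expect_identical(sum(count_crossings(traj, slab, 10)$counts), 0L)

  wraps <- data.frame(molecule = c(3L, 7L), frame = c(40L, 60L))
  traj_w <- simulate_membrane_trajectory(empty, slab, seed = 2, box_z = 80,
                                         wrap_events = wraps)
  expect_identical(sum(count_crossings(traj_w, slab, 10)$counts), 0L)
  # sanity: the injected jumps really do exceed half the box
  expect_gt(max(abs(diff(traj_w$z[, 3]))), 40)
})

test_that("trajectory generation is seed-deterministic", {
  slab <- membrane_slab(-15, 15)
  sched <- random_schedule(10, 200, 5, seed = 8)
  a <- simulate_membrane_trajectory(sched, slab, seed = 9)
  b <- simulate_membrane_trajectory(sched, slab, seed = 9)
  expect_identical(a$z, b$z)
})
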