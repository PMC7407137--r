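#' Configuration for the synthetic count-series generator
#'
#' Bundles the parameters of the generative model for per-window transition
#' counts: a latent log-rate following a Student-t autoregression
#' \eqn{\lambda_i = \rho \lambda_{i-1} + \sigma t_\nu} with negative-binomial
#' observations \eqn{Y_i \sim NB(\mu = e^{\lambda_i}, \phi)},
#' \eqn{Var(Y) = \mu + \mu^2/\phi}.
#'
#' Defaults mirror a 100 ns trajectory saved every 10 ps (10,000 observation
#' windows of 10 ps) with a bursty latent rate.
#'
#' @param n_windows number of observation windows (>= 2).
#' @param window_ps window duration in picoseconds.
#' @param rho autocorrelation of the latent log rate.
#' @param sigma innovation scale on the log scale (>= 0; 0 gives a
#'   deterministic latent path).
#' @param nu Student-t degrees of freedom (> 0); values <= 2 imply infinite
#'   innovation variance.
#' @param phi negative-binomial overdispersion (> 0; large values approach
#'   the Poisson limit).
#' @param lambda1 initial log expected count per window.
#' @param seed integer random seed.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_windows = 10000L, window_ps = 10, rho = 0.9,
                             sigma = 0.5, nu = 4, phi = 0.5,
                             lambda1 = log(0.1), seed = 1L) {
  chk <- function(ok, field, msg) {
    if (!ok) stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
  }
  chk(is.numeric(n_windows) && length(n_windows) == 1L && n_windows >= 2 &&
        n_windows == round(n_windows), "n_windows", "must be an integer >= 2")
  chk(is.numeric(window_ps) && window_ps > 0, "window_ps", "must be > 0")
  chk(is.numeric(rho) && is.finite(rho), "rho", "must be finite")
  chk(is.numeric(sigma) && sigma >= 0, "sigma", "must be >= 0")
  chk(is.numeric(nu) && nu > 0, "nu", "must be > 0")
  chk(is.numeric(phi) && phi > 0, "phi", "must be > 0")
  chk(is.numeric(lambda1) && is.finite(lambda1), "lambda1", "must be finite")
  chk(is.numeric(seed) && length(seed) == 1L && is.finite(seed), "seed",
      "must be an integer")
  structure(list(n_windows = as.integer(n_windows), window_ps = window_ps,
                 rho = rho, sigma = sigma, nu = nu, phi = phi,
                 lambda1 = lambda1, seed = as.integer(seed)),
            class = "generator_config")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

#' Simulate a transition-count series from the latent-rate model
#'
#' Forward simulation of the model the inference stage fits: the latent log
#' rate evolves as \eqn{\lambda_i = \rho\lambda_{i-1} + \sigma\,t_\nu} and
#' each window's count is drawn negative-binomial with mean
#' \eqn{e^{\lambda_i}} and overdispersion `phi`. The true latent path and
#' parameters are stored in the result's `meta`, so simulated series carry
#' their own ground truth for recovery tests.
#'
#' @param config a [generator_config()].
#' @return A [crossing_counts()]; `meta$true` holds the generating
#'   parameters and `meta$lambda` the latent log-rate path.
#' @examples
#' y <- simulate_count_series(generator_config(n_windows = 100, seed = 7))
#' y$meta$true$rho
#' @export
simulate_count_series <- function(config) {
  if (!inherits(config, "generator_config"))
    config <- do.call(generator_config, as.list(config))
  with_seed(config$seed, {
    n <- config$n_windows
    lambda <- numeric(n)
    lambda[1] <- config$lambda1
    if (n > 1) {
      eps <- if (config$sigma == 0) numeric(n - 1)
             else config$sigma * rt(n - 1, df = config$nu)
      for (i in 2:n) lambda[i] <- config$rho * lambda[i - 1] + eps[i - 1]
    }
    y <- rnbinom(n, size = config$phi, mu = exp(lambda))
  })
  if (anyNA(y) || any(y >= 2^31))
    stop("latent log rate drifted so high that counts overflow integer ",
         "range (max lambda = ", sprintf("%.1f", max(lambda)), "); ",
         "heavy-tailed innovations (small nu) with |rho| near 1 can do ",
         "this -- reduce sigma, raise nu, or shorten the series",
         call. = FALSE)
  crossing_counts(y, window_ps = config$window_ps,
                  meta = list(
                    true = list(rho = config$rho, sigma = config$sigma,
                                nu = config$nu, phi = config$phi,
                                lambda1 = config$lambda1),
                    lambda = lambda, seed = config$seed))
}

#' Ground-truth crossing schedule for kinematic trajectory fixtures
#'
#' Lists, per molecule, the frames at which a complete slab traversal ends
#' and its direction. A traversal occupies the completing frame and the
#' preceding in-slab frame, and needs a definite-side frame before that, so
#' completing frames start at 3 and events of one molecule must be
#' separated by at least two frames. Directions must alternate, since
#' completing a down crossing leaves the molecule below.
#'
#' @param events data frame with columns `molecule` (integer in
#'   `1..n_molecules`), `frame` (completing frame index, `3..n_frames`) and
#'   `direction` (`"down"` or `"up"`); may have zero rows.
#' @param n_molecules,n_frames fixture dimensions.
#' @return A list of class `crossing_schedule`.
#' @export
crossing_schedule <- function(events, n_molecules, n_frames) {
  if (is.null(events) || nrow(events) == 0L) {
    events <- data.frame(molecule = integer(), frame = integer(),
                         direction = character())
  }
  stopifnot(all(c("molecule", "frame", "direction") %in% names(events)))
  if (nrow(events) > 0) {
    if (any(events$frame < 3 | events$frame > n_frames))
      stop("event frames must lie in [3, n_frames]", call. = FALSE)
    if (any(events$molecule < 1 | events$molecule > n_molecules))
      stop("event molecules must lie in [1, n_molecules]", call. = FALSE)
    if (!all(events$direction %in% c("down", "up")))
      stop("direction must be 'down' or 'up'", call. = FALSE)
    for (m in unique(events$molecule)) {
      ev <- events[events$molecule == m, ]
      ev <- ev[order(ev$frame), ]
      if (nrow(ev) > 1) {
        if (any(diff(ev$frame) < 2))
          stop("events of one molecule must be >= 2 frames apart",
               call. = FALSE)
        if (any(ev$direction[-1] == ev$direction[-nrow(ev)]))
          stop("events of one molecule must alternate in direction",
               call. = FALSE)
      }
    }
  }
  structure(list(events = events[order(events$molecule, events$frame), ,
                                 drop = FALSE],
                 n_molecules = as.integer(n_molecules),
                 n_frames = as.integer(n_frames)),
            class = "crossing_schedule")
}

#' Draw a random crossing schedule
#'
#' Convenience generator for counter tests: scatters `n_events` complete
#' traversals over random molecules and frames, respecting the spacing and
#' direction-alternation constraints.
#'
#' @param n_molecules,n_frames fixture dimensions.
#' @param n_events total number of traversals to schedule.
#' @param seed integer random seed.
#' @return A [crossing_schedule()].
#' @export
random_schedule <- function(n_molecules, n_frames, n_events, seed = 1L) {
  with_seed(seed, {
    ev <- data.frame(molecule = integer(), frame = integer(),
                     direction = character())
    last_frame <- rep(-10L, n_molecules)
    last_dir <- rep(NA_character_, n_molecules)
    tries <- 0L
    while (nrow(ev) < n_events && tries < 50L * n_events) {
      tries <- tries + 1L
      m <- sample.int(n_molecules, 1L)
      f <- sample(3:n_frames, 1L)
      # only append after the molecule's last event, >= 2 frames later
      if (f < last_frame[m] + 2L) next
      d <- if (is.na(last_dir[m])) sample(c("down", "up"), 1L)
           else setdiff(c("down", "up"), last_dir[m])
      ev <- rbind(ev, data.frame(molecule = m, frame = f, direction = d))
      last_frame[m] <- f
      last_dir[m] <- d
    }
    if (nrow(ev) < n_events)
      stop("could not place all events; increase n_frames or n_molecules",
           call. = FALSE)
  })
  crossing_schedule(ev, n_molecules, n_frames)
}

#' Generate a kinematic membrane trajectory realising a crossing schedule
#'
#' Builds per-frame z-coordinates such that every scheduled event produces
#' exactly one complete slab traversal completing at its stated frame, and
#' no unscheduled traversal occurs anywhere. Non-crossing molecules perform
#' bounded random motion strictly on one side of the slab. Optionally a
#' periodic-image wrap (a single-frame jump across the box boundary) is
#' injected for chosen molecules; such wraps must not be counted as
#' crossings by a correct counter.
#'
#' The trajectories are kinematic fixtures with the geometry of a permeation
#' trajectory, not molecular dynamics.
#'
#' @param schedule a [crossing_schedule()].
#' @param slab a [membrane_slab()].
#' @param seed integer random seed.
#' @param frame_ps frame interval in picoseconds.
#' @param box_z periodic box height in Angstrom (`NULL` for none); wraps can
#'   only be injected when given.
#' @param wrap_events optional data frame `molecule, frame` of image wraps
#'   to inject (molecules must have no scheduled crossings).
#' @return A [trajectory_slice()] with the schedule attached as metadata.
#' @export
simulate_membrane_trajectory <- function(schedule, slab, seed = 1L,
                                         frame_ps = 10, box_z = NULL,
                                         wrap_events = NULL) {
  stopifnot(inherits(schedule, "crossing_schedule"),
            inherits(slab, "membrane_slab"))
  n_fr <- schedule$n_frames
  n_mol <- schedule$n_molecules
  zu <- slab$z_upper
  zl <- slab$z_lower
  margin <- max(2, 0.1 * (zu - zl))
  top <- zu + 2 * margin      # resting band centres
  bot <- zl - 2 * margin
  if (!is.null(box_z)) {
    need <- 2 * (max(abs(top), abs(bot)) + margin)
    if (box_z < need)
      stop(sprintf("box_z = %g too small for slab plus resting bands (need >= %g)",
                   box_z, need), call. = FALSE)
  }
  if (!is.null(wrap_events) && nrow(wrap_events) > 0) {
    if (is.null(box_z))
      stop("wrap injection requires box_z", call. = FALSE)
    if (anyNA(wrap_events$molecule) ||
        any(wrap_events$molecule < 1 | wrap_events$molecule > n_mol))
      stop("wrap molecules must lie in [1, n_molecules]", call. = FALSE)
    if (any(wrap_events$molecule %in% schedule$events$molecule))
      stop("wrap injection only supported for molecules without scheduled ",
           "crossings", call. = FALSE)
    if (any(wrap_events$frame < 2 | wrap_events$frame > n_fr))
      stop("wrap frames must lie in [2, n_frames]", call. = FALSE)
  }
  jitter_band <- function(n, centre) centre + runif(n, -margin / 2, margin / 2)
  with_seed(seed, {
    z <- matrix(NA_real_, n_fr, n_mol)
    for (m in seq_len(n_mol)) {
      ev <- schedule$events[schedule$events$molecule == m, , drop = FALSE]
      if (nrow(ev) == 0L) {
        centre <- if (runif(1) < 0.5) top else bot
        z[, m] <- jitter_band(n_fr, centre)
        next
      }
      # side before the first event is the origin side of that event
      side <- ifelse(ev$direction[1] == "down", 1, -1)
      pos <- 1L
      for (k in seq_len(nrow(ev))) {
        f <- ev$frame[k]
        centre <- if (side > 0) top else bot
        if (f - 1L >= pos)
          z[pos:(f - 1L), m] <- jitter_band(f - pos, centre)
        # traversal: frame f-1 rewritten to lie inside the slab, frame f on
        # the destination side
        z[f - 1L, m] <- (zu + zl) / 2 + runif(1, -0.3, 0.3) * (zu - zl)
        side <- -side
        z[f, m] <- if (side > 0) jitter_band(1, top) else jitter_band(1, bot)
        pos <- f + 1L
      }
      if (pos <= n_fr) {
        centre <- if (side > 0) top else bot
        z[pos:n_fr, m] <- jitter_band(n_fr - pos + 1L, centre)
      }
    }
    if (!is.null(wrap_events) && nrow(wrap_events) > 0) {
      for (k in seq_len(nrow(wrap_events))) {
        m <- wrap_events$molecule[k]
        f <- wrap_events$frame[k]
        # place the molecule near +box_z/2 before the wrap, near -box_z/2
        # after: a single-frame jump of ~box_z that is an image wrap, not
        # permeation
        hi <- box_z / 2 - margin / 2
        z[1:(f - 1L), m] <- hi + runif(f - 1L, -margin / 4, margin / 4)
        z[f:n_fr, m] <- -hi + runif(n_fr - f + 1L, -margin / 4, margin / 4)
      }
    }
  })
  trajectory_slice(z, times_ps = (seq_len(n_fr) - 1) * frame_ps,
                   molecule_ids = as.character(seq_len(n_mol)),
                   box_z = box_z)
}
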