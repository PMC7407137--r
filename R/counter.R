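#' Count complete membrane crossings per observation window
#'
#' Replays a three-state machine (above / inside / below the slab) over each
#' molecule's z-trace. A crossing is recorded when a molecule whose last
#' definite side was "above" first reaches "below" (direction down), or vice
#' versa (up); it is assigned to the window containing the completing frame.
#' Excursions into the slab that return to the origin side record nothing,
#' so boundary jitter cannot double-count. A molecule exactly on a boundary
#' plane is "inside". When `box_z` is available, a single-frame z
#' displacement exceeding `box_z / 2` is treated as a periodic-image wrap:
#' the molecule's side is reset to its new definite region without recording
#' a crossing.
#'
#' @param traj a [trajectory_slice()].
#' @param slab a [membrane_slab()].
#' @param window_ps window duration in picoseconds; must be an integer
#'   multiple of the frame interval.
#' @return A [crossing_counts()] with per-window totals (down + up) and
#'   per-direction totals.
#' @examples
#' z <- cbind(w1 = c(25, 10, -25))
#' traj <- trajectory_slice(z, times_ps = c(0, 10, 20))
#' count_crossings(traj, membrane_slab(-18, 18), window_ps = 10)$counts
#' @export
count_crossings <- function(traj, slab, window_ps = 10) {
  stopifnot(inherits(traj, "trajectory_slice"),
            inherits(slab, "membrane_slab"))
  if (traj$n_frames < 2L)
    stop("need at least two frames to count crossings", call. = FALSE)
  dts <- diff(traj$times_ps)
  dt <- dts[1]
  if (any(abs(dts - dt) > 1e-9 * max(dt, 1)))
    stop("frame interval must be uniform", call. = FALSE)
  ratio <- window_ps / dt
  if (abs(ratio - round(ratio)) > 1e-9 || round(ratio) < 1)
    stop(sprintf(
      "window_ps (%g) must be an integer multiple of the frame interval (%g)",
      window_ps, dt), call. = FALSE)
  t0 <- traj$times_ps[1]
  total_ps <- traj$times_ps[traj$n_frames] - t0
  n_windows <- max(1L, as.integer(ceiling(total_ps / window_ps - 1e-9)))

  counts <- integer(n_windows)
  n_down <- 0L
  n_up <- 0L
  half_box <- if (is.null(traj$box_z)) Inf else traj$box_z / 2

  for (j in seq_len(traj$n_molecules)) {
    z <- traj$z[, j]
    side <- integer(traj$n_frames)
    side[z > slab$z_upper] <- 1L
    side[z < slab$z_lower] <- -1L
    # segment id increments after each periodic-image wrap
    seg <- c(0, cumsum(abs(diff(z)) > half_box))
    def <- which(side != 0L)
    if (length(def) < 2L) next
    s <- side[def]
    g <- seg[def]
    k <- length(def)
    cross <- s[-1] != s[-k] & g[-1] == g[-k]
    if (!any(cross)) next
    at <- def[-1][cross]                       # completing frame index
    dir_down <- s[-k][cross] == 1L
    n_down <- n_down + sum(dir_down)
    n_up <- n_up + sum(!dir_down)
    win <- pmin(as.integer(ceiling((traj$times_ps[at] - t0) / window_ps -
                                     1e-9)), n_windows)
    tab <- tabulate(win, nbins = n_windows)
    counts <- counts + tab
  }
  crossing_counts(counts, window_ps = window_ps,
                  direction_totals = c(down = n_down, up = n_up),
                  meta = list(slab = unclass(slab)))
}
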