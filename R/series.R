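#' Per-window crossing-count series
#'
#' Container for an ordered series of non-negative transition counts, one per
#' fixed-duration observation window. This is the interface object between
#' the trajectory counter and the latent-rate model: `counts[i]` is the
#' number of complete water traversals whose completing frame fell in window
#' `i`.
#'
#' @param counts integer vector of non-negative per-window counts.
#' @param window_ps window duration in picoseconds (default 10).
#' @param direction_totals optional named numeric vector
#'   `c(down = ..., up = ...)`; when supplied it must sum to `sum(counts)`.
#' @param meta optional list of provenance metadata (seed, true parameters,
#'   latent path for synthetic series); stored as-is and written to the JSON
#'   sidecar by [write_counts()].
#'
#' @return An object of class `crossing_counts`: a list with elements
#'   `counts`, `window_ps`, `n_windows`, `direction_totals`, `meta`.
#' @examples
#' x <- crossing_counts(c(0L, 2L, 1L), window_ps = 10)
#' x$n_windows
#' @export
crossing_counts <- function(counts, window_ps = 10, direction_totals = NULL,
                            meta = list()) {
  if (length(counts) < 1L)
    stop("`counts` must be non-empty", call. = FALSE)
  if (anyNA(counts) || any(!is.finite(counts)))
    stop("`counts` must be finite", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("`counts` must be non-negative integers", call. = FALSE)
  if (!is.numeric(window_ps) || length(window_ps) != 1L || window_ps <= 0)
    stop("`window_ps` must be a positive scalar", call. = FALSE)
  counts <- as.integer(round(counts))
  if (is.null(direction_totals)) {
    direction_totals <- c(down = NA_integer_, up = NA_integer_)
  } else {
    direction_totals <- direction_totals[c("down", "up")]
    if (anyNA(direction_totals))
      stop("`direction_totals` must be named c(down=, up=)", call. = FALSE)
    if (sum(direction_totals) != sum(counts))
      stop("direction totals must sum to sum(counts)", call. = FALSE)
  }
  structure(
    list(counts = counts, window_ps = window_ps,
         n_windows = length(counts),
         direction_totals = direction_totals, meta = meta),
    class = "crossing_counts")
}

#' @export
print.crossing_counts <- function(x, ...) {
  cat(sprintf("<crossing_counts> %d windows of %g ps\n", x$n_windows,
              x$window_ps))
  cat(sprintf("  total %d crossings; mean %.3f / window (%.2f molecules/ns)\n",
              sum(x$counts), mean(x$counts),
              mean(x$counts) / (x$window_ps / 1000)))
  if (!anyNA(x$direction_totals))
    cat(sprintf("  down %d / up %d\n", x$direction_totals[["down"]],
                x$direction_totals[["up"]]))
  invisible(x)
}

#' Write / read a count series as CSV plus JSON sidecar
#'
#' The CSV holds columns `window_index,count`; the sidecar
#' (`<path>.json`) carries `window_ps`, direction totals and any metadata
#' (seed, true generator parameters, latent path) so a series round-trips
#' losslessly.
#'
#' @param x a [crossing_counts()] object.
#' @param path CSV file path; the sidecar is written next to it.
#' @return `write_counts()` returns `path` invisibly; `read_counts()`
#'   returns a `crossing_counts` object.
#' @export
write_counts <- function(x, path) {
  stopifnot(inherits(x, "crossing_counts"))
  df <- data.frame(window_index = seq_len(x$n_windows), count = x$counts)
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  side <- list(window_ps = x$window_ps, meta = x$meta)
  if (!anyNA(x$direction_totals))
    side$direction_totals <- as.list(x$direction_totals)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("window_index", "count") %in% names(df)))
    stop("count CSV must have columns window_index,count", call. = FALSE)
  df <- df[order(df$window_index), ]
  window_ps <- 10
  meta <- list()
  dirs <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(side$window_ps)) window_ps <- side$window_ps
    if (!is.null(side$meta)) meta <- side$meta
    if (!is.null(side$direction_totals))
      dirs <- unlist(side$direction_totals)
  }
  crossing_counts(df$count, window_ps = window_ps,
                  direction_totals = dirs, meta = meta)
}
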