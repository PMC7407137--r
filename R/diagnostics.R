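#' Compare a count series' marginal distribution to a matched Poisson
#'
#' The burstiness diagnostic: the observed per-window counts are compared
#' with a Poisson distribution of equivalent expectation (mean matched to
#' the sample mean). Bursty flow shows up as a dispersion index
#' (variance/mean) above 1 and an observed upper tail heavier than the
#' Poisson's. Tail heaviness is quantified at the threshold `k*`, the
#' smallest count with Poisson tail probability at most
#' `1 - tail_threshold_quantile`, as
#' `P_obs(Y >= k*) / P_pois(Y >= k*)`.
#'
#' @param counts a [crossing_counts()] or integer vector.
#' @param tail_threshold_quantile Poisson quantile defining `k*`
#'   (default 0.99).
#' @return A list of class `marginal_comparison`: `observed_histogram`
#'   (data frame count/frequency), `poisson_pmf` (data frame
#'   count/probability up to the largest observed count), `matched_mean`,
#'   `dispersion_index`, `tail_threshold` (`k*`), `tail_mass_ratio`,
#'   `observed_tail_mass`, `poisson_tail_mass`, `n_windows`, and
#'   `all_zero` flag (for an all-zero series the dispersion index is 1 by
#'   convention and the tail ratio undefined).
#' @examples
#' y <- crossing_counts(rpois(1000, 2))
#' compare_to_poisson(y)$dispersion_index
#' @export
compare_to_poisson <- function(counts, tail_threshold_quantile = 0.99) {
  y <- if (inherits(counts, "crossing_counts")) counts$counts
       else as.integer(counts)
  if (length(y) < 1L) stop("counts must be non-empty", call. = FALSE)
  if (tail_threshold_quantile <= 0 || tail_threshold_quantile >= 1)
    stop("`tail_threshold_quantile` must be in (0, 1)", call. = FALSE)
  n <- length(y)
  mu <- mean(y)
  # sparse histogram (counts can reach extreme values under bursty flow)
  tab <- table(y)
  hist_df <- data.frame(count = as.integer(names(tab)),
                        frequency = as.integer(tab))
  # dense matched pmf, truncated where the Poisson mass is exhausted
  pmf_max <- min(max(y), if (mu > 0) qpois(1 - 1e-12, mu) + 10L else 10L)
  pmf_df <- data.frame(count = 0:pmf_max,
                       probability = dpois(0:pmf_max, lambda = mu))
  if (mu == 0) {
    out <- list(observed_histogram = hist_df, poisson_pmf = pmf_df,
                matched_mean = 0, dispersion_index = 1,
                tail_threshold = NA_integer_, tail_mass_ratio = NA_real_,
                observed_tail_mass = NA_real_, poisson_tail_mass = NA_real_,
                n_windows = n, all_zero = TRUE)
    return(structure(out, class = "marginal_comparison"))
  }
  disp <- if (n > 1) var(y) / mu else 1
  # k* = smallest k with Poisson P(Y >= k) <= 1 - q
  kstar <- qpois(tail_threshold_quantile, lambda = mu) + 1L
  pois_tail <- ppois(kstar - 1L, lambda = mu, lower.tail = FALSE)
  obs_tail <- mean(y >= kstar)
  structure(list(observed_histogram = hist_df, poisson_pmf = pmf_df,
                 matched_mean = mu, dispersion_index = disp,
                 tail_threshold = kstar,
                 tail_mass_ratio = obs_tail / pois_tail,
                 observed_tail_mass = obs_tail,
                 poisson_tail_mass = pois_tail,
                 n_windows = n, all_zero = FALSE),
            class = "marginal_comparison")
}

#' @export
print.marginal_comparison <- function(x, ...) {
  cat(sprintf("<marginal_comparison> %d windows, mean %.4f counts/window\n",
              x$n_windows, x$matched_mean))
  if (x$all_zero) {
    cat("  all-zero series: dispersion index 1 by convention, tail ratio",
        "undefined\n")
    return(invisible(x))
  }
  cat(sprintf("  dispersion index (var/mean): %.3f\n", x$dispersion_index))
  cat(sprintf(
    "  tail (k* = %d): observed %.3g vs Poisson %.3g, ratio %.2f\n",
    x$tail_threshold, x$observed_tail_mass, x$poisson_tail_mass,
    x$tail_mass_ratio))
  invisible(x)
}

#' JSON burstiness report for a count series
#'
#' Pure function of its inputs: writes the [compare_to_poisson()] summary
#' (and, if a fit is supplied, the posterior mean flow and parameter
#' quantiles) to a JSON file.
#'
#' @param counts a [crossing_counts()].
#' @param fit optional `flow_fit` from [sample_posterior()].
#' @param path output JSON path.
#' @param tail_threshold_quantile passed to [compare_to_poisson()].
#' @return The report list, invisibly.
#' @export
write_diagnostics_report <- function(counts, path, fit = NULL,
                                     tail_threshold_quantile = 0.99) {
  cmp <- compare_to_poisson(counts, tail_threshold_quantile)
  report <- list(
    n_windows = cmp$n_windows,
    window_ps = if (inherits(counts, "crossing_counts")) counts$window_ps
                else NULL,
    matched_mean = cmp$matched_mean,
    dispersion_index = cmp$dispersion_index,
    tail_threshold = cmp$tail_threshold,
    tail_mass_ratio = cmp$tail_mass_ratio,
    observed_tail_mass = cmp$observed_tail_mass,
    poisson_tail_mass = cmp$poisson_tail_mass,
    all_zero = cmp$all_zero,
    observed_histogram = cmp$observed_histogram,
    poisson_pmf = cmp$poisson_pmf,
    poisson_survival = data.frame(
      count = cmp$poisson_pmf$count,
      probability = ppois(cmp$poisson_pmf$count - 1,
                          lambda = cmp$matched_mean, lower.tail = FALSE)))
  if (!is.null(fit)) {
    rates <- summarize_rates(fit)
    q <- function(m) as.list(setNames(
      quantile(m, c(0.025, 0.5, 0.975)), c("q2.5", "median", "q97.5")))
    report$posterior <- list(
      mean_flow_molecules_per_ns = rates$mean_flow,
      rho = q(fit$rho), sigma = q(fit$sigma), nu = q(fit$nu),
      phi = q(fit$phi))
  }
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "columns")
  invisible(report)
}
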