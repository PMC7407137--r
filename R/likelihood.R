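#' Negative-binomial log-probability mass (mean/overdispersion form)
#'
#' Evaluates \deqn{\log NB(y \mid \mu, \phi) = \log\Gamma(y+\phi) -
#' \log\Gamma(\phi) - \log y! + \phi \log\frac{\phi}{\phi+\mu} +
#' y \log\frac{\mu}{\phi+\mu},} the parameterization with
#' \eqn{E(Y) = \mu} and \eqn{Var(Y) = \mu + \mu^2/\phi}. As
#' \eqn{\phi \to \infty} this converges to the Poisson log-pmf.
#'
#' @param y non-negative integer counts.
#' @param mu mean (> 0), recycled against `y`.
#' @param phi overdispersion (> 0).
#' @return Log-probability, vectorised over inputs.
#' @examples
#' nb_log_pmf(0, mu = 2, phi = 1)  # log(1/3)
#' @export
nb_log_pmf <- function(y, mu, phi) {
  if (any(y < 0) || any(y != round(y)))
    stop("`y` must be non-negative integers", call. = FALSE)
  if (any(mu <= 0) || any(phi <= 0))
    stop("`mu` and `phi` must be positive", call. = FALSE)
  # two numerically delicate pieces at large phi: phi*log(phi/(phi+mu)) is
  # written via log1p, and lgamma(y+phi) - lgamma(phi) via the exact ratio
  # Gamma(y+phi)/Gamma(phi) = prod_{j<y} (phi+j) -- the direct difference
  # of ~1e9-magnitude lgammas loses the 1e-10 target precision
  n_out <- max(length(y), length(mu), length(phi))
  y <- rep_len(y, n_out)
  mu <- rep_len(mu, n_out)
  phi <- rep_len(phi, n_out)
  lg_ratio <- lgamma(y + phi) - lgamma(phi)
  big <- which(phi > 1e6 & y > 0 & y <= 1e4)
  if (length(big))
    lg_ratio[big] <- vapply(big, function(i)
      sum(log(phi[i] + seq_len(y[i]) - 1)), numeric(1))
  out <- lg_ratio - lgamma(y + 1) -
    phi * log1p(mu / phi) + y * (log(mu) - log(phi + mu))
  if (any(!is.finite(out)))
    stop("non-finite negative-binomial log-pmf", call. = FALSE)
  out
}

#' Log-likelihood of a count series under the latent-rate model
#'
#' Sums the per-window negative-binomial observation densities
#' \eqn{\sum_i \log NB(Y_i \mid \mu = e^{\lambda_i}, \phi)} for a given
#' latent log-rate path.
#'
#' @param params list with `lambda` (per-window log expected counts, same
#'   length as the series) and `phi` (> 0); `rho`, `sigma`, `nu` may be
#'   present and are ignored here (they enter through
#'   [latent_transition_log_density()] and the priors).
#' @param counts a [crossing_counts()] object or plain integer vector.
#' @return Scalar log-likelihood.
#' @export
nb_log_likelihood <- function(params, counts) {
  y <- if (inherits(counts, "crossing_counts")) counts$counts else counts
  if (length(params$lambda) != length(y))
    stop("`params$lambda` and counts must have equal length", call. = FALSE)
  if (any(!is.finite(params$lambda)))
    stop("`params$lambda` must be finite", call. = FALSE)
  sum(nb_log_pmf(y, mu = exp(params$lambda), phi = params$phi))
}

#' Student-t log-density of latent transitions
#'
#' Location-scale t density of \eqn{\lambda_i} given \eqn{\lambda_{i-1}}:
#' location \eqn{\rho\lambda_{i-1}}, scale \eqn{\sigma}, degrees of freedom
#' \eqn{\nu}. Summed over the whole path (transitions 2..n).
#'
#' @param lambda latent log-rate path (length >= 2).
#' @param rho autocorrelation.
#' @param sigma innovation scale (> 0).
#' @param nu degrees of freedom (> 0).
#' @return Scalar log-density of the path's transitions.
#' @export
latent_transition_log_density <- function(lambda, rho, sigma, nu) {
  if (sigma <= 0 || nu <= 0)
    stop("`sigma` and `nu` must be positive", call. = FALSE)
  n <- length(lambda)
  if (n < 2) stop("need a path of length >= 2", call. = FALSE)
  e <- (lambda[-1] - rho * lambda[-n]) / sigma
  sum(stats::dt(e, df = nu, log = TRUE) - log(sigma))
}

#' Prior specification for the latent-rate model
#'
#' The model's weakly informative priors: `1/phi ~ HalfCauchy(0, 5)`,
#' `sigma ~ HalfCauchy(0, 5)`, `nu ~ Gamma(shape 2, rate 0.1)`,
#' `rho ~ Normal(0, 1)`, `lambda1 ~ Cauchy(0, 5)`. Scales/shapes can be
#' overridden; the families are fixed.
#'
#' @param inv_phi_scale HalfCauchy scale on `1/phi`.
#' @param sigma_scale HalfCauchy scale on `sigma`.
#' @param nu_shape,nu_rate Gamma shape and rate on `nu`.
#' @param rho_sd Normal standard deviation on `rho`.
#' @param lambda1_scale Cauchy scale on the initial log rate.
#' @return A list of class `prior_spec`.
#' @export
prior_spec <- function(inv_phi_scale = 5, sigma_scale = 5, nu_shape = 2,
                       nu_rate = 0.1, rho_sd = 1, lambda1_scale = 5) {
  vals <- c(inv_phi_scale, sigma_scale, nu_shape, nu_rate, rho_sd,
            lambda1_scale)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all prior hyperparameters must be positive", call. = FALSE)
  structure(list(inv_phi_scale = inv_phi_scale, sigma_scale = sigma_scale,
                 nu_shape = nu_shape, nu_rate = nu_rate, rho_sd = rho_sd,
                 lambda1_scale = lambda1_scale),
            class = "prior_spec")
}

half_cauchy_log_density <- function(x, scale) {
  ifelse(x < 0, -Inf, log(2) - log(pi * scale) - log1p((x / scale)^2))
}

#' Joint log-prior of the model parameters
#'
#' Evaluates the priors of [prior_spec()] at `(rho, sigma, nu, phi,
#' lambda1)`. `phi` enters through its reciprocal: the HalfCauchy prior is
#' placed on `1/phi` exactly as specified; `prior_on` selects whether the
#' returned density is with respect to `1/phi` (default, the sampled scale)
#' or `phi` (with the `1/phi^2` change-of-variables Jacobian), which define
#' the same distribution.
#'
#' @param params list with `rho`, `sigma`, `nu`, `phi`, and `lambda` (or
#'   `lambda1`).
#' @param priors a [prior_spec()].
#' @param prior_on `"inv_phi"` or `"phi"`: the variable of integration for
#'   the overdispersion component.
#' @return Scalar log-prior density.
#' @export
log_prior <- function(params, priors = prior_spec(),
                      prior_on = c("inv_phi", "phi")) {
  prior_on <- match.arg(prior_on)
  lambda1 <- if (!is.null(params$lambda1)) params$lambda1
             else params$lambda[1]
  lp <- stats::dnorm(params$rho, 0, priors$rho_sd, log = TRUE) +
    half_cauchy_log_density(params$sigma, priors$sigma_scale) +
    stats::dgamma(params$nu, shape = priors$nu_shape, rate = priors$nu_rate,
                  log = TRUE) +
    stats::dcauchy(lambda1, 0, priors$lambda1_scale, log = TRUE)
  u <- 1 / params$phi
  lp_u <- half_cauchy_log_density(u, priors$inv_phi_scale)
  lp + switch(prior_on,
              inv_phi = lp_u,
              phi = lp_u - 2 * log(params$phi))  # |d(1/phi)/dphi| = 1/phi^2
}

#' Joint log-posterior density (reference implementation)
#'
#' Plain-R evaluation of the unnormalised log posterior
#' `log p(Y | lambda, phi) + log p(lambda | rho, sigma, nu) + log prior`,
#' used as the reference the compiled sampler is checked against.
#'
#' @inheritParams nb_log_likelihood
#' @inheritParams log_prior
#' @return Scalar unnormalised log-posterior.
#' @export
log_posterior <- function(params, counts, priors = prior_spec()) {
  y <- if (inherits(counts, "crossing_counts")) counts$counts else counts
  ll <- nb_log_likelihood(params, y)
  lt <- if (length(params$lambda) >= 2)
    latent_transition_log_density(params$lambda, params$rho, params$sigma,
                                  params$nu) else 0
  ll + lt + log_prior(params, priors)
}
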