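test_that("NegBin log-pmf matches its closed form and stats::dnbinom", {
  # closed-form spot value: y = 0, mu = 2, phi = 1 -> log(1/3)
  expect_equal(nb_log_pmf(0, 2, 1), log(1 / 3), tolerance = 1e-12)
  # grid check against the independent evaluation
  grid <- expand.grid(y = c(0:10, 25, 50),
                      mu = c(0.01, 0.1, 0.5, 2, 10, 50),
                      phi = c(0.1, 0.5, 1, 5, 100))
  ours <- nb_log_pmf(grid$y, grid$mu, grid$phi)
  ref <- dnbinom(grid$y, size = grid$phi, mu = grid$mu, log = TRUE)
  expect_lt(max(abs(ours - ref)), 1e-10)
})

test_that("NegBin approaches the Poisson log-pmf as phi grows", {
  grid <- expand.grid(y = c(0, 1, 3, 10, 40), mu = c(0.3, 2, 12))
  ours <- nb_log_pmf(grid$y, grid$mu, 1e8)
  pois <- dpois(grid$y, grid$mu, log = TRUE)
  expect_lt(max(abs(ours - pois)), 1e-5)
})

test_that("single-observation likelihood is maximised at mu = y", {
  for (y in c(1L, 3L, 7L)) {
    mus <- seq(0.2, 3 * y, length.out = 400)
    ll <- nb_log_pmf(y, mus, phi = 2)
    expect_equal(mus[which.max(ll)], y, tolerance = 0.05)
  }
})

test_that("path likelihood and transition density validate inputs", {
  y <- c(1L, 0L, 2L)
  expect_equal(nb_log_likelihood(list(lambda = log(c(1, 1, 2)), phi = 2), y),
               sum(dnbinom(y, size = 2, mu = c(1, 1, 2), log = TRUE)),
               tolerance = 1e-12)
  expect_error(nb_log_likelihood(list(lambda = c(0, 0), phi = 2), y),
               "length")
  lam <- c(0.5, 0.4, 0.8)
  expect_equal(latent_transition_log_density(lam, 0.9, 0.5, 4),
               sum(dt((lam[-1] - 0.9 * lam[-3]) / 0.5, df = 4, log = TRUE) -
                     log(0.5)), tolerance = 1e-12)
  expect_error(latent_transition_log_density(lam, 0.9, 0, 4), "positive")
})

test_that("phi prior change-of-variables preserves posterior expectations", {
  # 1-D check by quadrature: the posterior expectation of phi for a tiny
  # dataset must agree whether the integration variable is phi (with
  # Jacobian) or u = 1/phi
  y <- c(0L, 2L, 1L, 4L, 0L)
  lam <- log(mean(y) + 0.2)
  target <- function(phi, on) {
    exp(sapply(phi, function(p)
      nb_log_likelihood(list(lambda = rep(lam, 5), phi = p), y) +
        log_prior(list(rho = 0, sigma = 0.5, nu = 5, phi = p,
                       lambda1 = lam), prior_on = on)))
  }
  # both routes integrated on the log scale so quadrature sees the peak;
  # the log-Jacobians differ exactly by the 1/phi^2 change of variables
  f_logphi <- function(t) target(exp(t), "phi") * exp(t)
  num_phi <- integrate(function(t) exp(t) * f_logphi(t), -14, 14,
                       rel.tol = 1e-10)$value /
    integrate(f_logphi, -14, 14, rel.tol = 1e-10)$value
  f_logu <- function(t) target(exp(-t), "inv_phi") * exp(t)
  num_u <- integrate(function(t) exp(-t) * f_logu(t), -14, 14,
                     rel.tol = 1e-10)$value /
    integrate(f_logu, -14, 14, rel.tol = 1e-10)$value
  expect_equal(num_phi, num_u, tolerance = 1e-6)
})

test_that("compiled log posterior matches the R reference plus Jacobians", {
  set.seed(42)
  y <- rpois(30, 1.2)
  n <- length(y)
  theta <- c(0.3, rnorm(n - 1, 0, 0.4), 0.7, log(0.6), log(8), -0.3)
  pr <- prior_spec()
  res <- permflow:::.flow_logp_grad(theta, y, unclass(pr))
  rho <- theta[n + 1]; sigma <- exp(theta[n + 2]); nu <- exp(theta[n + 3])
  phi <- exp(-theta[n + 4])
  lam <- numeric(n); lam[1] <- theta[1]
  for (i in 2:n) lam[i] <- rho * lam[i - 1] + sigma * theta[i]
  ref <- log_posterior(list(lambda = lam, rho = rho, sigma = sigma,
                            nu = nu, phi = phi), y, pr)
  # unconstrained scale: log-Jacobians of sigma, nu, 1/phi plus the
  # non-centered change of variables (eta has no 1/sigma factors)
  adj <- theta[n + 2] + theta[n + 3] + theta[n + 4] + (n - 1) * log(sigma)
  expect_equal(res$logp, ref + adj, tolerance = 1e-8)
})

test_that("compiled gradient matches finite differences everywhere", {
  set.seed(7)
  y <- rnbinom(25, size = 0.6, mu = 1.5)
  n <- length(y)
  pr <- unclass(prior_spec())
  for (rep in 1:3) {
    theta <- c(rnorm(1, 0, 0.5), rnorm(n - 1, 0, 0.6), runif(1, -0.9, 0.9),
               rnorm(1, -0.7, 0.3), rnorm(1, 2, 0.5), rnorm(1, 0, 0.5))
    res <- permflow:::.flow_logp_grad(theta, y, pr)
    h <- 1e-6
    num <- vapply(seq_along(theta), function(k) {
      tp <- theta; tm <- theta
      tp[k] <- tp[k] + h; tm[k] <- tm[k] - h
      (permflow:::.flow_logp_grad(tp, y, pr)$logp -
         permflow:::.flow_logp_grad(tm, y, pr)$logp) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(num - res$grad)), 1e-4)
  }
})
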