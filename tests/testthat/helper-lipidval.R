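# Shared fixtures and independent oracles for the test suite.
# Expected values marked "frozen" were computed once with the oracle
# and hard-coded; the oracles stay independent of the package code
# paths they check.

# Cohort with simulated outcomes under known (drift_a, drift_b)
# miscalibration relative to `model`.
make_cohort <- function(n, model = nonhdl_model(), drift_a = 0,
                        drift_b = 1, seed = 1L, ...) {
  spec <- cohort_spec(n = n, seed = seed, ...)
  cohort <- generate_cohort(spec)
  sim <- outcome_sim_spec(model, drift_intercept = drift_a,
                          drift_slope = drift_b, seed = seed + 1L)
  simulate_outcomes(cohort, sim)
}

# Brute-force pairwise concordance (ties count one half).
brute_auroc <- function(y, p) {
  cases <- p[y == 1]
  controls <- p[y == 0]
  tot <- 0
  for (x in cases) tot <- tot + sum(x > controls) + 0.5 * sum(x == controls)
  tot / (length(cases) * length(controls))
}

# Independent maximizer of the Bernoulli likelihood of
# logit P(y=1) = a + b*lp, by refining 2-D grid search (no glm).
grid_slope_mle <- function(y, lp) {
  loglik <- function(a, b) {
    eta <- a + b * lp
    sum(y * eta - log1p(exp(eta)))
  }
  a0 <- 0; b0 <- 1; half_a <- 5; half_b <- 5
  for (level in 1:6) {
    as <- seq(a0 - half_a, a0 + half_a, length.out = 41)
    bs <- seq(b0 - half_b, b0 + half_b, length.out = 41)
    ll <- outer(as, bs, Vectorize(loglik))
    best <- arrayInd(which.max(ll), dim(ll))
    a0 <- as[best[1]]; b0 <- bs[best[2]]
    half_a <- half_a / 10; half_b <- half_b / 10
  }
  c(a = a0, b = b0)
}

# Bernoulli log-likelihood of a model's predictions on a cohort.
model_loglik <- function(model, cohort) {
  y <- cohort[[paste0("y_", model$endpoint)]]
  p <- pmin(pmax(predicted_probability(model, cohort), 1e-12), 1 - 1e-12)
  sum(y * log(p) + (1 - y) * log(1 - p))
}

# Moments of a normal truncated to [lo, hi] (closed form), the honest
# expectation for the generator's rejection-sampled marginals.
truncnorm_moments <- function(mu, sd, lo = -Inf, hi = Inf) {
  a <- (lo - mu) / sd; b <- (hi - mu) / sd
  Z <- pnorm(b) - pnorm(a)
  da <- dnorm(a); db <- dnorm(b)
  m <- mu + sd * (da - db) / Z
  aa <- ifelse(is.finite(a), a * da, 0)
  bb <- ifelse(is.finite(b), b * db, 0)
  v <- sd^2 * (1 + (aa - bb) / Z - ((da - db) / Z)^2)
  c(mean = m, sd = sqrt(v))
}
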