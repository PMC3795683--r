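# Independent oracles and shared fixtures. Everything here is deliberately
# written from the definitions, not by calling package internals.

# Benjamini-Hochberg step-up, straight from the definition:
# q_(i) = min_{j >= i} p_(j) * n / j, capped at 1.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  po <- p[o]
  q_sorted <- rev(pmin(cummin(rev(po * n / seq_len(n))), 1))
  q <- numeric(n)
  q[o] <- q_sorted
  q
}

# Efron-tie Cox log partial likelihood for a single covariate, evaluated on
# a grid of coefficients (columns). Direct transcription of the likelihood.
efron_loglik_grid <- function(time, event, x, betas) {
  w <- exp(outer(x, betas))                       # n x B
  ll <- sum(x[event == 1]) * betas
  for (t in sort(unique(time[event == 1]))) {
    risk <- time >= t
    dset <- time == t & event == 1
    d <- sum(dset)
    sr <- colSums(w[risk, , drop = FALSE])
    sd_ <- colSums(w[dset, , drop = FALSE])
    for (l in seq_len(d) - 1) {
      ll <- ll - log(sr - (l / d) * sd_)
    }
  }
  ll
}

# Grid-search maximizer of the Efron partial likelihood.
cox_grid_oracle <- function(time, event, x, lo = -5, hi = 5, step = 1e-4) {
  betas <- seq(lo, hi, by = step)
  betas[which.max(efron_loglik_grid(time, event, x, betas))]
}

# Small survival fixtures (<= 8 subjects, one binary covariate), exercising
# distinct times, tied event times, and censoring.
cox_fixtures <- list(
  distinct = list(time = c(1, 2, 3, 4, 5, 6),
                  event = c(1, 1, 1, 1, 1, 1),
                  x = c(0, 1, 0, 1, 1, 0)),
  censored = list(time = c(2, 4, 4.5, 5, 7, 9),
                  event = c(1, 0, 1, 1, 0, 1),
                  x = c(1, 1, 0, 1, 0, 0)),
  tied = list(time = c(1, 1, 2, 2, 3, 4, 5, 6),
              event = c(1, 1, 1, 1, 0, 1, 1, 1),
              x = c(1, 0, 1, 1, 0, 0, 1, 0))
)

# Hand-computed two-group log-rank fixture. Group x: times 1 (event),
# 3 (event), 5 (censored); group y: 2, 4, 6 (all events).
#  t=1: n=6, n_x=3, d=1 -> E += 3/6,  V += (3/6)(3/6)(5/5)   = 0.25
#  t=2: n=5, n_x=2, d=1 -> E += 2/5,  V += (2/5)(3/5)(4/4)   = 0.24
#  t=3: n=4, n_x=2, d=1 -> E += 2/4,  V += (2/4)(2/4)(3/3)   = 0.25
#  t=4: n=3, n_x=1, d=1 -> E += 1/3,  V += (1/3)(2/3)(2/2)   = 2/9
#  t=6: n=1 (only the event itself)   -> no variance contribution, E += 0
#  O_x = 2, E_x = 0.5+0.4+0.5+1/3 = 26/15, V = 0.25+0.24+0.25+2/9
logrank_fixture <- list(
  time = c(1, 3, 5, 2, 4, 6),
  event = c(1, 1, 0, 1, 1, 1),
  group = c("x", "x", "x", "y", "y", "y"),
  observed = 2,
  expected = 26 / 15,
  variance = 0.25 + 0.24 + 0.25 + 2 / 9
)
logrank_fixture$statistic <-
  (logrank_fixture$observed - logrank_fixture$expected)^2 /
  logrank_fixture$variance

# Tiny default simulations reused across tests.
small_two_pop <- function(seed = 3, ...) {
  simulate_two_population_expression(
    two_pop_sim_config(n_genes = 300, n_marker_per_direction = 15,
                       seed = seed, ...))
}

small_cohort <- function(seed = 5, ...) {
  simulate_survival_cohort(cohort_sim_config(seed = seed, ...))
}
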