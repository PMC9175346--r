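# Shared fixtures, built in code.

# Brute-force pseudo-covariate oracle: the double sum over (u, k) written
# out directly, independent of the convolution used by the package.
brute_pseudo <- function(doses, basis) {
  B <- basis$matrix
  Tw <- basis$window
  L <- length(doses)
  Z <- matrix(0, L, ncol(B))
  for (t in seq_len(L)) {
    for (u in seq_len(t)) {
      v <- t - u + 1
      if (v <= Tw) {
        for (k in seq_len(ncol(B))) {
          Z[t, k] <- Z[t, k] + B[v, k] * doses[u]
        }
      }
    }
  }
  Z
}

# A small simulated dataset with one code of each truth type, shared across
# test files (built once per test run).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      truth <- tibble::tibble(
        code = c("ACU", "CONF", "NUL1", "NUL2"),
        code_system = c("ATC5", "ATC5", "ICD10", "PROC"),
        type = c("acute", "confounded_null", "null", "null"),
        baseline_multiplier = 1,
        sev_loghr = c(0, log(3), 0, 0),
        weight = list(weight_acute(12, log(3)), weight_null(12),
                      weight_null(12), weight_null(12))
      )
      cfg <- sim_config(n_patients = 250, study_months = 48, p_init = 0.1,
                        p_persist = 0.8, truth = truth,
                        baseline_hazard = 0.008, seed = 2024)
      cache <<- simulate_cohort(cfg)
    }
    cache
  }
})

# Person-period table with pseudo-covariates for one code of small_sim().
small_pp <- function(code = "ACU", basis = wce_basis(12, 1)) {
  sim <- small_sim()
  ev <- event_dates(sim$claims, sim$cohort, code)
  pp <- wcescreen:::build_pp_table(sim$cohort, ev)
  wcescreen:::add_pseudo_covariates(pp, sim$cohort, basis)
}

# Independent 1-D maximizer of the matched conditional likelihood:
# coarse grid then interval refinement, never Newton.
grid_mle <- function(xr, xc) {
  ll <- function(b) sum(b * xr - log(exp(b * xr) + rowSums(exp(b * xc))))
  grid <- seq(-4, 4, by = 0.01)
  b0 <- grid[which.max(vapply(grid, ll, 0))]
  stats::optimize(ll, c(b0 - 0.02, b0 + 0.02), maximum = TRUE,
                  tol = 1e-10)$maximum
}

# Matched 1:3 case-crossover sets from (risk, c1, c2, c3) patterns.
make_sets <- function(patterns, counts) {
  purrr::map2_dfr(patterns, counts, function(p, n) {
    tibble::tibble(patient_id = "x", event_month = 0L, risk = p[1],
                   control1 = p[2], control2 = p[3],
                   control3 = p[4])[rep(1, n), ]
  })
}

# Random counting-process dataset in person-period form (monthly rows).
random_pp_data <- function(n = 150, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n), function(i) {
    L <- sample(3:10, 1)
    x1 <- rbinom(1, 1, 0.5)
    x2 <- rnorm(1)
    ev <- rbinom(1, 1, 0.5)
    data.frame(id = i, start = 0:(L - 1), stop = 1:L,
               event = c(rep(0L, L - 1), ev), x1 = x1, x2 = x2,
               xt = round(rnorm(L), 2))
  }))
}
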