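test_that("pseudo-covariates match the brute-force double sum", {
  basis <- wce_basis(8, 1)
  # single dose at month 1: Z_k(3) = B_k(3)
  Z <- pseudo_covariates(c(1, 0, 0, 0, 0), basis)
  expect_equal(Z[3, ], basis$matrix[3, ], tolerance = 1e-14)
  # all-zero exposure
  expect_equal(pseudo_covariates(rep(0, 10), basis),
               matrix(0, 10, ncol(basis$matrix)), ignore_attr = TRUE)
  # random exposures vs the double loop
  set.seed(11)
  for (i in 1:20) {
    Tw <- sample(7:12, 1)
    b <- wce_basis(Tw, sample(0:2, 1))
    x <- rbinom(sample(Tw:(3 * Tw), 1), 1, 0.4)
    expect_equal(pseudo_covariates(x, b), brute_pseudo(x, b),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("linear predictor equals the brute-force weighted sum for any theta", {
  set.seed(12)
  basis <- wce_basis(6, 1)
  for (i in 1:10) {
    x <- rbinom(15, 1, 0.5)
    theta <- rnorm(ncol(basis$matrix))
    w <- drop(basis$matrix %*% theta)
    Z <- pseudo_covariates(x, basis)
    lp_direct <- sapply(seq_along(x), function(t) {
      s <- 0
      for (u in seq_len(t)) {
        v <- t - u + 1
        if (v <= 6) s <- s + w[v] * x[u]
      }
      s
    })
    expect_equal(drop(Z %*% theta), lp_direct, tolerance = 1e-12)
  }
})

test_that("a constant basis reduces the WCE fit to a cumulative-dose Cox model", {
  skip_if_not_installed("survival")
  pp <- small_pp("ACU")
  Tw <- 12
  ones <- structure(list(
    matrix = matrix(1, Tw, 1, dimnames = list(NULL, "Z1")),
    window = Tw, nknots = 0L, degree = 3L, constrained = "none",
    knots = numeric(0)), class = "wce_basis")
  sim <- small_sim()
  ev <- event_dates(sim$claims, sim$cohort, "ACU")
  base <- wcescreen:::build_pp_table(sim$cohort, ev)
  base <- wcescreen:::add_pseudo_covariates(base, sim$cohort, ones)
  fit <- fit_wce(base, ones, covariates = c("age", "sex", "severity"),
                 eps = 1e-10)
  # oracle: survival::coxph on the rolling cumulative dose
  cum <- base$Z1
  cp <- survival::coxph(
    survival::Surv(Start, Stop, Event) ~ cum + age + sex + severity,
    data = dplyr::mutate(base, cum = cum), ties = "efron",
    control = survival::coxph.control(eps = 1e-10, iter.max = 100,
                                      timefix = FALSE))
  expect_lt(abs(fit$theta[["Z1"]] - coef(cp)[["cum"]]) /
              abs(coef(cp)[["cum"]]), 1e-6)
  expect_equal(unname(fit$gamma), unname(coef(cp)[2:4]), tolerance = 1e-6)
})

test_that("cloning every patient leaves estimates unchanged (likelihood homogeneity)", {
  # With month-level ties, duplication changes the tie structure: under
  # Breslow the score doubles exactly (identical estimates) and the loglik
  # doubles up to the deterministic tie constant -2 log(2) per event; Efron
  # re-weights within enlarged tie groups, so it is only checked loosely.
  basis <- wce_basis(12, 1)
  pp <- small_pp("ACU", basis)
  pp2 <- dplyr::bind_rows(pp, dplyr::mutate(pp, Id = paste0(Id, "_clone")))
  fit1 <- fit_wce(pp, basis, ties = "breslow")
  fit2 <- fit_wce(pp2, basis, ties = "breslow")
  expect_equal(fit2$theta, fit1$theta, tolerance = 1e-7)
  expect_equal(fit2$gamma, fit1$gamma, tolerance = 1e-7)
  D <- sum(pp$Event)
  expect_equal(fit2$loglik, 2 * fit1$loglik - 2 * log(2) * D,
               tolerance = 1e-7)
  fe1 <- fit_wce(pp, basis, ties = "efron")
  fe2 <- fit_wce(pp2, basis, ties = "efron")
  expect_equal(fe2$theta, fe1$theta, tolerance = 0.05)
})

test_that("row order and patient labels do not affect the fit", {
  basis <- wce_basis(12, 1)
  pp <- small_pp("ACU", basis)
  fit1 <- fit_wce(pp, basis)
  set.seed(13)
  perm <- sample(nrow(pp))
  pp_shuffled <- dplyr::mutate(pp[perm, ], Id = paste0("relabelled", Id))
  fit2 <- fit_wce(pp_shuffled, basis)
  expect_equal(fit2$theta, fit1$theta, tolerance = 1e-8)
  expect_equal(fit2$loglik, fit1$loglik, tolerance = 1e-8)
})

test_that("likelihood at the optimum dominates the null", {
  basis <- wce_basis(12, 1)
  fit <- fit_wce(small_pp("ACU", basis), basis)
  expect_true(fit$converged)
  expect_gte(fit$loglik, fit$loglik_null)
})

test_that("weight function and window HR follow from the coefficients", {
  basis <- wce_basis(12, 1)
  fit <- fit_wce(small_pp("ACU", basis), basis)
  expect_equal(fit$weight, drop(basis$matrix %*% fit$theta), tolerance = 1e-12)
  wf <- weight_function(fit)
  expect_equal(wf$weight, fit$weight)
  expect_equal(window_hr(fit), exp(sum(fit$weight)), tolerance = 1e-12)
  # closed forms on constructed fits
  f0 <- fit
  f0$weight <- rep(0, 12); f0$window_hr <- exp(sum(f0$weight))
  expect_equal(window_hr(f0), 1)
  f2 <- fit
  f2$weight <- rep(log(2) / 12, 12); f2$window_hr <- exp(sum(f2$weight))
  expect_equal(window_hr(f2), 2, tolerance = 1e-12)
})

test_that("null data give a weight function indistinguishable from zero", {
  basis <- wce_basis(12, 1)
  pp <- small_pp("NUL1", basis)
  fit <- fit_wce(pp, basis)
  expect_true(fit$converged)
  expect_true(all(abs(fit$weight) < 3.5 * fit$se_weight))
  ci <- fit$log_window_hr + c(-3, 3) * fit$se_log_window_hr
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("sparse codes are reported as not evaluated, empty ones refused", {
  basis <- wce_basis(12, 1)
  pp <- small_pp("ACU", basis)
  ids <- unique(pp$Id)
  few <- dplyr::filter(pp, Id %in% ids[1:12])
  fit <- fit_wce(few, basis, min_events = 1000)
  expect_equal(fit$status, "not evaluated")
  expect_error(fit_wce(dplyr::mutate(pp, Event = 0L), basis), "no events")
})

test_that("tidy and glance return well-formed summaries", {
  basis <- wce_basis(12, 1)
  fit <- fit_wce(small_pp("ACU", basis), basis)
  td <- tidy(fit)
  expect_equal(nrow(td), ncol(basis$matrix) + 3)
  expect_true(all(c("term", "estimate", "std.error") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$status, "ok")
  expect_equal(gl$window_hr, window_hr(fit))
})
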