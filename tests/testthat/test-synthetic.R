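test_that("configs validate probabilities and sizes", {
  expect_error(sim_config(p_init = 1.2), "invalid probability")
  expect_error(sim_config(p_persist = -0.1), "invalid probability")
  expect_error(sim_config(n_patients = 0), "n_patients")
  expect_error(sim_config(study_months = 40,
                          truth = default_truth(window = 24)), "2 x")
})

test_that("identical config and seed give byte-identical datasets", {
  cfg <- sim_config(n_patients = 60, study_months = 48,
                    truth = default_truth(window = 12, n_null = 3), seed = 9)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$claims, b$claims)
  expect_identical(a$demographics, b$demographics)
  expect_identical(a$cohort, b$cohort)
})

test_that("degenerate exposure processes behave as stated", {
  base_truth <- default_truth(window = 12, n_null = 1)
  # initiation probability ~1 at the first eligible month, persistence 1:
  # every patient exposed every month of follow-up
  cfg <- sim_config(n_patients = 40, study_months = 30, p_init = 0.999999,
                    p_persist = 1, sev_persist_logodds = 0,
                    truth = base_truth, seed = 4)
  sim <- simulate_cohort(cfg)
  expect_true(all(sim$cohort$index_month == cfg$lookback))
  expect_true(all(purrr::map_lgl(sim$cohort$doses, ~ all(.x == 1))))
  # persistence 0: exactly one dispensing month each
  cfg0 <- sim_config(n_patients = 40, study_months = 30, p_persist = 0,
                     sev_persist_logodds = 0, truth = base_truth, seed = 4)
  sim0 <- simulate_cohort(cfg0)
  n_disp <- sim0$claims %>%
    dplyr::filter(code == "P01BA02") %>%
    dplyr::count(patient_id)
  expect_true(all(n_disp$n == 1))
  expect_equal(nrow(n_disp), 40)
})

test_that("every patient is exposed and events never precede the index dispensing", {
  sim <- small_sim()
  drug <- dplyr::filter(sim$claims, code == "P01BA02")
  expect_setequal(unique(drug$patient_id), sim$demographics$patient_id)
  first_disp <- dplyr::summarise(drug, first = min(date), .by = patient_id)
  ev <- sim$claims %>%
    dplyr::filter(code_system != "ALD", code != "P01BA02") %>%
    dplyr::left_join(first_disp, by = "patient_id")
  expect_true(all(ev$date >= ev$first))
})

test_that("zero hazard produces no events and negative baseline errors", {
  expect_identical(simulate_first_event(c(1, 1, 0), weight_null(3),
                                        baseline = 0.5, multiplier = 0),
                   NA_integer_)
  expect_error(simulate_first_event(c(1, 0), weight_null(2), baseline = -1),
               "negative baseline")
})

test_that("null weights give equal hazards in exposed and unexposed person-months", {
  # stratified empirical event rates over one large simulation
  truth <- tibble::tibble(code = "NUL", code_system = "ICD10", type = "null",
                          baseline_multiplier = 1, sev_loghr = 0,
                          weight = list(weight_null(6)))
  cfg <- sim_config(n_patients = 4000, study_months = 40, p_init = 0.15,
                    p_persist = 0.6, sev_persist_logodds = 0, truth = truth,
                    baseline_hazard = 0.01, seed = 77)
  sim <- simulate_cohort(cfg)
  ev <- event_dates(sim$claims, sim$cohort, "NUL")
  pp <- wcescreen:::build_pp_table(sim$cohort, ev)
  pp <- dplyr::filter(pp, Stop >= 2) # events only possible after the index month
  rate <- pp %>%
    dplyr::summarise(events = sum(Event), months = dplyr::n(), .by = dose)
  p1 <- rate$events[rate$dose == 1] / rate$months[rate$dose == 1]
  p0 <- rate$events[rate$dose == 0] / rate$months[rate$dose == 0]
  se <- sqrt(1 / rate$events[rate$dose == 1] + 1 / rate$events[rate$dose == 0])
  expect_lt(abs(log(p1 / p0)), 3 * se)
  # and both near the nominal monthly probability
  expect_equal(p1, 1 - exp(-0.01), tolerance = 0.15)
})

test_that("a purely acute weight concentrates hazard in dosed months", {
  w <- c(log(4), rep(0, 5))
  truth <- tibble::tibble(code = "ACU", code_system = "ATC5", type = "acute",
                          baseline_multiplier = 1, sev_loghr = 0,
                          weight = list(w))
  cfg <- sim_config(n_patients = 4000, study_months = 40, p_init = 0.15,
                    p_persist = 0.6, sev_persist_logodds = 0, truth = truth,
                    baseline_hazard = 0.004, seed = 78)
  sim <- simulate_cohort(cfg)
  ev <- event_dates(sim$claims, sim$cohort, "ACU")
  pp <- wcescreen:::build_pp_table(sim$cohort, ev)
  pp <- dplyr::filter(pp, Stop >= 2)
  rate <- pp %>%
    dplyr::summarise(events = sum(Event), months = dplyr::n(), .by = dose)
  p1 <- rate$events[rate$dose == 1] / rate$months[rate$dose == 1]
  p0 <- rate$events[rate$dose == 0] / rate$months[rate$dose == 0]
  # discrete-hazard ratio between currently-dosed and undosed months
  # reproduces exp(w(1)) = 4 within Monte-Carlo error
  se <- sqrt(1 / rate$events[rate$dose == 1] + 1 / rate$events[rate$dose == 0])
  expect_lt(abs(log(p1 / p0) - log(4)), 3 * se)
})

test_that("truth_report classifies codes and handles edge cases", {
  truth <- default_truth(window = 12, n_null = 2)
  signals <- tibble::tibble(
    code = truth$code,
    status = c("significant", "significant", "not significant",
               "not significant", "not significant")
  )
  rep <- truth_report(truth, signals)
  expect_equal(rep$metrics$sensitivity, 1)
  expect_equal(rep$metrics$specificity, 1)
  expect_equal(rep$metrics$fp_rate, 0)
  expect_equal(sort(unique(rep$codes$label)),
               c("true negative", "true positive"))

  empty <- truth_report(truth[0, ], signals[0, ])
  expect_equal(nrow(empty$codes), 0)

  # weight-function error against truth
  fw <- list(N02BE01 = truth$weight[[1]] + 0.1)
  rep2 <- truth_report(truth, signals, fitted_weights = fw)
  expect_equal(rep2$metrics$weight_mae, 0.1, tolerance = 1e-12)
  expect_error(truth_report(truth, signals, fitted_weights = list(ZZ = 1:12)),
               "absent from truth")

  bad <- dplyr::mutate(signals, code = paste0("X", code))
  expect_error(truth_report(truth, bad), "absent from truth")
})
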