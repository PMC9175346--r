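toy_claims <- function(months, code = "DRUG", id = "P1", system = "ATC5") {
  tibble::tibble(patient_id = id, date = month_date(months),
                 code_system = system, code = code,
                 month = as.integer(months))
}

test_that("new-user selection applies the lookback observability rule", {
  # first dispensing at month 15, none before: included with index 15
  cl <- toy_claims(c(15, 20))
  out <- select_new_users(cl, "DRUG", lookback = 12, obs_start = 0)
  expect_equal(out$index_month, 15L)
  # first dispensing at month 3 with data starting at 0: lookback window
  # extends before the data -> excluded
  cl2 <- toy_claims(c(3, 10))
  expect_equal(nrow(select_new_users(cl2, "DRUG", 12, obs_start = 0)), 0)
  # same dispensing pattern but 12 months of observation before month 2
  cl3 <- toy_claims(c(2, 20))
  expect_equal(nrow(select_new_users(cl3, "DRUG", 12, obs_start = 0)), 0)
  out3 <- select_new_users(cl3, "DRUG", 12, obs_start = -12)
  expect_equal(out3$index_month, 2L)
})

test_that("unknown drug code yields an empty cohort with a warning", {
  cl <- toy_claims(15)
  expect_warning(out <- select_new_users(cl, "NOPE"), "not found")
  expect_equal(nrow(out), 0)
})

test_that("monthly exposure collapses dispensings and respects length", {
  cohort <- tibble::tibble(patient_id = "P1", index_month = 20L)
  cl <- toy_claims(c(20, 20, 20)) # three dispensings in the index month
  out <- monthly_exposure(cl, "DRUG", cohort, end_month = 23)
  expect_equal(out$doses[[1]], c(1L, 0L, 0L, 0L))
  cl2 <- toy_claims(20:25)
  out2 <- monthly_exposure(cl2, "DRUG", cohort, end_month = 25)
  expect_equal(out2$doses[[1]], rep(1L, 6))
  expect_equal(out2$followup, 6L)
  expect_equal(length(out2$doses[[1]]), 25 - 20 + 1)
})

test_that("severity flag requires a matching certification at or before index", {
  cohort <- tibble::tibble(patient_id = c("P1", "P2", "P3", "P4"),
                           index_month = 20L)
  cl <- dplyr::bind_rows(
    toy_claims(5, code = "ALD-LUPUS", id = "P1", system = "ALD"),
    toy_claims(5, code = "ALD-OTHER", id = "P2", system = "ALD"),
    toy_claims(25, code = "ALD-LUPUS", id = "P4", system = "ALD")
  )
  out <- severity_flag(cl, cohort, c("ALD-LUPUS", "ALD-RA"))
  expect_equal(out$severity, c(1L, 0L, 0L, 0L))
})

test_that("censoring takes the earliest of death and study end", {
  cohort <- tibble::tibble(patient_id = c("A", "B"), index_month = c(10L, 10L))
  dem <- tibble::tibble(patient_id = c("A", "B"),
                        death_date = c(month_date(30), as.Date(NA)))
  out <- censor_months(cohort, dem, study_end = 59)
  expect_equal(out$censor_month, c(30L, 59L))
  # opt-in last-activity censoring truncates at the last claim
  cl <- dplyr::bind_rows(toy_claims(c(10, 22), id = "A"),
                         toy_claims(c(10, 40), id = "B"))
  out2 <- censor_months(cohort, dem, study_end = 59, claims = cl,
                        censor_at_last_activity = TRUE)
  expect_equal(out2$censor_month, c(22L, 40L))
})

test_that("event dating is incident-only and month-granular", {
  cohort <- tibble::tibble(patient_id = c("P1", "P2", "P3", "P4"),
                           index_month = 20L, followup = 10L)
  cl <- dplyr::bind_rows(
    toy_claims(24, code = "EV", id = "P1", system = "ICD10"), # rel month 5
    toy_claims(18, code = "EV", id = "P2", system = "ICD10"), # prevalent
    toy_claims(20, code = "EV", id = "P3", system = "ICD10")  # index month
  )
  out <- event_dates(cl, cohort, "EV")
  expect_equal(out$event_month[out$patient_id == "P1"], 5L)
  expect_false(out$evaluable[out$patient_id == "P2"])
  expect_false(out$evaluable[out$patient_id == "P3"])
  expect_true(is.na(out$event_month[out$patient_id == "P4"]))
  expect_true(out$evaluable[out$patient_id == "P4"])
})

test_that("person-period rows chain, close on the right, and end at the event", {
  pp <- build_person_period(c(1, 1, 0, 0, 0), event_month = 4, followup = 5)
  expect_equal(nrow(pp), 4)
  expect_equal(pp$Event, c(0L, 0L, 0L, 1L))
  expect_equal(pp$Start, 0:3)
  expect_equal(pp$Stop, 1:4)

  pp2 <- build_person_period(c(1, 0, 0), event_month = NA, followup = 3)
  expect_equal(nrow(pp2), 3)
  expect_equal(sum(pp2$Event), 0)

  pp3 <- build_person_period(c(1), event_month = 1, followup = 1)
  expect_equal(nrow(pp3), 1)
  expect_equal(pp3$Event, 1L)
  expect_equal(c(pp3$Start, pp3$Stop), c(0L, 1L))

  expect_error(build_person_period(c(1, 0), event_month = 5, followup = 2),
               "event after censoring")
})

test_that("cohort-level table conserves rows, events and exposure", {
  sim <- small_sim()
  ev <- event_dates(sim$claims, sim$cohort, "ACU")
  pp <- wcescreen:::build_pp_table(sim$cohort, ev)
  d <- dplyr::inner_join(sim$cohort, ev, by = "patient_id") %>%
    dplyr::filter(evaluable)
  len <- ifelse(is.na(d$event_month), d$followup, d$event_month)
  expect_equal(nrow(pp), sum(len))
  expect_equal(sum(pp$Event), sum(!is.na(d$event_month)))
  # interval chaining and right closure per patient
  chain <- pp %>%
    dplyr::summarise(ok = all(Stop == Start + 1L) && Start[1] == 0 &&
                       all(diff(Start) == 1L) &&
                       all(Event[-dplyr::n()] == 0L), .by = Id)
  expect_true(all(chain$ok))
  # the dose column reconstructs each exposure series prefix
  recon <- split(pp$dose, pp$Id)
  for (id in names(recon)[1:25]) {
    orig <- d$doses[[match(id, d$patient_id)]]
    expect_identical(recon[[id]], orig[seq_along(recon[[id]])])
  }
})
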