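# Synthetic claims generator with known ground truth.
#
# Emulates the statistical structure the screening pipeline assumes: a
# case-only cohort of new users of a drug of interest, monthly binary
# exposure trajectories, covariates (age, sex, a binary disease-severity
# flag that shifts exposure persistence), and first-occurrence event streams
# whose discrete-time hazards follow known weight functions. The generative
# hazard uses a complementary log-log link to a Cox-type linear predictor at
# month granularity, so the fitted WCE model is correctly specified and
# parameter recovery is a clean end-to-end check.

#' Ground-truth weight functions
#'
#' Convenience constructors for the per-lag log-hazard contribution w(v) of
#' one dose taken v months ago, v = 1..`window`. `weight_acute()` decays
#' exponentially from lag 1 (short-term effect), `weight_delayed()` ramps up
#' with lag (cumulative/delayed effect), `weight_constant()` spreads the
#' total evenly, `weight_null()` is identically zero. The non-null shapes
#' are scaled so that `sum(w) = total`, i.e. the window hazard ratio for a
#' fully exposed window is `exp(total)`.
#'
#' @param window window length T in months.
#' @param total target value of `sum(w)`; the log window hazard ratio.
#' @param half_life decay half-life in months for the acute shape.
#' @return numeric vector of length `window`.
#' @export
weight_acute <- function(window, total = log(3), half_life = 2) {
  w <- exp(-(seq_len(window) - 1) * log(2) / half_life)
  w * total / sum(w)
}

#' @rdname weight_acute
#' @export
weight_delayed <- function(window, total = log(3)) {
  w <- seq_len(window)
  w * total / sum(w)
}

#' @rdname weight_acute
#' @export
weight_constant <- function(window, total = log(3)) {
  rep(total / window, window)
}

#' @rdname weight_acute
#' @export
weight_null <- function(window) rep(0, window)

#' Default ground-truth event catalog
#'
#' One acute-decay code, one delayed-cumulative code, one severity-confounded
#' null code (zero weight but a direct severity effect on the hazard) and
#' `n_null` pure-null codes spread over drug (ATC5), diagnosis (ICD10) and
#' procedure (PROC) code systems.
#'
#' @param window weight-function length T in months.
#' @param n_null number of pure-null codes (>= 1).
#' @param total log window hazard ratio for the associated codes.
#' @param sev_loghr log hazard ratio of the severity flag for the confounded
#'   code.
#' @return a tibble with one row per code: `code`, `code_system`, `type`,
#'   `baseline_multiplier`, `sev_loghr` and a `weight` list-column of length-T
#'   vectors.
#' @export
default_truth <- function(window = 24, n_null = 20, total = log(3),
                          sev_loghr = log(3)) {
  stopifnot(n_null >= 1)
  systems <- rep(c("ATC5", "ICD10", "PROC"), length.out = n_null)
  null_codes <- dplyr::case_when(
    systems == "ATC5" ~ sprintf("C09AA%02d", seq_len(n_null)),
    systems == "ICD10" ~ sprintf("J%02d", 10 + seq_len(n_null)),
    TRUE ~ sprintf("AAQP%03d", seq_len(n_null))
  )
  tibble::tibble(
    code = c("N02BE01", "H02AB09", "M01AE01", null_codes),
    code_system = c("ATC5", "ATC5", "ATC5", systems),
    type = c("acute", "delayed", "confounded_null", rep("null", n_null)),
    baseline_multiplier = 1,
    sev_loghr = c(0, 0, sev_loghr, rep(0, n_null)),
    weight = c(list(weight_acute(window, total), weight_delayed(window, total)),
               replicate(n_null + 1, weight_null(window), simplify = FALSE))
  )
}

#' Simulation configuration
#'
#' Bundles and validates all knobs of the synthetic claims generator. The
#' defaults emulate the structure of a national-claims new-user cohort:
#' patients initiate the drug of interest at some study month, stay on it
#' with a monthly persistence probability (higher for severe patients, which
#' is what makes severity a confounder), and accrue first occurrences of
#' candidate health events under known discrete-time hazards.
#'
#' @param n_patients number of patients (all exposed at least once).
#' @param study_months calendar length of the study in months; must be at
#'   least twice the truth window.
#' @param drug_code ATC5 code of the drug of interest.
#' @param p_init per-month probability of initiating the drug once eligible.
#' @param p_persist baseline probability of staying exposed next month given
#'   exposed this month; once exposure stops it does not restart.
#' @param age_mean,age_sd age at index (years), truncated below at 18.
#' @param p_female proportion of women (`sex = 1`).
#' @param p_severe proportion with the disease-severity flag.
#' @param sev_persist_logodds shift in the log-odds of monthly persistence
#'   for severe patients (creates exposure-severity confounding).
#' @param truth ground-truth catalog, see [default_truth()].
#' @param baseline_hazard baseline event rate per person-month.
#' @param covariate_log_hazards named vector of log hazard ratios applied to
#'   every code: supported names `age10` (per 10 years above 55) and `sex`.
#' @param death_rate per-month death hazard (0 disables deaths).
#' @param lookback months of pre-index observation guaranteed for every
#'   patient, so new-user selection with the same lookback retains everyone.
#' @param severity_codes chronic-certification codes marking severity.
#' @param origin calendar date of study month 0.
#' @param seed integer seed; identical configs and seeds give byte-identical
#'   datasets.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 500,
                       study_months = 72,
                       drug_code = "P01BA02",
                       p_init = 0.08,
                       p_persist = 0.9,
                       age_mean = 54.8, age_sd = 16.2,
                       p_female = 0.78,
                       p_severe = 0.35,
                       sev_persist_logodds = 1.5,
                       truth = default_truth(window = 24),
                       baseline_hazard = 0.004,
                       covariate_log_hazards = c(age10 = 0, sex = 0),
                       death_rate = 0,
                       lookback = 12,
                       severity_codes = c("ALD-LUPUS", "ALD-RA"),
                       origin = "2008-01-01",
                       seed = 1L) {
  probs <- c(p_init = p_init, p_persist = p_persist, p_female = p_female,
             p_severe = p_severe, baseline_hazard = baseline_hazard,
             death_rate = death_rate)
  bad <- probs < 0 | probs > 1 | is.na(probs)
  if (any(bad)) {
    stop("invalid probability: ", paste(names(probs)[bad], collapse = ", "),
         call. = FALSE)
  }
  if (p_init == 0) stop("invalid probability: p_init must be > 0", call. = FALSE)
  if (n_patients < 1) stop("n_patients must be >= 1", call. = FALSE)
  window <- length(truth$weight[[1]])
  if (!all(lengths(truth$weight) == window)) {
    stop("all truth weight vectors must have the same length", call. = FALSE)
  }
  if (study_months < 2 * window) {
    stop("study_months must be >= 2 x the truth window", call. = FALSE)
  }
  structure(
    list(n_patients = as.integer(n_patients),
         study_months = as.integer(study_months),
         drug_code = drug_code, p_init = p_init, p_persist = p_persist,
         age_mean = age_mean, age_sd = age_sd, p_female = p_female,
         p_severe = p_severe, sev_persist_logodds = sev_persist_logodds,
         truth = truth, window = as.integer(window),
         baseline_hazard = baseline_hazard,
         covariate_log_hazards = covariate_log_hazards,
         death_rate = death_rate, lookback = as.integer(lookback),
         severity_codes = severity_codes, origin = origin,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Weighted exposure history: lp[t] = sum_v w(v) x(t - v + 1), lag v = t-u+1.
# stats::filter with sides = 1 computes exactly this convolution.
#' @noRd
weighted_history <- function(x, w) {
  Tw <- length(w)
  padded <- c(rep(0, Tw - 1), x)
  out <- stats::filter(padded, w, method = "convolution", sides = 1)
  as.numeric(out)[Tw - 1 + seq_along(x)]
}

#' Simulate the first occurrence of one event for one patient
#'
#' Discrete-time hazard at relative month t (t = 1 is the index month):
#' `p(t) = 1 - exp(-baseline * multiplier * exp(sum_v w(v) x(t-v+1) + lp))`,
#' a complementary log-log link to the WCE linear predictor. The first month
#' where a uniform draw falls below p(t) is the event month; follow-up stops
#' there. Events are generated from month `from` onward (default 2: strictly
#' after the index month, since month granularity cannot order within-month
#' occurrences).
#'
#' @param doses binary exposure vector x(1..F), x(1) = 1.
#' @param weight true weight function w(1..T).
#' @param lp extra (covariate) log-hazard for this patient.
#' @param baseline baseline hazard per person-month (>= 0).
#' @param multiplier positive code-specific baseline multiplier.
#' @param from first relative month at which the event may occur.
#' @param u optional vector of uniforms (for reproducibility); drawn if NULL.
#' @return integer relative event month, or `NA_integer_` if censored.
#' @export
simulate_first_event <- function(doses, weight, lp = 0, baseline, multiplier = 1,
                                 from = 2L, u = NULL) {
  if (baseline < 0) stop("negative baseline hazard", call. = FALSE)
  Fm <- length(doses)
  if (is.null(u)) u <- runif(Fm)
  haz <- baseline * multiplier * exp(weighted_history(doses, weight) + lp)
  p <- 1 - exp(-haz)
  hit <- which(u < p & seq_len(Fm) >= from)
  if (length(hit) == 0) NA_integer_ else as.integer(hit[1])
}

#' Simulate a synthetic claims dataset with known ground truth
#'
#' Generates, under one seed, the three tables the pipeline consumes:
#' dispensing/event claims, demographics, and the ground-truth catalog.
#' Severity is drawn first and shifts exposure persistence, so
#' severity-linked codes are confounded with cumulative exposure exactly the
#' way disease severity confounds drug trajectories in real claims. Every
#' patient initiates the drug inside the study (case-only cohort) with at
#' least `lookback` months of prior observation and at least one post-index
#' month.
#'
#' @param config a [sim_config()].
#' @return a list of class `sim_claims` with tibbles `claims` (`patient_id`,
#'   `date`, `code_system`, `code`), `demographics` (`patient_id`, `sex`,
#'   `birth_year`, `death_date`), `truth`, and a `cohort` table of generator
#'   internals (index month, exposure run length, covariates) useful for
#'   validation.
#' @export
#' @examples
#' sim <- simulate_cohort(sim_config(n_patients = 50, study_months = 48,
#'                                   truth = default_truth(window = 12)))
#' head(sim$claims)
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_patients
    M <- config$study_months
    lb <- config$lookback

    severity <- rbinom(n, 1, config$p_severe)
    sex <- rbinom(n, 1, config$p_female)
    age <- pmax(18, round(rnorm(n, config$age_mean, config$age_sd)))

    # index month: lookback + truncated geometric, leaving >= 1 post-index month
    max_extra <- M - 2L - lb
    if (max_extra < 0) stop("study too short for the lookback", call. = FALSE)
    u <- runif(n)
    extra <- qgeom(u * pgeom(max_extra, config$p_init), config$p_init)
    index <- lb + pmin(extra, max_extra)

    # exposure run: exposed at index, continues with per-patient persistence
    pper <- plogis(qlogis(config$p_persist) + config$sev_persist_logodds * severity)
    pper <- pmin(pper, 1 - 1e-12)
    run <- 1L + rgeom(n, 1 - pper)
    followup <- M - index                       # months incl. index month
    if (config$death_rate > 0) {
      dm <- 1L + rgeom(n, config$death_rate)    # relative death month
      died <- dm <= followup
      followup <- pmin(followup, dm)
    } else {
      died <- rep(FALSE, n)
    }
    run <- pmin(run, followup)
    doses <- purrr::map2(run, followup, function(r, f) {
      c(rep(1L, r), rep(0L, f - r))
    })

    # covariate linear predictor shared across codes
    clh <- config$covariate_log_hazards
    lp_cov <- clh[["age10"]] * (age - 55) / 10 + clh[["sex"]] * sex

    # events: first occurrence per code under the discrete-time WCE hazard
    truth <- config$truth
    event_tbl <- purrr::map_dfr(seq_len(nrow(truth)), function(j) {
      w <- truth$weight[[j]]
      lp <- lp_cov + truth$sev_loghr[j] * severity
      em <- purrr::map_int(seq_len(n), function(i) {
        simulate_first_event(doses[[i]], w, lp[i], config$baseline_hazard,
                             truth$baseline_multiplier[j])
      })
      tibble::tibble(patient = which(!is.na(em)),
                     code = truth$code[j],
                     code_system = truth$code_system[j],
                     rel_month = em[!is.na(em)])
    })

    ids <- sprintf("P%06d", seq_len(n))
    disp <- tibble::tibble(
      patient = rep(seq_len(n), run),
      month = unlist(purrr::map2(index, run, function(ix, r) ix + seq_len(r) - 1L))
    )
    claims <- dplyr::bind_rows(
      tibble::tibble(patient = disp$patient, month = disp$month,
                     code_system = "ATC5", code = config$drug_code),
      tibble::tibble(patient = event_tbl$patient,
                     month = index[event_tbl$patient] + event_tbl$rel_month - 1L,
                     code_system = event_tbl$code_system, code = event_tbl$code),
      tibble::tibble(patient = which(severity == 1), month = 0L,
                     code_system = "ALD",
                     code = rep_len(config$severity_codes, sum(severity == 1)))
    )
    claims <- claims %>%
      dplyr::mutate(patient_id = ids[.data$patient],
                    date = month_date(.data$month, config$origin)) %>%
      dplyr::arrange(.data$patient_id, .data$month, .data$code_system, .data$code) %>%
      dplyr::select("patient_id", "date", "code_system", "code")

    index_year <- as.integer(format(month_date(index, config$origin), "%Y"))
    demographics <- tibble::tibble(
      patient_id = ids,
      sex = sex,
      birth_year = index_year - as.integer(age),
      death_date = dplyr::if_else(died,
                                  month_date(index + followup - 1L, config$origin),
                                  as.Date(NA))
    )
    cohort <- tibble::tibble(
      patient_id = ids, index_month = as.integer(index),
      followup = as.integer(followup), exposure_months = as.integer(run),
      age = as.numeric(age), sex = sex, severity = severity,
      doses = doses
    )
    structure(list(claims = claims, demographics = demographics,
                   truth = truth, cohort = cohort, config = config),
              class = "sim_claims")
  })
}

#' @export
print.sim_claims <- function(x, ...) {
  cat(sprintf("<sim_claims> %d patients, %d claim rows, %d truth codes, seed %d\n",
              nrow(x$demographics), nrow(x$claims), nrow(x$truth),
              x$config$seed))
  invisible(x)
}

#' Score screening results against simulation ground truth
#'
#' Labels every screened code as true/false positive/negative by comparing
#' its significance call with the generator's truth (`acute` and `delayed`
#' codes are truly associated; `null` and `confounded_null` are not), and
#' summarises sensitivity, specificity and the false-positive proportion.
#' Codes with status `"not evaluated"` or `"non-estimable"` are labelled
#' `"not evaluated"` and excluded from the metrics.
#'
#' @param truth truth catalog as in [default_truth()].
#' @param signals a signal table with columns `code`, `status` (one row per
#'   code, or filter to one method first).
#' @param fitted_weights optional named list (by code) of fitted weight
#'   vectors; adds a per-code mean absolute error against the true weight
#'   function and its average over codes.
#' @return list of class `truth_report`: `codes` (per-code labels) and
#'   `metrics` (one-row tibble: counts, sensitivity, specificity,
#'   false-positive proportion, and `weight_mae` when fitted weights are
#'   supplied).
#' @export
truth_report <- function(truth, signals, fitted_weights = NULL) {
  if (nrow(truth) == 0 && nrow(signals) == 0) {
    return(structure(list(
      codes = tibble::tibble(code = character(), type = character(),
                             status = character(), label = character()),
      metrics = tibble::tibble(tp = 0L, fp = 0L, tn = 0L, fn = 0L,
                               not_evaluated = 0L, sensitivity = NA_real_,
                               specificity = NA_real_, fp_rate = NA_real_)),
      class = "truth_report"))
  }
  missing <- setdiff(signals$code, truth$code)
  if (length(missing) > 0) {
    stop("codes in signal table absent from truth: ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  }
  codes <- truth %>%
    dplyr::select("code", "type") %>%
    dplyr::inner_join(dplyr::select(signals, "code", "status"), by = "code") %>%
    dplyr::mutate(
      associated = .data$type %in% c("acute", "delayed"),
      label = dplyr::case_when(
        !(.data$status %in% c("significant", "not significant")) ~ "not evaluated",
        .data$associated & .data$status == "significant" ~ "true positive",
        .data$associated ~ "false negative",
        .data$status == "significant" ~ "false positive",
        TRUE ~ "true negative"
      )
    )
  cnt <- function(lbl) sum(codes$label == lbl)
  tp <- cnt("true positive"); fp <- cnt("false positive")
  tn <- cnt("true negative"); fn <- cnt("false negative")
  metrics <- tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn, not_evaluated = cnt("not evaluated"),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    fp_rate = if (tn + fp > 0) fp / (tn + fp) else NA_real_
  )
  if (!is.null(fitted_weights)) {
    unknown <- setdiff(names(fitted_weights), truth$code)
    if (length(unknown) > 0) {
      stop("fitted weights for codes absent from truth: ",
           paste(head(unknown, 5), collapse = ", "), call. = FALSE)
    }
    mae <- vapply(names(fitted_weights), function(cd) {
      mean(abs(fitted_weights[[cd]] - truth$weight[[match(cd, truth$code)]]))
    }, numeric(1))
    codes$weight_mae <- unname(mae[match(codes$code, names(mae))])
    metrics$weight_mae <- mean(mae)
  }
  structure(list(codes = codes, metrics = metrics), class = "truth_report")
}

#' @export
print.truth_report <- function(x, ...) {
  print(x$metrics)
  invisible(x)
}
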