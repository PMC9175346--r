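# Screening orchestration: run the WCE + bootstrap test and/or the
# case-crossover comparator over every candidate event code and assemble a
# forest-plot-ready signal table.

#' Enumerate candidate event codes
#'
#' Every distinct (code_system, code) pair observed in the claims, excluding
#' the drug of interest itself. Only health-event code systems are screened
#' (by default ATC5 drug initiations, ICD10 diagnoses and PROC procedures);
#' chronic-certification records feed the severity covariate, not the
#' candidate list.
#'
#' @param claims claims tibble.
#' @param drug_code code of the drug of interest.
#' @param code_systems code systems eligible for screening.
#' @return tibble `code_system`, `code`, sorted.
#' @export
enumerate_candidates <- function(claims, drug_code,
                                 code_systems = c("ATC5", "ICD10", "PROC")) {
  claims %>%
    dplyr::filter(.data$code != drug_code,
                  .data$code_system %in% code_systems) %>%
    dplyr::distinct(.data$code_system, .data$code) %>%
    dplyr::arrange(.data$code_system, .data$code)
}

#' Screening configuration
#'
#' Bundles every tuning knob of [run_screen()]. The defaults are the
#' standard operating point of the pipeline: month time period, 24-month
#' exposure window, one interior spline knot, 1,000 bootstrap replicates,
#' 5% significance level with no multiple-testing correction, covariates
#' age, sex and disease severity.
#'
#' @param drug_code code of the drug of interest.
#' @param study_months calendar length of the study in months.
#' @param window exposure window T in months.
#' @param nknots interior knots of the weight-function spline.
#' @param constrained `"none"` or `"right"` (weight forced to 0 at lag T).
#' @param bootstraps bootstrap replicates B per code.
#' @param alpha significance level.
#' @param covariates covariate columns entered in the WCE model.
#' @param methods any of `"wce"`, `"cco"`.
#' @param period_len case-crossover period durations (months).
#' @param severity_codes chronic-certification codes defining severity.
#' @param lookback new-user washout in months.
#' @param min_events minimum events to attempt a WCE fit.
#' @param ties `"efron"` or `"breslow"`.
#' @param fdr if TRUE, significance is re-called on Benjamini-Hochberg
#'   adjusted p-values at level `alpha` (off by default: the pipeline is
#'   exploratory).
#' @param dictionary optional tibble `code`, `label` used to label output.
#' @param origin calendar date of study month 0.
#' @param seed master seed; per-code seeds are derived deterministically
#'   from it, so results are identical whatever the order codes are run in.
#' @return list of class `screen_config`.
#' @export
screen_config <- function(drug_code = "P01BA02",
                          study_months = 132,
                          window = 24, nknots = 1,
                          constrained = c("none", "right"),
                          bootstraps = 1000, alpha = 0.05,
                          covariates = c("age", "sex", "severity"),
                          methods = c("wce", "cco"),
                          period_len = c(3, 6, 9),
                          severity_codes = c("ALD-LUPUS", "ALD-RA"),
                          lookback = 12, min_events = 10,
                          ties = c("efron", "breslow"),
                          fdr = FALSE, dictionary = NULL,
                          origin = "2008-01-01", seed = 1L) {
  constrained <- match.arg(constrained)
  ties <- match.arg(ties)
  stopifnot(alpha > 0, alpha < 1, bootstraps >= 2, window >= nknots + 5)
  structure(
    list(drug_code = drug_code, study_months = as.integer(study_months),
         window = as.integer(window), nknots = as.integer(nknots),
         constrained = constrained, bootstraps = as.integer(bootstraps),
         alpha = alpha, covariates = covariates,
         methods = intersect(methods, c("wce", "cco")),
         period_len = as.integer(period_len),
         severity_codes = severity_codes, lookback = as.integer(lookback),
         min_events = as.integer(min_events), ties = ties, fdr = fdr,
         dictionary = dictionary, origin = origin, seed = as.integer(seed)),
    class = "screen_config"
  )
}

# Build the analysis cohort shared by all candidate codes.
#' @noRd
screen_cohort <- function(claims, demographics, config) {
  claims <- claims_months(claims, config$origin)
  cohort <- select_new_users(claims, config$drug_code,
                             lookback = config$lookback, obs_start = 0)
  if (nrow(cohort) == 0) return(cohort)
  cohort <- censor_months(cohort, demographics,
                          study_end = config$study_months - 1L,
                          origin = config$origin)
  cohort <- monthly_exposure(claims, config$drug_code, cohort,
                             end_month = cohort$censor_month,
                             origin = config$origin)
  cohort <- severity_flag(claims, cohort, config$severity_codes,
                          origin = config$origin)
  dem <- demographics[match(cohort$patient_id, demographics$patient_id), ]
  index_year <- as.integer(format(month_date(cohort$index_month, config$origin),
                                  "%Y"))
  cohort$age <- as.numeric(index_year - dem$birth_year)
  cohort$sex <- as.numeric(dem$sex)
  cohort
}

# One WCE + bootstrap row for a single code. Never throws: failures become
# "not evaluated" rows with the reason recorded.
#' @noRd
screen_wce_one <- function(claims, cohort, basis, cand, config, seed) {
  n_pat <- nrow(cohort)
  empty <- tibble::tibble(
    code = cand$code, code_system = cand$code_system, method = "WCE",
    n_patients_evaluable = n_pat, n_events = 0L,
    hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
    status = "not evaluated", reason = NA_character_
  )
  tryCatch({
    ev <- event_dates(claims, cohort, cand$code, origin = config$origin)
    n_eval <- sum(ev$evaluable)
    n_events <- sum(!is.na(ev$event_month[ev$evaluable]))
    if (n_events < config$min_events) {
      return(dplyr::mutate(empty, n_patients_evaluable = n_eval,
                           n_events = n_events, reason = "too few events"))
    }
    pp <- build_pp_table(cohort, ev, covariates = config$covariates)
    pp <- add_pseudo_covariates(pp, cohort, basis)
    bt <- wce_bootstrap(pp, basis, B = config$bootstraps,
                        alpha = config$alpha, seed = seed,
                        covariates = config$covariates, ties = config$ties,
                        min_events = config$min_events)
    status <- select_signal(bt)
    tibble::tibble(
      code = cand$code, code_system = cand$code_system, method = "WCE",
      n_patients_evaluable = n_eval, n_events = n_events,
      hr = bt$fit$window_hr %||% NA_real_,
      ci_low = if (is.null(bt$ci_hr)) NA_real_ else bt$ci_hr[1],
      ci_high = if (is.null(bt$ci_hr)) NA_real_ else bt$ci_hr[2],
      p = bt$p_value %||% NA_real_,
      status = status,
      reason = if (status == "not evaluated") bt$status else NA_character_
    )
  }, error = function(e) {
    dplyr::mutate(empty, reason = conditionMessage(e))
  })
}

#' @noRd
screen_cco_one <- function(claims, cohort, cand, config) {
  tryCatch({
    res <- cco_sensitivity(claims, cohort, cand$code, config$drug_code,
                           durations = config$period_len,
                           alpha = config$alpha, origin = config$origin)
    res %>%
      dplyr::mutate(
        code = cand$code, code_system = cand$code_system,
        method = paste0("CCO-", .data$duration),
        n_patients_evaluable = nrow(cohort), n_events = .data$n_sets,
        hr = .data$or,
        status = dplyr::case_when(
          .data$status != "ok" ~ "non-estimable",
          .data$ci_low > 1 | .data$ci_high < 1 ~ "significant",
          TRUE ~ "not significant"
        ),
        reason = NA_character_
      ) %>%
      dplyr::select("code", "code_system", "method", "n_patients_evaluable",
                    "n_events", "hr", "ci_low", "ci_high", "p", "status",
                    "reason")
  }, error = function(e) {
    purrr::map_dfr(config$period_len, function(L) {
      tibble::tibble(code = cand$code, code_system = cand$code_system,
                     method = paste0("CCO-", L),
                     n_patients_evaluable = nrow(cohort), n_events = 0L,
                     hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                     p = NA_real_, status = "non-estimable",
                     reason = conditionMessage(e))
    })
  })
}

#' Screen every candidate code for association with drug exposure
#'
#' The full pipeline: builds the new-user cohort (index month, monthly
#' exposure, censoring, covariates), enumerates candidate event codes, and
#' for each code runs the WCE model with the bootstrap association test
#' and/or the case-crossover comparator at each configured period length.
#' Per-code failures are isolated: a pathological code yields a
#' `"not evaluated"` row, never an aborted screen. Deterministic under a
#' fixed `config$seed` regardless of execution order (per-code seeds are
#' derived from the code's rank in the sorted catalog).
#'
#' @param claims claims tibble (`patient_id`, `date`, `code_system`,
#'   `code`), or a path to such a CSV.
#' @param demographics demographics tibble (`patient_id`, `sex`,
#'   `birth_year`, `death_date`), or a path to such a CSV.
#' @param config a [screen_config()].
#' @return a signal table of class `wce_signals`: one row per code x method
#'   with `code`, `code_system`, `label`, `n_patients_evaluable`,
#'   `n_events`, `method` (WCE, CCO-3, ...), `hr`, `ci_low`, `ci_high`, `p`,
#'   `q` (Benjamini-Hochberg within method), `status`, `reason`.
#' @export
run_screen <- function(claims, demographics, config = screen_config()) {
  if (is.character(claims)) claims <- read_claims(claims, config$origin)
  if (is.character(demographics)) demographics <- read_demographics(demographics)
  claims <- claims_months(claims, config$origin)
  cohort <- screen_cohort(claims, demographics, config)
  cands <- enumerate_candidates(claims, config$drug_code)
  empty <- tibble::tibble(
    code = character(), code_system = character(), label = character(),
    n_patients_evaluable = integer(), n_events = integer(),
    method = character(), hr = numeric(), ci_low = numeric(),
    ci_high = numeric(), p = numeric(), q = numeric(), status = character(),
    reason = character()
  )
  if (length(config$methods) == 0 || nrow(cands) == 0 || nrow(cohort) == 0) {
    return(structure(empty, class = c("wce_signals", class(empty))))
  }
  basis <- wce_basis(config$window, config$nknots, config$constrained)
  rows <- purrr::map_dfr(seq_len(nrow(cands)), function(i) {
    cand <- cands[i, ]
    out <- list()
    if ("wce" %in% config$methods) {
      out$wce <- screen_wce_one(claims, cohort, basis, cand, config,
                                seed = derive_seed(config$seed, i))
    }
    if ("cco" %in% config$methods) {
      out$cco <- screen_cco_one(claims, cohort, cand, config)
    }
    dplyr::bind_rows(out)
  })
  dict <- config$dictionary
  rows <- rows %>%
    dplyr::mutate(label = if (is.null(dict)) .data$code else
      dplyr::coalesce(dict$label[match(.data$code, dict$code)], .data$code)) %>%
    dplyr::mutate(q = stats::p.adjust(.data$p, method = "BH"),
                  .by = "method")
  if (isTRUE(config$fdr)) {
    rows <- dplyr::mutate(rows, status = dplyr::case_when(
      !(.data$status %in% c("significant", "not significant")) ~ .data$status,
      .data$q <= config$alpha & .data$status == "significant" ~ "significant",
      TRUE ~ "not significant"
    ))
  }
  rows <- dplyr::select(rows, "code", "code_system", "label",
                        "n_patients_evaluable", "n_events", "method", "hr",
                        "ci_low", "ci_high", "p", "q", "status", "reason")
  structure(rows, class = c("wce_signals", class(rows)))
}

#' Overlap between WCE and case-crossover signals
#'
#' Set algebra over the codes called significant by each method, per code
#' system: codes significant under WCE only, under case-crossover only
#' (any period length), and under both.
#'
#' @param signals a signal table from [run_screen()] containing both
#'   methods.
#' @return tibble per code system with counts `n_wce_only`, `n_cco_only`,
#'   `n_both` and list-columns of the corresponding codes.
#' @export
compare_methods <- function(signals) {
  sig <- dplyr::filter(signals, .data$status == "significant")
  wce <- dplyr::filter(sig, .data$method == "WCE")
  cco <- dplyr::filter(sig, grepl("^CCO", .data$method))
  systems <- sort(unique(signals$code_system))
  purrr::map_dfr(systems, function(cs) {
    w <- unique(wce$code[wce$code_system == cs])
    c_ <- unique(cco$code[cco$code_system == cs])
    tibble::tibble(
      code_system = cs,
      n_wce_only = length(setdiff(w, c_)),
      n_cco_only = length(setdiff(c_, w)),
      n_both = length(intersect(w, c_)),
      wce_only = list(sort(setdiff(w, c_))),
      cco_only = list(sort(setdiff(c_, w))),
      both = list(sort(intersect(w, c_)))
    )
  })
}

#' Forest plot of screening results
#'
#' Hazard / odds ratios with confidence intervals for every estimable code,
#' faceted by code system and coloured by method. Codes with
#' `"not evaluated"` or `"non-estimable"` status are dropped.
#'
#' @param object a signal table from [run_screen()].
#' @param significant_only plot only significant rows.
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.wce_signals <- function(object, significant_only = FALSE, ...) {
  d <- dplyr::filter(object, !is.na(.data$hr), !is.na(.data$ci_low))
  if (significant_only) d <- dplyr::filter(d, .data$status == "significant")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$hr, y = .data$label,
                                  colour = .data$method)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high),
                             position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$code_system),
                        scales = "free_y", space = "free_y") +
    ggplot2::labs(x = "hazard / odds ratio (log scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.wce_signals
#' @param signals a signal table from [run_screen()].
#' @export
plot_forest <- function(signals, significant_only = FALSE) {
  autoplot.wce_signals(signals, significant_only = significant_only)
}
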