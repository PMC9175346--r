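# Case-crossover comparator: one risk period immediately before the event
# and three earlier control periods of the same length, each pair separated
# by a one-month washout. Each patient is their own match, so time-invariant
# confounders cancel; the odds ratio is estimated by conditional logistic
# maximum likelihood on the 1:3 matched sets.

#' Case-crossover design
#'
#' @param period_len length of the risk and control periods in months
#'   (typically 3, 6 or 9).
#' @param n_controls number of control periods (fixed design: 3).
#' @param washout washout length between periods in months (fixed design: 1).
#' @return list of class `cco_design`.
#' @export
cco_design <- function(period_len, n_controls = 3, washout = 1) {
  stopifnot(period_len > 0, n_controls >= 1, washout >= 0)
  structure(list(period_len = as.integer(period_len),
                 n_controls = as.integer(n_controls),
                 washout = as.integer(washout)),
            class = "cco_design")
}

#' Risk and control periods for one event
#'
#' Half-open month ranges (lower, upper], counted backwards from the event
#' month e with period length L and washout W: the risk period is (e-L, e],
#' control i is (e - (i+1)L - iW, e - iL - iW]. With the standard design
#' (3 controls, 1-month washout) the full span covers 4L + 3 months.
#'
#' @param event_month absolute month of the case-defining event.
#' @param design a [cco_design()].
#' @return tibble `period` ("risk", "control1", ...), `lower`, `upper`.
#' @export
#' @examples
#' build_periods(20, cco_design(3))
build_periods <- function(event_month, design) {
  stopifnot(inherits(design, "cco_design"))
  L <- design$period_len
  W <- design$washout
  i <- 0:design$n_controls
  tibble::tibble(
    period = c("risk", paste0("control", seq_len(design$n_controls))),
    lower = event_month - (i + 1L) * L - i * W,
    upper = event_month - i * L - i * W
  )
}

#' Binary exposure within a period
#'
#' 1 iff at least one dispensing month of the drug of interest falls inside
#' the half-open range (lower, upper].
#'
#' @param months integer vector of dispensing months (absolute offsets).
#' @param lower,upper period bounds, lower open, upper closed.
#' @return 0 or 1.
#' @export
exposure_in_period <- function(months, lower, upper) {
  as.integer(any(months > lower & months <= upper))
}

#' Matched sets for one candidate code
#'
#' Builds one 1:3 matched set per case: a patient whose first occurrence of
#' the code after the index month falls at event month e, with all four
#' periods fully inside the patient's observed time. Periods may extend
#' before the index month (exposure there is legitimately 0); sets are
#' excluded only when a period would precede the observation start.
#'
#' @param claims claims tibble (needs `month`, or `date` plus `origin`).
#' @param cohort tibble with `patient_id`, `index_month`, `followup`.
#' @param code candidate event code.
#' @param design a [cco_design()].
#' @param drug_code code of the drug of interest.
#' @param obs_start first observed month (default 0).
#' @param origin used if `claims` lacks a `month` column.
#' @return tibble of class-free matched sets: `patient_id`, `event_month`
#'   (absolute), `risk` and `control1..3` exposure indicators; the number of
#'   span-excluded cases is attached as attribute `n_excluded`.
#' @export
build_matched_sets <- function(claims, cohort, code, design, drug_code,
                               obs_start = 0, origin = "2008-01-01") {
  claims <- claims_months(claims, origin)
  ev <- event_dates(claims, cohort, code, origin = origin)
  cases <- cohort %>%
    dplyr::inner_join(ev, by = "patient_id") %>%
    dplyr::filter(.data$evaluable, !is.na(.data$event_month)) %>%
    dplyr::mutate(abs_event = .data$index_month + .data$event_month - 1L)
  span <- (design$n_controls + 1L) * design$period_len +
    design$n_controls * design$washout
  keep <- cases$abs_event - span >= obs_start
  n_excluded <- sum(!keep)
  cases <- cases[keep, , drop = FALSE]
  disp <- claims %>%
    dplyr::filter(.data$code == drug_code,
                  .data$patient_id %in% cases$patient_id) %>%
    dplyr::distinct(.data$patient_id, .data$month)
  by_pat <- split(disp$month, disp$patient_id)
  sets <- purrr::map2_dfr(cases$patient_id, cases$abs_event, function(id, e) {
    per <- build_periods(e, design)
    expo <- purrr::map2_int(per$lower, per$upper, function(lo, up) {
      exposure_in_period(by_pat[[id]] %||% integer(0), lo, up)
    })
    out <- tibble::tibble(patient_id = id, event_month = e)
    out[per$period] <- as.list(expo)
    out
  })
  if (nrow(sets) == 0) {
    sets <- tibble::tibble(patient_id = character(), event_month = integer(),
                           risk = integer(), control1 = integer(),
                           control2 = integer(), control3 = integer())
  }
  attr(sets, "n_excluded") <- n_excluded
  sets
}

# Conditional log-likelihood pieces for 1:m matched sets with binary
# exposure. `xr` risk-period exposures, `xc` matrix of control exposures.
#' @noRd
cco_loglik <- function(beta, xr, xc) {
  den <- exp(beta * xr) + rowSums(exp(beta * xc))
  sum(beta * xr - log(den))
}

#' Conditional logistic estimate for matched sets
#'
#' Maximizes the matched conditional likelihood
#' prod_i exp(beta x_risk) / sum_periods exp(beta x_period) by 1-D Newton
#' from beta = 0, and reports the odds ratio with a Wald interval. Sets in
#' which all four periods have the same exposure are uninformative;
#' estimation with only one direction of discordance (separation) is
#' reported as `"non-estimable"`.
#'
#' @param sets matched sets from [build_matched_sets()] (columns `risk`,
#'   `control1..`).
#' @param alpha level for the Wald interval.
#' @return object of class `cco_fit`: `beta`, `se`, `or`, `ci`, `p_value`,
#'   `n_sets`, `n_informative`, `status`.
#' @export
fit_cco <- function(sets, alpha = 0.05) {
  ctrl_cols <- grep("^control", names(sets), value = TRUE)
  xr <- sets$risk
  xc <- as.matrix(sets[, ctrl_cols, drop = FALSE])
  informative <- xr != 1 | rowSums(xc) != length(ctrl_cols)
  informative <- informative & (xr != 0 | rowSums(xc) != 0)
  out <- structure(list(n_sets = nrow(sets),
                        n_informative = sum(informative), alpha = alpha),
                   class = "cco_fit")
  if (sum(informative) == 0) stop("no information: all sets concordant",
                                  call. = FALSE)
  xr <- xr[informative]
  xc <- xc[informative, , drop = FALSE]
  beta <- 0
  status <- "ok"
  for (it in 1:50) {
    er <- exp(beta * xr)
    ec <- exp(beta * xc)
    den <- er + rowSums(ec)
    mu <- (xr * er + rowSums(xc * ec)) / den
    v <- (xr^2 * er + rowSums(xc^2 * ec)) / den - mu^2
    score <- sum(xr - mu)
    info <- sum(v)
    if (info < 1e-12 || abs(beta) > 12) { status <- "non-estimable"; break }
    step <- score / info
    beta <- beta + step
    if (abs(step) < 1e-10) break
  }
  if (abs(beta) > 12) status <- "non-estimable"
  out$status <- status
  if (status == "ok") {
    er <- exp(beta * xr); ec <- exp(beta * xc); den <- er + rowSums(ec)
    mu <- (xr * er + rowSums(xc * ec)) / den
    v <- (xr^2 * er + rowSums(xc^2 * ec)) / den - mu^2
    se <- 1 / sqrt(sum(v))
    z <- qnorm(1 - alpha / 2)
    out$beta <- beta
    out$se <- se
    out$or <- exp(beta)
    out$ci <- exp(beta + c(-1, 1) * z * se)
    out$p_value <- 2 * pnorm(-abs(beta / se))
    out$loglik <- cco_loglik(beta, xr, xc)
  }
  out
}

#' @export
print.cco_fit <- function(x, ...) {
  cat(sprintf("<cco_fit> %d sets (%d informative), status: %s\n",
              x$n_sets, x$n_informative, x$status))
  if (x$status == "ok") {
    cat(sprintf("  OR %.3f [%.3f, %.3f], p = %.4g\n",
                x$or, x$ci[1], x$ci[2], x$p_value))
  }
  invisible(x)
}

#' @export
tidy.cco_fit <- function(x, ...) {
  tibble::tibble(term = "exposure",
                 estimate = x$beta %||% NA_real_,
                 std.error = x$se %||% NA_real_,
                 conf.low = if (is.null(x$ci)) NA_real_ else log(x$ci[1]),
                 conf.high = if (is.null(x$ci)) NA_real_ else log(x$ci[2]),
                 p.value = x$p_value %||% NA_real_)
}

#' @export
glance.cco_fit <- function(x, ...) {
  tibble::tibble(n_sets = x$n_sets, n_informative = x$n_informative,
                 or = x$or %||% NA_real_,
                 ci_low = if (is.null(x$ci)) NA_real_ else x$ci[1],
                 ci_high = if (is.null(x$ci)) NA_real_ else x$ci[2],
                 p.value = x$p_value %||% NA_real_, status = x$status)
}

#' Case-crossover sensitivity analysis over period lengths
#'
#' Runs the case-crossover analysis for one code at each period duration
#' (by default 3, 6 and 9 months) and collects one result row per duration.
#'
#' @inheritParams build_matched_sets
#' @param durations period lengths in months.
#' @param alpha level for the Wald intervals.
#' @return tibble: `duration`, `n_sets`, `n_excluded`, `n_informative`,
#'   `or`, `ci_low`, `ci_high`, `p`, `status`.
#' @export
cco_sensitivity <- function(claims, cohort, code, drug_code,
                            durations = c(3, 6, 9), alpha = 0.05,
                            obs_start = 0, origin = "2008-01-01") {
  purrr::map_dfr(durations, function(L) {
    sets <- build_matched_sets(claims, cohort, code, cco_design(L),
                               drug_code, obs_start, origin)
    base <- tibble::tibble(duration = L, n_sets = nrow(sets),
                           n_excluded = attr(sets, "n_excluded"))
    fit <- tryCatch(fit_cco(sets, alpha), error = function(e) NULL)
    if (is.null(fit)) {
      return(dplyr::mutate(base, n_informative = 0L, or = NA_real_,
                           ci_low = NA_real_, ci_high = NA_real_,
                           p = NA_real_, status = "non-estimable"))
    }
    dplyr::mutate(base,
                  n_informative = fit$n_informative,
                  or = fit$or %||% NA_real_,
                  ci_low = if (is.null(fit$ci)) NA_real_ else fit$ci[1],
                  ci_high = if (is.null(fit$ci)) NA_real_ else fit$ci[2],
                  p = fit$p_value %||% NA_real_,
                  status = fit$status)
  })
}
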