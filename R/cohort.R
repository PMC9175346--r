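# Cohort construction: new-user selection, monthly exposure coding,
# severity flag, first-occurrence event dating, and the person-period
# (counting-process) table the WCE model is fitted on.
#
# Conventions used throughout:
#   * calendar months are integer offsets from a study origin (month_index);
#   * relative months count from the index month, t = 1 being the index
#     month itself, so a patient with F months of follow-up has t = 1..F;
#   * person-period rows are right-closed intervals (Start, Stop] = (t-1, t];
#   * an event in relative month e terminates follow-up in row e.

#' Read claims / demographics files
#'
#' Delimited text readers for the two pipeline inputs. Claims: `patient_id`,
#' `date` (ISO-8601), `code_system`, `code`. Demographics: `patient_id`,
#' `sex` (1 = female), `birth_year`, optional `death_date`. A `month` offset
#' column (months since `origin`) is added to claims.
#'
#' @param path file path (anything `readr::read_csv()` accepts).
#' @param origin calendar date of study month 0.
#' @return a tibble.
#' @export
read_claims <- function(path, origin = "2008-01-01") {
  x <- readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(), date = readr::col_date(),
    code_system = readr::col_character(), code = readr::col_character()
  ))
  dplyr::mutate(x, month = month_index(.data$date, origin))
}

#' @rdname read_claims
#' @export
read_demographics <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(), sex = readr::col_integer(),
    birth_year = readr::col_integer(), death_date = readr::col_date()
  ))
}

#' @noRd
claims_months <- function(claims, origin) {
  if (!"month" %in% names(claims)) {
    claims <- dplyr::mutate(claims, month = month_index(.data$date, origin))
  }
  claims
}

#' Select new users of the drug of interest
#'
#' A patient enters the cohort iff their first in-study dispensing of
#' `drug_code` is preceded by `lookback` fully observed months with no
#' dispensing of the same drug. Requiring full lookback observability (the
#' window may not extend before `obs_start`) avoids classifying patients as
#' new users merely because the data start too late to see prior use.
#'
#' @param claims claims tibble (with `month`, or `date` plus `origin`).
#' @param drug_code code of the drug of interest.
#' @param lookback washout length in months (default 12).
#' @param obs_start first observed month of the data (default 0).
#' @param origin used only if `claims` lacks a `month` column.
#' @return tibble `patient_id`, `index_month`; empty (with a warning) if the
#'   drug code never occurs.
#' @export
select_new_users <- function(claims, drug_code, lookback = 12, obs_start = 0,
                             origin = "2008-01-01") {
  stopifnot(lookback >= 1)
  claims <- claims_months(claims, origin)
  disp <- dplyr::filter(claims, .data$code == drug_code)
  if (nrow(disp) == 0) {
    warning("drug code '", drug_code, "' not found in claims; empty cohort",
            call. = FALSE)
    return(tibble::tibble(patient_id = character(), index_month = integer()))
  }
  disp %>%
    dplyr::summarise(index_month = min(.data$month), .by = "patient_id") %>%
    dplyr::filter(.data$index_month - lookback >= obs_start) %>%
    dplyr::arrange(.data$patient_id)
}

#' Monthly binary exposure series
#'
#' Dose in a month is 1 iff the patient had at least one dispensing of the
#' drug of interest in that month; multiple dispensings collapse to 1. The
#' series runs from the index month (always 1) to `end_month`.
#'
#' @inheritParams select_new_users
#' @param cohort tibble with `patient_id`, `index_month` (from
#'   [select_new_users()]).
#' @param end_month last observed absolute month per patient: a single value
#'   or a vector matching `cohort` rows (typically the censoring month).
#' @return `cohort` with a `doses` list-column of 0/1 integer vectors and a
#'   `followup` column (series length).
#' @export
monthly_exposure <- function(claims, drug_code, cohort, end_month,
                             origin = "2008-01-01") {
  claims <- claims_months(claims, origin)
  end_month <- rep_len(end_month, nrow(cohort))
  stopifnot(all(cohort$index_month <= end_month))
  disp <- claims %>%
    dplyr::filter(.data$code == drug_code,
                  .data$patient_id %in% cohort$patient_id) %>%
    dplyr::distinct(.data$patient_id, .data$month)
  by_pat <- split(disp$month, disp$patient_id)
  doses <- purrr::pmap(list(cohort$patient_id, cohort$index_month, end_month),
                       function(id, ix, end) {
    as.integer(ix:end %in% by_pat[[id]])
  })
  dplyr::mutate(cohort, doses = doses,
                followup = as.integer(end_month - .data$index_month + 1L))
}

#' Disease-severity flag
#'
#' 1 iff the patient has any chronic-certification record for a code in
#' `severity_codes` dated at or before the index month. Certification is a
#' marker of disease severity used as a confounding covariate; it must
#' predate (or accompany) drug initiation to be a baseline characteristic.
#'
#' @inheritParams monthly_exposure
#' @param severity_codes character vector of certification codes.
#' @return `cohort` with an integer `severity` column.
#' @export
severity_flag <- function(claims, cohort, severity_codes,
                          origin = "2008-01-01") {
  claims <- claims_months(claims, origin)
  sev <- claims %>%
    dplyr::filter(.data$code %in% severity_codes) %>%
    dplyr::inner_join(dplyr::select(cohort, "patient_id", "index_month"),
                      by = "patient_id") %>%
    dplyr::filter(.data$month <= .data$index_month) %>%
    dplyr::distinct(.data$patient_id)
  dplyr::mutate(cohort,
                severity = as.integer(.data$patient_id %in% sev$patient_id))
}

#' Censoring month per patient
#'
#' Follow-up ends at the earliest of the death month and the end of the
#' study period. Optionally (`censor_at_last_activity = TRUE`) it can also
#' end at the patient's last month with any claim record, a proxy for
#' leaving the insurance scheme; by default follow-up continues after the
#' last dispensing with exposure simply becoming 0.
#'
#' @inheritParams monthly_exposure
#' @param demographics demographics tibble (for `death_date`).
#' @param study_end last month of the study period (absolute offset).
#' @param censor_at_last_activity see Details.
#' @return `cohort` with a `censor_month` column (absolute month offset).
#' @export
censor_months <- function(cohort, demographics, study_end, claims = NULL,
                          censor_at_last_activity = FALSE,
                          origin = "2008-01-01") {
  cm <- rep(as.integer(study_end), nrow(cohort))
  dem <- demographics[match(cohort$patient_id, demographics$patient_id), ]
  if ("death_date" %in% names(dem)) {
    death <- month_index(dem$death_date, origin)
    cm <- pmin(cm, dplyr::coalesce(death, cm))
  }
  if (censor_at_last_activity) {
    if (is.null(claims)) stop("claims needed for last-activity censoring",
                              call. = FALSE)
    claims <- claims_months(claims, origin)
    last <- claims %>%
      dplyr::summarise(last_month = max(.data$month), .by = "patient_id")
    la <- last$last_month[match(cohort$patient_id, last$patient_id)]
    cm <- pmin(cm, dplyr::coalesce(la, cm))
  }
  cm <- pmax(cm, cohort$index_month) # at least the index month is observed
  dplyr::mutate(cohort, censor_month = as.integer(cm))
}

#' First-occurrence event months for one candidate code
#'
#' Returns, for each cohort patient, the relative month (t = 1 is the index
#' month) of the first occurrence of `code`, with the incident-event rules
#' applied: patients whose first occurrence predates the index are excluded
#' for this code (prevalent), occurrences in the index month itself are
#' discarded (month granularity cannot order within-month events), and
#' occurrences after the censoring month are not observed.
#'
#' @inheritParams monthly_exposure
#' @param code candidate event code.
#' @param code_system optional code system to disambiguate.
#' @return tibble `patient_id`, `event_month` (relative, `NA` = censored),
#'   `evaluable` (FALSE for prevalent patients).
#' @export
event_dates <- function(claims, cohort, code, code_system = NULL,
                        origin = "2008-01-01") {
  claims <- claims_months(claims, origin)
  ev <- dplyr::filter(claims, .data$code == !!code)
  if (!is.null(code_system)) {
    ev <- dplyr::filter(ev, .data$code_system == !!code_system)
  }
  first <- ev %>%
    dplyr::summarise(first_month = min(.data$month), .by = "patient_id")
  out <- cohort %>%
    dplyr::select("patient_id", "index_month", "followup") %>%
    dplyr::left_join(first, by = "patient_id") %>%
    dplyr::mutate(
      rel = .data$first_month - .data$index_month + 1L,
      evaluable = is.na(.data$rel) | .data$rel > 1L,
      event_month = dplyr::if_else(!is.na(.data$rel) & .data$rel > 1L &
                                     .data$rel <= .data$followup,
                                   .data$rel, NA_integer_)
    )
  dplyr::select(out, "patient_id", "event_month", "evaluable")
}

#' Person-period rows for one patient
#'
#' One row per month from the index month to the earlier of the event month
#' and the censoring month. Intervals are right-closed: row t covers
#' (t-1, t], the first Start is 0 and the Event indicator may be 1 only in
#' the last row.
#'
#' @param doses binary exposure vector x(1..followup).
#' @param event_month relative event month (>= 1) or `NA` if censored.
#' @param followup censoring month (relative, = length of `doses`).
#' @param covariates optional named list / one-row data frame of baseline
#'   covariates replicated across rows.
#' @param id patient identifier for the `Id` column.
#' @return tibble `Id`, `Start`, `Stop`, `Event`, `dose`, then covariates.
#' @export
#' @examples
#' build_person_period(c(1, 1, 0, 0, 0), event_month = 4, followup = 5)
build_person_period <- function(doses, event_month = NA, followup = length(doses),
                                covariates = NULL, id = 1L) {
  stopifnot(length(doses) >= followup)
  has_event <- !is.na(event_month)
  if (has_event && event_month < 1) stop("event month must be >= 1", call. = FALSE)
  if (has_event && event_month > followup) {
    stop("event after censoring: inconsistent input", call. = FALSE)
  }
  len <- if (has_event) event_month else followup
  out <- tibble::tibble(
    Id = rep(id, len),
    Start = seq_len(len) - 1L,
    Stop = seq_len(len),
    Event = c(rep(0L, len - 1L), as.integer(has_event)),
    dose = as.integer(doses[seq_len(len)])
  )
  if (!is.null(covariates)) {
    for (nm in names(covariates)) out[[nm]] <- covariates[[nm]]
  }
  out
}

# Vectorised person-period assembly for a whole cohort and one candidate
# code. `events` comes from event_dates(); prevalent patients are dropped.
#' @noRd
build_pp_table <- function(cohort, events, covariates = c("age", "sex", "severity")) {
  d <- cohort %>%
    dplyr::inner_join(events, by = "patient_id") %>%
    dplyr::filter(.data$evaluable)
  if (nrow(d) == 0) {
    return(tibble::tibble(Id = character(), Start = integer(), Stop = integer(),
                          Event = integer(), dose = integer()))
  }
  has_event <- !is.na(d$event_month)
  len <- ifelse(has_event, d$event_month, d$followup)
  rows <- rep(seq_len(nrow(d)), len)
  t_seq <- sequence(len)
  out <- tibble::tibble(
    Id = d$patient_id[rows],
    Start = t_seq - 1L,
    Stop = t_seq,
    Event = as.integer(has_event[rows] & t_seq == len[rows]),
    dose = unlist(purrr::map2(d$doses, len, function(x, l) x[seq_len(l)]),
                  use.names = FALSE)
  )
  for (nm in covariates) out[[nm]] <- d[[nm]][rows]
  out
}
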