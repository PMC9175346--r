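# Bootstrap association test for the WCE model.
#
# The WCE model was designed to characterise a known exposure-outcome
# relationship, not to test for one; the screening pipeline therefore tests
# association with a nonparametric patient-level bootstrap: patients are
# resampled with replacement (all person-period rows of a patient move
# together), the model is refitted on each replicate, and percentile
# confidence intervals are read off the order statistics of the replicated
# log window hazard ratio at ranks j = [alpha/2 * B], k = [(1-alpha/2) * B].

#' Bootstrap replicates of the WCE statistic
#'
#' Resamples patients with replacement `B` times, refits the WCE model on
#' each replicate and records the log window hazard ratio and covariate
#' coefficients. Replicates whose fit fails to converge (or has no events)
#' are recorded with `converged = FALSE` and excluded downstream; they are
#' counted, never silently imputed.
#'
#' @inheritParams fit_wce
#' @param B number of bootstrap replicates.
#' @param seed integer seed for the resampling (mandatory: screening must be
#'   reproducible).
#' @return tibble with one row per replicate: `replicate`, `log_whr`, one
#'   column per covariate coefficient, `converged`.
#' @export
bootstrap_replicates <- function(pp, basis, B = 1000, seed,
                                 covariates = c("age", "sex", "severity"),
                                 ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  zcols <- colnames(basis$matrix)
  cols <- c(zcols, covariates)
  X <- as.matrix(pp[, cols])
  start <- pp$Start; stop_ <- pp$Stop; event <- pp$Event
  ids <- unique(pp$Id)
  n <- length(ids)
  idx <- split(seq_len(nrow(pp)), factor(pp$Id, levels = ids))
  sB <- colSums(basis$matrix)

  log_whr <- rep(NA_real_, B)
  gam <- matrix(NA_real_, B, length(covariates),
                dimnames = list(NULL, covariates))
  converged <- logical(B)
  with_seed(seed, {
    for (b in seq_len(B)) {
      draw <- sample.int(n, n, replace = TRUE)
      rows <- unlist(idx[draw], use.names = FALSE)
      res <- tryCatch(
        cox_newton(start[rows], stop_[rows], event[rows],
                   X[rows, , drop = FALSE], ties = ties),
        error = function(e) NULL
      )
      if (!is.null(res) && res$converged) {
        converged[b] <- TRUE
        log_whr[b] <- sum(sB * res$coef[zcols])
        if (length(covariates)) gam[b, ] <- res$coef[covariates]
      }
    }
  })
  out <- tibble::tibble(replicate = seq_len(B), log_whr = log_whr,
                        converged = converged)
  for (nm in covariates) out[[nm]] <- gam[, nm]
  out
}

#' Percentile bootstrap confidence interval
#'
#' The interval is read off the sorted replicates at 1-based order-statistic
#' ranks `j = floor(alpha/2 * B)` (at least 1) and
#' `k = floor((1 - alpha/2) * B)`, with B the number of replicates supplied.
#'
#' @param replicates numeric vector of replicate statistics.
#' @param alpha significance level.
#' @return length-2 numeric vector `c(lower, upper)`.
#' @export
#' @examples
#' percentile_ci(1:1000, alpha = 0.05) # c(25, 975)
percentile_ci <- function(replicates, alpha = 0.05) {
  replicates <- replicates[!is.na(replicates)]
  B <- length(replicates)
  if (B < ceiling(2 / alpha)) {
    stop("too few replicates for a percentile interval at this alpha",
         call. = FALSE)
  }
  # tolerate floating-point fuzz in alpha/2 * B before flooring
  j <- max(1L, as.integer(floor(alpha / 2 * B + 1e-9)))
  k <- as.integer(floor((1 - alpha / 2) * B + 1e-9))
  s <- sort(replicates)
  c(s[j], s[k])
}

#' Two-sided bootstrap p-value
#'
#' Twice the smaller tail proportion of replicates on either side of the
#' null value, floored at 1/B and capped at 1. Consistent with the
#' percentile interval: p < alpha iff the alpha-level interval excludes the
#' null, up to rank rounding.
#'
#' @param replicates numeric vector of replicate statistics.
#' @param null null value on the statistic's scale (0 for a log hazard
#'   ratio).
#' @return p-value in `[1/B, 1]`.
#' @export
bootstrap_pvalue <- function(replicates, null = 0) {
  replicates <- replicates[!is.na(replicates)]
  B <- length(replicates)
  if (B < 50) stop("too few replicates for a bootstrap p-value", call. = FALSE)
  p <- 2 * min(sum(replicates <= null), sum(replicates >= null)) / B
  min(max(p, 1 / B), 1)
}

#' Bootstrap association test for a WCE fit
#'
#' Runs the full test for one candidate code: fits the model on the original
#' data, draws `B` patient-level bootstrap replicates, and summarises the
#' log window hazard ratio with a percentile confidence interval and
#' two-sided bootstrap p-value. If more than 20% of replicates fail to
#' converge the result is flagged unreliable and reported as not evaluated
#' by [select_signal()].
#'
#' @inheritParams bootstrap_replicates
#' @param alpha significance level for the interval.
#' @param min_events passed to [fit_wce()].
#' @return object of class `wce_boot`: the original `fit`, `replicates`
#'   tibble, `ci_log` / `ci_hr`, `p_value`, `B`, `B_eff`, `n_failed`,
#'   `alpha`, `seed`, `reliable`.
#' @export
wce_bootstrap <- function(pp, basis, B = 1000, alpha = 0.05, seed = 1L,
                          covariates = c("age", "sex", "severity"),
                          ties = c("efron", "breslow"), min_events = 10) {
  ties <- match.arg(ties)
  fit <- fit_wce(pp, basis, covariates = covariates, ties = ties,
                 min_events = min_events)
  out <- structure(list(fit = fit, B = B, alpha = alpha, seed = seed),
                   class = "wce_boot")
  if (fit$status != "ok") {
    out$reliable <- FALSE
    out$status <- fit$status
    return(out)
  }
  reps <- bootstrap_replicates(pp, basis, B = B, seed = seed,
                               covariates = covariates, ties = ties)
  good <- reps$log_whr[reps$converged]
  out$replicates <- reps
  out$n_failed <- sum(!reps$converged)
  out$B_eff <- length(good)
  out$reliable <- out$n_failed <= 0.2 * B
  out$statistic <- fit$log_window_hr
  if (out$reliable) {
    out$ci_log <- percentile_ci(good, alpha)
    out$ci_hr <- exp(out$ci_log)
    out$p_value <- bootstrap_pvalue(good, 0)
    gamma_ci <- purrr::map(covariates, function(nm) {
      percentile_ci(reps[[nm]][reps$converged], alpha)
    })
    names(gamma_ci) <- covariates
    out$gamma_ci <- gamma_ci
    out$status <- "ok"
  } else {
    out$status <- "unreliable"
  }
  out
}

#' Significance call for a bootstrap result
#'
#' `"significant"` iff the percentile interval for the log window hazard
#' ratio excludes 0 at level `alpha`; `"not evaluated"` for unreliable
#' results (too many failed replicates) or fits below the event threshold.
#' No multiple-testing correction is applied here; see [run_screen()] for
#' the optional false-discovery-rate adjustment.
#'
#' @param result a [wce_bootstrap()] object.
#' @param alpha level at which to call significance (defaults to the level
#'   the interval was built at).
#' @return one of `"significant"`, `"not significant"`, `"not evaluated"`.
#' @export
select_signal <- function(result, alpha = result$alpha) {
  stopifnot(inherits(result, "wce_boot"))
  if (!isTRUE(result$reliable)) return("not evaluated")
  ci <- if (alpha == result$alpha) {
    result$ci_log
  } else {
    percentile_ci(result$replicates$log_whr[result$replicates$converged], alpha)
  }
  if (ci[1] > 0 || ci[2] < 0) "significant" else "not significant"
}

#' @export
print.wce_boot <- function(x, ...) {
  cat(sprintf("<wce_boot> B = %d (%d failed), alpha = %.3f, status: %s\n",
              x$B, x$n_failed %||% NA_integer_, x$alpha, x$status %||% "?"))
  if (!is.null(x$ci_hr)) {
    cat(sprintf("  window HR %.3f [%.3f, %.3f], p = %.4g\n",
                x$fit$window_hr, x$ci_hr[1], x$ci_hr[2], x$p_value))
  }
  invisible(x)
}

#' @export
tidy.wce_boot <- function(x, ...) {
  tibble::tibble(
    term = "log_window_hr",
    estimate = x$statistic %||% NA_real_,
    conf.low = if (is.null(x$ci_log)) NA_real_ else x$ci_log[1],
    conf.high = if (is.null(x$ci_log)) NA_real_ else x$ci_log[2],
    p.value = x$p_value %||% NA_real_
  )
}

#' @export
glance.wce_boot <- function(x, ...) {
  tibble::tibble(
    B = x$B, B_eff = x$B_eff %||% NA_integer_,
    n_failed = x$n_failed %||% NA_integer_, alpha = x$alpha,
    window_hr = x$fit$window_hr %||% NA_real_,
    ci_low = if (is.null(x$ci_hr)) NA_real_ else x$ci_hr[1],
    ci_high = if (is.null(x$ci_hr)) NA_real_ else x$ci_hr[2],
    p.value = x$p_value %||% NA_real_,
    status = x$status %||% "?"
  )
}

#' Plot the bootstrap distribution
#'
#' Histogram of the replicated log window hazard ratio with the percentile
#' interval and the point estimate.
#'
#' @param object a [wce_bootstrap()] object.
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.wce_boot <- function(object, ...) {
  stopifnot(!is.null(object$replicates))
  d <- dplyr::filter(object$replicates, .data$converged)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log_whr)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$ci_log, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$statistic, colour = "red") +
    ggplot2::labs(x = "log window hazard ratio (bootstrap replicates)",
                  y = "count") +
    ggplot2::theme_minimal()
}
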