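# The weighted-cumulative-exposure engine.
#
# The WCE model writes the log hazard at month t as
#   sum_{u <= t} w(t - u + 1) x(u) + gamma' C,
# with w(.) a cubic spline over lags 1..T. Because w = B theta is linear in
# the spline coefficients, the weighted exposure history collapses to K
# artificial time-dependent covariates Z_k(t) = sum_u B_k(t-u+1) x(u), and
# (theta, gamma) are estimated by an ordinary time-dependent Cox partial
# likelihood on the person-period table augmented with the Z columns.

#' Artificial spline pseudo-covariates
#'
#' Computes the K time-dependent covariates that linearize the weighted
#' cumulative exposure: `Z_k(t) = sum_{u <= t, t-u+1 <= T} B_k(t-u+1) x(u)`,
#' with lag convention v = t - u + 1 (a dose in the current month has lag 1).
#' Doses older than the window contribute nothing.
#'
#' @param doses binary exposure vector x(1..L).
#' @param basis a [wce_basis()].
#' @return an L x K matrix with the basis column names.
#' @export
#' @examples
#' b <- wce_basis(window = 6, nknots = 1)
#' pseudo_covariates(c(1, 0, 0, 1, 0, 0, 0, 0), b)
pseudo_covariates <- function(doses, basis) {
  stopifnot(inherits(basis, "wce_basis"))
  B <- basis$matrix
  L <- length(doses)
  Z <- vapply(seq_len(ncol(B)),
              function(k) weighted_history(doses, B[, k]),
              numeric(L))
  Z <- matrix(Z, nrow = L)
  colnames(Z) <- colnames(B)
  Z
}

# Append Z columns to a person-period table, patient by patient. Rows of a
# patient must be in Stop order (as built by build_pp_table).
#' @noRd
add_pseudo_covariates <- function(pp, cohort, basis) {
  if (nrow(pp) == 0) return(pp)
  doses <- cohort$doses[match(unique(pp$Id), cohort$patient_id)]
  Z <- do.call(rbind, purrr::map2(doses, split(pp$Stop, factor(pp$Id, levels = unique(pp$Id))),
                                  function(x, stops) {
    pseudo_covariates(x, basis)[stops, , drop = FALSE]
  }))
  dplyr::bind_cols(pp, tibble::as_tibble(Z))
}

#' Fit the weighted-cumulative-exposure Cox model
#'
#' Maximizes the Cox partial likelihood over the spline coefficients theta
#' and covariate coefficients gamma, treating each person-month row of the
#' person-period table as a risk interval (counting-process form). Ties are
#' handled with the Efron approximation by default (month granularity makes
#' ties pervasive); estimation is Newton with step-halving from a start at
#' zero, gradient tolerance `eps`.
#'
#' @param pp person-period tibble with columns `Id`, `Start`, `Stop`,
#'   `Event`, the pseudo-covariate columns `Z1..ZK` matching `basis`, and
#'   any covariate columns named in `covariates`.
#' @param basis the [wce_basis()] that generated the Z columns.
#' @param covariates character vector of covariate column names (possibly
#'   empty).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param min_events fits with fewer events are reported as status
#'   `"not evaluated"` rather than attempted.
#' @param eps,max_iter Newton convergence controls.
#' @return an object of class `wce_fit`: spline coefficients `theta`,
#'   covariate coefficients `gamma`, the fitted weight function `weight`
#'   (= B theta) with delta-method standard errors, `window_hr`
#'   (= exp(sum(weight)): hazard ratio of a fully exposed window vs an
#'   unexposed one) with its Wald interval, `loglik`, `vcov`, convergence
#'   information and a `status` of `"ok"`, `"not evaluated"` or
#'   `"not converged"`.
#' @export
fit_wce <- function(pp, basis, covariates = c("age", "sex", "severity"),
                    ties = c("efron", "breslow"), min_events = 10,
                    eps = 1e-8, max_iter = 100L) {
  ties <- match.arg(ties)
  stopifnot(inherits(basis, "wce_basis"))
  zcols <- colnames(basis$matrix)
  missing_cols <- setdiff(c(zcols, covariates), names(pp))
  if (length(missing_cols) > 0) {
    stop("person-period table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  n_events <- sum(pp$Event)
  if (n_events == 0) stop("no events", call. = FALSE)
  out <- structure(
    list(basis = basis, covariates = covariates, ties = ties,
         n = length(unique(pp$Id)), n_rows = nrow(pp), n_events = n_events,
         status = "ok", converged = FALSE),
    class = "wce_fit"
  )
  if (n_events < min_events) {
    out$status <- "not evaluated"
    return(out)
  }
  X <- as.matrix(pp[, c(zcols, covariates)])
  fit <- cox_newton(pp$Start, pp$Stop, pp$Event, X, ties = ties,
                    eps = eps, max_iter = max_iter)
  B <- basis$matrix
  theta <- fit$coef[zcols]
  gamma <- fit$coef[setdiff(names(fit$coef), zcols)]
  weight <- drop(B %*% theta)
  vth <- fit$vcov[zcols, zcols, drop = FALSE]
  se_weight <- sqrt(pmax(0, rowSums((B %*% vth) * B)))
  sB <- colSums(B)
  log_whr <- sum(weight)
  se_log_whr <- sqrt(max(0, drop(t(sB) %*% vth %*% sB)))

  out$theta <- theta
  out$gamma <- gamma
  out$weight <- weight
  out$se_weight <- se_weight
  out$window_hr <- exp(log_whr)
  out$log_window_hr <- log_whr
  out$se_log_window_hr <- se_log_whr
  out$loglik <- fit$loglik
  out$loglik_null <- fit$loglik_null
  out$vcov <- fit$vcov
  out$iter <- fit$iter
  out$converged <- fit$converged
  if (!fit$converged) out$status <- "not converged"
  out
}

#' Fitted weight function
#'
#' The estimated weight function as a tibble: exposure `lag` months ago
#' multiplies the hazard by `exp(weight)`.
#'
#' @param fit a converged [fit_wce()] object.
#' @return tibble `lag`, `weight`, `se`.
#' @export
weight_function <- function(fit) {
  stopifnot(inherits(fit, "wce_fit"))
  if (is.null(fit$weight)) stop("fit has no estimate (status: ", fit$status, ")",
                                call. = FALSE)
  tibble::tibble(lag = seq_len(fit$basis$window),
                 weight = fit$weight, se = fit$se_weight)
}

#' Window hazard ratio
#'
#' `exp(sum_v w(v))`: the hazard ratio comparing a patient exposed during
#' every month of the window to one not exposed during the window.
#'
#' @param fit a converged [fit_wce()] object.
#' @return positive scalar.
#' @export
window_hr <- function(fit) {
  stopifnot(inherits(fit, "wce_fit"))
  if (is.null(fit$window_hr)) stop("fit has no estimate (status: ", fit$status,
                                   ")", call. = FALSE)
  fit$window_hr
}

#' @export
print.wce_fit <- function(x, ...) {
  cat(sprintf("<wce_fit> %d patients, %d events, status: %s\n",
              x$n, x$n_events, x$status))
  if (!is.null(x$window_hr)) {
    cat(sprintf("  window HR over %d months: %.3f (log %.3f, se %.3f)\n",
                x$basis$window, x$window_hr, x$log_window_hr,
                x$se_log_window_hr))
  }
  invisible(x)
}

#' @export
tidy.wce_fit <- function(x, ...) {
  if (is.null(x$theta)) {
    return(tibble::tibble(term = character(), estimate = numeric(),
                          std.error = numeric(), statistic = numeric(),
                          p.value = numeric()))
  }
  est <- c(x$theta, x$gamma)
  se <- sqrt(pmax(0, diag(x$vcov)))[names(est)]
  z <- est / se
  tibble::tibble(term = names(est), estimate = unname(est),
                 std.error = unname(se), statistic = unname(z),
                 p.value = unname(2 * pnorm(-abs(z))))
}

#' @export
glance.wce_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events,
                 window = x$basis$window, nknots = x$basis$nknots,
                 window_hr = x$window_hr %||% NA_real_,
                 log_window_hr = x$log_window_hr %||% NA_real_,
                 loglik = x$loglik %||% NA_real_,
                 loglik_null = x$loglik_null %||% NA_real_,
                 iter = x$iter %||% NA_integer_,
                 converged = x$converged, status = x$status)
}

#' Plot a fitted weight function
#'
#' Estimated weight function with a pointwise 95% Wald band; the dashed line
#' at zero is "no effect of a dose at this lag".
#'
#' @param object a [fit_wce()] object.
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.wce_fit <- function(object, ...) {
  wf <- weight_function(object)
  ggplot2::ggplot(wf, ggplot2::aes(x = .data$lag, y = .data$weight)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$weight - 1.96 * .data$se,
                                      ymax = .data$weight + 1.96 * .data$se),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "months since exposure",
                  y = "weight (log hazard ratio per dose)") +
    ggplot2::theme_minimal()
}
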