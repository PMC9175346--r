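# R wrapper around the compiled Cox partial-likelihood Newton solver.
# Counting-process (start, stop] rows, Efron (default) or Breslow ties,
# step-halving, deterministic start at 0, gradient tolerance 1e-8.

#' @noRd
cox_newton <- function(start, stop, event, X, init = NULL,
                       ties = c("efron", "breslow"),
                       eps = 1e-8, max_iter = 100L) {
  ties <- match.arg(ties)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(init)) init <- rep(0, ncol(X))
  n_events <- sum(event)
  if (n_events == 0) stop("no events", call. = FALSE)
  res <- .cox_fit_cpp(as.numeric(start), as.numeric(stop), as.integer(event),
                      X, as.numeric(init), as.integer(max_iter), eps, ties == "efron")
  coef <- drop(res$coef)
  names(coef) <- colnames(X)
  vcov <- tryCatch(solve(res$imat), error = function(e) {
    matrix(NA_real_, ncol(X), ncol(X))
  })
  dimnames(vcov) <- list(colnames(X), colnames(X))
  # monotone likelihood (e.g. all events among the exposed) shows up as
  # runaway coefficients; flag rather than report a spurious optimum
  monotone <- any(abs(coef) > 15)
  list(coef = coef, vcov = vcov,
       loglik = res$loglik, loglik_null = res$loglik0,
       gradient = drop(res$gradient), imat = res$imat,
       iter = res$iter, n_events = n_events,
       converged = isTRUE(res$converged) && !isTRUE(res$singular) && !monotone,
       monotone = monotone)
}
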