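#' Cubic B-spline basis for the exposure weight function
#'
#' Builds the spline basis used to model the weight function w(v): the
#' log-hazard contribution of one dose of the drug of interest taken `v`
#' months before the current risk interval, for lags v = 1..`window`.
#' The basis is a cubic B-spline with `nknots` interior knots equally spaced
#' over `[1, window]` and boundary knots of full multiplicity, so the basis
#' dimension is `nknots + 4` ( `nknots + 2` when right-constrained).
#'
#' The `"right"` constraint forces the weight function and its first
#' derivative to zero at the end of the window (doses `window` months old no
#' longer affect the hazard), implemented by dropping the last two basis
#' columns.
#'
#' @param window length T of the exposure window in months: how far back a
#'   dose can affect the hazard. Default 24.
#' @param nknots number of interior knots. Default 1.
#' @param constrained `"none"` (default) or `"right"`.
#' @return an object of class `wce_basis`: a list with the T x K basis
#'   `matrix`, `window`, `nknots`, `degree`, `constrained` and the full
#'   `knots` vector.
#' @export
#' @examples
#' b <- wce_basis(window = 24, nknots = 1)
#' dim(b$matrix) # 24 x 5
wce_basis <- function(window = 24, nknots = 1, constrained = c("none", "right")) {
  constrained <- match.arg(constrained)
  if (nknots < 0) stop("`nknots` must be >= 0", call. = FALSE)
  if (window < nknots + 5) {
    stop("`window` too small: need window >= nknots + 5 lags to identify the basis",
         call. = FALSE)
  }
  interior <- if (nknots > 0) {
    seq(1, window, length.out = nknots + 2)[-c(1, nknots + 2)]
  } else {
    numeric(0)
  }
  knots <- c(rep(1, 4), interior, rep(window, 4))
  B <- splines::splineDesign(knots, x = seq_len(window), ord = 4)
  if (constrained == "right") {
    B <- B[, seq_len(ncol(B) - 2), drop = FALSE]
  }
  colnames(B) <- paste0("Z", seq_len(ncol(B)))
  structure(
    list(matrix = B, window = as.integer(window), nknots = as.integer(nknots),
         degree = 3L, constrained = constrained, knots = knots),
    class = "wce_basis"
  )
}

# Evaluate the basis at arbitrary (possibly non-integer) lags in [1, window];
# used to check smoothness of the fitted weight function across knots.
#' @noRd
basis_eval <- function(basis, v) {
  B <- splines::splineDesign(basis$knots, x = v, ord = 4)
  if (basis$constrained == "right") B <- B[, seq_len(ncol(B) - 2), drop = FALSE]
  colnames(B) <- colnames(basis$matrix)
  B
}

#' @export
print.wce_basis <- function(x, ...) {
  cat(sprintf("<wce_basis> window %d months, %d interior knot(s), K = %d%s\n",
              x$window, x$nknots, ncol(x$matrix),
              if (x$constrained == "right") ", right-constrained" else ""))
  invisible(x)
}
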