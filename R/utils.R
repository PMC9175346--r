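# internal helpers: seeded evaluation, month arithmetic, seed derivation

# Evaluate `code` under `seed` and restore the caller's RNG state afterwards.
#' @noRd
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-unit seed stream below 2^31, so screening results are
# identical whatever the execution order of candidate codes.
#' @noRd
derive_seed <- function(master, i) {
  as.integer((as.numeric(master) + 7919 * as.numeric(i)) %% 2147483629) + 1L
}

#' Convert calendar dates to month offsets
#'
#' Months are counted from the first day of the month containing `origin`
#' (offset 0). Day-of-month is discarded: the pipeline operates at month
#' granularity.
#'
#' @param dates a `Date` vector or anything `as.Date()` accepts.
#' @param origin origin date; its month is offset 0.
#' @return integer vector of month offsets.
#' @export
#' @examples
#' month_index(c("2008-01-15", "2009-03-01"), origin = "2008-01-01")
month_index <- function(dates, origin = "2008-01-01") {
  d <- as.POSIXlt(as.Date(dates))
  o <- as.POSIXlt(as.Date(origin))
  (d$year - o$year) * 12L + (d$mon - o$mon)
}

#' Convert month offsets back to dates (first of month)
#'
#' @param index integer month offsets.
#' @inheritParams month_index
#' @return `Date` vector, first day of each month.
#' @export
month_date <- function(index, origin = "2008-01-01") {
  o <- as.POSIXlt(as.Date(origin))
  tot <- o$mon + index
  y <- o$year + 1900L + tot %/% 12L
  m <- tot %% 12L + 1L
  as.Date(sprintf("%04d-%02d-01", y, m))
}
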