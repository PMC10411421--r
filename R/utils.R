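#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero, the
#' convention used when reporting percentages in clinical tables (base R's
#' `round()` rounds ties to even).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return Numeric vector of the same length.
#' @examples
#' round_half_up(0.25, 1) # 0.3
#' round_half_up(52.757, 1) # 52.8
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Truncated normal draws by inverse-CDF; a < b required, vectorised over n.
rtruncnorm <- function(n, mean, sd, a = -Inf, b = Inf) {
  if (sd == 0) {
    return(rep(pmin(pmax(mean, a), b), n))
  }
  lo <- stats::pnorm(a, mean, sd)
  hi <- stats::pnorm(b, mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

as_date_strict <- function(x, what = "date") {
  if (inherits(x, "Date")) {
    return(x)
  }
  out <- suppressWarnings(as.Date(as.character(x), format = "%Y-%m-%d"))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_date <- function(x, name) {
  x <- as_date_strict(x)
  if (length(x) != 1 || is.na(x)) {
    abort(sprintf("`%s` must be a single valid date (YYYY-MM-DD).", name))
  }
  x
}
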