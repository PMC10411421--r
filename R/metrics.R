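#' Proportion estimate with a binomial confidence interval
#'
#' Computes `100 * numerator / denominator` with a 95% (by default)
#' confidence interval — Wilson score (via `prop.test` without continuity
#' correction) or Wald. Full precision is retained in the returned columns;
#' clinical-table display at one decimal (half-up) is available through
#' `format()`/`print()` or [round_half_up()].
#'
#' @param numerator,denominator Non-negative counts,
#'   `numerator <= denominator`, `denominator > 0`.
#' @param ci_method `"wilson"` (default) or `"wald"`.
#' @param conf_level Confidence level, default 0.95.
#' @return A one-row tibble of class `proportion_estimate`: `numerator`,
#'   `denominator`, `percent`, `ci_low`, `ci_high`, `ci_method` (all
#'   percentages on the 0-100 scale, unrounded).
#' @examples
#' prevalence(1391, 93216) # 1.5 (1.4-1.6)
#' @export
prevalence <- function(numerator, denominator, ci_method = c("wilson", "wald"),
                       conf_level = 0.95) {
  ci_method <- match.arg(ci_method)
  if (length(numerator) != 1 || length(denominator) != 1 ||
    is.na(numerator) || is.na(denominator)) {
    abort("`numerator` and `denominator` must be single counts.")
  }
  if (denominator <= 0) {
    abort("`denominator` must be positive.")
  }
  if (numerator < 0 || numerator > denominator) {
    abort("`numerator` must lie in [0, denominator].")
  }
  p <- numerator / denominator
  ci <- binom_ci(numerator, denominator, ci_method, conf_level)
  out <- tibble(
    numerator = as.numeric(numerator),
    denominator = as.numeric(denominator),
    percent = 100 * p,
    ci_low = 100 * ci[1],
    ci_high = 100 * ci[2],
    ci_method = ci_method
  )
  class(out) <- c("proportion_estimate", class(out))
  out
}

binom_ci <- function(x, n, method, conf_level) {
  if (method == "wilson") {
    # prop.test's chi-square small-count warning concerns its test p-value,
    # not the score interval used here.
    ci <- as.numeric(suppressWarnings(
      stats::prop.test(x, n, correct = FALSE, conf.level = conf_level)$conf.int
    ))
    if (x == 0) ci[1] <- 0
    if (x == n) ci[2] <- 1
    ci
  } else {
    p <- x / n
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    half <- z * sqrt(p * (1 - p) / n)
    c(max(0, p - half), min(1, p + half))
  }
}

#' @export
format.proportion_estimate <- function(x, ...) {
  sprintf(
    "%.0f/%.0f = %.1f%% (%.1f-%.1f)",
    x$numerator, x$denominator,
    round_half_up(x$percent, 1),
    round_half_up(x$ci_low, 1), round_half_up(x$ci_high, 1)
  )
}

#' @export
print.proportion_estimate <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Build a 2x2 confusion table from id sets
#'
#' Cross-classifies a predicted-positive set against a reference-positive
#' set over a finite universe of patients.
#'
#' @param pred,ref Character vectors of positive patient ids; both must be
#'   subsets of `universe`.
#' @param universe Character vector of all evaluated patient ids.
#' @return Object of class `confusion_table`: list with `tp`, `fp`, `fn`,
#'   `tn`, `n`.
#' @examples
#' confusion(c("A", "B"), c("A", "C"), c("A", "B", "C", "D"))
#' @export
confusion <- function(pred, ref, universe) {
  universe <- unique(as.character(universe))
  pred <- unique(as.character(pred))
  ref <- unique(as.character(ref))
  if (!all(pred %in% universe)) {
    abort("`pred` must be a subset of `universe`.")
  }
  if (!all(ref %in% universe)) {
    abort("`ref` must be a subset of `universe`.")
  }
  tp <- length(intersect(pred, ref))
  fp <- length(setdiff(pred, ref))
  fn <- length(setdiff(ref, pred))
  structure(
    list(tp = tp, fp = fp, fn = fn, tn = length(universe) - tp - fp - fn, n = length(universe)),
    class = "confusion_table"
  )
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf(
    "<confusion_table> n=%d  tp=%d fp=%d fn=%d tn=%d\n",
    x$n, x$tp, x$fp, x$fn, x$tn
  ))
  invisible(x)
}

#' Diagnostic accuracy metrics from a confusion table
#'
#' Sensitivity, specificity, positive and negative predictive value, each
#' with a binomial confidence interval on its own denominator. A metric
#' whose denominator is zero is reported as `NA` (undefined), not 0.
#'
#' @param table A `confusion_table` from [confusion()].
#' @param ci_method,conf_level Passed to the interval computation (Wilson
#'   default).
#' @return Tibble: `metric`, `estimate` (proportion, 0-1), `ci_low`,
#'   `ci_high`, `numerator`, `denominator`.
#' @export
accuracy_stats <- function(table, ci_method = c("wilson", "wald"),
                           conf_level = 0.95) {
  stopifnot(inherits(table, "confusion_table"))
  ci_method <- match.arg(ci_method)
  rows <- list(
    sensitivity = c(table$tp, table$tp + table$fn),
    specificity = c(table$tn, table$tn + table$fp),
    ppv = c(table$tp, table$tp + table$fp),
    npv = c(table$tn, table$tn + table$fn)
  )
  out <- lapply(names(rows), function(m) {
    num <- rows[[m]][1]
    den <- rows[[m]][2]
    if (den == 0) {
      tibble(
        metric = m, estimate = NA_real_, ci_low = NA_real_,
        ci_high = NA_real_, numerator = num, denominator = den
      )
    } else {
      ci <- binom_ci(num, den, ci_method, conf_level)
      tibble(
        metric = m, estimate = num / den, ci_low = ci[1],
        ci_high = ci[2], numerator = num, denominator = den
      )
    }
  })
  bind_rows(out)
}
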