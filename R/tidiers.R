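## broom-style tidiers for fitted objects.

#' Tidy a standard curve
#'
#' @param x A `standard_curve` from [fit_standard_curve()].
#' @param ... Unused.
#' @return One row per coefficient: `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`.
#' @method tidy standard_curve
#' @export
tidy.standard_curve <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))$coefficients # exact fits warn
  tibble(
    term = rownames(s),
    estimate = s[, "Estimate"],
    std.error = s[, "Std. Error"],
    statistic = s[, "t value"],
    p.value = s[, "Pr(>|t|)"]
  )
}

#' One-row summary of a standard curve
#'
#' @param x A `standard_curve` from [fit_standard_curve()].
#' @param ... Unused.
#' @return A one-row tibble: `slope`, `intercept`, `efficiency`,
#'   `amplification`, `r_squared`, `n`.
#' @method glance standard_curve
#' @export
glance.standard_curve <- function(x, ...) {
  tibble(
    slope = x$slope,
    intercept = x$intercept,
    efficiency = x$efficiency,
    amplification = x$amplification,
    r_squared = x$r_squared,
    n = x$n
  )
}

#' @export
generics::tidy

#' @export
generics::glance
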