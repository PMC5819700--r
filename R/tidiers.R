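#' @importFrom generics glance
#' @export
generics::glance

#' @export
generics::tidy

#' Tidy a Cobb-Douglas panel fit
#'
#' @param x a `cd_panel_fit`.
#' @param ... unused.
#' @return Tibble with one row per coefficient: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`.
#' @export
tidy.cd_panel_fit <- function(x, ...) {
  x$coefficients
}

#' One-row summary of a Cobb-Douglas panel fit
#'
#' @param x a `cd_panel_fit`.
#' @param ... unused.
#' @return Tibble with `effect`, `r.squared`, `rss`, `statistic` (overall
#'   F), `df1`, `df2`, `p.value`, `nobs`, `n_units`.
#' @export
glance.cd_panel_fit <- function(x, ...) {
  f <- x$fstatistic
  tibble::tibble(
    effect = x$effect,
    r.squared = x$r.squared,
    rss = x$rss,
    statistic = unname(f["value"]),
    df1 = unname(f["df1"]), df2 = unname(f["df2"]),
    p.value = if (is.na(f["value"])) NA_real_ else
      stats::pf(f["value"], f["df1"], f["df2"], lower.tail = FALSE),
    nobs = x$nobs, n_units = x$n_units
  )
}

#' @export
print.cd_panel_fit <- function(x, ...) {
  cat("<cd_panel_fit> ", x$effect, " form: ln(", x$output, ") ~ ",
      paste0("ln(", x$inputs, ")", collapse = " + "), "\n", sep = "")
  cat("  n = ", x$nobs, " (", x$n_units, " units x ", x$n_periods,
      " periods), R-squared = ", signif(x$r.squared, 4), "\n", sep = "")
  if (!is.null(x$beta)) {
    cat("  slopes:",
        paste(names(x$beta), signif(x$beta, 4), sep = " = ",
              collapse = ", "), "\n")
  } else {
    cat("  per-unit coefficients; see tidy()\n")
  }
  invisible(x)
}

#' Residuals of a Cobb-Douglas panel fit
#' @param object a `cd_panel_fit`.
#' @param ... unused.
#' @export
residuals.cd_panel_fit <- function(object, ...) {
  object$residuals$.resid
}
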