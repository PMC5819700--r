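#' Coefficient-of-variation ranking of candidate variables
#'
#' Computes the sample coefficient of variation (SD / mean) of every
#' candidate column and returns them sorted by decreasing dispersion, the
#' ranking the final variable shortlist is read from.
#'
#' @param data panel data frame.
#' @param candidates character vector of column names.
#' @return A tibble with columns `variable`, `mean`, `sd`, `cv`, sorted
#'   by decreasing `cv`.  Variables with zero mean are dropped with a
#'   warning (their CV is undefined).
#' @export
#' @examples
#' dispersion_rank(data.frame(a = c(2, 4, 6), b = c(5, 5, 5)), c("a", "b"))
dispersion_rank <- function(data, candidates) {
  stopifnot(length(candidates) > 0, all(candidates %in% names(data)))
  out <- tibble::tibble(
    variable = candidates,
    mean = vapply(candidates, function(v) mean(data[[v]]), 0,
                  USE.NAMES = FALSE),
    sd = vapply(candidates, function(v) stats::sd(data[[v]]), 0,
                USE.NAMES = FALSE)
  )
  zero <- out$mean == 0
  if (any(zero)) {
    warning("dropping variable(s) with zero mean (undefined CV): ",
            paste(out$variable[zero], collapse = ", "), call. = FALSE)
    out <- out[!zero, ]
  }
  out |>
    dplyr::mutate(cv = .data$sd / .data$mean) |>
    dplyr::arrange(dplyr::desc(.data$cv))
}

#' Drop near-collinear candidates by pairwise correlation
#'
#' For every pair of candidates whose absolute Pearson correlation
#' reaches `threshold`, the member with the lower coefficient of
#' variation is dropped (ties broken by dropping the lexicographically
#' later name).  Pairs are processed in decreasing order of |r| so the
#' result does not depend on the ordering of `candidates`.
#'
#' @param data panel data frame.
#' @param candidates character vector of column names.
#' @param threshold absolute-correlation cutoff in (0, 1].
#' @return A tibble with columns `variable`, `retained`, `reason`
#'   (`NA` or `"collinear"`) and `cv`; the correlation matrix is attached
#'   as the `"correlations"` attribute.  Constant columns have undefined
#'   correlations: they are flagged with a warning and retained.
#' @export
#' @examples
#' d <- data.frame(a = 1:10, b = 2 * (1:10), c = rnorm(10))
#' correlation_filter(d, c("a", "b", "c"), threshold = 0.9)
correlation_filter <- function(data, candidates, threshold = 0.9) {
  stopifnot(threshold > 0, threshold <= 1,
            all(candidates %in% names(data)), nrow(data) >= 2)
  candidates <- unique(candidates)
  X <- as.data.frame(data[candidates])
  const <- vapply(X, function(x) stats::sd(x) == 0, TRUE)
  if (any(const)) {
    warning("constant column(s) with undefined correlations retained: ",
            paste(candidates[const], collapse = ", "), call. = FALSE)
  }
  cv <- vapply(candidates, function(v) {
    m <- mean(X[[v]])
    if (m == 0) NA_real_ else stats::sd(X[[v]]) / m
  }, 0)
  cmat <- suppressWarnings(stats::cor(X))
  live <- candidates[!const]
  dropped <- character(0)
  if (length(live) >= 2) {
    pairs <- t(utils::combn(sort(live), 2))
    r <- abs(cmat[pairs])
    ord <- order(-r, pairs[, 1], pairs[, 2])
    for (i in ord) {
      if (r[i] < threshold || is.na(r[i])) next
      a <- pairs[i, 1]; b <- pairs[i, 2]
      if (a %in% dropped || b %in% dropped) next
      # keep the more dispersed member; tie -> keep the earlier name
      drop_b <- isTRUE(cv[b] < cv[a]) || isTRUE(cv[b] == cv[a])
      dropped <- c(dropped, if (drop_b) b else a)
    }
  }
  out <- tibble::tibble(
    variable = candidates,
    retained = !candidates %in% dropped,
    reason = ifelse(candidates %in% dropped, "collinear", NA_character_),
    cv = unname(cv)
  )
  attr(out, "correlations") <- cmat
  out
}

#' Screen inputs by explanatory power against the outputs
#'
#' An input survives when the simple one-regressor least-squares fit of
#' at least one output on it attains a coefficient of determination of at
#' least `benchmark` (the conventional 60% cutoff by default).
#'
#' @param data panel data frame.
#' @param inputs,outputs character vectors of column names.
#' @param benchmark R-squared benchmark in (0, 1).
#' @return A tibble with one row per input: `variable`, `best_r2`,
#'   `best_output`, `retained`, `reason` (`NA` or `"low_r2"`); the full
#'   input-by-output R-squared matrix is attached as attribute `"r2"`.
#' @export
r2_screen <- function(data, inputs, outputs, benchmark = 0.6) {
  stopifnot(benchmark > 0, benchmark < 1,
            all(inputs %in% names(data)), all(outputs %in% names(data)),
            nrow(data) >= 3)
  r2 <- matrix(NA_real_, length(inputs), length(outputs),
               dimnames = list(inputs, outputs))
  for (y in outputs) {
    if (stats::sd(data[[y]]) == 0) {
      warning("output '", y, "' has zero variance; R-squared undefined",
              call. = FALSE)
      next
    }
    for (x in inputs) {
      r <- suppressWarnings(stats::cor(data[[x]], data[[y]]))
      r2[x, y] <- if (is.na(r)) 0 else r^2
    }
  }
  best <- apply(r2, 1, function(z) {
    if (all(is.na(z))) NA_real_ else max(z, na.rm = TRUE)
  })
  keep <- unname(!is.na(best) & best >= benchmark)
  out <- tibble::tibble(
    variable = inputs,
    best_r2 = unname(best),
    best_output = outputs[apply(r2, 1, function(z) {
      if (all(is.na(z))) NA_integer_ else which.max(z)
    })],
    retained = keep,
    reason = ifelse(keep, NA_character_, "low_r2")
  )
  attr(out, "r2") <- r2
  out
}

#' Full three-stage variable screen
#'
#' Applies, in order: the pairwise correlation filter separately within
#' the inputs and within the outputs, the R-squared benchmark of the
#' surviving inputs against the surviving outputs, and the
#' coefficient-of-variation ranking of everything retained.  The
#' combination is idempotent: screening an already-screened variable set
#' changes nothing.
#'
#' @param data panel data frame.
#' @param inputs,outputs character vectors of candidate column names.
#' @param cor_threshold absolute-correlation cutoff for the collinearity
#'   filter.
#' @param r2_benchmark R-squared benchmark for the explanatory-power
#'   screen.
#' @return An object of class `screening_report`: a list with `variables`
#'   (per-candidate tibble with `role`, `retained`, `reason`, `cv`),
#'   `retained_inputs`, `retained_outputs`, the pairwise `correlations`,
#'   the `r2` matrix and the `dispersion` ranking.
#' @export
#' @examples
#' panel <- generate_panel(synthetic_config(n_units = 8, n_periods = 4))
#' screen_variables(panel,
#'   inputs = c("doctors", "nurses", "beds", "financial"),
#'   outputs = c("outpatients", "inpatients"))
screen_variables <- function(data, inputs, outputs,
                             cor_threshold = 0.9, r2_benchmark = 0.6) {
  cf_in <- correlation_filter(data, inputs, cor_threshold)
  cf_out <- correlation_filter(data, outputs, cor_threshold)
  in1 <- cf_in$variable[cf_in$retained]
  out1 <- cf_out$variable[cf_out$retained]
  r2 <- r2_screen(data, in1, out1, r2_benchmark)
  in2 <- r2$variable[r2$retained]
  disp <- dispersion_rank(data, c(in2, out1))

  vars <- dplyr::bind_rows(
    dplyr::mutate(cf_in, role = "input"),
    dplyr::mutate(cf_out, role = "output")
  ) |>
    dplyr::left_join(
      dplyr::select(r2, "variable", r2_retained = "retained",
                    r2_reason = "reason"),
      by = "variable") |>
    dplyr::mutate(
      retained = .data$retained & !(.data$role == "input" &
                                      !is.na(.data$r2_retained) &
                                      !.data$r2_retained),
      reason = dplyr::coalesce(.data$reason, .data$r2_reason)
    ) |>
    dplyr::select("variable", "role", "retained", "reason", "cv")

  structure(list(
    variables = vars,
    retained_inputs = in2,
    retained_outputs = out1,
    correlations = list(inputs = attr(cf_in, "correlations"),
                        outputs = attr(cf_out, "correlations")),
    r2 = attr(r2, "r2"),
    dispersion = disp,
    settings = list(cor_threshold = cor_threshold,
                    r2_benchmark = r2_benchmark)
  ), class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat("<screening_report>\n")
  cat("  retained inputs: ", paste(x$retained_inputs, collapse = ", "),
      "\n  retained outputs:", paste(x$retained_outputs, collapse = ", "),
      "\n")
  drops <- dplyr::filter(x$variables, !.data$retained)
  if (nrow(drops) > 0) {
    cat("  dropped:\n")
    for (i in seq_len(nrow(drops))) {
      cat("    ", drops$variable[i], " (", drops$reason[i], ")\n", sep = "")
    }
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.screening_report <- function(x, ...) {
  x$variables
}
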