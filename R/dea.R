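#' Solve one input-oriented DEA envelopment program
#'
#' Low-level matrix interface.  Phase 1 minimises the radial contraction
#' factor theta subject to the evaluated point being dominated by a
#' nonnegative (CRS) or convex (VRS) combination of the reference units;
#' phase 2 maximises the total slack at the optimal theta, which resolves
#' the non-uniqueness of the reference weights without resorting to a
#' non-Archimedean epsilon in the objective.  Data are rescaled
#' internally by per-variable maxima, so results are invariant to the
#' units of measurement.
#'
#' The evaluated point need not belong to the reference set
#' (cross-period evaluation); in that case theta may exceed 1, and under
#' VRS the program can be infeasible, which is reported through `status`
#' rather than as a number.
#'
#' @param X reference inputs, a `n_dmu x n_input` matrix (rows = units).
#' @param Y reference outputs, a `n_dmu x n_output` matrix.
#' @param x0,y0 input and output vectors of the evaluated unit; default
#'   to row `eval` of `X` and `Y`.
#' @param eval row index of the evaluated unit within the reference set.
#' @param rts returns-to-scale assumption: `"crs"` (CCR) or `"vrs"`
#'   (BCC, adds the convexity constraint `sum(lambda) = 1`).
#' @param tol numeric tolerance for efficiency comparisons.
#' @return A list with `status`, `theta`, `lambda` (reference weights),
#'   `slack_input`, `slack_output`, `k = sum(lambda)`,
#'   `ideal_input = theta * x0 - slack_input` and
#'   `ideal_output = y0 + slack_output`.
#' @export
#' @examples
#' X <- matrix(c(2, 4), ncol = 1)  # two units, one input
#' Y <- matrix(c(4, 4), ncol = 1)
#' dea_solve(X, Y, eval = 2)$theta  # 0.5
dea_solve <- function(X, Y, x0 = NULL, y0 = NULL, eval = NULL,
                      rts = c("crs", "vrs"), tol = 1e-6) {
  rts <- match.arg(rts)
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); m <- ncol(X); s <- ncol(Y)
  stopifnot(nrow(Y) == n, n >= 1)
  if (!is.null(eval)) {
    x0 <- X[eval, ]; y0 <- Y[eval, ]
  }
  stopifnot(length(x0) == m, length(y0) == s)
  if (any(X <= 0) || any(Y <= 0) || any(x0 <= 0) || any(y0 <= 0)) {
    stop("DEA requires strictly positive inputs and outputs", call. = FALSE)
  }

  # units-invariant rescaling
  cx <- pmax(apply(X, 2, max), x0)
  cy <- pmax(apply(Y, 2, max), y0)
  Xs <- sweep(X, 2, cx, "/"); x0s <- x0 / cx
  Ys <- sweep(Y, 2, cy, "/"); y0s <- y0 / cy

  # phase 1: variables (theta, lambda)
  A <- rbind(cbind(-x0s, t(Xs)),
             cbind(0, t(Ys)))
  rhs <- c(rep(0, m), y0s)
  dir <- c(rep("<=", m), rep(">=", s))
  if (rts == "vrs") {
    A <- rbind(A, c(0, rep(1, n)))
    rhs <- c(rhs, 1)
    dir <- c(dir, "=")
  }
  p1 <- lp_solve(c(1, rep(0, n)), A, rhs, dir, maximize = FALSE)
  if (p1$status != "optimal") {
    if (p1$status == "infeasible") {
      return(list(status = "infeasible", theta = NA_real_,
                  lambda = rep(NA_real_, n),
                  slack_input = rep(NA_real_, m),
                  slack_output = rep(NA_real_, s),
                  k = NA_real_, ideal_input = NULL, ideal_output = NULL))
    }
    stop("DEA phase-1 solver failure: ", p1$status, call. = FALSE)
  }
  theta <- p1$value

  # phase 2: variables (lambda, s_in, s_out), theta fixed
  A2 <- rbind(cbind(t(Xs), diag(m), matrix(0, m, s)),
              cbind(t(Ys), matrix(0, s, m), -diag(s)))
  rhs2 <- c(theta * x0s, y0s)
  dir2 <- rep("=", m + s)
  if (rts == "vrs") {
    A2 <- rbind(A2, c(rep(1, n), rep(0, m + s)))
    rhs2 <- c(rhs2, 1)
    dir2 <- c(dir2, "=")
  }
  p2 <- lp_solve(c(rep(0, n), rep(1, m + s)), A2, rhs2, dir2,
                 maximize = TRUE)
  if (p2$status != "optimal") {
    stop("DEA phase-2 solver failure: ", p2$status, call. = FALSE)
  }
  lambda <- p2$x[seq_len(n)]
  s_in <- p2$x[n + seq_len(m)] * cx
  s_out <- p2$x[n + m + seq_len(s)] * cy
  names(s_in) <- colnames(X); names(s_out) <- colnames(Y)
  proj <- project_to_frontier(theta, x0, y0, s_in, s_out)
  list(status = "optimal", theta = theta, lambda = lambda,
       slack_input = s_in, slack_output = s_out, k = sum(lambda),
       ideal_input = proj$ideal_input, ideal_output = proj$ideal_output)
}

#' Project a unit onto the efficient frontier
#'
#' Ideal (target) values of an evaluated unit: inputs are radially
#' contracted and then reduced by the input slacks, outputs are raised by
#' the output slacks: `X' = theta * X0 - S-`, `Y' = Y0 + S+`.
#' Re-evaluating the projected point against the same reference set
#' yields an efficiency of 1 with zero slack.
#'
#' @param theta radial efficiency of the unit.
#' @param x0,y0 actual input and output vectors.
#' @param slack_input,slack_output phase-2 slack vectors.
#' @return List with `ideal_input` and `ideal_output`.
#' @export
project_to_frontier <- function(theta, x0, y0, slack_input, slack_output) {
  xi <- theta * x0 - slack_input
  yi <- y0 + slack_output
  if (any(xi <= 0)) {
    stop("degenerate projection: nonpositive ideal input", call. = FALSE)
  }
  list(ideal_input = xi, ideal_output = yi)
}

#' Three-way DEA efficiency classification
#'
#' A unit is DEA efficient when theta = 1 with all slacks zero, weakly
#' DEA efficient when theta = 1 but some slack is positive, and non-DEA
#' efficient when theta < 1 (all comparisons within `tol`).
#'
#' @param theta radial efficiency (vectorised).
#' @param total_slack sum of all input and output slacks (vectorised).
#' @param tol comparison tolerance.
#' @return Character vector with levels `"efficient"`,
#'   `"weakly_efficient"`, `"non_efficient"`.
#' @export
#' @examples
#' classify_efficiency(c(1, 1, 0.51), c(0, 0.3, 0))
classify_efficiency <- function(theta, total_slack, tol = 1e-6) {
  dplyr::case_when(
    theta >= 1 - tol & total_slack <= tol ~ "efficient",
    theta >= 1 - tol ~ "weakly_efficient",
    .default = "non_efficient"
  )
}

#' Returns-to-scale classification from the reference-weight sum
#'
#' Under constant returns the sum `k` of the optimal reference weights
#' measures the scale of the benchmark: `k = 1` means scale-invariant
#' operation, `k < 1` increasing returns (the unit is below its most
#' productive scale) and `k > 1` decreasing returns.
#'
#' @param k sum of the slack-maximal CRS reference weights (vectorised).
#' @param tol half-width of the `k = 1` band.
#' @return Character vector with levels `"invariant"`, `"increasing"`,
#'   `"decreasing"`.
#' @export
#' @examples
#' returns_to_scale(c(1, 0.73, 1.10))
returns_to_scale <- function(k, tol = 1e-6) {
  dplyr::case_when(
    abs(k - 1) <= tol ~ "invariant",
    k < 1 ~ "increasing",
    .default = "decreasing"
  )
}

#' Scale efficiency
#'
#' Ratio of overall (CRS) to pure technical (VRS) efficiency; 1 when the
#' unit operates at its most productive scale size.
#'
#' @param theta_crs,theta_vrs CCR and BCC efficiencies (vectorised).
#' @param tol tolerance for the consistency check `theta_vrs >=
#'   theta_crs`.
#' @return Numeric vector of scale efficiencies in (0, 1].
#' @export
#' @examples
#' scale_efficiency(0.5, 0.8)  # 0.625
scale_efficiency <- function(theta_crs, theta_vrs, tol = 1e-6) {
  if (any(theta_vrs < theta_crs - tol)) {
    stop("inconsistent solver output: theta_vrs < theta_crs",
         call. = FALSE)
  }
  pmin(theta_crs / theta_vrs, 1)
}

# internal: slice a panel into X/Y matrices with unit row names
panel_slice <- function(data, inputs, outputs, unit) {
  X <- as.matrix(data[inputs])
  Y <- as.matrix(data[outputs])
  rownames(X) <- rownames(Y) <- as.character(data[[unit]])
  list(X = X, Y = Y)
}

#' Per-unit DEA efficiency table
#'
#' Solves the input-oriented envelopment program for every unit of every
#' period cross-section and returns a tidy table of efficiencies,
#' classifications, slacks and frontier projections.
#'
#' @param data panel data frame with strictly positive input and output
#'   columns.
#' @param inputs,outputs character vectors of column names.
#' @param unit name of the unit-identifier column.
#' @param period name of the period column, or `NULL` to treat `data` as
#'   a single cross-section.
#' @param returns `"crs"` or `"vrs"`.
#' @param tol numeric tolerance.
#' @return A tibble with one row per unit-period: `theta`,
#'   `efficiency_class`, `k` and `rts_class` (CRS only), the reference
#'   weights as a `lambda` list-column, slack columns
#'   (`slack_in_*`, `slack_out_*`) and projected ideal values
#'   (`ideal_*`).
#' @export
#' @examples
#' panel <- generate_panel(synthetic_config(n_units = 6, n_periods = 2))
#' dea_efficiency(panel, inputs = c("doctors", "beds"),
#'                outputs = "outpatients", period = "year")
dea_efficiency <- function(data, inputs, outputs, unit = "unit",
                           period = NULL, returns = c("crs", "vrs"),
                           tol = 1e-6) {
  returns <- match.arg(returns)
  stopifnot(all(c(inputs, outputs, unit) %in% names(data)))
  if (!is.null(period)) stopifnot(period %in% names(data))
  groups <- if (is.null(period)) list(data) else
    split(data, data[[period]])

  res <- purrr::map(groups, function(slice) {
    sl <- panel_slice(slice, inputs, outputs, unit)
    purrr::map(seq_len(nrow(sl$X)), function(j) {
      r <- dea_solve(sl$X, sl$Y, eval = j, rts = returns, tol = tol)
      if (r$status != "optimal") {
        stop("DEA program ", r$status, " for unit ",
             rownames(sl$X)[j], call. = FALSE)
      }
      row <- tibble::tibble(
        unit = slice[[unit]][j],
        theta = r$theta,
        efficiency_class = classify_efficiency(
          r$theta, sum(r$slack_input) + sum(r$slack_output), tol),
        k = if (returns == "crs") r$k else NA_real_,
        rts_class = if (returns == "crs") returns_to_scale(r$k, tol)
                    else NA_character_,
        lambda = list(stats::setNames(r$lambda, rownames(sl$X)))
      )
      for (v in inputs) row[[paste0("slack_in_", v)]] <- r$slack_input[[v]]
      for (v in outputs) row[[paste0("slack_out_", v)]] <- r$slack_output[[v]]
      for (v in inputs) row[[paste0("ideal_", v)]] <- r$ideal_input[[v]]
      for (v in outputs) row[[paste0("ideal_", v)]] <- r$ideal_output[[v]]
      if (!is.null(period)) row[[period]] <- slice[[period]][j]
      row
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  names(res)[names(res) == "unit"] <- unit
  front <- c(unit, period, "theta", "efficiency_class", "k", "rts_class")
  res |> dplyr::relocate(dplyr::all_of(front)) |> tibble::as_tibble()
}

#' Combined CRS/VRS efficiency scores
#'
#' Convenience wrapper computing, per unit and period, the overall (CCR)
#' efficiency, pure technical (BCC) efficiency, their ratio (scale
#' efficiency), the efficiency classification and the returns-to-scale
#' class -- the row vocabulary of a regional efficiency table.
#'
#' @inheritParams dea_efficiency
#' @return A tibble with columns `unit`, `period`,
#'   `overall_efficiency`, `pure_technical_efficiency`,
#'   `scale_efficiency`, `efficiency_class`, `k`, `rts_class`.
#' @export
dea_scores <- function(data, inputs, outputs, unit = "unit",
                       period = NULL, tol = 1e-6) {
  crs <- dea_efficiency(data, inputs, outputs, unit, period, "crs", tol)
  vrs <- dea_efficiency(data, inputs, outputs, unit, period, "vrs", tol)
  keys <- c(unit, period)
  slack_cols <- grep("^slack_", names(crs), value = TRUE)
  crs$total_slack <- rowSums(crs[slack_cols])
  out <- crs |>
    dplyr::select(dplyr::all_of(keys), overall_efficiency = "theta",
                  "efficiency_class", "k", "rts_class") |>
    dplyr::left_join(
      vrs |> dplyr::select(dplyr::all_of(keys),
                           pure_technical_efficiency = "theta"),
      by = keys) |>
    dplyr::mutate(scale_efficiency = scale_efficiency(
      .data$overall_efficiency, .data$pure_technical_efficiency, tol))
  out |>
    dplyr::relocate(dplyr::all_of(c(keys, "overall_efficiency",
                                    "pure_technical_efficiency",
                                    "scale_efficiency")))
}
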