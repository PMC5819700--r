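# package-local cache (ADF quantile table)
the <- new.env(parent = emptyenv())

# Finite-sample quantile table of the ADF t statistic, simulated under
# the unit-root null for a grid of series lengths (see
# data-raw/adf_quantiles.R for the generating script and seed).
adf_table <- function() {
  if (is.null(the$adf_tab)) {
    path <- system.file("extdata", "adf_tau_quantiles.csv",
                        package = "deapanel")
    the$adf_tab <- utils::read.csv(path)
  }
  the$adf_tab
}

# MacKinnon-style asymptotic tail approximation, used only beyond the
# tabulated quantile range
adf_tail_p <- function(tau, case) {
  co <- switch(case,
    c  = list(star = -1.61, small = c(2.1659, 1.4412, 0.038269),
              large = c(1.7339, 0.93202, -0.12745, -0.010368)),
    ct = list(star = -2.89, small = c(3.2512, 1.6047, 0.049588),
              large = c(2.5261, 0.61654, -0.37956, -0.060285)))
  cf <- if (tau <= co$star) co$small else co$large
  stats::pnorm(sum(cf * tau^(seq_along(cf) - 1)))
}

#' Finite-sample p-value of the ADF t statistic
#'
#' Interpolates the simulated null quantile table of the augmented
#' Dickey-Fuller t statistic in the statistic and in `1/T` between the
#' tabulated series lengths; beyond the tabulated probability range
#' (p < 0.0005 or p > 0.9995) it falls back on the asymptotic
#' response-surface tail approximation.
#'
#' @param tau ADF t statistic.
#' @param n series length.
#' @param deterministic `"intercept"` or `"trend"` (intercept plus
#'   linear trend), matching the test regression.
#' @return p-value in (0, 1).
#' @export
adf_pvalue <- function(tau, n, deterministic = c("intercept", "trend")) {
  deterministic <- match.arg(deterministic)
  case <- if (deterministic == "intercept") "c" else "ct"
  tab <- adf_table()
  tab <- tab[tab$case == case, ]
  Ts <- sort(unique(tab$T))
  n <- min(max(n, min(Ts)), max(Ts))

  p_at <- function(T0) {
    sl <- tab[tab$T == T0, ]
    if (tau < min(sl$tau)) {
      return(min(adf_tail_p(tau, case), min(sl$prob)))
    }
    if (tau > max(sl$tau)) {
      return(max(adf_tail_p(tau, case), max(sl$prob)))
    }
    stats::approx(sl$tau, sl$prob, xout = tau, ties = "ordered")$y
  }
  if (n %in% Ts) return(p_at(n))
  lo <- max(Ts[Ts < n]); hi <- min(Ts[Ts > n])
  w <- (1 / n - 1 / hi) / (1 / lo - 1 / hi)
  w * p_at(lo) + (1 - w) * p_at(hi)
}

#' Augmented Dickey-Fuller test for a single series
#'
#' Regresses the first difference on the lagged level, the chosen
#' deterministic terms and `lags` lagged differences; the t statistic of
#' the lagged level is referred to the finite-sample null distribution
#' via [adf_pvalue()].
#'
#' @param y numeric series (time order).
#' @param deterministic `"intercept"` or `"trend"` (intercept + trend).
#' @param lags number of lagged differences in the test regression.
#' @return One-row tibble: `statistic`, `p.value`, `lags`,
#'   `deterministic`, `n`.
#' @export
#' @examples
#' set.seed(1)
#' adf_test(cumsum(rnorm(60)))
adf_test <- function(y, deterministic = c("intercept", "trend"),
                     lags = 1L) {
  deterministic <- match.arg(deterministic)
  y <- as.numeric(y)
  T <- length(y)
  if (T < lags + 5L) {
    stop("series too short for an ADF regression with ", lags,
         " lag(s)", call. = FALSE)
  }
  if (stats::sd(y) == 0) {
    stop("constant series: ADF statistic degenerate", call. = FALSE)
  }
  dy <- diff(y)
  idx <- (lags + 1L):(T - 1L)
  X <- cbind(1, y[idx])
  if (deterministic == "trend") X <- cbind(X, idx)
  for (l in seq_len(lags)) X <- cbind(X, dy[idx - l])
  yy <- dy[idx]
  fit <- stats::lm.fit(X, yy)
  rss <- sum(fit$residuals^2)
  dof <- length(yy) - ncol(X)
  if (dof <= 0 || rss <= 0) {
    stop("degenerate ADF regression", call. = FALSE)
  }
  se <- sqrt(rss / dof * chol2inv(chol(crossprod(X)))[2, 2])
  tau <- unname(fit$coefficients[2] / se)
  tibble::tibble(statistic = tau,
                 p.value = adf_pvalue(tau, T, deterministic),
                 lags = lags, deterministic = deterministic, n = T)
}

#' Panel unit-root tests
#'
#' For each requested variable, runs (a) the individual-process route: an
#' ADF test per unit combined across units with Fisher's statistic
#' `P = -2 sum(log p_i)`, chi-square with `2N` degrees of freedom under
#' the joint unit-root null; and (b) a simplified common-process
#' statistic in the spirit of the pooled panel test: the t statistic of
#' the common lagged-level coefficient in the pooled lag-augmented
#' regression on per-unit demeaned (or detrended) data.  The pooled t is
#' reported without the small-sample mean/variance corrections of the
#' full common-process test and therefore without a p-value; the Fisher
#' test is the decision statistic.
#'
#' @param data panel data frame.
#' @param vars character vector of (positive) variable names; tests run
#'   on their natural logs when `log = TRUE`.
#' @param unit,period names of the unit and period columns.
#' @param deterministic `"intercept"` or `"trend"` per variable
#'   (recycled): use `"trend"` for trending series.
#' @param lags lagged differences in each test regression.
#' @param log test the natural log of each variable.
#' @return A tibble with one row per variable and test
#'   (`"adf_fisher"`, `"pooled_t"`): `statistic`, `df`, `p.value`,
#'   `lags`, `deterministic`.
#' @export
unit_root_tests <- function(data, vars, unit = "unit", period = "year",
                            deterministic = "intercept", lags = 1L,
                            log = TRUE) {
  stopifnot(all(c(vars, unit, period) %in% names(data)))
  deterministic <- rep_len(deterministic, length(vars))
  purrr::map2(vars, deterministic, function(v, det) {
    det <- match.arg(det, c("intercept", "trend"))
    series <- data |>
      dplyr::arrange(.data[[unit]], .data[[period]]) |>
      dplyr::group_by(.data[[unit]]) |>
      dplyr::summarise(y = list(.data[[v]]), .groups = "drop")
    ys <- series$y
    if (log) {
      if (any(unlist(ys) <= 0)) {
        stop("nonpositive values in '", v, "'; cannot take logs",
             call. = FALSE)
      }
      ys <- purrr::map(ys, base::log)
    }
    Nu <- length(ys)
    ps <- purrr::map_dbl(seq_len(Nu), function(i) {
      res <- tryCatch(adf_test(ys[[i]], det, lags),
                      error = function(e) {
                        stop("unit '", series[[unit]][i], "', variable '",
                             v, "': ", conditionMessage(e), call. = FALSE)
                      })
      res$p.value
    })
    fisher <- -2 * sum(base::log(pmax(ps, 1e-300)))

    # pooled t on demeaned/detrended series
    Xl <- list(); yl <- list()
    for (yy in ys) {
      T <- length(yy)
      D <- matrix(1, T, 1)
      if (det == "trend") D <- cbind(D, seq_len(T))
      yt <- stats::lm.fit(D, yy)$residuals
      dy <- diff(yt)
      idx <- (lags + 1L):(T - 1L)
      Xi <- cbind(yt[idx])
      for (l in seq_len(lags)) Xi <- cbind(Xi, dy[idx - l])
      Xl[[length(Xl) + 1L]] <- Xi
      yl[[length(yl) + 1L]] <- dy[idx]
    }
    Xp <- do.call(rbind, Xl); yp <- unlist(yl)
    fitp <- stats::lm.fit(Xp, yp)
    rssp <- sum(fitp$residuals^2)
    dofp <- length(yp) - ncol(Xp)
    sep <- sqrt(rssp / dofp * chol2inv(chol(crossprod(Xp)))[1, 1])
    tpool <- unname(fitp$coefficients[1] / sep)

    tibble::tibble(
      variable = v,
      test = c("adf_fisher", "pooled_t"),
      statistic = c(fisher, tpool),
      df = c(2 * Nu, NA_real_),
      p.value = c(stats::pchisq(fisher, 2 * Nu, lower.tail = FALSE),
                  NA_real_),
      lags = lags, deterministic = det
    )
  }) |> purrr::list_rbind()
}
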