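#' Fit a log-linear Cobb-Douglas panel production model
#'
#' Estimates `ln Y = b0 + b1 ln X1 + ... + bk ln Xk + u` on a panel of
#' units observed over periods, in one of four forms:
#'
#' * `"pooled"` -- common intercept and slopes (OLS on the stacked data);
#' * `"fixed_intercept"` -- unit-specific intercepts, common slopes
#'   (least-squares dummy variables; identical to the within estimator);
#' * `"fixed_coefficient"` -- unit-specific intercepts *and* slopes
#'   (equivalent to independent per-unit regressions under a common error
#'   variance);
#' * `"random"` -- one-way error-components feasible GLS with
#'   Swamy-Arora variance components (quasi-demeaning), the comparator
#'   the Hausman test requires.
#'
#' All variables are log-transformed internally; nonpositive values are
#' rejected with the offending record named, never offset.
#'
#' @param data panel data frame.
#' @param output name of the output column.
#' @param inputs character vector of input column names.
#' @param unit,period names of the unit and period columns.
#' @param effect model form, see above.
#' @return An object of class `cd_panel_fit` with components
#'   `coefficients` (tidy tibble), `beta` and `vcov` (common slopes and
#'   their covariance, where defined), `r.squared`, `rss`, `fstatistic`,
#'   `residuals`, `nobs` and bookkeeping fields.  Supports [tidy()],
#'   [glance()] and `autoplot()`.
#' @export
#' @examples
#' panel <- generate_panel(synthetic_config(n_units = 8, n_periods = 6))
#' fit <- fit_panel(panel, "diagnoses",
#'                  c("health_workers", "beds", "financial"),
#'                  effect = "fixed_intercept")
#' glance(fit)
fit_panel <- function(data, output, inputs, unit = "unit",
                      period = "year",
                      effect = c("pooled", "fixed_intercept",
                                 "fixed_coefficient", "random")) {
  effect <- match.arg(effect)
  stopifnot(all(c(output, inputs, unit, period) %in% names(data)))
  vars <- c(output, inputs)
  for (v in vars) {
    bad <- which(data[[v]] <= 0)
    if (length(bad) > 0) {
      stop("nonpositive value of '", v, "' at (",
           data[[unit]][bad[1]], ", ", data[[period]][bad[1]],
           "); logs are undefined", call. = FALSE)
    }
  }
  df <- tibble::tibble(
    .unit = factor(data[[unit]]),
    .period = data[[period]],
    ly = log(data[[output]])
  )
  for (v in inputs) df[[paste0("l_", v)]] <- log(data[[v]])
  lx <- paste0("l_", inputs)
  k <- length(inputs)
  n <- nrow(df)
  N <- nlevels(df$.unit)
  if (n <= k + 1) stop("more parameters than observations", call. = FALSE)
  if (effect %in% c("fixed_intercept", "random") && N < 2) {
    stop("panel effects need at least 2 units", call. = FALSE)
  }
  if (effect == "fixed_intercept") {
    single <- names(which(table(df$.unit) == 1L))
    if (length(single) > 0) {
      warning("unit(s) with a single observation contribute no within ",
              "variation: ", paste(single, collapse = ", "),
              call. = FALSE)
    }
  }

  tss <- sum((df$ly - mean(df$ly))^2)
  fit <- switch(
    effect,
    pooled = {
      f <- stats::as.formula(paste("ly ~", paste(lx, collapse = " + ")))
      stats::lm(f, data = df)
    },
    fixed_intercept = {
      f <- stats::as.formula(paste("ly ~ 0 + .unit +",
                                   paste(lx, collapse = " + ")))
      stats::lm(f, data = df)
    },
    fixed_coefficient = {
      Tmin <- min(table(df$.unit))
      if (Tmin <= k + 1) {
        short <- names(which(table(df$.unit) <= k + 1))
        stop("too few observations for per-unit coefficients in unit(s): ",
             paste(short, collapse = ", "), call. = FALSE)
      }
      f <- stats::as.formula(paste(
        "ly ~ 0 + .unit +",
        paste(sprintf(".unit:%s", lx), collapse = " + ")))
      stats::lm(f, data = df)
    },
    random = fit_re_gls(df, lx)
  )

  if (effect == "random") {
    res <- fit
  } else {
    sm <- suppressWarnings(summary(fit))   # noise-free data fit exactly
    co <- as.data.frame(sm$coefficients)
    terms <- rownames(co)
    coefs <- tibble::tibble(
      term = terms,
      estimate = co[, 1], std.error = co[, 2],
      statistic = co[, 3], p.value = co[, 4]
    )
    rss <- sum(stats::residuals(fit)^2)
    p <- length(stats::coef(fit))
    df2 <- n - p
    fstat <- if (tss > 0 && rss > 0 && p > 1) {
      c(value = ((tss - rss) / (p - 1)) / (rss / df2),
        df1 = p - 1, df2 = df2)
    } else c(value = NA_real_, df1 = p - 1, df2 = df2)
    beta <- vc <- NULL
    if (effect %in% c("pooled", "fixed_intercept")) {
      beta <- stats::setNames(stats::coef(fit)[lx], inputs)
      vc <- (sm$sigma^2 * sm$cov.unscaled)[lx, lx, drop = FALSE]
      dimnames(vc) <- list(inputs, inputs)
    }
    res <- list(coefficients = coefs, beta = beta, vcov = vc,
                rss = rss, df.residual = df2,
                fitted = stats::fitted(fit),
                resid = stats::residuals(fit), fstatistic = fstat)
  }

  r2 <- if (tss > 0) 1 - res$rss / tss else NA_real_
  # readable coefficient labels: per-unit intercepts become
  # "intercept_<unit>", per-unit slopes "<unit>:ln_<input>"
  tm <- res$coefficients$term
  slope <- grepl(":", tm)
  tm[!slope] <- sub("^\\.unit", "intercept_", tm[!slope])
  tm[slope] <- sub("^\\.unit", "", tm[slope])
  tm <- sub("^l_", "ln_", tm)
  tm <- sub(":l_", ":ln_", tm)
  res$coefficients$term <- tm

  structure(list(
    effect = effect,
    coefficients = tibble::as_tibble(res$coefficients),
    beta = res$beta, vcov = res$vcov,
    r.squared = r2, rss = res$rss, df.residual = res$df.residual,
    fstatistic = res$fstatistic,
    residuals = tibble::tibble(unit = as.character(df$.unit),
                               period = df$.period,
                               .fitted = res$fitted, .resid = res$resid),
    nobs = n, n_units = N, n_periods = length(unique(df$.period)),
    output = output, inputs = inputs,
    unit = unit, period = period
  ), class = "cd_panel_fit")
}

# Swamy-Arora one-way error-components FGLS on the log-scale frame
fit_re_gls <- function(df, lx) {
  k <- length(lx)
  n <- nrow(df)
  N <- nlevels(df$.unit)
  Ti <- as.numeric(table(df$.unit)[as.character(df$.unit)])
  Tbar <- n / N

  # within residual variance
  Xw <- as.matrix(df[lx])
  yw <- df$ly
  for (j in seq_len(k)) {
    Xw[, j] <- Xw[, j] - stats::ave(Xw[, j], df$.unit)
  }
  yw <- yw - stats::ave(yw, df$.unit)
  fw <- stats::lm.fit(Xw, yw)
  df_w <- n - N - k
  s2e <- if (df_w > 0) sum(fw$residuals^2) / df_w else 0

  # between variance
  um <- stats::aggregate(df[c("ly", lx)], list(unit = df$.unit), mean)
  Xb <- cbind(1, as.matrix(um[lx]))
  fb <- stats::lm.fit(Xb, um$ly)
  df_b <- N - k - 1
  s2b <- if (df_b > 0) sum(fb$residuals^2) / df_b else 0
  s2u <- s2b - s2e / Tbar
  if (s2u < 0) {
    warning("negative unit-effect variance estimate truncated at 0",
            call. = FALSE)
    s2u <- 0
  }

  th <- if (s2e == 0 && s2u == 0) {
    rep(0, n)                    # degenerate noise-free case: plain OLS
  } else if (s2e == 0) {
    rep(1 - 1e-8, n)             # all variation is the unit effect
  } else {
    1 - sqrt(s2e / (s2e + Ti * s2u))
  }

  X <- cbind(`(Intercept)` = 1, as.matrix(df[lx]))
  y <- df$ly
  Xt <- X; yt <- y
  for (j in seq_len(ncol(X))) {
    Xt[, j] <- X[, j] - th * stats::ave(X[, j], df$.unit)
  }
  yt <- y - th * stats::ave(y, df$.unit)
  fg <- stats::lm.fit(Xt, yt)
  p <- ncol(X)
  rss_t <- sum(fg$residuals^2)
  s2 <- rss_t / (n - p)
  XtXi <- chol2inv(chol(crossprod(Xt)))
  vc_full <- s2 * XtXi
  dimnames(vc_full) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(vc_full))
  est <- fg$coefficients
  coefs <- tibble::tibble(
    term = colnames(X), estimate = unname(est), std.error = unname(se),
    statistic = unname(est / se),
    p.value = 2 * stats::pnorm(-abs(unname(est / se)))
  )
  fitted <- drop(X %*% est)
  inputs <- sub("^l_", "", lx)
  list(coefficients = coefs,
       beta = stats::setNames(est[lx], inputs),
       vcov = `dimnames<-`(vc_full[lx, lx, drop = FALSE],
                           list(inputs, inputs)),
       rss = sum((y - fitted)^2), df.residual = n - p,
       fitted = fitted, resid = y - fitted,
       fstatistic = c(value = NA_real_, df1 = p - 1, df2 = n - p),
       variance_components = c(idiosyncratic = s2e, unit = s2u))
}

#' Hausman specification test
#'
#' Contrasts the fixed-effects (within) and random-effects slope
#' estimates: `H = d' [V_FE - V_RE]^{-1} d` with `d = b_FE - b_RE`,
#' chi-square with as many degrees of freedom as slopes under the null
#' that the unit effects are uncorrelated with the regressors.  When the
#' covariance difference is not positive definite the Moore-Penrose
#' pseudo-inverse is used and the result flagged.
#'
#' @param fe a `cd_panel_fit` with `effect = "fixed_intercept"`.
#' @param re a `cd_panel_fit` with `effect = "random"`.
#' @return A one-row tibble: `statistic`, `df`, `p.value`,
#'   `pseudo_inverse`.
#' @export
hausman_test <- function(fe, re) {
  stopifnot(inherits(fe, "cd_panel_fit"), inherits(re, "cd_panel_fit"))
  if (!identical(names(fe$beta), names(re$beta))) {
    stop("fits have different slope parameterizations", call. = FALSE)
  }
  d <- fe$beta - re$beta
  V <- fe$vcov - re$vcov
  ev <- eigen(V, symmetric = TRUE)
  pseudo <- any(ev$values < sqrt(.Machine$double.eps) * max(abs(ev$values), 1))
  pos <- ev$values > sqrt(.Machine$double.eps) * max(abs(ev$values), 1)
  Vinv <- if (any(pos)) {
    ev$vectors[, pos, drop = FALSE] %*%
      diag(1 / ev$values[pos], sum(pos)) %*%
      t(ev$vectors[, pos, drop = FALSE])
  } else {
    matrix(0, length(d), length(d))
  }
  H <- max(0, drop(t(d) %*% Vinv %*% d))
  df <- length(d)
  tibble::tibble(statistic = H, df = df,
                 p.value = stats::pchisq(H, df, lower.tail = FALSE),
                 pseudo_inverse = pseudo)
}

#' Poolability (covariance-analysis) F tests
#'
#' Tests the homogeneity restrictions linking the three fixed-effects
#' forms.  `F2` contrasts the fully pooled model with the
#' fixed-coefficient model (all intercepts and slopes common); `F1`
#' contrasts the fixed-intercept model with the fixed-coefficient model
#' (slopes common given unit intercepts).  Each statistic is
#' `[(RSS_restricted - RSS_unrestricted)/df_num] /
#' [RSS_unrestricted/df_den]` with degrees of freedom taken from the
#' actual fits.
#'
#' @param pooled,fixed_intercept,fixed_coefficient `cd_panel_fit`
#'   objects on identical data.
#' @return A tibble with rows `F1` and `F2`: `statistic`, `df1`, `df2`,
#'   `p.value`.
#' @export
poolability_f_tests <- function(pooled, fixed_intercept,
                                fixed_coefficient) {
  fits <- list(pooled, fixed_intercept, fixed_coefficient)
  stopifnot(all(vapply(fits, inherits, TRUE, "cd_panel_fit")))
  if (length(unique(vapply(fits, function(f) f$nobs, 0))) != 1) {
    stop("fits are not on identical data", call. = FALSE)
  }
  rss_u <- fixed_coefficient$rss
  df_u <- fixed_coefficient$df.residual
  if (rss_u <= 1e-16 * fixed_coefficient$nobs) {   # numerically zero
    stop("unrestricted RSS is zero (noise-free data); ",
         "F statistics undefined", call. = FALSE)
  }
  one <- function(restricted, label) {
    df1 <- restricted$df.residual - df_u
    f <- ((restricted$rss - rss_u) / df1) / (rss_u / df_u)
    tibble::tibble(test = label, statistic = f, df1 = df1, df2 = df_u,
                   p.value = stats::pf(f, df1, df_u, lower.tail = FALSE))
  }
  dplyr::bind_rows(one(fixed_intercept, "F1"), one(pooled, "F2"))
}
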