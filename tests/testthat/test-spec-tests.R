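cd_inputs <- c("health_workers", "beds", "financial")

test_that("Hausman statistic matches direct matrix arithmetic", {
  # a draw whose covariance difference is positive definite, so the
  # plain-inverse formula is the oracle
  p <- generate_panel(synthetic_config(n_units = 10, n_periods = 8,
                                       noise_sd = 0.2, seed = 51))
  fe <- fit_panel(p, "diagnoses", cd_inputs, effect = "fixed_intercept")
  re <- fit_panel(p, "diagnoses", cd_inputs, effect = "random")
  V <- fe$vcov - re$vcov
  expect_true(all(eigen(V)$values > 0))
  h <- hausman_test(fe, re)
  d <- fe$beta - re$beta
  H_direct <- drop(t(d) %*% solve(V) %*% d)
  expect_equal(h$statistic, H_direct, tolerance = 1e-6)
  expect_equal(h$df, 3)
  expect_equal(h$p.value, pchisq(H_direct, 3, lower.tail = FALSE),
               tolerance = 1e-6)
  expect_false(h$pseudo_inverse)
})

test_that("a non-positive-definite covariance difference is flagged and
          still yields a nonnegative statistic", {
  p <- generate_panel(synthetic_config(n_units = 10, n_periods = 8,
                                       noise_sd = 0.2, seed = 31))
  fe <- fit_panel(p, "diagnoses", cd_inputs, effect = "fixed_intercept")
  re <- fit_panel(p, "diagnoses", cd_inputs, effect = "random")
  expect_true(any(eigen(fe$vcov - re$vcov)$values < 0))
  h <- hausman_test(fe, re)
  expect_true(h$pseudo_inverse)
  expect_gte(h$statistic, 0)
})

test_that("identical estimates give H = 0 with p = 1", {
  p <- generate_panel(synthetic_config(n_units = 8, n_periods = 6,
                                       noise_sd = 0.2, seed = 32))
  fe <- fit_panel(p, "diagnoses", cd_inputs, effect = "fixed_intercept")
  re <- fe
  re$effect <- "random"
  h <- hausman_test(fe, re)
  expect_equal(h$statistic, 0)
  expect_equal(h$p.value, 1)
})

test_that("poolability F statistics follow the RSS formula and detect
          heterogeneity", {
  p <- generate_panel(synthetic_config(n_units = 8, n_periods = 8,
                                       noise_sd = 0.2, seed = 33))
  fits <- lapply(c("pooled", "fixed_intercept", "fixed_coefficient"),
                 function(e) fit_panel(p, "diagnoses", cd_inputs,
                                       effect = e))
  ft <- poolability_f_tests(fits[[1]], fits[[2]], fits[[3]])
  f1_direct <- ((fits[[2]]$rss - fits[[3]]$rss) /
                  (fits[[2]]$df.residual - fits[[3]]$df.residual)) /
    (fits[[3]]$rss / fits[[3]]$df.residual)
  expect_equal(ft$statistic[ft$test == "F1"], f1_direct,
               tolerance = 1e-10)
  expect_true(all(ft$statistic >= 0))
  expect_equal(ft$df1[ft$test == "F2"],
               fits[[1]]$df.residual - fits[[3]]$df.residual)

  # equal RSS with genuinely nested parameter counts means F = 0
  mock <- function(rss, dfres) {
    structure(list(rss = rss, df.residual = dfres, nobs = 104),
              class = "cd_panel_fit")
  }
  ft0 <- poolability_f_tests(mock(5, 100), mock(5, 88), mock(5, 52))
  expect_equal(ft0$statistic, c(0, 0))
  expect_equal(ft0$p.value, c(1, 1))

  # strong unit heterogeneity drives F1 up
  ph <- generate_panel(synthetic_config(n_units = 8, n_periods = 8,
                                        noise_sd = 0.05,
                                        fixed_effect_sd = 1,
                                        seed = 34))
  fh <- lapply(c("pooled", "fixed_intercept", "fixed_coefficient"),
               function(e) fit_panel(ph, "diagnoses", cd_inputs,
                                     effect = e))
  fth <- poolability_f_tests(fh[[1]], fh[[2]], fh[[3]])
  expect_lt(fth$p.value[fth$test == "F2"], 0.01)
})

test_that("noise-free data make the F statistics undefined", {
  p <- generate_panel(synthetic_config(n_units = 6, n_periods = 6,
                                       noise_sd = 0,
                                       inefficiency_scale = 0,
                                       fixed_effect_sd = 0, seed = 35))
  fits <- lapply(c("pooled", "fixed_intercept", "fixed_coefficient"),
                 function(e) fit_panel(p, "diagnoses", cd_inputs,
                                       effect = e))
  expect_error(poolability_f_tests(fits[[1]], fits[[2]], fits[[3]]),
               "noise-free|zero")
})

test_that("ADF regression and finite-sample p-values behave sensibly", {
  # frozen check against the simulated quantile table: at the tabulated
  # 5% quantile the p-value is 5% by construction
  tab <- read.csv(system.file("extdata", "adf_tau_quantiles.csv",
                              package = "deapanel"))
  q5 <- tab$tau[tab$case == "c" & tab$T == 60 & tab$prob == 0.05]
  expect_equal(adf_pvalue(q5, 60, "intercept"), 0.05, tolerance = 1e-10)
  # monotone in tau
  taus <- seq(-5, 1, by = 0.5)
  ps <- vapply(taus, adf_pvalue, 0, n = 60, deterministic = "intercept")
  expect_true(all(diff(ps) >= 0))
  # stationary series reject, random-walk-like statistics do not
  set.seed(41)
  y_stat <- as.numeric(arima.sim(list(ar = 0.2), 80))
  expect_lt(adf_test(y_stat)$p.value, 0.05)
  expect_error(adf_test(rep(1, 50)), "constant")
  expect_error(adf_test(rnorm(5)), "too short")
})

test_that("Fisher combination follows -2 sum log p with 2N df", {
  # all per-unit p-values equal to 1 give a Fisher statistic of 0:
  # construct via the formula directly
  expect_equal(-2 * sum(log(rep(1, 13))), 0)
  p <- generate_panel(synthetic_config(n_units = 6, n_periods = 8,
                                       seed = 42))
  ur <- unit_root_tests(p, c("diagnoses", "financial"))
  expect_setequal(unique(ur$test), c("adf_fisher", "pooled_t"))
  fr <- ur[ur$test == "adf_fisher", ]
  expect_equal(fr$df, rep(12, 2))
  expect_true(all(fr$statistic >= 0))
  expect_equal(fr$p.value,
               pchisq(fr$statistic, 12, lower.tail = FALSE),
               tolerance = 1e-12)
  # pooled t reported without a p-value (uncorrected statistic)
  expect_true(all(is.na(ur$p.value[ur$test == "pooled_t"])))
})

test_that("panel unit-root tests have power against stationary panels", {
  set.seed(43)
  N <- 13; T <- 60
  d <- purrr::map(1:N, function(i) {
    tibble::tibble(unit = sprintf("u%02d", i), year = 1:T,
                   v = exp(as.numeric(arima.sim(list(ar = 0.2), T))))
  }) |> purrr::list_rbind()
  ur <- unit_root_tests(d, "v")
  expect_lt(ur$p.value[ur$test == "adf_fisher"], 0.01)
  expect_lt(ur$statistic[ur$test == "pooled_t"], -5)
})
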