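noise_free_cfg <- function(seed = 5, n_units = 8, n_periods = 6) {
  synthetic_config(n_units = n_units, n_periods = n_periods,
                   elasticities = c(health_workers = 0.3, beds = 0.2,
                                    financial = 0.5),
                   noise_sd = 0, inefficiency_scale = 0,
                   fixed_effect_sd = 0, seed = seed)
}
cd_inputs <- c("health_workers", "beds", "financial")

test_that("pooled OLS recovers the production law exactly without noise", {
  cfg <- noise_free_cfg()
  p <- generate_panel(cfg)
  fit <- fit_panel(p, "diagnoses", cd_inputs, effect = "pooled")
  expect_equal(unname(fit$beta), c(0.3, 0.2, 0.5), tolerance = 1e-9)
  expect_equal(
    fit$coefficients$estimate[fit$coefficients$term == "(Intercept)"],
    cfg$intercept[["diagnoses"]], tolerance = 1e-9)
  expect_equal(fit$r.squared, 1, tolerance = 1e-12)
})

test_that("fixed-intercept fit is exact under unit effects and matches
          the within estimator", {
  cfg <- synthetic_config(n_units = 8, n_periods = 6, noise_sd = 0,
                          inefficiency_scale = 0, fixed_effect_sd = 0.5,
                          seed = 6)
  p <- generate_panel(cfg)
  fit <- fit_panel(p, "diagnoses", cd_inputs, effect = "fixed_intercept")
  expect_equal(unname(fit$beta), c(0.3, 0.2, 0.5), tolerance = 1e-8)

  # independent within (demeaning) implementation
  ly <- log(p$diagnoses)
  X <- log(as.matrix(p[cd_inputs]))
  for (j in 1:3) X[, j] <- X[, j] - ave(X[, j], p$unit)
  lyw <- ly - ave(ly, p$unit)
  bw <- qr.coef(qr(X), lyw)
  expect_equal(unname(fit$beta), unname(bw), tolerance = 1e-10)

  # residuals sum to zero within each unit
  rs <- tapply(fit$residuals$.resid, fit$residuals$unit, sum)
  expect_equal(max(abs(rs)), 0, tolerance = 1e-8)
})

test_that("within and dummy-variable estimators agree on noisy panels", {
  p <- generate_panel(synthetic_config(n_units = 10, n_periods = 7,
                                       noise_sd = 0.3, seed = 8))
  fit <- fit_panel(p, "diagnoses", cd_inputs, effect = "fixed_intercept")
  ly <- log(p$diagnoses)
  X <- log(as.matrix(p[cd_inputs]))
  for (j in 1:3) X[, j] <- X[, j] - ave(X[, j], p$unit)
  lyw <- ly - ave(ly, p$unit)
  bw <- qr.coef(qr(X), lyw)
  expect_equal(unname(fit$beta), unname(bw), tolerance = 1e-10)
})

test_that("shifting one unit's output moves only that unit's intercept", {
  p <- generate_panel(synthetic_config(n_units = 5, n_periods = 6,
                                       seed = 9))
  f1 <- fit_panel(p, "diagnoses", cd_inputs, effect = "fixed_intercept")
  p2 <- p
  shift <- 0.7
  p2$diagnoses[p2$unit == "U03"] <- p2$diagnoses[p2$unit == "U03"] *
    exp(shift)
  f2 <- fit_panel(p2, "diagnoses", cd_inputs, effect = "fixed_intercept")
  expect_equal(unname(f2$beta), unname(f1$beta), tolerance = 1e-10)
  a1 <- f1$coefficients$estimate[f1$coefficients$term == "intercept_U03"]
  a2 <- f2$coefficients$estimate[f2$coefficients$term == "intercept_U03"]
  expect_equal(a2 - a1, shift, tolerance = 1e-10)
  others <- paste0("intercept_U0", c(1, 2, 4, 5))
  expect_equal(
    f2$coefficients$estimate[f2$coefficients$term %in% others],
    f1$coefficients$estimate[f1$coefficients$term %in% others],
    tolerance = 1e-10)
})

test_that("fixed-coefficient fit equals independent per-unit regressions", {
  p <- generate_panel(synthetic_config(n_units = 6, n_periods = 8,
                                       noise_sd = 0.2, seed = 10))
  fit <- fit_panel(p, "diagnoses", cd_inputs,
                   effect = "fixed_coefficient")
  co <- fit$coefficients
  for (u in unique(p$unit)) {
    sub <- p[p$unit == u, ]
    b <- coef(lm(log(diagnoses) ~ log(health_workers) + log(beds) +
                   log(financial), data = sub))
    est <- function(pat) co$estimate[co$term == pat]
    expect_equal(est(paste0(u, ":ln_health_workers")), unname(b[2]),
                 tolerance = 1e-8)
    expect_equal(est(paste0(u, ":ln_beds")), unname(b[3]),
                 tolerance = 1e-8)
    expect_equal(est(paste0(u, ":ln_financial")), unname(b[4]),
                 tolerance = 1e-8)
    expect_equal(est(paste0("intercept_", u)), unname(b[1]),
                 tolerance = 1e-8)
  }
})

test_that("two units with different laws are each recovered exactly", {
  # hand-built noise-free two-unit panel with distinct coefficients
  set.seed(11)
  T <- 8
  mk <- function(u, b0, b) {
    W <- runif(T, 50, 400); B <- runif(T, 40, 300); F <- runif(T, 200, 900)
    tibble::tibble(unit = u, year = seq_len(T),
                   health_workers = W, beds = B, financial = F,
                   diagnoses = exp(b0 + b[1] * log(W) + b[2] * log(B) +
                                     b[3] * log(F)))
  }
  p <- dplyr::bind_rows(mk("a", 1.5, c(0.4, 0.1, 0.6)),
                        mk("b", 3.0, c(0.2, 0.3, 0.3)))
  fit <- fit_panel(p, "diagnoses", cd_inputs,
                   effect = "fixed_coefficient")
  co <- fit$coefficients
  expect_equal(co$estimate[grepl("a:ln_health_workers", co$term)], 0.4,
               tolerance = 1e-8)
  expect_equal(co$estimate[grepl("b:ln_beds", co$term)], 0.3,
               tolerance = 1e-8)
  expect_equal(co$estimate[co$term == "intercept_b"], 3.0,
               tolerance = 1e-8)
  expect_equal(fit$r.squared, 1, tolerance = 1e-10)
})

test_that("model nesting orders the R-squared values", {
  for (seed in c(12, 13, 14)) {
    p <- generate_panel(synthetic_config(n_units = 7, n_periods = 8,
                                         noise_sd = 0.25, seed = seed))
    r2 <- vapply(c("pooled", "fixed_intercept", "fixed_coefficient"),
                 function(e) fit_panel(p, "diagnoses", cd_inputs,
                                       effect = e)$r.squared, 0)
    expect_true(r2[1] <= r2[2] + 1e-12 && r2[2] <= r2[3] + 1e-12)
  }
})

test_that("random effects reduces to pooled when effects are absent and
          is exact without noise", {
  # noise-free: exact recovery
  p0 <- generate_panel(noise_free_cfg(seed = 15))
  suppressWarnings(
    f0 <- fit_panel(p0, "diagnoses", cd_inputs, effect = "random"))
  expect_equal(unname(f0$beta), c(0.3, 0.2, 0.5), tolerance = 1e-7)

  # no unit effects, ample data: RE close to pooled
  p <- generate_panel(synthetic_config(n_units = 40, n_periods = 8,
                                       fixed_effect_sd = 0,
                                       inefficiency_scale = 0,
                                       noise_sd = 0.2, seed = 16))
  fre <- suppressWarnings(
    fit_panel(p, "diagnoses", cd_inputs, effect = "random"))
  fp <- fit_panel(p, "diagnoses", cd_inputs, effect = "pooled")
  expect_equal(unname(fre$beta), unname(fp$beta), tolerance = 0.02)
})

test_that("random effects shrinks between the pooled and within
          estimates for a scalar regressor", {
  set.seed(17)
  N <- 12; T <- 8
  u <- rep(rnorm(N, 0, 0.6), each = T)
  x <- rep(rnorm(N, 0, 0.5), each = T) + rnorm(N * T)
  y <- 2 + 0.5 * x + u + rnorm(N * T, 0, 0.4)
  d <- tibble::tibble(unit = rep(sprintf("u%02d", 1:N), each = T),
                      year = rep(1:T, N), x = exp(x), y = exp(y))
  bp <- fit_panel(d, "y", "x", effect = "pooled")$beta
  bw <- fit_panel(d, "y", "x", effect = "fixed_intercept")$beta
  br <- fit_panel(d, "y", "x", effect = "random")$beta
  lo <- min(bp, bw); hi <- max(bp, bw)
  expect_gte(br, lo - 1e-8)
  expect_lte(br, hi + 1e-8)
})

test_that("log-domain errors name the offending record", {
  p <- generate_panel(synthetic_config(n_units = 4, n_periods = 3,
                                       seed = 18))
  p$beds[5] <- 0
  expect_error(fit_panel(p, "diagnoses", cd_inputs),
               "beds.*U02|U02.*beds")
})

test_that("insufficient per-unit data for per-unit coefficients errors", {
  p <- generate_panel(synthetic_config(n_units = 5, n_periods = 3,
                                       seed = 19))
  expect_error(fit_panel(p, "diagnoses", cd_inputs,
                         effect = "fixed_coefficient"), "too few")
})

test_that("tidy and glance return well-formed frames", {
  p <- generate_panel(synthetic_config(n_units = 6, n_periods = 6,
                                       seed = 20))
  fit <- fit_panel(p, "diagnoses", cd_inputs, effect = "fixed_intercept")
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std.error", "statistic",
                    "p.value") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$effect, "fixed_intercept")
  expect_true(gl$r.squared > 0 && gl$r.squared <= 1)
  expect_s3_class(autoplot(fit), "ggplot")
})
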