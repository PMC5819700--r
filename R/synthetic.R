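#' Default zone resource profiles
#'
#' Per-zone means and standard deviations of community-health-center
#' input stocks, patterned on the published 2015 staffing and bed
#' statistics of the three economic zones of Jiangsu Province (southern,
#' middle, northern).  Financial input is not part of the published
#' table; the values used here are the package's own choice of a
#' realistic public-financing profile (ten-thousand yuan, real terms)
#' and are documented in the methods vignette.
#'
#' @return A tibble with columns `zone`, `variable`, `mean`, `sd`.
#' @export
#' @examples
#' default_zone_profiles()
default_zone_profiles <- function() {
  tibble::tribble(
    ~zone,      ~variable,     ~mean,  ~sd,
    "south",    "doctors",     156.78, 163.49,
    "south",    "nurses",      184.52, 216.58,
    "south",    "pharmacists",  30.12,  33.52,
    "south",    "other_staff",  63.66,  74.82,
    "south",    "beds",        323.17, 352.76,
    "south",    "financial",   900.00, 700.00,
    "middle",   "doctors",     100.44,  84.33,
    "middle",   "nurses",       90.88, 107.79,
    "middle",   "pharmacists",  24.30,  20.71,
    "middle",   "other_staff",  41.66,  41.29,
    "middle",   "beds",        206.59, 195.04,
    "middle",   "financial",   600.00, 420.00,
    "north",    "doctors",      71.13,  94.52,
    "north",    "nurses",      109.08, 219.54,
    "north",    "pharmacists",  16.30,  16.88,
    "north",    "other_staff",  38.52,  59.24,
    "north",    "beds",        220.95, 284.52,
    "north",    "financial",   450.00, 380.00
  )
}

#' Configuration of the synthetic community-health panel generator
#'
#' Bundles every knob of the synthetic data-generating process: a
#' Cobb-Douglas production law on the input stocks, unit fixed effects
#' (optionally correlated with a regressor so that Hausman-test power
#' scenarios can be constructed), two-sided log-normal measurement noise
#' and a one-sided half-normal inefficiency term applied
#' multiplicatively to the outputs.
#'
#' @param n_units number of decision-making units (cities/centers).
#' @param n_periods number of years.
#' @param start_year first calendar year label.
#' @param zone_profiles tibble with columns `zone`, `variable`, `mean`,
#'   `sd` giving the per-zone log-normal input profiles; see
#'   [default_zone_profiles()].
#' @param zone_allocation named integer vector, units per zone.  Defaults
#'   to an (almost) even split across the zones in profile order.
#' @param elasticities output elasticities of the production law, named
#'   `health_workers`, `beds`, `financial`.
#' @param intercept log-scale production intercepts, either a scalar or a
#'   named vector over the outputs `outpatients`, `inpatients`,
#'   `diagnoses`.
#' @param size_factor_share fraction (in \[0, 1)) of each input's
#'   log-scale variance carried by a persistent unit-level "size" factor
#'   shared across all input variables.  Real facilities differ mostly in
#'   overall scale -- a large center has more doctors, beds and funding
#'   at once -- and this factor reproduces that joint dispersion while
#'   leaving every per-variable mean and SD exactly at its configured
#'   value.  Set to 0 for fully independent draws.
#' @param fixed_effect_sd standard deviation of the unit fixed effect on
#'   the log scale.
#' @param fixed_effect_regressor_corr correlation (in \[-1, 1\]) between
#'   the unit effect and the unit-level mean log of
#'   `fixed_effect_regressor`.
#' @param fixed_effect_regressor input whose unit mean the fixed effect
#'   is tied to.
#' @param noise_sd standard deviation of the idiosyncratic log-scale
#'   disturbance.
#' @param inefficiency_scale scale of the half-normal inefficiency term;
#'   outputs are multiplied by `exp(-|N(0, scale)|)`.
#' @param price_index optional tibble (`year`, `deflator`) used to
#'   deflate the financial input; `NULL` leaves it untouched.
#' @param base_year base year of `price_index`.
#' @param floor positive lower truncation applied to every drawn input.
#' @param seed integer seed; identical configurations generate identical
#'   panels.
#' @return An object of class `synthetic_config`.
#' @export
#' @examples
#' cfg <- synthetic_config(n_units = 6, n_periods = 3, seed = 1)
#' generate_panel(cfg)
synthetic_config <- function(n_units = 13L,
                             n_periods = 8L,
                             start_year = 2008L,
                             zone_profiles = default_zone_profiles(),
                             zone_allocation = NULL,
                             elasticities = c(health_workers = 0.3,
                                              beds = 0.2,
                                              financial = 0.5),
                             intercept = c(outpatients = 6.5,
                                           inpatients = 2.7,
                                           diagnoses = 6.7),
                             size_factor_share = 0.6,
                             fixed_effect_sd = 0.3,
                             fixed_effect_regressor_corr = 0,
                             fixed_effect_regressor = "health_workers",
                             noise_sd = 0.1,
                             inefficiency_scale = 0.15,
                             price_index = NULL,
                             base_year = start_year,
                             floor = 1,
                             seed = 1L) {
  cfg <- structure(list(
    n_units = as.integer(n_units),
    n_periods = as.integer(n_periods),
    start_year = as.integer(start_year),
    zone_profiles = tibble::as_tibble(zone_profiles),
    zone_allocation = zone_allocation,
    elasticities = elasticities,
    intercept = intercept,
    size_factor_share = size_factor_share,
    fixed_effect_sd = fixed_effect_sd,
    fixed_effect_regressor_corr = fixed_effect_regressor_corr,
    fixed_effect_regressor = fixed_effect_regressor,
    noise_sd = noise_sd,
    inefficiency_scale = inefficiency_scale,
    price_index = price_index,
    base_year = as.integer(base_year),
    floor = floor,
    seed = as.integer(seed)
  ), class = "synthetic_config")
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (cfg$n_units < 2L) stop("`n_units` must be at least 2", call. = FALSE)
  if (cfg$n_periods < 1L) stop("`n_periods` must be at least 1", call. = FALSE)
  prof <- cfg$zone_profiles
  req <- c("zone", "variable", "mean", "sd")
  if (!all(req %in% names(prof))) {
    stop("`zone_profiles` needs columns zone, variable, mean, sd",
         call. = FALSE)
  }
  if (any(prof$mean <= 0)) stop("profile means must be positive", call. = FALSE)
  if (any(prof$sd < 0)) stop("profile SDs must be nonnegative", call. = FALSE)
  if (cfg$fixed_effect_sd < 0 || cfg$noise_sd < 0 ||
      cfg$inefficiency_scale < 0) {
    stop("dispersion parameters must be nonnegative", call. = FALSE)
  }
  if (cfg$size_factor_share < 0 || cfg$size_factor_share >= 1) {
    stop("`size_factor_share` must lie in [0, 1)", call. = FALSE)
  }
  if (abs(cfg$fixed_effect_regressor_corr) > 1) {
    stop("`fixed_effect_regressor_corr` must lie in [-1, 1]", call. = FALSE)
  }
  if (cfg$floor <= 0) stop("`floor` must be positive", call. = FALSE)
  if (!is.null(cfg$zone_allocation)) {
    zones <- unique(prof$zone)
    unknown <- setdiff(names(cfg$zone_allocation), zones)
    if (length(unknown) > 0L) {
      stop("unknown zone label in `zone_allocation`: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    if (sum(cfg$zone_allocation) != cfg$n_units) {
      stop("`zone_allocation` must sum to `n_units`", call. = FALSE)
    }
  }
  if (!is.null(cfg$price_index)) {
    pi <- cfg$price_index
    if (!all(c("year", "deflator") %in% names(pi))) {
      stop("`price_index` needs columns year and deflator", call. = FALSE)
    }
    if (any(pi$deflator <= 0)) stop("deflators must be positive", call. = FALSE)
    if (!cfg$base_year %in% pi$year) {
      stop("base year missing from `price_index`", call. = FALSE)
    }
  }
  if (!all(c("health_workers", "beds", "financial") %in%
           names(cfg$elasticities))) {
    stop("`elasticities` must be named health_workers, beds, financial",
         call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config>\n")
  cat("  units x periods: ", x$n_units, " x ", x$n_periods,
      " (", x$start_year, "-", x$start_year + x$n_periods - 1L, ")\n",
      sep = "")
  cat("  zones:", paste(unique(x$zone_profiles$zone), collapse = ", "), "\n")
  cat("  elasticities:",
      paste(names(x$elasticities), round(x$elasticities, 3),
            sep = "=", collapse = ", "), "\n")
  cat("  noise_sd =", x$noise_sd,
      " inefficiency_scale =", x$inefficiency_scale,
      " fixed_effect_sd =", x$fixed_effect_sd, "\n")
  cat("  seed =", x$seed, "\n")
  invisible(x)
}

# log-normal parameters matched to a target mean and SD
lnorm_params <- function(mean, sd) {
  sdlog2 <- log(1 + (sd / mean)^2)
  c(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Generate a synthetic community-health-center panel
#'
#' Draws input stocks from per-zone log-normal profiles (truncated below
#' at a small positive floor) and produces outputs through a
#' Cobb-Douglas law `ln Y = b0 + b1 ln(workers) + b2 ln(beds) +
#' b3 ln(financial) + unit effect + noise`, damped multiplicatively by a
#' half-normal inefficiency draw.  The derived `health_workers` column is
#' the sum of the four staff categories and is the labour aggregate that
#' the production law and the panel stage use.
#'
#' @param config a [synthetic_config()].
#' @return A tibble with one row per unit-year: `unit`, `zone`, `year`,
#'   the input columns (`doctors`, `nurses`, `pharmacists`,
#'   `other_staff`, `beds`, `financial`, derived `health_workers`) and
#'   the output columns (`outpatients`, `inpatients`, `diagnoses`).
#' @export
#' @examples
#' panel <- generate_panel(synthetic_config(n_units = 6, n_periods = 3))
#' dplyr::glimpse(panel)
generate_panel <- function(config) {
  validate_synthetic_config(config)
  cfg <- config
  zones <- unique(cfg$zone_profiles$zone)
  alloc <- cfg$zone_allocation
  if (is.null(alloc)) {
    base <- cfg$n_units %/% length(zones)
    extra <- cfg$n_units %% length(zones)
    alloc <- stats::setNames(
      base + ifelse(seq_along(zones) <= extra, 1L, 0L), zones)
  }
  unit_zone <- rep(names(alloc), times = alloc)
  units <- sprintf("U%02d", seq_len(cfg$n_units))
  years <- cfg$start_year + seq_len(cfg$n_periods) - 1L
  invars <- unique(cfg$zone_profiles$variable)
  outvars <- c("outpatients", "inpatients", "diagnoses")

  b0 <- cfg$intercept
  if (length(b0) == 1L && is.null(names(b0))) {
    b0 <- stats::setNames(rep(b0, length(outvars)), outvars)
  }
  stopifnot(all(outvars %in% names(b0)))

  grid <- tidyr::expand_grid(unit = units, year = years) |>
    dplyr::mutate(zone = unit_zone[match(.data$unit, units)])

  panel <- withr::with_seed(cfg$seed, {
    draws <- grid
    # persistent unit-size factor shared by all input variables
    lam <- cfg$size_factor_share
    size_u <- rnorm(cfg$n_units)
    size_rec <- size_u[match(draws$unit, units)]
    for (v in invars) {
      vals <- numeric(nrow(draws))
      for (z in zones) {
        prof <- cfg$zone_profiles[cfg$zone_profiles$zone == z &
                                    cfg$zone_profiles$variable == v, ]
        if (nrow(prof) != 1L) {
          stop("no unique profile for zone '", z, "', variable '", v, "'",
               call. = FALSE)
        }
        idx <- draws$zone == z
        if (prof$sd == 0) {
          vals[idx] <- prof$mean
        } else {
          pp <- lnorm_params(prof$mean, prof$sd)
          zdev <- sqrt(lam) * size_rec[idx] +
            sqrt(1 - lam) * rnorm(sum(idx))
          vals[idx] <- exp(pp[["meanlog"]] + pp[["sdlog"]] * zdev)
        }
      }
      draws[[v]] <- pmax(vals, cfg$floor)
      if (any(draws[[v]] <= 0)) {
        stop("non-positive draw for '", v, "' after flooring; ",
             "invalid configuration", call. = FALSE)
      }
    }
    draws$health_workers <- draws$doctors + draws$nurses +
      draws$pharmacists + draws$other_staff

    # unit fixed effects, optionally tied to a regressor's unit mean
    rho <- cfg$fixed_effect_regressor_corr
    lx_mean <- tapply(log(draws[[cfg$fixed_effect_regressor]]),
                      draws$unit, mean)[units]
    z_x <- if (stats::sd(lx_mean) > 0) {
      as.numeric(scale(lx_mean))
    } else {
      rep(0, cfg$n_units)
    }
    eff <- cfg$fixed_effect_sd *
      (rho * z_x + sqrt(1 - rho^2) * rnorm(cfg$n_units))
    draws$.effect <- eff[match(draws$unit, units)]

    lin <- cfg$elasticities[["health_workers"]] * log(draws$health_workers) +
      cfg$elasticities[["beds"]] * log(draws$beds) +
      cfg$elasticities[["financial"]] * log(draws$financial)
    ineff <- abs(rnorm(nrow(draws), 0, cfg$inefficiency_scale))
    for (o in outvars) {
      noise <- rnorm(nrow(draws), 0, cfg$noise_sd)
      draws[[o]] <- exp(b0[[o]] + lin + draws$.effect + noise - ineff)
    }
    draws$.effect <- NULL
    draws
  })

  if (!is.null(cfg$price_index)) {
    panel$financial <- deflate_series(panel$financial, panel$year,
                                      cfg$price_index, cfg$base_year)
  }
  panel |>
    dplyr::select(dplyr::all_of(c("unit", "zone", "year", invars,
                                  "health_workers", outvars))) |>
    tibble::as_tibble()
}

#' Deflate a currency series to base-year prices
#'
#' Converts nominal values to real values with
#' `real = nominal * deflator(base year) / deflator(year)`, so the
#' base-year values are unchanged.
#'
#' @param values numeric vector of nominal values.
#' @param years year of each value.
#' @param price_index tibble (`year`, `deflator`) or a numeric vector
#'   named by year.
#' @param base_year year whose price level is the reference.
#' @return Numeric vector of deflated values.
#' @export
#' @examples
#' idx <- tibble::tibble(year = 2008:2009, deflator = c(100, 110))
#' deflate_series(c(100, 110), c(2008, 2009), idx, base_year = 2008)
deflate_series <- function(values, years, price_index, base_year) {
  if (is.data.frame(price_index)) {
    defl <- stats::setNames(price_index$deflator, price_index$year)
  } else {
    defl <- price_index
  }
  if (any(defl <= 0)) stop("deflators must be positive", call. = FALSE)
  if (!as.character(base_year) %in% names(defl)) {
    stop("base year ", base_year, " missing from the price index",
         call. = FALSE)
  }
  d <- defl[as.character(years)]
  if (anyNA(d)) {
    stop("no deflator for year(s): ",
         paste(unique(years[is.na(d)]), collapse = ", "), call. = FALSE)
  }
  unname(values * defl[[as.character(base_year)]] / d)
}

#' Deflate currency columns of a panel
#'
#' Data-frame wrapper around [deflate_series()].
#'
#' @param data panel data frame.
#' @param cols character vector of currency columns to deflate.
#' @param price_index,base_year passed to [deflate_series()].
#' @param year name of the year column.
#' @return `data` with the named columns deflated, as a tibble.
#' @export
deflate_panel <- function(data, cols, price_index, base_year,
                          year = "year") {
  stopifnot(all(cols %in% names(data)), year %in% names(data))
  data |>
    dplyr::mutate(dplyr::across(
      dplyr::all_of(cols),
      ~ deflate_series(.x, data[[year]], price_index, base_year))) |>
    tibble::as_tibble()
}

#' Write and read a panel table
#'
#' The on-disk format is a plain comma-separated table with a header row,
#' preceded by `#`-prefixed comment lines recording the generating seed
#' when one is supplied.
#'
#' @param data panel data frame.
#' @param path file path.
#' @param seed optional integer recorded in the file header.
#' @return `write_panel()` returns `path` invisibly; `read_panel()`
#'   returns a tibble.
#' @export
write_panel <- function(data, path, seed = NULL) {
  if (!is.null(seed)) {
    readr::write_lines(paste0("# seed: ", seed), path)
    readr::write_csv(data, path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_csv(data, path)
  }
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE)
}
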