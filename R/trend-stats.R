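# Bay-scale descriptive statistics: species proportions, deviance-from-
# long-term-mean ratios, the two-sample Kolmogorov-Smirnov variability
# comparison, seasonal discharge aggregation and the flow-change
# regression.

#' Proportion of total SAV cover held by one species
#'
#' @param species_ha Annual areal cover of the species (hectares).
#' @param total_ha Annual total SAV cover, aligned with `species_ha`.
#' @return Numeric vector of fractions; NA where `total_ha` is 0.
#' @examples
#' species_proportion(20, 80)
#' @export
species_proportion <- function(species_ha, total_ha) {
  if (length(species_ha) != length(total_ha)) {
    stop("series must be aligned (equal length)", call. = FALSE)
  }
  if (any(species_ha < 0 | total_ha < 0, na.rm = TRUE)) {
    stop("areal cover must be non-negative", call. = FALSE)
  }
  if (any(species_ha > total_ha, na.rm = TRUE)) {
    stop("species cover exceeds total cover", call. = FALSE)
  }
  out <- species_ha / total_ha
  out[!is.na(total_ha) & total_ha == 0] <- NA_real_
  out
}

#' Deviance of annual cover around the long-term mean
#'
#' Divides each year's areal cover by the mean cover over a fixed
#' reference period, putting species with different absolute extents on
#' a common scale for variability comparison: values above 1 are
#' better-than-average years, below 1 worse. By construction the mean
#' ratio over the reference period is 1.
#'
#' @param data Data frame with columns `year` and `area_ha`; an
#'   optional `species` column is handled per species.
#' @param reference_years Integer vector of reference years (default:
#'   every year present).
#' @return The input tibble with an added `ratio` column.
#' @export
deviance_ratio <- function(data, reference_years = NULL) {
  stopifnot(is.data.frame(data))
  check_columns(data, c("year", "area_ha"), "data")
  one <- function(d) {
    ref <- reference_years %||% d$year
    if (!all(ref %in% d$year)) {
      stop("reference years must be a subset of the series years",
           call. = FALSE)
    }
    m <- mean(d$area_ha[d$year %in% ref])
    if (!is.finite(m) || m <= 0) {
      stop("long-term mean cover must be positive", call. = FALSE)
    }
    mutate(d, ratio = .data$area_ha / m)
  }
  if ("species" %in% names(data)) {
    data |> group_by(.data$species) |> group_modify(~ one(.x)) |> ungroup()
  } else {
    as_tibble(one(data))
  }
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum distance between the two empirical CDFs. The
#' p-value uses the exact (permutation) distribution when
#' `n * m <= 10000` and the samples are tie-free, otherwise the
#' asymptotic Kolmogorov distribution with effective size
#' `n * m / (n + m)`.
#'
#' @param a,b Numeric samples, each of size >= 2.
#' @return One-row tibble with `statistic` (D), `p_value`, `exact`.
#' @examples
#' ks_two_sample(rnorm(10), rnorm(12))
#' @export
ks_two_sample <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("both samples need at least 2 observations", call. = FALSE)
  }
  exact <- length(a) * length(b) <= 10000 && !anyDuplicated(c(a, b))
  kt <- suppressWarnings(stats::ks.test(a, b, exact = exact))
  tibble(statistic = unname(kt$statistic), p_value = kt$p.value,
         exact = exact)
}

#' Compare interannual variability of two deviance-ratio series
#'
#' Applies the two-sample Kolmogorov-Smirnov test to the two species'
#' deviance ratios over a common reference period and reports the ratio
#' of their sample standard deviations (how many times more variable
#' the first series is).
#'
#' @param ratio_a,ratio_b Deviance-ratio samples (see
#'   [deviance_ratio()]).
#' @return One-row tibble with `statistic`, `p_value`, `exact`,
#'   `sd_ratio` (= sd(a) / sd(b)).
#' @export
compare_variability <- function(ratio_a, ratio_b) {
  ks <- ks_two_sample(ratio_a, ratio_b)
  mutate(ks, sd_ratio = sd(ratio_a, na.rm = TRUE) / sd(ratio_b, na.rm = TRUE))
}

season_window <- function(period, year) {
  switch(period,
    annual = c(as.Date(sprintf("%d-01-01", year)),
               as.Date(sprintf("%d-12-31", year))),
    spring = c(as.Date(sprintf("%d-03-01", year)),
               as.Date(sprintf("%d-05-31", year))),
    winter = c(as.Date(sprintf("%d-12-01", year - 1L)),
               as.Date(sprintf("%d-03-01", year)) - 1L),
    stop("unknown period: ", period, call. = FALSE)
  )
}

#' Aggregate a daily discharge series by year and season
#'
#' Annual means cover the calendar year; spring covers March--May;
#' winter follows the climatological DJF convention, December of the
#' previous year through February (assigned to the January year).
#' Missing days are excluded from the mean, with a warning when fewer
#' than 90% of the window's days are present.
#'
#' @param discharge Data frame with columns `date` (Date) and
#'   `discharge`.
#' @param period One of `"annual"`, `"spring"`, `"winter"`.
#' @param years Integer vector of years to aggregate (default: all
#'   calendar years appearing in the series).
#' @return Tibble with `year`, `period`, `mean_discharge`, `n_days`,
#'   `coverage`.
#' @export
aggregate_discharge <- function(discharge, period = c("annual", "spring",
                                                      "winter"),
                                years = NULL) {
  period <- match.arg(period)
  stopifnot(is.data.frame(discharge))
  check_columns(discharge, c("date", "discharge"), "discharge")
  years <- years %||% sort(unique(as.integer(format(discharge$date, "%Y"))))
  out <- purrr::map_dfr(years, function(yr) {
    win <- season_window(period, yr)
    total_days <- as.integer(win[2] - win[1]) + 1L
    sel <- discharge$date >= win[1] & discharge$date <= win[2] &
      !is.na(discharge$discharge)
    n <- sum(sel)
    if (n == 0) {
      stop("no discharge observations in the ", period, " window of ", yr,
           call. = FALSE)
    }
    tibble(year = yr, period = period,
           mean_discharge = mean(discharge$discharge[sel]),
           n_days = n, coverage = n / total_days)
  })
  low <- out$year[out$coverage < 0.9]
  if (length(low) > 0) {
    warning("discharge coverage below 90% for ", period, " window(s) of: ",
            paste(low, collapse = ", "))
  }
  out
}

#' Regression of annual areal change on logged discharge
#'
#' Ordinary least-squares simple regression of bay-wide annual areal
#' change (hectares) on the natural log of mean discharge, the
#' flow--recolonization relationship: low-flow years line up with the
#' largest widgeongrass gains.
#'
#' @param data Data frame with one row per year holding the discharge
#'   and change columns.
#' @param discharge Name of the (positive) mean-discharge column.
#' @param change Name of the annual areal change column.
#' @param log Log the discharge before regressing? (default TRUE).
#' @return Object of class `sav_flowfit` with `slope`, `intercept`,
#'   `r2`, `f_stat`, `df` (= c(1, n - 2)), `p_value` and the underlying
#'   `lm` fit.
#' @export
fit_flow_regression <- function(data, discharge = "mean_discharge",
                                change = "areal_change", log = TRUE) {
  stopifnot(is.data.frame(data))
  check_columns(data, c(discharge, change), "data")
  d <- data[complete.cases(data[c(discharge, change)]), ]
  if (nrow(d) < 3) stop("need at least 3 aligned years", call. = FALSE)
  x <- d[[discharge]]
  if (log) {
    if (any(x <= 0)) {
      stop("discharge must be positive before logging", call. = FALSE)
    }
    x <- base::log(x)
  }
  y <- d[[change]]
  fit <- lm(y ~ x)
  sm <- summary(fit)
  n <- nrow(d)
  r2 <- sm$r.squared
  f_stat <- if (r2 < 1) r2 / (1 - r2) * (n - 2) else Inf
  structure(list(
    slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    r2 = r2, f_stat = f_stat, df = c(1L, n - 2L),
    p_value = pf(f_stat, 1, n - 2, lower.tail = FALSE),
    n = n, lm = fit, log = log,
    data = tibble(x = x, y = y)
  ), class = "sav_flowfit")
}

#' @export
print.sav_flowfit <- function(x, ...) {
  cat(sprintf(
    "Flow regression (%s discharge): slope %.4g, R2 = %.3f, F(%d,%d) = %.2f, P = %.3g\n",
    ifelse(x$log, "log", "raw"), x$slope, x$r2, x$df[1], x$df[2], x$f_stat,
    x$p_value))
  invisible(x)
}

#' @method tidy sav_flowfit
#' @export
tidy.sav_flowfit <- function(x, ...) {
  sm <- summary(x$lm)$coefficients
  tibble(term = c("(Intercept)", "log_discharge"),
         estimate = unname(sm[, 1]), std.error = unname(sm[, 2]),
         statistic = unname(sm[, 3]), p.value = unname(sm[, 4]))
}

#' @method glance sav_flowfit
#' @export
glance.sav_flowfit <- function(x, ...) {
  tibble(r2 = x$r2, f_stat = x$f_stat, df1 = x$df[1], df2 = x$df[2],
         p_value = x$p_value, nobs = x$n)
}
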