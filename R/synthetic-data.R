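# Seeded generators for synthetic subestuary and main-channel datasets
# with the causal and autocorrelation structure the analysis assumes:
# standardized Gaussian drivers wired along an allowed edge set, and
# zero-inflated boom-bust cover evolving as a clipped lag-1 process with
# site random intercepts and AR(1) noise.

subestuary_nodes <- function() {
  list(
    exogenous = c("frac_agriculture", "frac_developed", "flow"),
    loads = c("point_N", "nonpoint_N", "point_P", "nonpoint_P", "tss"),
    response = "change"
  )
}

# Allowed generative edges, per analysis mode: land use -> nonpoint
# loads, flow -> loads, loads + flow -> change (subestuary); total N ->
# chl-a, water column conditions -> change (main channel).
allowed_edges <- function(mode) {
  if (mode == "subestuary") {
    nd <- subestuary_nodes()
    nonpoint <- c("nonpoint_N", "nonpoint_P", "tss")
    rbind(
      expand.grid(from = c("frac_agriculture", "frac_developed"),
                  to = nonpoint, stringsAsFactors = FALSE),
      expand.grid(from = "flow", to = nd$loads, stringsAsFactors = FALSE),
      expand.grid(from = c(nd$loads, "flow"), to = "change",
                  stringsAsFactors = FALSE)
    )
  } else {
    rbind(
      data.frame(from = "total_N", to = "chla"),
      data.frame(from = c("chla", "secchi", "salinity", "temperature"),
                 to = "change")
    )
  }
}

default_paths <- function(mode) {
  if (mode == "subestuary") {
    c("frac_agriculture->nonpoint_N" = 0.5,
      "frac_agriculture->nonpoint_P" = 0.4,
      "frac_developed->nonpoint_N" = 0.3,
      "flow->nonpoint_N" = 0.4, "flow->nonpoint_P" = 0.4,
      "flow->tss" = 0.5,
      "nonpoint_N->change" = -0.4, "tss->change" = -0.25,
      "flow->change" = -0.3)
  } else {
    c("total_N->chla" = 0.5, "chla->change" = -0.4,
      "secchi->change" = 0.3, "salinity->change" = 0.5,
      "temperature->change" = -0.2)
  }
}

# Realistic output units: (mean, sd-like scale); positive quantities use
# a lognormal map exp(log(mean) + scale * z), others an affine map.
default_units <- function(mode) {
  if (mode == "subestuary") {
    list(flow = c(5e7, 0.4), point_N = c(2e4, 0.5), nonpoint_N = c(8e4, 0.4),
         point_P = c(2e3, 0.5), nonpoint_P = c(6e3, 0.4), tss = c(2e6, 0.5),
         frac_agriculture = c(0.3, 0.08), frac_developed = c(0.15, 0.05))
  } else {
    list(temperature = c(14, 1.5), salinity = c(12, 3), secchi = c(1.2, 0.3),
         total_N = c(0.8, 0.25), total_P = c(0.06, 0.3), chla = c(12, 0.4))
  }
}

#' Parameterize a synthetic-data scenario
#'
#' Collects every knob of the synthetic generators: the causal path
#' coefficients (on the standardized-driver scale), variance components
#' of the cover process, the zero floor and the survey layout. Defaults
#' emulate the study conditions: 35 subestuaries surveyed 1984--2015, or
#' 51 main-channel stations surveyed 1984--2019 with 1988 unflown.
#'
#' @param mode `"subestuary"` or `"mainchannel"`.
#' @param seed Integer RNG seed; a single generator seeded once drives
#'   every draw, so identical seeds give bit-identical datasets.
#' @param n_sites,n_years Survey dimensions.
#' @param start_year First survey year.
#' @param skip_years Unsurveyed calendar years (default 1988 in
#'   main-channel mode, none otherwise).
#' @param path_coefficients Named vector `"source->target" = value`;
#'   keys must belong to the mode's allowed edge set.
#' @param lag_interaction_coefficients Named vector, per driver, of the
#'   coefficient on driver x previous-year scaled cover.
#' @param random_intercept_sd,residual_sd,ar1_phi Site intercept SD,
#'   AR(1) marginal residual SD and lag-1 correlation of the cover
#'   innovations.
#' @param zero_threshold Scaled-cover floor below which cover is
#'   recorded as 0 (the zero-inflation mechanism).
#' @param initial_cover Scaled cover in the year before the survey
#'   starts.
#' @param site_area_ha Habitable area per site used to translate scaled
#'   cover back into bed hectares.
#' @param driver_means_sds Named list mapping drivers to `c(mean,
#'   scale)` for the affine/lognormal map onto survey units.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(mode = c("subestuary", "mainchannel"),
                            seed = 1L,
                            n_sites = NULL, n_years = NULL,
                            start_year = 1984L, skip_years = NULL,
                            path_coefficients = NULL,
                            lag_interaction_coefficients = numeric(0),
                            random_intercept_sd = 0.03,
                            residual_sd = 0.1,
                            ar1_phi = 0.3,
                            zero_threshold = 0.05,
                            initial_cover = 0.5,
                            site_area_ha = 100,
                            driver_means_sds = NULL) {
  mode <- match.arg(mode)
  n_sites <- n_sites %||% if (mode == "subestuary") 35L else 51L
  n_years <- n_years %||% if (mode == "subestuary") 32L else 36L
  skip_years <- skip_years %||%
    if (mode == "mainchannel") 1988L else integer(0)
  cfg <- list(
    mode = mode, seed = as.integer(seed), n_sites = as.integer(n_sites),
    n_years = as.integer(n_years), start_year = as.integer(start_year),
    skip_years = as.integer(skip_years),
    path_coefficients = path_coefficients %||% default_paths(mode),
    lag_interaction_coefficients = lag_interaction_coefficients,
    random_intercept_sd = random_intercept_sd, residual_sd = residual_sd,
    ar1_phi = ar1_phi, zero_threshold = zero_threshold,
    initial_cover = initial_cover, site_area_ha = site_area_ha,
    driver_means_sds = driver_means_sds %||% default_units(mode)
  )
  validate_scenario_config(cfg)
}

validate_scenario_config <- function(cfg) {
  if (cfg$n_sites < 2) stop("n_sites must be >= 2", call. = FALSE)
  if (cfg$n_years < 4) stop("n_years must be >= 4", call. = FALSE)
  if (abs(cfg$ar1_phi) >= 1) stop("|ar1_phi| must be < 1", call. = FALSE)
  if (cfg$residual_sd <= 0) stop("residual_sd must be > 0", call. = FALSE)
  if (cfg$random_intercept_sd < 0) {
    stop("random_intercept_sd must be >= 0", call. = FALSE)
  }
  allowed <- allowed_edges(cfg$mode)
  allowed_keys <- paste(allowed$from, allowed$to, sep = "->")
  bad <- setdiff(names(cfg$path_coefficients), allowed_keys)
  if (length(bad) > 0) {
    stop("path coefficient key(s) outside the allowed ", cfg$mode,
         " edge set: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  drivers_into_change <- allowed$from[allowed$to == "change"]
  badl <- setdiff(names(cfg$lag_interaction_coefficients),
                  drivers_into_change)
  if (length(badl) > 0) {
    stop("lag interaction key(s) are not drivers of change: ",
         paste(badl, collapse = ", "), call. = FALSE)
  }
  class(cfg) <- "scenario_config"
  cfg
}

# Split "src->dst" coefficient names into an edge table.
path_table <- function(path_coefficients) {
  if (length(path_coefficients) == 0) {
    return(tibble(from = character(0), to = character(0),
                  beta = numeric(0)))
  }
  parts <- strsplit(names(path_coefficients), "->", fixed = TRUE)
  tibble(from = vapply(parts, `[`, "", 1), to = vapply(parts, `[`, "", 2),
         beta = unname(path_coefficients))
}

# AR(1) series with marginal sd `sigma` and lag-1 correlation `phi`.
ar1_series <- function(n, phi, sigma) {
  e <- rnorm(n)
  x <- numeric(n)
  x[1] <- sigma * e[1]
  if (n > 1) {
    innov_sd <- sigma * sqrt(1 - phi^2)
    for (t in 2:n) x[t] <- phi * x[t - 1] + innov_sd * e[t]
  }
  x
}

# Driver layer: standardized exogenous variables i.i.d. N(0,1) across
# site-years; endogenous drivers take the linear structural value plus
# Gaussian noise sized to keep (approximately) unit marginal variance.
# Returns the matrix of standardized drivers and the analytic driver
# covariance used for standardized-truth bookkeeping.
generate_driver_layer <- function(cfg, n_obs) {
  paths <- path_table(cfg$path_coefficients)
  driver_paths <- filter(paths, .data$to != "change")
  vars <- names(cfg$driver_means_sds)
  endo <- intersect(unique(driver_paths$to), vars)
  exo <- setdiff(vars, endo)
  M <- matrix(NA_real_, n_obs, length(vars),
              dimnames = list(NULL, vars))
  S <- diag(length(vars))
  dimnames(S) <- list(vars, vars)
  for (v in exo) M[, v] <- rnorm(n_obs)
  for (v in endo) { # allowed edge sets are layered: parents are exogenous
    pp <- filter(driver_paths, .data$to == v)
    lp <- M[, pp$from, drop = FALSE] %*% pp$beta
    v_lp <- drop(crossprod(pp$beta, S[pp$from, pp$from, drop = FALSE]
                           %*% pp$beta))
    noise_var <- max(0.05, 1 - v_lp)
    M[, v] <- drop(lp) + rnorm(n_obs, sd = sqrt(noise_var))
    cv <- drop(S[, pp$from, drop = FALSE] %*% pp$beta)
    S[v, ] <- cv
    S[, v] <- cv
    S[v, v] <- v_lp + noise_var
  }
  list(M = M, S = S)
}

generate_scenario <- function(cfg) {
  cfg <- validate_scenario_config(cfg)
  set.seed(cfg$seed)
  years <- seq(cfg$start_year, length.out = cfg$n_years)
  sites <- sprintf("S%03d", seq_len(cfg$n_sites))
  n_obs <- cfg$n_sites * cfg$n_years
  site_vec <- rep(sites, each = cfg$n_years)
  year_vec <- rep(years, cfg$n_sites)

  layer <- generate_driver_layer(cfg, n_obs)
  M <- layer$M
  paths <- path_table(cfg$path_coefficients)
  cpaths <- filter(paths, .data$to == "change")
  b_site <- rnorm(cfg$n_sites, sd = cfg$random_intercept_sd)
  eps <- as.vector(vapply(seq_len(cfg$n_sites), function(i) {
    ar1_series(cfg$n_years, cfg$ar1_phi, cfg$residual_sd)
  }, numeric(cfg$n_years)))

  struct <- if (nrow(cpaths) > 0) {
    drop(M[, cpaths$from, drop = FALSE] %*% cpaths$beta)
  } else {
    numeric(n_obs)
  }
  lagc <- cfg$lag_interaction_coefficients

  cover <- numeric(n_obs)
  prev <- numeric(n_obs)
  for (i in seq_len(cfg$n_sites)) {
    idx <- ((i - 1) * cfg$n_years) + seq_len(cfg$n_years)
    s_prev <- cfg$initial_cover
    for (k in seq_along(idx)) {
      j <- idx[k]
      delta <- struct[j] + b_site[i] + eps[j]
      if (length(lagc) > 0) {
        delta <- delta + sum(lagc * M[j, names(lagc)] * s_prev)
      }
      s <- min(max(s_prev + delta, 0), 1)
      if (cfg$zero_threshold > 0 && s <= cfg$zero_threshold) s <- 0
      prev[j] <- s_prev
      cover[j] <- s
      s_prev <- s
    }
  }

  keep <- !(year_vec %in% cfg$skip_years)
  analysis <- tibble(
    site_id = site_vec, year = year_vec,
    as_tibble(M), cover = cover, prev_cover = prev,
    change = cover - prev
  )
  # the pre-survey level is latent, and a skipped survey year leaves no
  # record: neither forms an observable change pair
  analysis$change[analysis$year %in%
                    c(cfg$start_year, cfg$skip_years + 1L)] <- NA_real_
  analysis$prev_cover[analysis$year %in%
                        c(cfg$start_year, cfg$skip_years + 1L)] <- NA_real_
  analysis <- analysis[keep, ]

  density <- density_class_from_cover(cover)
  area <- ifelse(cover > 0,
                 cover * cfg$site_area_ha / density_midpoint(density), 0)
  area[cover == 0] <- 0
  beds <- tibble(site_id = site_vec, year = year_vec,
                 area_ha = area, density = density)[keep, ]

  drivers <- driver_units(cfg, M)
  drivers <- bind_cols(
    tibble(!!driver_id_column(cfg$mode) := site_vec, year = year_vec),
    drivers
  )[keep, ]

  v_struct <- if (nrow(cpaths) > 0) {
    drop(crossprod(cpaths$beta, layer$S[cpaths$from, cpaths$from,
                                        drop = FALSE] %*% cpaths$beta))
  } else {
    0
  }
  sd_change <- sqrt(v_struct + cfg$random_intercept_sd^2 +
                      cfg$residual_sd^2)
  truth <- cfg
  truth$std_change_coefficients <- if (nrow(cpaths) > 0) {
    setNames(cpaths$beta * sqrt(diag(layer$S)[cpaths$from]) / sd_change,
             cpaths$from)
  } else {
    numeric(0)
  }
  truth$sd_change_latent <- sd_change
  truth$driver_covariance <- layer$S

  structure(list(mode = cfg$mode, drivers = drivers, beds = beds,
                 analysis = analysis, truth = truth),
            class = "sav_synth")
}

driver_id_column <- function(mode) {
  if (mode == "subestuary") "subestuary_id" else "station_id"
}

# Map standardized drivers onto realistic survey units: lognormal for
# positive loads/concentrations, affine (clipped to valid ranges) for
# fractions, temperature, salinity and Secchi depth.
driver_units <- function(cfg, M) {
  out <- lapply(names(cfg$driver_means_sds), function(v) {
    ms <- cfg$driver_means_sds[[v]]
    z <- M[, v]
    if (v %in% c("frac_agriculture", "frac_developed")) {
      pmin(pmax(ms[1] + ms[2] * z, 0), 0.5)
    } else if (v %in% c("temperature", "salinity", "secchi")) {
      lo <- if (v == "secchi") 0.1 else 0
      pmax(ms[1] + ms[2] * z, lo)
    } else {
      exp(log(ms[1]) + ms[2] * z)
    }
  })
  names(out) <- names(cfg$driver_means_sds)
  as_tibble(out)
}

#' Generate a synthetic subestuary dataset
#'
#' Watershed drivers (land-use fractions, growing-season flow and
#' nutrient/sediment loads) are generated upstream-first along the
#' allowed causal edges with the configured standardized coefficients;
#' scaled cover then evolves as previous cover + structural change +
#' site random intercept + AR(1) noise, clipped to \[0, 1\] and floored
#' to 0 below the zero threshold. Density classes are back-assigned
#' from scaled-cover quartile bins.
#'
#' @param config A `scenario_config` with `mode = "subestuary"`.
#' @return A `sav_synth` list: `drivers` (watershed records in survey
#'   units), `beds` (bed observations), `analysis` (standardized
#'   site-year analysis table with `cover`, `prev_cover`, `change`) and
#'   `truth` (the config plus analytic standardized-coefficient
#'   expectations).
#' @examples
#' sim <- generate_subestuary_scenario(scenario_config("subestuary",
#'   seed = 42, n_sites = 5, n_years = 8))
#' head(sim$analysis)
#' @export
generate_subestuary_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  if (config$mode != "subestuary") {
    stop("config mode must be 'subestuary'", call. = FALSE)
  }
  generate_scenario(config)
}

#' Generate a synthetic main-channel dataset
#'
#' As [generate_subestuary_scenario()] but with spring water-quality
#' drivers: total nitrogen feeds chlorophyll-a; chlorophyll-a, Secchi
#' depth, salinity and temperature drive widgeongrass change (salinity
#' positive and chlorophyll-a negative by default). The 1988 survey
#' year is skipped by default, breaking that year's change pairs.
#'
#' @param config A `scenario_config` with `mode = "mainchannel"`.
#' @return A `sav_synth` list; see [generate_subestuary_scenario()].
#' @export
generate_main_channel_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  if (config$mode != "mainchannel") {
    stop("config mode must be 'mainchannel'", call. = FALSE)
  }
  generate_scenario(config)
}

#' Generate a random station-and-grid scene
#'
#' Places stations uniformly in a square extent and builds the 30 m
#' lattice of cell centers (offset 15 m), assigning each cell a random
#' density class or leaving it unvegetated.
#'
#' @param n_stations Number of stations (>= 1).
#' @param extent_m Side of the square extent in meters (>= 30).
#' @param seed Integer RNG seed.
#' @param p_vegetated Probability a cell is vegetated.
#' @return List with `stations` (tibble `station_id`, `x_m`, `y_m`) and
#'   `cells` (tibble `x_m`, `y_m`, `density`).
#' @export
generate_grid_scene <- function(n_stations, extent_m, seed,
                                p_vegetated = 0.6) {
  if (n_stations < 1) stop("n_stations must be >= 1", call. = FALSE)
  if (extent_m < 30) {
    stop("extent must fit at least one 30 m cell", call. = FALSE)
  }
  set.seed(seed)
  k <- floor(extent_m / 30)
  centers <- 15 + 30 * (seq_len(k) - 1)
  cells <- tidyr::expand_grid(x_m = centers, y_m = centers)
  veg <- runif(nrow(cells)) < p_vegetated
  density <- rep(NA_character_, nrow(cells))
  density[veg] <- sample(density_class_levels(), sum(veg), replace = TRUE)
  cells$density <- density
  stations <- tibble(
    station_id = sprintf("ST%02d", seq_len(n_stations)),
    x_m = runif(n_stations, 0, extent_m),
    y_m = runif(n_stations, 0, extent_m)
  )
  list(stations = stations, cells = cells)
}

#' Simulate a grouped time series for the mixed-model engine
#'
#' Gaussian predictors, a known fixed-effect vector, a per-group random
#' intercept and AR(1) residuals with given marginal SD: the
#' parameter-recovery harness for [fit_lmm()].
#'
#' @param n_groups,n_years Panel dimensions.
#' @param beta Named or unnamed coefficients for predictors
#'   `x1..xk` (one per element).
#' @param intercept Fixed intercept (default 0).
#' @param phi AR(1) lag-1 correlation of the residuals.
#' @param sigma_b Random-intercept SD.
#' @param sigma Marginal residual SD.
#' @param seed Integer RNG seed.
#' @return Tibble with `site`, `year`, predictors and `y`.
#' @export
simulate_lmm_dataset <- function(n_groups, n_years, beta, intercept = 0,
                                 phi = 0, sigma_b = 0, sigma = 1,
                                 seed = 1L) {
  set.seed(seed)
  n <- n_groups * n_years
  k <- length(beta)
  X <- matrix(rnorm(n * k), n, k,
              dimnames = list(NULL, paste0("x", seq_len(k))))
  b <- rep(rnorm(n_groups, sd = sigma_b), each = n_years)
  e <- as.vector(vapply(seq_len(n_groups), function(i) {
    ar1_series(n_years, phi, sigma)
  }, numeric(n_years)))
  tibble(
    site = rep(sprintf("g%03d", seq_len(n_groups)), each = n_years),
    year = rep(seq_len(n_years), n_groups),
    as_tibble(X),
    y = intercept + drop(X %*% beta) + b + e
  )
}

#' Template causal graphs for the two analyses
#'
#' Ready-made `causal_graph` objects matching the synthetic generators'
#' default path structure, with `change` as the response node.
#'
#' @param lag_interactions Named list of lag-interaction declarations
#'   (default none).
#' @return A validated `causal_graph`.
#' @export
subestuary_graph <- function(lag_interactions = list()) {
  causal_graph(
    edges = path_table(default_paths("subestuary"))[, c("from", "to")],
    lag_interactions = lag_interactions,
    group = "site_id",
    order = c("frac_agriculture", "frac_developed", "flow", "point_N",
              "nonpoint_N", "point_P", "nonpoint_P", "tss", "change")
  )
}

#' @rdname subestuary_graph
#' @export
main_channel_graph <- function(lag_interactions = list()) {
  causal_graph(
    edges = path_table(default_paths("mainchannel"))[, c("from", "to")],
    lag_interactions = lag_interactions,
    group = "site_id",
    order = c("temperature", "salinity", "secchi", "total_N", "total_P",
              "chla", "change")
  )
}
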