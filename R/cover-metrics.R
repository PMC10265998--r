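# Density-weighted cover pipeline: midpoint weighting -> per-site max
# scaling -> annual differencing -> consecutive-zero filtering.

#' Density-weighted cover of a bed
#'
#' Multiplies bed area by the percent-cover midpoint of its density
#' class, giving the effective vegetated bottom area in hectares.
#'
#' @param area_ha Bed area in hectares (non-negative).
#' @param density Density class label(s), see [density_class_levels()].
#'   Ignored (any label, including NA, accepted) where `area_ha` is 0.
#' @return Numeric vector of density-weighted hectares.
#' @examples
#' density_weighted_cover(100, "dense") # 55 ha
#' @export
density_weighted_cover <- function(area_ha, density) {
  if (any(area_ha < 0, na.rm = TRUE)) {
    stop("area_ha must be non-negative", call. = FALSE)
  }
  out <- numeric(length(area_ha))
  pos <- !is.na(area_ha) & area_ha > 0
  # integer percent form keeps the printed midpoints exact
  # (100 ha dense = 55 ha, 40 ha very sparse = 2 ha)
  out[pos] <- area_ha[pos] * round(100 * density_midpoint(density[pos])) / 100
  out[is.na(area_ha)] <- NA_real_
  out
}

#' Scale a cover series to its maximum
#'
#' Divides each value by the series maximum so the best year maps to 1
#' (the site's realized habitable extent) and bare years to 0. An
#' all-zero series stays all zero.
#'
#' @param dw_series Numeric vector of density-weighted hectares
#'   (non-negative, non-empty; NAs are carried through).
#' @return Numeric vector of fractions in \[0, 1\].
#' @examples
#' scale_to_site_max(c(10, 20, 40))
#' @export
scale_to_site_max <- function(dw_series) {
  if (length(dw_series) == 0) stop("series must be non-empty", call. = FALSE)
  if (any(dw_series < 0, na.rm = TRUE)) {
    stop("density-weighted cover must be non-negative", call. = FALSE)
  }
  m <- max(dw_series, na.rm = TRUE)
  if (!is.finite(m) || m == 0) return(ifelse(is.na(dw_series), NA_real_, 0))
  dw_series / m
}

#' Annual proportional change in scaled cover
#'
#' Differences the \[0, 1\]-scaled cover between consecutive calendar
#' years. Pairs spanning a survey gap (a missing year, e.g. 1988 in the
#' bay-wide survey) are not formed.
#'
#' @param scaled Numeric vector of scaled cover values.
#' @param years Integer vector of the same length, strictly increasing.
#' @return Numeric vector aligned with `scaled`: element t holds
#'   `scaled[t] - scaled[t-1]` when year t-1 was surveyed, otherwise NA
#'   (always NA for the first year).
#' @examples
#' proportional_change(c(0.2, 0.7), c(1990, 1991))
#' @export
proportional_change <- function(scaled, years = seq_along(scaled)) {
  if (length(scaled) != length(years)) {
    stop("scaled and years must have equal length", call. = FALSE)
  }
  if (length(scaled) > 1 && any(diff(years) <= 0)) {
    stop("years must be strictly increasing", call. = FALSE)
  }
  out <- rep(NA_real_, length(scaled))
  if (length(scaled) < 2) return(out)
  consec <- which(diff(years) == 1L) + 1L
  out[consec] <- scaled[consec] - scaled[consec - 1L]
  out
}

#' Flag the tail of long zero-cover runs
#'
#' Boom-bust widgeongrass series contain sites bare for many years.
#' A year is flagged when its cover is zero and it is the third or later
#' year of an unbroken run of zero-cover years; flagged years are
#' excluded from downstream regressions while the first two years of a
#' bust are retained as genuine observations.
#'
#' @param dw_series Numeric vector of density-weighted cover for
#'   consecutive surveyed years (non-empty).
#' @return Logical vector: TRUE where the year is filtered out.
#' @examples
#' zero_run_filter(c(5, 0, 0, 0, 3)) # F F F T F
#' @export
zero_run_filter <- function(dw_series) {
  if (length(dw_series) == 0) stop("series must be non-empty", call. = FALSE)
  zero <- !is.na(dw_series) & dw_series == 0
  run <- numeric(length(dw_series))
  for (i in seq_along(zero)) {
    run[i] <- if (zero[i]) (if (i > 1) run[i - 1] else 0) + 1 else 0
  }
  run >= 3
}

#' Build per-site cover series from bed observations
#'
#' Composes the full cover pipeline per site: density-weighted cover,
#' scaling to the site maximum over all surveyed years, proportional
#' change between consecutive years, and the three-zero run filter.
#' Missing survey years carry no record (they are not zeros); zero runs
#' are tracked within unbroken stretches of surveyed years and reset
#' across a survey gap.
#'
#' @param observations A data frame of bed observations with columns
#'   `site_id`, `year`, `area_ha`, `density` (as returned by
#'   [read_bed_observations()]).
#' @return A tibble with one row per site-year: `site_id`, `year`,
#'   `dw_cover_ha`, `scaled_cover`, `prop_change`, `filtered`, sorted by
#'   (`site_id`, `year`). The result is invariant to input row order.
#' @examples
#' obs <- tibble::tibble(
#'   site_id = "S1", year = 1990:1992, area_ha = c(10, 10, 20),
#'   density = c("sparse", "dense", "dense")
#' )
#' build_cover_series(obs)
#' @export
build_cover_series <- function(observations) {
  stopifnot(is.data.frame(observations))
  check_columns(observations, c("site_id", "year", "area_ha", "density"),
                "observations")
  if (anyDuplicated(observations[c("site_id", "year")])) {
    stop("duplicate (site_id, year) observations", call. = FALSE)
  }
  observations |>
    mutate(dw_cover_ha = density_weighted_cover(.data$area_ha, .data$density)) |>
    arrange(.data$site_id, .data$year) |>
    group_by(.data$site_id) |>
    group_modify(function(d, key) {
      scaled <- scale_to_site_max(d$dw_cover_ha)
      # segment at survey gaps so zero runs never span unsurveyed years
      seg <- cumsum(c(1L, diff(d$year) != 1L))
      filt <- unlist(lapply(split(d$dw_cover_ha, seg), zero_run_filter),
                     use.names = FALSE)
      tibble(
        year = d$year, dw_cover_ha = d$dw_cover_ha, scaled_cover = scaled,
        prop_change = proportional_change(scaled, d$year), filtered = filt
      )
    }) |>
    ungroup() |>
    select("site_id", "year", "dw_cover_ha", "scaled_cover",
           "prop_change", "filtered")
}
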