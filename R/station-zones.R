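# Nearest-station zone assignment of 30 x 30 m grid cells and
# per-station density-weighted cover aggregation.

CELL_AREA_HA <- 0.09 # a 30 x 30 m grid cell

#' Assign grid cells to their nearest monitoring station
#'
#' Each 30 x 30 m cell is mapped to the station minimizing the planar
#' Euclidean distance from the cell center; ties go to the
#' lexicographically smallest `station_id`. Together the zones partition
#' the mapped bottom into one independent spatial zone per station.
#'
#' @param cells Data frame with cell-center coordinates `x_m`, `y_m`
#'   (meters, projected CRS) and optionally `density` (class label or NA
#'   for unvegetated cells).
#' @param stations Data frame with columns `station_id`, `x_m`, `y_m`.
#' @return The `cells` tibble with an added `station_id` column. Output
#'   row order follows input row order; assignment is deterministic and
#'   independent of row order.
#' @export
assign_zones <- function(cells, stations) {
  stopifnot(is.data.frame(cells), is.data.frame(stations))
  check_columns(cells, c("x_m", "y_m"), "cells")
  check_columns(stations, c("station_id", "x_m", "y_m"), "stations")
  if (nrow(stations) == 0) stop("at least one station is required", call. = FALSE)
  if (!all(is.finite(stations$x_m)) || !all(is.finite(stations$y_m))) {
    stop("station coordinates must be finite", call. = FALSE)
  }
  st <- arrange(stations, .data$station_id)
  # squared distances, cells x stations; ties.method = "first" on the
  # id-sorted columns implements the smallest-station_id tie rule
  d2 <- outer(cells$x_m, st$x_m, "-")^2 + outer(cells$y_m, st$y_m, "-")^2
  idx <- max.col(-d2, ties.method = "first")
  out <- as_tibble(cells)
  out$station_id <- st$station_id[idx]
  out
}

#' Density-weighted cover per station zone
#'
#' Sums, per station, 0.09 ha times the density-class midpoint over the
#' vegetated cells assigned to that station's zone. Stations with no
#' vegetated cells report 0.
#'
#' @param assigned_cells Output of [assign_zones()] (must carry a
#'   `station_id` column covering every vegetated cell).
#' @param stations Optional station table; guarantees that every listed
#'   station appears in the output even with zero cover.
#' @return Tibble with `station_id` and `dw_cover_ha`, sorted by
#'   `station_id`.
#' @export
zone_cover <- function(assigned_cells, stations = NULL) {
  stopifnot(is.data.frame(assigned_cells))
  check_columns(assigned_cells, c("station_id", "density"), "assigned_cells")
  veg <- filter(assigned_cells, !is.na(.data$density))
  if (any(is.na(veg$station_id))) {
    stop("vegetated cell without a station assignment", call. = FALSE)
  }
  out <- veg |>
    mutate(dw = CELL_AREA_HA * density_midpoint(.data$density)) |>
    group_by(.data$station_id) |>
    summarise(dw_cover_ha = sum(.data$dw), .groups = "drop")
  if (!is.null(stations)) {
    check_columns(stations, "station_id", "stations")
    out <- tibble(station_id = sort(unique(stations$station_id))) |>
      left_join(out, by = "station_id") |>
      mutate(dw_cover_ha = tidyr::replace_na(.data$dw_cover_ha, 0))
  }
  arrange(out, .data$station_id)
}
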