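# Delimited-text readers/writers shared by every pipeline stage.
# All tables are comma-delimited UTF-8 with "." decimal separator and the
# literal "NA" for missing values; zero is always a real cover value and is
# never used to encode missingness.

check_columns <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("file '", path, "' is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

read_csv_quiet <- function(path, col_types) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  # a missing mandatory column is reported by check_columns() with the
  # column's name; readr's own named-parser warning adds nothing
  suppressWarnings(
    readr::read_csv(path, col_types = col_types, progress = FALSE,
                    na = c("NA", ""))
  )
}

#' Read annual seagrass bed observations
#'
#' One row per site-year: vegetated bed area in hectares plus the aerial
#' density class. A year with no vegetation is recorded as `area_ha = 0`
#' (its density label, if any, is ignored downstream).
#'
#' @param path Path to a CSV file with columns `site_id`, `year`,
#'   `area_ha`, `density`.
#' @return A tibble sorted by (`site_id`, `year`) with columns `site_id`
#'   (character), `year` (integer), `area_ha` (double), `density`
#'   (character, validated against [density_class_levels()]).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("site_id,year,area_ha,density", "S1,1990,12.5,sparse"), f)
#' read_bed_observations(f)
#' @export
read_bed_observations <- function(path) {
  df <- read_csv_quiet(path, readr::cols(
    site_id = readr::col_character(), year = readr::col_integer(),
    area_ha = readr::col_double(), density = readr::col_character()
  ))
  check_columns(df, c("site_id", "year", "area_ha", "density"), path)
  mids <- density_class_levels()
  bad <- which(!is.na(df$density) & !(df$density %in% mids))
  if (length(bad) > 0) {
    stop("unknown density class '", df$density[bad[1]], "' in '", path,
         "' at data row ", bad[1], " (file line ", bad[1] + 1L, ")",
         call. = FALSE)
  }
  neg <- which(!is.na(df$area_ha) & df$area_ha < 0)
  if (length(neg) > 0) {
    stop("negative area_ha in '", path, "' at data row ", neg[1], call. = FALSE)
  }
  dup <- duplicated(df[c("site_id", "year")])
  if (any(dup)) {
    stop("duplicate (site_id, year) record(s), e.g. ",
         df$site_id[dup][1], "/", df$year[dup][1], call. = FALSE)
  }
  arrange(df, .data$site_id, .data$year)
}

#' Read per-subestuary annual watershed driver records
#'
#' Growing-season (April--August) freshwater discharge, point/nonpoint
#' nitrogen and phosphorus loads, suspended-solid loads and land-use
#' fractions for each subestuary-year.
#'
#' @param path CSV with columns `subestuary_id`, `year`, `flow`,
#'   `point_N`, `nonpoint_N`, `point_P`, `nonpoint_P`, `tss`,
#'   `frac_agriculture`, `frac_developed`.
#' @return Tibble sorted by (`subestuary_id`, `year`).
#' @export
read_watershed_records <- function(path) {
  cols <- c("subestuary_id", "year", "flow", "point_N", "nonpoint_N",
            "point_P", "nonpoint_P", "tss", "frac_agriculture",
            "frac_developed")
  df <- read_csv_quiet(path, readr::cols(
    subestuary_id = readr::col_character(), year = readr::col_integer(),
    .default = readr::col_double()
  ))
  check_columns(df, cols, path)
  loads <- c("flow", "point_N", "nonpoint_N", "point_P", "nonpoint_P", "tss")
  for (v in loads) {
    if (any(df[[v]] < 0, na.rm = TRUE)) {
      stop("negative ", v, " in '", path, "'", call. = FALSE)
    }
  }
  fr <- df$frac_agriculture + df$frac_developed
  if (any(fr > 1 + 1e-9, na.rm = TRUE)) {
    stop("frac_agriculture + frac_developed exceeds 1 in '", path, "'",
         call. = FALSE)
  }
  arrange(df, .data$subestuary_id, .data$year)
}

#' Read per-station spring water-quality records
#'
#' Springtime (March--May) mean temperature, salinity, Secchi depth,
#' total nitrogen, total phosphorus and chlorophyll-a per station-year.
#'
#' @param path CSV with columns `station_id`, `year`, `temperature`,
#'   `salinity`, `secchi`, `total_N`, `total_P`, `chla`.
#' @return Tibble sorted by (`station_id`, `year`).
#' @export
read_water_quality_records <- function(path) {
  cols <- c("station_id", "year", "temperature", "salinity", "secchi",
            "total_N", "total_P", "chla")
  df <- read_csv_quiet(path, readr::cols(
    station_id = readr::col_character(), year = readr::col_integer(),
    .default = readr::col_double()
  ))
  check_columns(df, cols, path)
  if (any(df$secchi <= 0, na.rm = TRUE)) {
    stop("secchi depth must be positive in '", path, "'", call. = FALSE)
  }
  if (any(df$salinity < 0, na.rm = TRUE) || any(df$chla < 0, na.rm = TRUE)) {
    stop("salinity and chla must be non-negative in '", path, "'",
         call. = FALSE)
  }
  arrange(df, .data$station_id, .data$year)
}

#' Read a daily discharge series
#'
#' @param path CSV with columns `date` (ISO 8601) and `discharge`
#'   (volume per second, non-negative).
#' @return Tibble with `date` (Date) and `discharge` (double), sorted by
#'   date; duplicate dates are an error.
#' @export
read_discharge_series <- function(path) {
  df <- read_csv_quiet(path, readr::cols(
    date = readr::col_date(), discharge = readr::col_double()
  ))
  check_columns(df, c("date", "discharge"), path)
  if (anyDuplicated(df$date)) stop("duplicate dates in '", path, "'", call. = FALSE)
  if (any(df$discharge < 0, na.rm = TRUE)) {
    stop("negative discharge in '", path, "'", call. = FALSE)
  }
  arrange(df, .data$date)
}

#' Write a tabular result as delimited text
#'
#' Writes comma-delimited UTF-8 with a header row. Identifiers and
#' integers round-trip bit-exactly through the matching reader; reals
#' round-trip to at least 12 significant digits.
#'
#' @param records A data frame (possibly zero-row).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  if (is.null(records)) stop("records must be non-null", call. = FALSE)
  records <- as.data.frame(records)
  num <- vapply(records, is.double, logical(1))
  records[num] <- lapply(records[num], function(x) {
    ifelse(is.na(x), NA, formatC(x, digits = 15, format = "g"))
  })
  ok <- tryCatch({
    utils::write.csv(records, path, row.names = FALSE, quote = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write '", path, "': ", conditionMessage(ok),
                        call. = FALSE)
  invisible(path)
}
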