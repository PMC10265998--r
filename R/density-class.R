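#' Aerial-survey density classes and their percent-cover midpoints
#'
#' Aerial photo-interpretation assigns each mapped SAV bed one of four
#' ordinal density classes. Quantitative cover uses the midpoint of the
#' percent-cover interval each class represents: very sparse (0--10%)
#' maps to 5%, sparse (10--40%) to 25%, dense (40--70%) to 55% and
#' very dense (70--100%) to 85%.
#'
#' @return A named numeric vector of midpoints (fractions in (0, 1)),
#'   named by class label in increasing density order.
#' @examples
#' density_class_midpoints()
#' @export
density_class_midpoints <- function() {
  c(very_sparse = 0.05, sparse = 0.25, dense = 0.55, very_dense = 0.85)
}

#' Density-class labels in increasing order
#' @return Character vector of the four valid labels.
#' @export
density_class_levels <- function() {
  names(density_class_midpoints())
}

#' Look up the percent-cover midpoint of a density class
#'
#' @param density Character vector of class labels.
#' @return Numeric vector of midpoints (fractions). Unknown labels are an
#'   error naming the offending label.
#' @examples
#' density_midpoint(c("sparse", "very_dense"))
#' @export
density_midpoint <- function(density) {
  mids <- density_class_midpoints()
  bad <- setdiff(unique(density[!is.na(density)]), names(mids))
  if (length(bad) > 0) {
    stop("unknown density class label(s): ", paste(bad, collapse = ", "),
         " (valid: ", paste(names(mids), collapse = ", "), ")", call. = FALSE)
  }
  unname(mids[density])
}

#' Back-assign a density class from scaled cover
#'
#' Inverse of the midpoint weighting used when generating synthetic bed
#' observations: scaled cover in (0, 0.25] is very sparse, (0.25, 0.5]
#' sparse, (0.5, 0.75] dense and (0.75, 1] very dense. Zero cover has no
#' class (NA).
#'
#' @param scaled Numeric vector of scaled cover values in \[0, 1\].
#' @return Character vector of class labels (NA where `scaled` is 0).
#' @export
density_class_from_cover <- function(scaled) {
  if (any(scaled < 0 | scaled > 1, na.rm = TRUE)) {
    stop("scaled cover must lie in [0, 1]", call. = FALSE)
  }
  lev <- density_class_levels()
  idx <- findInterval(scaled, c(0, 0.25, 0.5, 0.75), left.open = TRUE)
  out <- lev[pmax(idx, 1L)]
  out[!is.na(scaled) & scaled == 0] <- NA_character_
  out
}
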