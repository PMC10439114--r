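#' Construct a point pattern
#'
#' A `point_pattern` is the unit of all spatial statistics in the package: a
#' set of planar coordinates (in nanometres) together with the rectangular
#' analysis region that contains them. Regions are half-open
#' `[0, width) x [0, height)` with the origin at the top-left corner of the
#' field, x along columns and y along rows.
#'
#' @param x,y Numeric vectors of coordinates in nm.
#' @param width_nm,height_nm Region dimensions in nm (must be positive).
#' @returns An object of class `point_pattern` with elements `x`, `y`,
#'   `width_nm`, `height_nm`.
#' @export
point_pattern <- function(x, y, width_nm, height_nm) {
  stopifnot(length(x) == length(y), is.numeric(width_nm), is.numeric(height_nm))
  if (width_nm <= 0 || height_nm <= 0)
    stop("region must have positive area")
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) && (any(!is.finite(x)) || any(!is.finite(y))))
    stop("coordinates must be finite")
  structure(list(x = x, y = y,
                 width_nm = as.numeric(width_nm),
                 height_nm = as.numeric(height_nm)),
            class = "point_pattern")
}

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf("point_pattern: %d points in %.0f x %.0f nm (%.2f /um^2)\n",
              npoints(x), x$width_nm, x$height_nm, pattern_density(x)))
  invisible(x)
}

#' Number of points in a pattern
#' @param p A `point_pattern`.
#' @export
npoints <- function(p) length(p$x)

#' Region area of a pattern in square micrometres
#' @param p A `point_pattern`.
#' @export
pattern_area_um2 <- function(p) p$width_nm * p$height_nm / 1e6

#' Overall density of a pattern in localizations per square micrometre
#' @param p A `point_pattern`.
#' @export
pattern_density <- function(p) npoints(p) / pattern_area_um2(p)

#' Crop a localization table to a rectangular analysis region
#'
#' Points are included with the half-open convention
#' `[x0, x0+w) x [y0, y0+h)` and re-expressed relative to the region origin.
#'
#' @param table A localization table (see [read_localizations()]).
#' @param region Numeric `c(x0, y0, width, height)` in nm.
#' @returns A [point_pattern()] carrying the region dimensions.
#' @export
crop_region <- function(table, region) {
  stopifnot(is.numeric(region), length(region) == 4)
  if (region[3] <= 0 || region[4] <= 0) stop("empty region")
  keep <- table$x_nm >= region[1] & table$x_nm < region[1] + region[3] &
          table$y_nm >= region[2] & table$y_nm < region[2] + region[4]
  point_pattern(table$x_nm[keep] - region[1], table$y_nm[keep] - region[2],
                region[3], region[4])
}
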