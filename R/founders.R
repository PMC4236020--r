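#' Ventricular surface area from serial section contours
#'
#' Reconstructs the ventricular surface of the dorsal telencephalon as a
#' polygon built from the traced contour lengths of equally spaced coronal
#' sections laid out along the anterior-posterior (horizontal) axis, and
#' returns its area as the sum of trapezoid strips.
#'
#' @param section_contour_lengths contour length of each section (mm),
#'   ordered along the anterior-posterior axis; at least 2 sections.
#' @param horizontal_length anterior-posterior extent (mm) spanned by the
#'   sections (assumed equally spaced, 0-based).
#' @return Surface area in mm^2.
#' @examples
#' surface_from_sections(c(2, 2), 5)      # rectangle: 10
#' surface_from_sections(c(0, 4, 0), 6)   # triangle: 12
#' @export
surface_from_sections <- function(section_contour_lengths,
                                  horizontal_length) {
  L <- section_contour_lengths
  if (length(L) < 2L) stop("need at least 2 sections", call. = FALSE)
  if (any(!is.finite(L)) || any(L < 0)) {
    stop("contour lengths must be non-negative", call. = FALSE)
  }
  if (!is.finite(horizontal_length) || horizontal_length <= 0) {
    stop("'horizontal_length' must be positive", call. = FALSE)
  }
  dx <- horizontal_length / (length(L) - 1L)
  sum((L[-length(L)] + L[-1L]) / 2 * dx)
}

#' Apical end-foot area of a neuroepithelial cell
#'
#' The apical end-foot is approximated as a regular hexagon whose
#' across-flats diameter is the measured distance between adherens
#' junctions: area = (sqrt(3) / 2) * d^2.
#'
#' @param apical_diameter across-flats diameter in micrometres.
#' @return Area in square micrometres.
#' @examples
#' endfoot_area(1)  # 0.866
#' @export
endfoot_area <- function(apical_diameter) {
  if (any(!is.finite(apical_diameter)) || any(apical_diameter <= 0)) {
    stop("'apical_diameter' must be positive", call. = FALSE)
  }
  sqrt(3) / 2 * apical_diameter^2
}

#' Founder-cell count from ventricular surface and end-foot area
#'
#' Divides the ventricular surface of the dorsal telencephalon by the
#' apical end-foot area of a single neuroepithelial cell.
#'
#' @param surface_area_mm2 ventricular surface area in mm^2.
#' @param endfoot_area_um2 end-foot area in um^2 (note the unit
#'   difference; 1 mm^2 = 1e6 um^2).
#' @return Estimated founder-cell count.
#' @examples
#' founders_from_surface(1, 2.5)  # 4e5 founders per mm^2 at 2.5 um^2
#' @export
founders_from_surface <- function(surface_area_mm2, endfoot_area_um2) {
  if (any(surface_area_mm2 <= 0) || any(endfoot_area_um2 <= 0)) {
    stop("areas must be positive", call. = FALSE)
  }
  surface_area_mm2 * 1e6 / endfoot_area_um2
}

#' Ventricular surface area from ventricular volume
#'
#' Approximates the ventricle as a cylinder with a 4.5-to-1
#' height-to-diameter proportion and returns the lateral surface (end caps
#' excluded, as the ventricular lining approximation): with `h = 4.5 d`,
#' `d = (4V / (4.5 pi))^(1/3)` and lateral surface `pi d h = 4.5 pi d^2`.
#'
#' @param ventricular_volume_mm3 ventricular volume in mm^3.
#' @param aspect height-to-diameter ratio (default 4.5).
#' @return Lateral surface area in mm^2.
#' @examples
#' cylinder_surface_from_volume(4.5 * pi / 4)  # d = 1: 4.5 * pi
#' @export
cylinder_surface_from_volume <- function(ventricular_volume_mm3,
                                         aspect = 4.5) {
  if (any(!is.finite(ventricular_volume_mm3)) ||
      any(ventricular_volume_mm3 <= 0)) {
    stop("'ventricular_volume_mm3' must be positive", call. = FALSE)
  }
  d <- (4 * ventricular_volume_mm3 / (aspect * pi))^(1 / 3)
  aspect * pi * d^2
}

#' Ventricular volume from lateral surface area (inverse)
#'
#' @param surface_area_mm2 lateral surface area in mm^2.
#' @param aspect height-to-diameter ratio (default 4.5).
#' @return Ventricular volume in mm^3.
#' @export
cylinder_volume_from_surface <- function(surface_area_mm2, aspect = 4.5) {
  if (any(surface_area_mm2 <= 0)) {
    stop("'surface_area_mm2' must be positive", call. = FALSE)
  }
  d <- sqrt(surface_area_mm2 / (aspect * pi))
  pi * d^2 / 4 * (aspect * d)
}

#' Founder-cell count from ventricular volume
#'
#' Converts ventricular volume to lateral cylinder surface and multiplies
#' by the founder density per surface area (near-identical in mouse and
#' human, 4e5 cells per mm^2).
#'
#' @param ventricular_volume_mm3 ventricular volume in mm^3.
#' @param density_per_mm2 founder cells per mm^2 of ventricular surface.
#' @param aspect cylinder height-to-diameter ratio.
#' @return Estimated founder-cell count.
#' @export
founders_from_volume <- function(ventricular_volume_mm3,
                                 density_per_mm2 = 4e5, aspect = 4.5) {
  if (any(density_per_mm2 <= 0)) {
    stop("'density_per_mm2' must be positive", call. = FALSE)
  }
  density_per_mm2 *
    cylinder_surface_from_volume(ventricular_volume_mm3, aspect)
}

#' Impute missing traits from ln-ln allometric regression
#'
#' Fits an ordinary least-squares regression of `ln(y)` on `ln(x)` over
#' the complete rows of a trait table (or uses supplied published
#' coefficients) and imputes the missing `y` values. Standard pairings are
#' neurogenic period against gestation period, ventricular volume against
#' adult brain weight, and neonate brain weight against adult brain
#' weight.
#'
#' @param tab `data.frame` with the predictor and response columns.
#' @param response,predictor column names.
#' @param coefficients optional `c(slope, intercept)` on the ln-ln scale;
#'   when supplied, no fit is performed.
#' @return A list with `table` (response column imputed), `slope`,
#'   `intercept`, `r_squared` (`NA` in coefficients-supplied mode) and
#'   `n_imputed`.
#' @examples
#' tab <- data.frame(gestation_days = c(19, 21, 30, 146),
#'                   neurogenic_days = c(9, 10, 13, NA))
#' estimate_missing(tab, "neurogenic_days", "gestation_days",
#'                  coefficients = c(0.91, -0.42))
#' @export
estimate_missing <- function(tab, response, predictor,
                             coefficients = NULL) {
  if (!all(c(response, predictor) %in% names(tab))) {
    stop("columns '", response, "' and '", predictor,
         "' must be present", call. = FALSE)
  }
  y <- tab[[response]]
  x <- tab[[predictor]]
  if (is.null(coefficients)) {
    complete <- !is.na(y) & !is.na(x)
    if (sum(complete) < 3L) {
      stop("need >= 3 complete rows to fit, or supply coefficients",
           call. = FALSE)
    }
    fit <- stats::lm(log(y[complete]) ~ log(x[complete]))
    slope <- unname(stats::coef(fit)[2L])
    intercept <- unname(stats::coef(fit)[1L])
    r2 <- summary(fit)$r.squared
  } else {
    slope <- coefficients[1L]
    intercept <- coefficients[2L]
    r2 <- NA_real_
  }
  fill <- is.na(y) & !is.na(x)
  y[fill] <- exp(slope * log(x[fill]) + intercept)
  tab[[response]] <- y
  list(table = tab, slope = slope, intercept = intercept,
       r_squared = r2, n_imputed = sum(fill))
}
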