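#' Construct a catheter tip specification
#'
#' @param shape `"flat"` or `"round"`.
#' @param diameter tip diameter in mm.
#' @param electrodeLength electrode length in mm.
#' @param surfaceArea optional preset electrode surface area in mm^2; when
#'   `NA` the area is derived geometrically by [tipSurfaceArea()].
#' @return a [TipSpec-class] object.
#' @examples
#' TipSpec("flat", diameter = 2.33, electrodeLength = 4.5)
#' @export
TipSpec <- function(shape = c("flat", "round"), diameter = 2.33,
                    electrodeLength = 4.5, surfaceArea = NA_real_) {
  shape <- match.arg(shape)
  new("TipSpec", shape = shape, diameter = as.numeric(diameter),
      electrodeLength = as.numeric(electrodeLength),
      surfaceArea = as.numeric(surfaceArea))
}

#' Reference study catheter tips
#'
#' The two catheter tips of the study: a flat-ended 7 Fr irrigated tip and
#' a round-ended (hemispherical) 7 Fr irrigated tip, both with a 2.33 mm
#' tip diameter, carrying the published electrode surface areas of
#' 37.26 mm^2 (flat) and 25.67 mm^2 (round) as presets.
#'
#' @return a [TipSpec-class] object.
#' @examples
#' tipSurfaceArea(flatTip())
#' @export
flatTip <- function() {
  TipSpec("flat", diameter = 2.33, electrodeLength = 4.5,
          surfaceArea = 37.26)
}

#' @rdname flatTip
#' @export
roundTip <- function() {
  TipSpec("round", diameter = 2.33, electrodeLength = 3.5,
          surfaceArea = 25.67)
}

#' Electrode surface area of a catheter tip
#'
#' For a flat tip, lateral cylinder plus flat end cap:
#' `pi*d*L + pi*d^2/4`.  For a round tip, lateral cylinder up to the
#' hemisphere plus the hemisphere: `pi*d*(L - d/2) + pi*d^2/2`.  A preset
#' `surfaceArea` carried by the tip (the published constants on
#' [flatTip()] / [roundTip()]) takes precedence unless `usePreset = FALSE`.
#'
#' @param tip a [TipSpec-class].
#' @param usePreset honour a preset surface area if the tip has one.
#' @return surface area in mm^2.
#' @examples
#' tipSurfaceArea(flatTip())                      # published preset
#' tipSurfaceArea(flatTip(), usePreset = FALSE)   # from geometry
#' @export
tipSurfaceArea <- function(tip, usePreset = TRUE) {
  stopifnot(is(tip, "TipSpec"))
  validObject(tip)
  if (usePreset && !is.na(tip@surfaceArea))
    return(tip@surfaceArea)
  d <- tip@diameter
  L <- tip@electrodeLength
  if (tip@shape == "flat")
    pi * d * L + pi * d^2 / 4
  else
    pi * d * (L - d / 2) + pi * d^2 / 2
}

#' Convert gram-force to Newton
#'
#' `1 gf = 0.00981 N` (gravitational acceleration 9.81 m/s^2).
#'
#' @param force force in gf, non-negative; vectorized.
#' @return force in Newton.
#' @examples
#' gfToNewton(c(2, 40))   # 0.0196, 0.392 N at 3 significant figures
#' @export
gfToNewton <- function(force) {
  if (any(!is.finite(force)) || any(force < 0))
    stop("force must be finite and >= 0 gf")
  force * 0.00981
}

#' Percentage contact area
#'
#' Contact area as a percentage of the catheter tip electrode surface
#' area: `100 * area / tipArea`.  Reporting layers round this to the
#' nearest integer percent.
#'
#' @param area contact area, mm^2 (>= 0); vectorized.
#' @param tipArea tip electrode surface area, mm^2 (> 0).
#' @return percentage contact area.
#' @examples
#' percentageContactArea(19.097, 37.26)   # 51.25 -> reported as 51
#' @export
percentageContactArea <- function(area, tipArea) {
  if (any(!is.finite(tipArea)) || any(tipArea <= 0))
    stop("tipArea must be > 0")
  if (any(!is.finite(area)) || any(area < 0))
    stop("area must be >= 0")
  100 * area / tipArea
}
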