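#' @import methods
NULL

#' Catheter tip geometry
#'
#' An ablation catheter tip, described by the shape of its distal end
#' (`"flat"`: cylinder closed by a flat disc; `"round"`: cylinder closed by
#' a hemisphere), its diameter and electrode length in mm, and optionally a
#' preset total electrode surface area in mm^2.  When `surfaceArea` is `NA`
#' it is derived from the cylinder + end-cap geometry by
#' [tipSurfaceArea()]; a finite value (e.g. a manufacturer constant) takes
#' precedence.
#'
#' @slot shape character, `"flat"` or `"round"`.
#' @slot diameter tip diameter, mm.
#' @slot electrodeLength electrode length, mm.
#' @slot surfaceArea preset electrode surface area, mm^2, or `NA`.
#' @name TipSpec-class
#' @aliases TipSpec-class
#' @exportClass TipSpec
setClass("TipSpec",
  representation(shape = "character", diameter = "numeric",
                 electrodeLength = "numeric", surfaceArea = "numeric"),
  prototype(shape = "flat", diameter = 2.33, electrodeLength = 4.5,
            surfaceArea = NA_real_))

setValidity("TipSpec", function(object) {
  msg <- character()
  if (length(object@shape) != 1L || !object@shape %in% c("flat", "round"))
    msg <- c(msg, "shape must be \"flat\" or \"round\"")
  if (!isTRUE(object@diameter > 0))
    msg <- c(msg, "diameter must be > 0")
  if (!isTRUE(object@electrodeLength > 0))
    msg <- c(msg, "electrodeLength must be > 0")
  if (!is.na(object@surfaceArea) && !isTRUE(object@surfaceArea > 0))
    msg <- c(msg, "surfaceArea must be > 0 when set")
  if (isTRUE(object@diameter > 2 * object@electrodeLength))
    msg <- c(msg, "diameter must not exceed twice the electrode length")
  if (length(msg)) msg else TRUE
})

#' Logarithmic force-area ground-truth law
#'
#' The generating law `area = a * ln(force) + b` used by the synthetic
#' contact-print generator, with a multiplicative Gaussian replicate noise
#' of coefficient of variation `noiseCV` on the area.
#'
#' @slot a slope, mm^2 per ln(gf).
#' @slot b intercept, mm^2.
#' @slot noiseCV coefficient of variation of replicate areas (>= 0).
#' @name ContactLaw-class
#' @aliases ContactLaw-class
#' @exportClass ContactLaw
setClass("ContactLaw",
  representation(a = "numeric", b = "numeric", noiseCV = "numeric"),
  prototype(a = 2.685, b = 7.782, noiseCV = 0))

setValidity("ContactLaw", function(object) {
  msg <- character()
  for (s in c("a", "b", "noiseCV"))
    if (length(slot(object, s)) != 1L || !is.finite(slot(object, s)))
      msg <- c(msg, sprintf("%s must be a finite scalar", s))
  if (length(object@noiseCV) == 1L && isTRUE(object@noiseCV < 0))
    msg <- c(msg, "noiseCV must be >= 0")
  if (length(msg)) msg else TRUE
})

#' A single experimental contact condition
#'
#' One cell of the study grid: a tip, a contact angle (degrees between the
#' catheter shaft and the tissue plane; 90 = perpendicular), a contact
#' force in gram-force, and a replicate index.
#'
#' @slot tip a [TipSpec-class] object.
#' @slot angle contact angle in degrees, within \[0, 90\].
#' @slot force contact force, gf (> 0).
#' @slot replicate positive integer replicate index.
#' @name ContactCondition-class
#' @aliases ContactCondition-class
#' @exportClass ContactCondition
setClass("ContactCondition",
  representation(tip = "TipSpec", angle = "numeric", force = "numeric",
                 replicate = "integer"),
  prototype(angle = 0, force = 2, replicate = 1L))

setValidity("ContactCondition", function(object) {
  msg <- character()
  if (!isTRUE(object@angle >= 0 && object@angle <= 90))
    msg <- c(msg, "angle must lie in [0, 90] degrees")
  if (!isTRUE(object@force > 0))
    msg <- c(msg, "force must be > 0 gf")
  if (!isTRUE(object@replicate >= 1L))
    msg <- c(msg, "replicate must be >= 1")
  if (length(msg)) msg else TRUE
})

#' A contact-print image
#'
#' A single grayscale contact print: pixel intensities in \[0, 1\], the
#' pixel calibration in mm per pixel, the generating condition, and (for
#' synthetic prints) the analytic post-noise footprint area known to the
#' generator.
#'
#' @slot pixels numeric matrix of intensities in \[0, 1\].
#' @slot pixelScale mm per pixel (> 0).
#' @slot condition a [ContactCondition-class].
#' @slot truthArea analytic footprint area, mm^2 (`NA` for real images).
#' @name ContactPrint-class
#' @aliases ContactPrint-class
#' @exportClass ContactPrint
setClass("ContactPrint",
  representation(pixels = "matrix", pixelScale = "numeric",
                 condition = "ContactCondition", truthArea = "numeric"))

setValidity("ContactPrint", function(object) {
  msg <- character()
  if (!is.numeric(object@pixels) || length(dim(object@pixels)) != 2L)
    msg <- c(msg, "pixels must be a 2-D numeric matrix")
  else if (any(object@pixels < 0 | object@pixels > 1))
    msg <- c(msg, "pixel intensities must lie in [0, 1]")
  if (!isTRUE(object@pixelScale > 0))
    msg <- c(msg, "pixelScale must be > 0")
  if (length(msg)) msg else TRUE
})

#' A binary footprint mask
#'
#' A logical pixel grid (TRUE = footprint) with its mm-per-pixel
#' calibration.
#'
#' @slot pixels logical matrix.
#' @slot pixelScale mm per pixel (> 0).
#' @name BinaryMask-class
#' @aliases BinaryMask-class
#' @exportClass BinaryMask
setClass("BinaryMask",
  representation(pixels = "matrix", pixelScale = "numeric"))

setValidity("BinaryMask", function(object) {
  msg <- character()
  if (!is.logical(object@pixels) || length(dim(object@pixels)) != 2L ||
      any(dim(object@pixels) < 1L))
    msg <- c(msg, "pixels must be a logical matrix of dimension >= 1x1")
  if (!isTRUE(object@pixelScale > 0))
    msg <- c(msg, "pixelScale must be > 0")
  if (length(msg)) msg else TRUE
})

#' Moment-based shape descriptors of a footprint mask
#'
#' @slot areaMm2 footprint area, mm^2.
#' @slot centroid centroid as (row, col) in pixel coordinates.
#' @slot orientation major-axis angle, degrees from the image vertical in
#'   (-90, 90\], positive counterclockwise.
#' @slot eccentricity moment-ellipse eccentricity in \[0, 1\].
#' @slot rectangularity area over principal-axis bounding-box area, (0, 1\].
#' @slot axialAsymmetry normalized area mismatch between the two halves
#'   split by the minor axis through the centroid, \[0, 1\].
#' @name ShapeDescriptors-class
#' @aliases ShapeDescriptors-class
#' @exportClass ShapeDescriptors
setClass("ShapeDescriptors",
  representation(areaMm2 = "numeric", centroid = "numeric",
                 orientation = "numeric", eccentricity = "numeric",
                 rectangularity = "numeric", axialAsymmetry = "numeric"))

setValidity("ShapeDescriptors", function(object) {
  msg <- character()
  vals <- c(object@areaMm2, object@centroid, object@orientation,
            object@eccentricity, object@rectangularity,
            object@axialAsymmetry)
  if (!all(is.finite(vals)))
    msg <- c(msg, "all descriptor fields must be finite")
  if (!isTRUE(object@eccentricity >= 0 && object@eccentricity <= 1))
    msg <- c(msg, "eccentricity must lie in [0, 1]")
  if (!isTRUE(object@rectangularity > 0 && object@rectangularity <= 1))
    msg <- c(msg, "rectangularity must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Average footprint morphology of a replicate set
#'
#' Per-pixel occupancy of centroid-aligned, axis-rotated replicate masks on
#' a common canvas, the majority-vote consensus mask (occupancy >= 0.5,
#' ties included), and the assigned T1-T4 morphology class.
#'
#' @slot occupancy numeric matrix with values in \[0, 1\].
#' @slot consensusMask a [BinaryMask-class].
#' @slot nReplicates number of replicate masks averaged.
#' @slot morphologyClass one of `"T1"`, `"T2"`, `"T3"`, `"T4"`.
#' @name MorphologyProfile-class
#' @aliases MorphologyProfile-class
#' @exportClass MorphologyProfile
setClass("MorphologyProfile",
  representation(occupancy = "matrix", consensusMask = "BinaryMask",
                 nReplicates = "integer", morphologyClass = "character"))

setValidity("MorphologyProfile", function(object) {
  msg <- character()
  if (any(object@occupancy < 0 | object@occupancy > 1))
    msg <- c(msg, "occupancy values must lie in [0, 1]")
  if (!object@morphologyClass %in% c("T1", "T2", "T3", "T4"))
    msg <- c(msg, "morphologyClass must be one of T1-T4")
  if (!isTRUE(object@nReplicates >= 1L))
    msg <- c(msg, "nReplicates must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Logarithmic force-area fit
#'
#' Ordinary least-squares fit of contact area (mm^2) on the natural log of
#' contact force (gf): `area = a * ln(force) + b`.
#'
#' @slot a slope, mm^2 per ln(gf).
#' @slot b intercept, mm^2.
#' @slot r2 coefficient of determination in \[0, 1\].
#' @slot nPoints number of (force, area) points fitted.
#' @name LogFit-class
#' @aliases LogFit-class
#' @exportClass LogFit
setClass("LogFit",
  representation(a = "numeric", b = "numeric", r2 = "numeric",
                 nPoints = "integer"))

setValidity("LogFit", function(object) {
  msg <- character()
  if (!isTRUE(object@r2 >= 0 && object@r2 <= 1))
    msg <- c(msg, "r2 must lie in [0, 1]")
  if (!isTRUE(object@nPoints >= 3L))
    msg <- c(msg, "nPoints must be >= 3")
  if (length(msg)) msg else TRUE
})

#' Full study report
#'
#' The output of [runStudy()]: per-condition summaries (mean, SD,
#' percentage contact area), per-(tip, angle) logarithmic fits,
#' per-image shape descriptors, per-condition average-morphology
#' profiles, and provenance (configuration hash, seed, package version).
#'
#' @slot summaries data.frame of per-condition summaries.
#' @slot fits data.frame of per-(tip, angle) fits.
#' @slot descriptors data.frame of per-image descriptors (may be empty
#'   when the study was run from an area-records table).
#' @slot profiles named list of [MorphologyProfile-class] objects.
#' @slot provenance list with elements `configHash`, `seed`, `version`.
#' @name StudyReport-class
#' @aliases StudyReport-class
#' @exportClass StudyReport
setClass("StudyReport",
  representation(summaries = "data.frame", fits = "data.frame",
                 descriptors = "data.frame", profiles = "list",
                 provenance = "list"))
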