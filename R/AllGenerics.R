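#' @include AllClasses.R
NULL

#' Measure the calibrated area of a footprint
#'
#' @param x a [BinaryMask-class] (or object coercible to one).
#' @param ... further arguments for methods.
#' @return area in mm^2 (foreground pixel count times pixelScale^2).
#' @export
setGeneric("measureArea", function(x, ...) standardGeneric("measureArea"))

#' Binarize a grayscale image into a footprint mask
#'
#' @param x a grayscale matrix in \[0, 1\] or a [ContactPrint-class].
#' @param ... further arguments for methods; see the matrix method.
#' @return a [BinaryMask-class].
#' @export
setGeneric("binarize", function(x, ...) standardGeneric("binarize"))

#' Align a mask: centroid to canvas center, longest axis to vertical
#'
#' @param x a [BinaryMask-class].
#' @param ... further arguments for methods; see the BinaryMask method.
#' @export
setGeneric("alignMask", function(x, ...) standardGeneric("alignMask"))

#' @rdname accessors
#' @export
setGeneric("maskPixels", function(x) standardGeneric("maskPixels"))

#' @rdname accessors
#' @export
setGeneric("pixelScale", function(x) standardGeneric("pixelScale"))

#' @rdname accessors
#' @export
setGeneric("truthArea", function(x) standardGeneric("truthArea"))

#' @rdname accessors
#' @export
setGeneric("condition", function(x) standardGeneric("condition"))

#' @rdname accessors
#' @export
setGeneric("tipShape", function(x) standardGeneric("tipShape"))

#' @rdname accessors
#' @export
setGeneric("occupancy", function(x) standardGeneric("occupancy"))

#' @rdname accessors
#' @export
setGeneric("consensusMask", function(x) standardGeneric("consensusMask"))

#' @rdname accessors
#' @export
setGeneric("morphologyClass", function(x) standardGeneric("morphologyClass"))

#' @rdname accessors
#' @export
setGeneric("slope", function(x) standardGeneric("slope"))

#' @rdname accessors
#' @export
setGeneric("intercept", function(x) standardGeneric("intercept"))

#' @rdname accessors
#' @export
setGeneric("rsquared", function(x) standardGeneric("rsquared"))

#' @rdname accessors
#' @export
setGeneric("summaries", function(x) standardGeneric("summaries"))

#' @rdname accessors
#' @export
setGeneric("fits", function(x) standardGeneric("fits"))

#' @rdname accessors
#' @export
setGeneric("profiles", function(x) standardGeneric("profiles"))

#' @rdname accessors
#' @export
setGeneric("descriptors", function(x) standardGeneric("descriptors"))

#' Accessors for contactprint classes
#'
#' Slot accessors: `maskPixels` (logical/numeric pixel grid), `pixelScale`
#' (mm/px), `truthArea` (generator-known analytic area), `condition`,
#' `tipShape`, `occupancy`, `consensusMask`, `morphologyClass`, `slope`,
#' `intercept`, `rsquared`, and the [StudyReport-class] accessors
#' `summaries`, `fits`, `profiles`, `descriptors`.
#'
#' @param x an object of the documented classes.
#' @name accessors
NULL

setMethod("maskPixels", "BinaryMask", function(x) x@pixels)
setMethod("maskPixels", "ContactPrint", function(x) x@pixels)
setMethod("pixelScale", "BinaryMask", function(x) x@pixelScale)
setMethod("pixelScale", "ContactPrint", function(x) x@pixelScale)
setMethod("truthArea", "ContactPrint", function(x) x@truthArea)
setMethod("condition", "ContactPrint", function(x) x@condition)
setMethod("tipShape", "TipSpec", function(x) x@shape)
setMethod("tipShape", "ContactCondition", function(x) x@tip@shape)
setMethod("tipShape", "ContactPrint", function(x) x@condition@tip@shape)
setMethod("occupancy", "MorphologyProfile", function(x) x@occupancy)
setMethod("consensusMask", "MorphologyProfile", function(x) x@consensusMask)
setMethod("morphologyClass", "MorphologyProfile", function(x) x@morphologyClass)
setMethod("slope", "LogFit", function(x) x@a)
setMethod("intercept", "LogFit", function(x) x@b)
setMethod("rsquared", "LogFit", function(x) x@r2)
setMethod("summaries", "StudyReport", function(x) x@summaries)
setMethod("fits", "StudyReport", function(x) x@fits)
setMethod("profiles", "StudyReport", function(x) x@profiles)
setMethod("descriptors", "StudyReport", function(x) x@descriptors)

setMethod("show", "TipSpec", function(object) {
  cat(sprintf("TipSpec: %s tip, d = %.2f mm, L = %.2f mm, surface = %s mm^2\n",
              object@shape, object@diameter, object@electrodeLength,
              if (is.na(object@surfaceArea)) "derived"
              else format(object@surfaceArea)))
})

setMethod("show", "ContactLaw", function(object) {
  cat(sprintf("ContactLaw: area = %.3f ln(F) + %.3f  (noise CV %.3f)\n",
              object@a, object@b, object@noiseCV))
})

setMethod("show", "ContactCondition", function(object) {
  cat(sprintf("ContactCondition: %s tip, %g deg, %g gf, replicate %d\n",
              object@tip@shape, object@angle, object@force,
              object@replicate))
})

setMethod("show", "ContactPrint", function(object) {
  cat(sprintf("ContactPrint: %d x %d px at %.4g mm/px (%s tip, %g deg, %g gf)\n",
              nrow(object@pixels), ncol(object@pixels), object@pixelScale,
              object@condition@tip@shape, object@condition@angle,
              object@condition@force))
  if (!is.na(object@truthArea))
    cat(sprintf("  analytic footprint area: %.3f mm^2\n", object@truthArea))
})

setMethod("show", "BinaryMask", function(object) {
  cat(sprintf("BinaryMask: %d x %d px at %.4g mm/px, %d foreground px (%.3f mm^2)\n",
              nrow(object@pixels), ncol(object@pixels), object@pixelScale,
              sum(object@pixels), sum(object@pixels) * object@pixelScale^2))
})

setMethod("show", "ShapeDescriptors", function(object) {
  cat(sprintf(paste0("ShapeDescriptors: area %.3f mm^2, orientation %.1f deg, ",
                     "ecc %.3f, rect %.3f, asym %.3f\n"),
              object@areaMm2, object@orientation, object@eccentricity,
              object@rectangularity, object@axialAsymmetry))
})

setMethod("show", "MorphologyProfile", function(object) {
  cat(sprintf("MorphologyProfile: %s, %d replicates, canvas %d x %d px\n",
              object@morphologyClass, object@nReplicates,
              nrow(object@occupancy), ncol(object@occupancy)))
})

setMethod("show", "LogFit", function(object) {
  cat(sprintf("LogFit: area = %.3f ln(force) + %.3f, R^2 = %.3f (n = %d)\n",
              object@a, object@b, object@r2, object@nPoints))
})

setMethod("show", "StudyReport", function(object) {
  cat(sprintf("StudyReport: %d condition summaries, %d fits, %d profiles\n",
              nrow(object@summaries), nrow(object@fits),
              length(object@profiles)))
  cat(sprintf("  seed %s, config %s, contactprint %s\n",
              format(object@provenance$seed),
              substr(object@provenance$configHash, 1, 8),
              format(object@provenance$version)))
})
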