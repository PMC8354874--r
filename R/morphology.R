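#' Construct a binary mask
#'
#' @param pixels logical matrix (TRUE = footprint).
#' @param pixelScale mm per pixel.
#' @return a [BinaryMask-class].
#' @export
BinaryMask <- function(pixels, pixelScale) {
  if (!is.logical(pixels)) {
    storage.mode(pixels) <- "logical"
  }
  new("BinaryMask", pixels = pixels, pixelScale = as.numeric(pixelScale))
}

#' Convert a raster image to grayscale
#'
#' Single-channel input is returned unchanged; 3-channel RGB is collapsed
#' with the luminance weights 0.299, 0.587, 0.114.
#'
#' @param img a matrix, or an array with a trailing channel dimension of
#'   1 or 3 (values in \[0, 1\]).
#' @return a numeric matrix in \[0, 1\].
#' @export
toGrayscale <- function(img) {
  d <- dim(img)
  if (length(d) == 2L) return(img)
  if (length(d) == 3L && d[3] == 1L) return(img[, , 1])
  if (length(d) == 3L && d[3] == 3L)
    return(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
  stop("unsupported channel count: images must have 1 or 3 channels")
}

#' Otsu threshold of a grayscale image
#'
#' Exhaustive maximization of the between-class variance over the 256
#' candidate thresholds k/256, k = 1..255, using the exact partition
#' statistics (per-bin counts and intensity sums, so class means are those
#' of the raw pixel values).  Ties take the lowest threshold.
#'
#' @param gray numeric matrix or vector with values in \[0, 1\].
#' @return scalar threshold in \[0, 1\], or `NA` for a constant image.
#' @export
otsuThreshold <- function(gray) {
  v <- as.numeric(gray)
  if (any(v < 0 | v > 1)) stop("intensities must lie in [0, 1]")
  if (max(v) == min(v)) return(NA_real_)
  nb <- 256L
  bin <- pmin(pmax(ceiling(v * nb), 1L), nb)   # v in ((k-1)/256, k/256]
  cnt <- tabulate(bin, nbins = nb)
  sums <- numeric(nb)
  agg <- rowsum(v, bin)
  sums[as.integer(rownames(agg))] <- agg
  n <- length(v); S <- sum(v)
  n0 <- as.numeric(cumsum(cnt)); s0 <- cumsum(sums)
  n1 <- n - n0; s1 <- S - s0
  ok <- n0 > 0 & n1 > 0
  sigmaB <- rep(-Inf, nb)
  sigmaB[ok] <- n0[ok] * n1[ok] * (s0[ok] / n0[ok] - s1[ok] / n1[ok])^2
  k <- which.max(sigmaB)
  k / nb
}

## Keep only the largest 4-connected foreground component (the print is a
## single region); ties resolve to the lowest label.
largestComponent <- function(mask) {
  if (!any(mask)) return(mask)
  lab <- EBImage::bwlabel(mask)
  counts <- tabulate(lab[lab > 0])
  keep <- which.max(counts)
  lab == keep
}

#' @describeIn binarize Threshold a grayscale matrix.  `method = "otsu"`
#'   (default) uses [otsuThreshold()]; `method = "fixed"` requires
#'   `threshold`.  Foreground is strictly above the threshold; only the
#'   largest connected component is retained.  A constant image yields an
#'   empty mask with a warning.
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold fixed threshold in \[0, 1\] (required iff
#'   `method = "fixed"`).
#' @param pixelScale mm per pixel of the image (matrix method only).
#' @param keepLargest retain only the largest connected component.
#' @export
setMethod("binarize", "matrix", function(x, method = c("otsu", "fixed"),
                                         threshold = NULL, pixelScale = 1,
                                         keepLargest = TRUE) {
  method <- match.arg(method)
  if (any(x < 0 | x > 1)) stop("intensities must lie in [0, 1]")
  if (method == "fixed") {
    if (is.null(threshold)) stop("method = \"fixed\" requires a threshold")
    t <- threshold
  } else {
    t <- otsuThreshold(x)
    if (is.na(t)) {
      warning("constant image: returning an empty mask")
      return(BinaryMask(matrix(FALSE, nrow(x), ncol(x)), pixelScale))
    }
  }
  fg <- x > t
  if (keepLargest) fg <- largestComponent(fg)
  BinaryMask(fg, pixelScale)
})

#' @describeIn binarize Binarize the pixels of a [ContactPrint-class];
#'   the mask inherits the print's pixel scale.
#' @export
setMethod("binarize", "ContactPrint", function(x, ...) {
  binarize(x@pixels, pixelScale = x@pixelScale, ...)
})

#' @describeIn measureArea Foreground pixel count times pixelScale^2.
#' @export
setMethod("measureArea", "BinaryMask", function(x) {
  sum(x@pixels) * x@pixelScale^2
})

## Centroid (row, col) and central second moments of a mask, normalized
## by the pixel count.
maskMoments <- function(pixels) {
  idx <- which(pixels, arr.ind = TRUE)
  n <- nrow(idx)
  if (n < 2L) stop("mask must contain at least 2 foreground pixels")
  r <- idx[, 1]; c <- idx[, 2]
  rbar <- mean(r); cbar <- mean(c)
  dr <- r - rbar; dc <- c - cbar
  list(n = n, centroid = c(rbar, cbar),
       mu20 = mean(dr * dr), mu02 = mean(dc * dc), mu11 = mean(dr * dc),
       dr = dr, dc = dc)
}

#' Principal orientation and eccentricity of a mask
#'
#' The major axis is found from the second central moments:
#' `theta = 0.5 * atan2(2*mu11, mu20 - mu02)` (mu20 taken along image
#' rows), reported in degrees from the image vertical in (-90, 90\],
#' positive counterclockwise.  Eccentricity comes from the moment-ellipse
#' eigenvalues.  Shapes with eccentricity below `eccMin` have no
#' meaningful longest axis and report orientation 0.
#'
#' @param mask a [BinaryMask-class] with >= 2 foreground pixels.
#' @param eccMin rotational-ambiguity cutoff (default 0.1).
#' @return list with elements `orientation` (degrees) and `eccentricity`.
#' @export
principalOrientation <- function(mask, eccMin = 0.1) {
  stopifnot(is(mask, "BinaryMask"))
  m <- maskMoments(mask@pixels)
  ecc <- momentEccentricity(m)
  theta <- 0.5 * atan2(2 * m$mu11, m$mu20 - m$mu02) * 180 / pi
  if (theta <= -90) theta <- theta + 180
  if (theta > 90) theta <- theta - 180
  if (ecc < eccMin) theta <- 0
  list(orientation = theta, eccentricity = ecc)
}

momentEccentricity <- function(m) {
  tr <- m$mu20 + m$mu02
  det <- sqrt(((m$mu20 - m$mu02) / 2)^2 + m$mu11^2)
  lmax <- tr / 2 + det
  lmin <- tr / 2 - det
  if (lmax <= 0) return(0)
  sqrt(pmax(1 - lmin / lmax, 0))
}

#' Moment-based shape descriptors of a footprint mask
#'
#' Computes area, centroid, principal orientation, eccentricity,
#' rectangularity (area over the bounding box taken along the principal
#' axes, so the descriptor is rotation-invariant) and axial asymmetry
#' (the fraction of footprint pixels whose mirror image across the minor
#' axis through the centroid falls outside the footprint).
#'
#' @param mask a [BinaryMask-class] with >= 2 foreground pixels.
#' @param eccMin rotational-ambiguity cutoff passed to
#'   [principalOrientation()].
#' @return a [ShapeDescriptors-class].
#' @export
shapeDescriptors <- function(mask, eccMin = 0.1) {
  stopifnot(is(mask, "BinaryMask"))
  m <- maskMoments(mask@pixels)
  po <- principalOrientation(mask, eccMin = eccMin)
  theta <- 0.5 * atan2(2 * m$mu11, m$mu20 - m$mu02)  # radians, unclamped
  ## principal-frame coordinates of the foreground pixels
  u <- cos(theta) * m$dr + sin(theta) * m$dc
  v <- -sin(theta) * m$dr + cos(theta) * m$dc
  bbox <- (diff(range(u)) + 1) * (diff(range(v)) + 1)
  rect <- min(m$n / bbox, 1)
  ## mirror each pixel across the minor axis (u -> -u), map back to the
  ## pixel grid, and count mirrors that miss the footprint
  mr <- round(m$centroid[1] + cos(theta) * (-u) - sin(theta) * v)
  mc <- round(m$centroid[2] + sin(theta) * (-u) + cos(theta) * v)
  inside <- mr >= 1 & mr <= nrow(mask@pixels) &
            mc >= 1 & mc <= ncol(mask@pixels)
  hit <- logical(m$n)
  hit[inside] <- mask@pixels[cbind(mr[inside], mc[inside])]
  asym <- 1 - sum(hit) / m$n
  new("ShapeDescriptors",
      areaMm2 = measureArea(mask), centroid = m$centroid,
      orientation = po$orientation, eccentricity = po$eccentricity,
      rectangularity = rect, axialAsymmetry = asym)
}

#' @describeIn alignMask Translate the centroid to the canvas center and
#'   rotate the mask about it so the longest axis is vertical
#'   (nearest-neighbour resampling, which preserves binarity; rotation is
#'   skipped for rotationally ambiguous shapes with eccentricity below
#'   `eccMin`).  The residual 180-degree ambiguity is resolved by placing
#'   the half with the larger area toward the bottom of the canvas.
#' @param canvas output canvas c(rows, cols); defaults to the input size.
#' @param eccMin rotational-ambiguity cutoff (default 0.1).
#' @return a [BinaryMask-class] on `canvas`; area is preserved within 2%.
#' @export
setMethod("alignMask", "BinaryMask", function(x, canvas = dim(x@pixels),
                                              eccMin = 0.1) {
  m <- maskMoments(x@pixels)
  po <- principalOrientation(x, eccMin = eccMin)
  theta <- if (po$eccentricity < eccMin) 0 else po$orientation * pi / 180
  rows <- as.integer(canvas[1]); cols <- as.integer(canvas[2])
  ## forward-map the foreground to check the canvas is large enough
  uu <- cos(theta) * m$dr + sin(theta) * m$dc
  vv <- -sin(theta) * m$dr + cos(theta) * m$dc
  if (max(abs(uu)) > (rows - 1) / 2 || max(abs(vv)) > (cols - 1) / 2)
    stop("canvas too small to hold the aligned footprint")
  cr <- (rows + 1) / 2; cc <- (cols + 1) / 2
  ## inverse mapping: output pixel -> source pixel (nearest neighbour)
  dr <- seq_len(rows) - cr
  dc <- seq_len(cols) - cc
  srcR <- round(m$centroid[1] +
                outer(dr, dc, function(r, c) cos(theta) * r - sin(theta) * c))
  srcC <- round(m$centroid[2] +
                outer(dr, dc, function(r, c) sin(theta) * r + cos(theta) * c))
  ok <- srcR >= 1 & srcR <= nrow(x@pixels) & srcC >= 1 & srcC <= ncol(x@pixels)
  out <- matrix(FALSE, rows, cols)
  out[ok] <- x@pixels[cbind(srcR[ok], srcC[ok])]
  ## canonical pose: larger-area half toward the canvas bottom
  if (po$eccentricity >= eccMin) {
    rowsFg <- which(out, arr.ind = TRUE)[, 1]
    below <- sum(rowsFg > cr); above <- sum(rowsFg < cr)
    if (above - below > 0.02 * length(rowsFg))
      out <- out[rows:1, cols:1]
  }
  BinaryMask(out, x@pixelScale)
})

#' Average morphology of a replicate set
#'
#' Each mask is centroid-aligned and axis-rotated onto a common canvas
#' ([alignMask()]); the occupancy map is the per-pixel mean of the aligned
#' masks and the consensus mask keeps pixels with occupancy >= 0.5 (ties
#' included).  The profile's morphology class is the classification of
#' the consensus mask.
#'
#' @param masks list of [BinaryMask-class] objects with a shared pixel
#'   scale.
#' @param canvas common canvas c(rows, cols); default is the largest
#'   input padded by 25%.
#' @param eccMin rotational-ambiguity cutoff passed to [alignMask()].
#' @param ... classification thresholds passed to [classifyMorphology()].
#' @return a [MorphologyProfile-class].
#' @export
averageMorphology <- function(masks, canvas = NULL, eccMin = 0.1, ...) {
  if (length(masks) == 0) stop("masks must contain at least one mask")
  scales <- vapply(masks, function(m) m@pixelScale, numeric(1))
  if (diff(range(scales)) > 1e-12)
    stop("all masks must share the same pixel scale")
  if (is.null(canvas)) {
    dims <- vapply(masks, function(m) dim(m@pixels), integer(2))
    canvas <- as.integer(ceiling(apply(dims, 1, max) * 1.25))
  }
  acc <- matrix(0, canvas[1], canvas[2])
  for (m in masks)
    acc <- acc + alignMask(m, canvas = canvas, eccMin = eccMin)@pixels
  occ <- acc / length(masks)
  consensus <- BinaryMask(occ >= 0.5, scales[1])
  cls <- classifyMask(consensus, eccMin = eccMin, ...)
  new("MorphologyProfile", occupancy = occ, consensusMask = consensus,
      nReplicates = length(masks), morphologyClass = cls)
}

#' Classify a footprint into the four morphology types
#'
#' Decision rule on [shapeDescriptors()]: eccentricity below `eccCircular`
#' is circular (`T3`); otherwise rectangularity above `rectMin` is
#' rectangular (`T1`); otherwise axial asymmetry above `asymMin` is
#' semi-ellipsoidal (`T2`); anything else is ellipsoidal (`T4`).
#'
#' @param x a [ShapeDescriptors-class].
#' @param eccCircular circularity cutoff (default 0.3).
#' @param rectMin rectangularity cutoff (default 0.9).
#' @param asymMin asymmetry cutoff (default 0.15).
#' @return one of `"T1"`, `"T2"`, `"T3"`, `"T4"`.
#' @export
classifyMorphology <- function(x, eccCircular = 0.3, rectMin = 0.9,
                               asymMin = 0.15) {
  stopifnot(is(x, "ShapeDescriptors"))
  if (x@eccentricity < eccCircular) return("T3")
  if (x@rectangularity > rectMin) return("T1")
  if (x@axialAsymmetry > asymMin) return("T2")
  "T4"
}

#' @rdname classifyMorphology
#' @param mask a [BinaryMask-class] to describe and classify in one step.
#' @param eccMin rotational-ambiguity cutoff for the descriptors.
#' @param ... thresholds passed on to `classifyMorphology`.
#' @export
classifyMask <- function(mask, eccMin = 0.1, ...) {
  classifyMorphology(shapeDescriptors(mask, eccMin = eccMin), ...)
}

#' Read a contact-print image from disk
#'
#' Reads 8- or 16-bit grayscale/RGB PNG or TIFF and converts to a
#' grayscale matrix in \[0, 1\].
#'
#' @param path image path (`.png`, `.tif`, `.tiff`).
#' @return numeric matrix in \[0, 1\].
#' @export
readContactImage <- function(path) {
  img <- if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    tiff::readTIFF(path)
  else
    png::readPNG(path)
  toGrayscale(img)
}
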