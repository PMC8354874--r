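#' Construct a contact condition
#'
#' @param tip a [TipSpec-class].
#' @param angle contact angle in degrees, within \[0, 90\].
#' @param force contact force in gf.
#' @param replicate replicate index (>= 1).
#' @return a [ContactCondition-class].
#' @export
ContactCondition <- function(tip, angle, force, replicate = 1L) {
  new("ContactCondition", tip = tip, angle = as.numeric(angle),
      force = as.numeric(force), replicate = as.integer(replicate))
}

#' Study grids of contact angles and forces
#'
#' The contact angles (0, 30, 45, 60, 90 degrees) and contact forces
#' (2, 4, 6, 10, 15, 20, 30, 40 gf) of the study design.
#'
#' @return numeric vector.
#' @export
studyAngles <- function() c(0, 30, 45, 60, 90)

#' @rdname studyAngles
#' @export
studyForces <- function() c(2, 4, 6, 10, 15, 20, 30, 40)

#' Footprint morphology class implied by tip shape and contact angle
#'
#' The four footprint types: `T1` rectangular (flat tip lying parallel,
#' 0 degrees), `T2` semi-ellipsoidal (round tip at 0 degrees), `T3`
#' circular (either tip perpendicular, 90 degrees), `T4` ellipsoidal
#' (either tip at an intermediate angle).
#'
#' @param tipShape `"flat"`, `"round"`, or a [TipSpec-class].
#' @param angle contact angle in degrees, within \[0, 90\].
#' @return one of `"T1"`, `"T2"`, `"T3"`, `"T4"`.
#' @examples
#' footprintClass("flat", 0)    # "T1"
#' footprintClass("round", 90)  # "T3"
#' @export
footprintClass <- function(tipShape, angle) {
  if (is(tipShape, "TipSpec")) tipShape <- tipShape@shape
  stopifnot(tipShape %in% c("flat", "round"))
  if (!is.finite(angle) || angle < 0 || angle > 90)
    stop("angle must lie in [0, 90] degrees")
  if (angle == 90) return("T3")
  if (angle == 0) return(if (tipShape == "flat") "T1" else "T2")
  "T4"
}

#' Human-readable names of the four morphology classes
#' @return named character vector.
#' @export
morphologyLabels <- function() {
  c(T1 = "rectangular", T2 = "semi-ellipsoidal",
    T3 = "circular", T4 = "ellipsoidal")
}

## Evaluate code under a temporary RNG seed, restoring global RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Solved footprint geometry for one class/area; lengths in mm.
## Returns a membership closure over principal-frame coordinates
## (u along the major/length direction, positive = down-canvas; v across)
## plus the analytic extents used for fit checks.
footprintGeometry <- function(class, area, tip, angle) {
  d <- tip@diameter
  switch(class,
    T1 = {
      len <- area / d
      if (len >= d) w <- d
      else {                       # small print: keep a 2:1 template
        len <- sqrt(2 * area)
        w <- len / 2
      }
      list(extentU = len, extentV = w,
           member = function(u, v) abs(u) <= len / 2 & abs(v) <= w / 2)
    },
    T3 = {
      r <- sqrt(area / pi)
      list(extentU = 2 * r, extentV = 2 * r,
           member = function(u, v) u * u + v * v <= r * r)
    },
    T4 = {
      ## inclined-tip projection template: aspect 1/sin(angle), minor
      ## capped at the tip diameter once the print has grown to it
      kappa <- 1 / sin(angle * pi / 180)
      bm <- sqrt(area / (pi * kappa))
      if (2 * bm > d) {
        bm <- d / 2
        am <- area / (pi * bm)
      } else am <- kappa * bm
      list(extentU = 2 * am, extentV = 2 * bm,
           member = function(u, v) (u / am)^2 + (v / bm)^2 <= 1)
    },
    T2 = {
      ## half-ellipse, flat cut along the minor axis; width = tip diameter
      bm <- d / 2
      h <- 2 * area / (pi * bm)   # extent along the cut direction
      if (h < 3 * bm) {           # small print: keep a 3:1 template
        bm <- sqrt(2 * area / (3 * pi))
        h <- 3 * bm
      }
      list(extentU = h, extentV = 2 * bm,
           ## bounding-box centred: flat edge at u = h/2 (bottom), cap up
           member = function(u, v) {
             up <- h / 2 - u
             up >= 0 & up <= h & (up / h)^2 + (v / bm)^2 <= 1
           })
    },
    stop("unknown footprint class: ", class))
}

#' Render one synthetic contact print
#'
#' Draws the footprint class implied by the condition's tip shape and
#' angle, with dimensions solved so that the analytic shape area equals
#' `targetArea(law, force) * (1 + eps)`, `eps ~ Normal(0, noiseCV)` drawn
#' deterministically from `seed`.  The fixed transverse dimension defaults
#' to the tip diameter; when the solved length would fall below it, the
#' dimensions scale isotropically from a class template so the print keeps
#' its characteristic elongation.  A small replicate pose jitter (rotation
#' up to `jitterRotation` degrees, centroid offset up to `jitterOffset`
#' pixels) emulates print-to-print placement variability; foreground
#' intensity is 0.9, background 0.1, with additive Gaussian pixel noise
#' (SD `intensityNoise`) clipped to \[0, 1\].
#'
#' @param condition a [ContactCondition-class].
#' @param law a [ContactLaw-class] for this (tip, angle).
#' @param pixelScale mm per pixel.
#' @param canvas canvas size, c(rows, cols) pixels.
#' @param seed integer seed; identical inputs give bit-identical prints.
#' @param jitterRotation max |rotation| jitter, degrees.
#' @param jitterOffset max |centroid offset| jitter, pixels.
#' @param intensityNoise SD of additive pixel noise.
#' @return a [ContactPrint-class] whose `truthArea` is the analytic
#'   post-noise area in mm^2.
#' @examples
#' p <- renderFootprint(ContactCondition(roundTip(), 90, 10),
#'                      ContactLaw(2.341, 2.709), seed = 1)
#' truthArea(p)
#' @export
renderFootprint <- function(condition, law, pixelScale = 0.02,
                            canvas = c(512L, 512L), seed = 1L,
                            jitterRotation = 5, jitterOffset = 5,
                            intensityNoise = 0.05) {
  stopifnot(is(condition, "ContactCondition"), is(law, "ContactLaw"))
  validObject(condition)
  withSeed(seed, {
    eps <- if (law@noiseCV > 0) stats::rnorm(1, 0, law@noiseCV) else 0
    area <- targetArea(law, condition@force) * (1 + eps)
    if (area <= 0)
      stop("replicate noise drew a non-positive area")
    theta <- if (jitterRotation > 0)
      stats::runif(1, -jitterRotation, jitterRotation) * pi / 180 else 0
    off <- if (jitterOffset > 0)
      stats::runif(2, -jitterOffset, jitterOffset) else c(0, 0)

    cls <- footprintClass(condition@tip, condition@angle)
    geo <- footprintGeometry(cls, area, condition@tip, condition@angle)
    if (min(geo$extentU, geo$extentV) / pixelScale < 50)
      warning("footprint spans fewer than 50 pixels along its shortest axis")

    rows <- canvas[1]; cols <- canvas[2]
    cr <- (rows + 1) / 2 + off[1]
    cc <- (cols + 1) / 2 + off[2]
    dr <- (seq_len(rows) - cr) * pixelScale        # mm, down-canvas
    dc <- (seq_len(cols) - cc) * pixelScale
    ## principal-frame coordinates: rotate by -theta
    u <- outer(dr, dc, function(r, c)  cos(theta) * r + sin(theta) * c)
    v <- outer(dr, dc, function(r, c) -sin(theta) * r + cos(theta) * c)
    member <- geo$member(u, v)
    half <- sqrt(geo$extentU^2 + geo$extentV^2) / 2 / pixelScale
    if (half + max(abs(off)) > min(rows, cols) / 2 ||
        any(member[1, ]) || any(member[rows, ]) ||
        any(member[, 1]) || any(member[, cols]))
      stop("footprint does not fit on the canvas")

    img <- matrix(0.1, rows, cols)
    img[member] <- 0.9
    if (intensityNoise > 0)
      img <- img + matrix(stats::rnorm(rows * cols, 0, intensityNoise),
                          rows, cols)
    img <- pmin(pmax(img, 0), 1)
    new("ContactPrint", pixels = img, pixelScale = pixelScale,
        condition = condition, truthArea = area)
  })
}

## Per-image seed derived from the dataset seed and the image index;
## kept below 2^31 - 1.
imageSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 16807) %% 2147483647)
}

#' Generate a synthetic contact-print dataset
#'
#' Renders `replicates` prints for every combination of tip, angle and
#' force for which a ground-truth law is supplied, and returns the prints
#' together with a manifest (one row per image).  The full default grid
#' (2 tips x 5 angles x 8 forces x 6 replicates) yields 480 images.
#'
#' @param laws nested list `laws[[tipShape]][[as.character(angle)]]` of
#'   [ContactLaw-class] objects, e.g. [defaultLaws()].
#' @param tips list of [TipSpec-class] objects.
#' @param angles contact angles, degrees.
#' @param forces contact forces, gf.
#' @param replicates replicates per condition (>= 1).
#' @param pixelScale mm per pixel.
#' @param canvas canvas size, pixels.
#' @param seed integer dataset seed; each image gets a seed derived from
#'   it, so identical inputs give a byte-identical dataset and manifest.
#' @param render if `FALSE`, skip pixel rendering (prints are `NULL`) but
#'   still draw the per-replicate areas; the manifest is identical to the
#'   rendered one.  Useful for fast law-recovery simulations.
#' @param outDir optional directory; when given, each print is written as
#'   an 8-bit grayscale PNG and the manifest as `manifest.csv`.
#' @param ... passed to [renderFootprint()].
#' @return list with `prints` (list of [ContactPrint-class] or `NULL`s)
#'   and `manifest` (data.frame with columns `file`, `tip`, `angle_deg`,
#'   `force_gf`, `replicate`, `truth_area_mm2`, `pixel_scale_mm_per_px`,
#'   `seed`).
#' @examples
#' ds <- generateDataset(defaultLaws(noiseCV = 0), tips = list(roundTip()),
#'                       angles = 90, forces = c(2, 10), replicates = 1,
#'                       seed = 7)
#' ds$manifest
#' @export
generateDataset <- function(laws, tips = list(flatTip(), roundTip()),
                            angles = studyAngles(), forces = studyForces(),
                            replicates = 6L, pixelScale = 0.02,
                            canvas = c(512L, 512L), seed = 1L,
                            render = TRUE, outDir = NULL, ...) {
  stopifnot(replicates >= 1)
  prints <- list()
  rowsL <- list()
  idx <- 0L
  for (tip in tips) for (angle in angles) {
    law <- laws[[tip@shape]][[as.character(angle)]]
    if (is.null(law))
      stop(sprintf("no ground-truth law for (%s, %g deg)", tip@shape, angle))
    for (force in forces) for (rep in seq_len(replicates)) {
      idx <- idx + 1L
      iseed <- imageSeed(seed, idx)
      cond <- ContactCondition(tip, angle, force, rep)
      file <- sprintf("%s_a%02d_f%02d_r%d.png", tip@shape, angle, force, rep)
      if (render) {
        p <- renderFootprint(cond, law, pixelScale = pixelScale,
                             canvas = canvas, seed = iseed, ...)
        ta <- p@truthArea
        prints[[idx]] <- p
      } else {
        ta <- withSeed(iseed, {
          eps <- if (law@noiseCV > 0) stats::rnorm(1, 0, law@noiseCV) else 0
          a <- targetArea(law, force) * (1 + eps)
          if (a <= 0) stop("replicate noise drew a non-positive area")
          a
        })
        prints[idx] <- list(NULL)
      }
      rowsL[[idx]] <- data.frame(
        file = file, tip = tip@shape, angle_deg = angle, force_gf = force,
        replicate = rep, truth_area_mm2 = ta,
        pixel_scale_mm_per_px = pixelScale, seed = iseed,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rowsL)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    if (render)
      for (i in seq_along(prints))
        png::writePNG(prints[[i]]@pixels,
                      file.path(outDir, manifest$file[i]))
    utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(prints = prints, manifest = manifest)
}
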