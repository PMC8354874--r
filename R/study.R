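#' Default study configuration
#'
#' Thresholds and switches used by [runStudy()]: binarization method and
#' optional fixed threshold, the rotational-ambiguity cutoff `eccMin`,
#' the classification thresholds (`eccCircular`, `rectMin`, `asymMin`),
#' and whether fits use per-force mean areas.
#'
#' @param ... overrides of the defaults.
#' @return named list.
#' @export
studyConfig <- function(...) {
  cfg <- list(binarizeMethod = "otsu", threshold = NULL, eccMin = 0.1,
              eccCircular = 0.3, rectMin = 0.9, asymMin = 0.15,
              fitOnMeans = TRUE)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

configHash <- function(config, seed) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(c(deparse(config[order(names(config))]), format(seed)), f)
  unname(tools::md5sum(f))
}

#' Run the full contact-print study pipeline
#'
#' For image input, every print is binarized, its area and shape
#' descriptors measured, and each (tip, angle, force) condition is
#' combined into an average-morphology profile; per (tip, angle) the
#' replicate areas are aggregated and the logarithmic force-area model
#' fitted.  For an area-records table (no images), only the aggregation
#' and fits are produced.
#'
#' @param x one of: the list returned by [generateDataset()] (`prints` +
#'   `manifest`); a manifest data.frame whose `file` column names images
#'   under `imagesDir`; or a records data.frame with columns `tip`,
#'   `angle_deg`, `force_gf`, `replicate` and `area_mm2` /
#'   `avg_area_mm2`.
#' @param imagesDir directory holding the manifest's images.
#' @param config list from [studyConfig()].
#' @param seed seed recorded in the provenance (the pipeline itself is
#'   deterministic).
#' @return a [StudyReport-class].
#' @export
runStudy <- function(x, imagesDir = NULL, config = studyConfig(),
                     seed = NA_integer_) {
  recordsOnly <- is.data.frame(x) && !("file" %in% names(x))
  if (recordsOnly) {
    acol <- intersect(c("area_mm2", "avg_area_mm2", "mean_area_mm2"),
                      names(x))[1]
    if (is.na(acol)) stop("records input needs an area column")
    rec <- x
    if (!"replicate" %in% names(rec)) rec$replicate <- 1L
    rec$area_mm2 <- rec[[acol]]
    descriptors <- data.frame()
    profs <- list()
  } else {
    if (is.data.frame(x)) {
      if (nrow(x) == 0) stop("empty manifest")
      if (is.null(imagesDir)) stop("manifest input requires imagesDir")
      missing <- !file.exists(file.path(imagesDir, x$file))
      if (any(missing))
        stop("missing image file(s): ",
             paste(utils::head(x$file[missing], 3), collapse = ", "))
      manifest <- x
      getPixels <- function(i)
        readContactImage(file.path(imagesDir, manifest$file[i]))
      scales <- manifest$pixel_scale_mm_per_px
    } else if (is.list(x) && !is.null(x$manifest)) {
      manifest <- x$manifest
      if (nrow(manifest) == 0) stop("empty manifest")
      if (any(vapply(x$prints, is.null, logical(1))))
        stop("dataset contains unrendered prints (render = FALSE?)")
      getPixels <- function(i) x$prints[[i]]@pixels
      scales <- vapply(x$prints, function(p) p@pixelScale, numeric(1))
    } else stop("unsupported input to runStudy()")

    n <- nrow(manifest)
    masks <- vector("list", n)
    drows <- vector("list", n)
    for (i in seq_len(n)) {
      mask <- binarize(getPixels(i), method = config$binarizeMethod,
                       threshold = config$threshold,
                       pixelScale = scales[i])
      d <- shapeDescriptors(mask, eccMin = config$eccMin)
      cls <- classifyMorphology(d, eccCircular = config$eccCircular,
                                rectMin = config$rectMin,
                                asymMin = config$asymMin)
      masks[[i]] <- mask
      drows[[i]] <- data.frame(
        file = manifest$file[i], tip = manifest$tip[i],
        angle_deg = manifest$angle_deg[i], force_gf = manifest$force_gf[i],
        replicate = manifest$replicate[i], area_mm2 = d@areaMm2,
        centroid_row = d@centroid[1], centroid_col = d@centroid[2],
        orientation_deg = d@orientation, eccentricity = d@eccentricity,
        rectangularity = d@rectangularity,
        axial_asymmetry = d@axialAsymmetry, class = cls,
        stringsAsFactors = FALSE)
    }
    descriptors <- do.call(rbind, drows)
    rec <- descriptors[, c("tip", "angle_deg", "force_gf", "replicate",
                           "area_mm2")]
    key <- interaction(descriptors$tip, descriptors$angle_deg,
                       descriptors$force_gf, drop = TRUE)
    profs <- list()
    for (grp in split(seq_len(n), key)) {
      nm <- sprintf("%s_a%02d_f%02d", descriptors$tip[grp[1]],
                    descriptors$angle_deg[grp[1]],
                    descriptors$force_gf[grp[1]])
      profs[[nm]] <- averageMorphology(
        masks[grp], eccMin = config$eccMin,
        eccCircular = config$eccCircular, rectMin = config$rectMin,
        asymMin = config$asymMin)
    }
    profs <- profs[order(names(profs))]
  }

  summ <- aggregateAreas(rec)
  summ$below_six <- summ$n < 6L
  fitsTab <- fitByCondition(rec, onMeans = config$fitOnMeans)
  new("StudyReport", summaries = summ, fits = fitsTab,
      descriptors = descriptors, profiles = profs,
      provenance = list(configHash = configHash(config, seed), seed = seed,
                        version = as.character(utils::packageVersion("contactprint"))))
}

round3 <- function(x) round(x, 3)

#' Export a study report to disk
#'
#' Writes `summary.csv` (per-condition means, SD, integer percentage
#' contact area), `fits.csv` (per-(tip, angle) coefficients to 3
#' decimals), `descriptors.csv`, per-condition occupancy and consensus
#' PNGs, and `run_log.txt`.  Re-running on identical inputs reproduces
#' every file byte for byte.
#'
#' @param report a [StudyReport-class].
#' @param outDir output directory (created if needed).
#' @return character vector of the files written, invisibly.
#' @export
exportReport <- function(report, outDir) {
  stopifnot(is(report, "StudyReport"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(outDir, 2) != 0) stop("output directory is not writable")
  files <- character()
  w <- function(df, name) {
    path <- file.path(outDir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  s <- report@summaries
  s$mean_area_mm2 <- round3(s$mean_area_mm2)
  s$sd_area_mm2 <- round3(s$sd_area_mm2)
  s$pca_pct <- round(s$mean_pca_pct)
  s$mean_pca_pct <- NULL
  w(s, "summary.csv")
  f <- report@fits
  f$a <- round3(f$a); f$b <- round3(f$b); f$r2 <- round3(f$r2)
  w(f, "fits.csv")
  if (nrow(report@descriptors)) {
    d <- report@descriptors
    num <- vapply(d, is.numeric, logical(1))
    d[num] <- lapply(d[num], function(col) signif(col, 7))
    w(d, "descriptors.csv")
  }
  for (nm in names(report@profiles)) {
    prof <- report@profiles[[nm]]
    op <- file.path(outDir, sprintf("occupancy_%s.png", nm))
    png::writePNG(prof@occupancy, op)
    cp <- file.path(outDir, sprintf("consensus_%s.png", nm))
    png::writePNG(prof@consensusMask@pixels * 1.0, cp)
    files <- c(files, op, cp)
  }
  logPath <- file.path(outDir, "run_log.txt")
  writeLines(c(
    sprintf("contactprint version: %s", report@provenance$version),
    sprintf("config hash: %s", report@provenance$configHash),
    sprintf("seed: %s", format(report@provenance$seed)),
    sprintf("conditions summarized: %d", nrow(report@summaries)),
    sprintf("fits: %d (%d fitted)", nrow(report@fits),
            sum(report@fits$fitted)),
    sprintf("morphology profiles: %d", length(report@profiles))), logPath)
  files <- c(files, logPath)
  invisible(files)
}
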