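#' Construct a force-area ground-truth law
#'
#' @param a slope, mm^2 per ln(gf).
#' @param b intercept, mm^2.
#' @param noiseCV coefficient of variation of replicate areas (>= 0).
#' @return a [ContactLaw-class].
#' @examples
#' targetArea(ContactLaw(2.685, 7.782), 10)
#' @export
ContactLaw <- function(a, b, noiseCV = 0) {
  new("ContactLaw", a = as.numeric(a), b = as.numeric(b),
      noiseCV = as.numeric(noiseCV))
}

#' Noise-free target footprint area under a law
#'
#' Evaluates `a * ln(force) + b` for a contact force in gf.
#'
#' @param law a [ContactLaw-class].
#' @param force contact force in gf (> 0); vectorized.
#' @return area in mm^2; errors if any force or resulting area is
#'   non-positive.
#' @examples
#' targetArea(ContactLaw(2.685, 7.782), 1)    # = b
#' targetArea(ContactLaw(2.685, 7.782), 10)   # 13.965
#' @export
targetArea <- function(law, force) {
  stopifnot(is(law, "ContactLaw"))
  if (any(!is.finite(force)) || any(force <= 0))
    stop("force must be finite and > 0 gf")
  area <- law@a * log(force) + law@b
  if (any(area <= 0))
    stop(sprintf("law predicts non-positive area (%.3f mm^2) at force %g gf",
                 min(area), force[which.min(area)]))
  area
}

#' Published per-condition area tables
#'
#' The bundled plain-text transcriptions of the published mean contact
#' areas: per tip shape, contact angle and contact force, the mean area of
#' 6 replicates (mm^2), its standard deviation, and the reported integer
#' percentage contact area.
#'
#' @param tip `"flat"`, `"round"`, or `"both"` (default).
#' @return data.frame with columns `tip`, `angle_deg`, `force_gf`,
#'   `avg_area_mm2`, `sd_mm2`, `pca_pct`.
#' @export
paperAreaTable <- function(tip = c("both", "flat", "round")) {
  tip <- match.arg(tip)
  rd <- function(f) utils::read.csv(
    system.file("extdata", f, package = "contactprint"),
    stringsAsFactors = FALSE)
  out <- rbind(rd("table1_flat.csv"), rd("table2_round.csv"))
  if (tip != "both") out <- out[out$tip == tip, ]
  rownames(out) <- NULL
  out
}

#' Published per-(tip, angle) logarithmic fit coefficients
#'
#' @return data.frame with columns `tip`, `angle_deg`, `a`, `b`, `r2`.
#' @export
paperFitTable <- function() {
  utils::read.csv(system.file("extdata", "table3_fits.csv",
                              package = "contactprint"),
                  stringsAsFactors = FALSE)
}

#' Default ground-truth laws for the synthetic generator
#'
#' One [ContactLaw-class] per (tip shape, contact angle), taken from the
#' published logarithmic fit coefficients, with a common replicate-noise
#' coefficient of variation (default 0.08, matching the SD/mean ratios of
#' the published replicate tables).
#'
#' @param noiseCV replicate-noise CV applied to every law.
#' @return nested named list `laws[[tip]][[as.character(angle)]]`.
#' @examples
#' laws <- defaultLaws(noiseCV = 0)
#' targetArea(laws$flat[["0"]], 2)
#' @export
defaultLaws <- function(noiseCV = 0.08) {
  tab <- paperFitTable()
  laws <- list()
  for (i in seq_len(nrow(tab))) {
    tip <- tab$tip[i]
    ang <- as.character(tab$angle_deg[i])
    if (is.null(laws[[tip]])) laws[[tip]] <- list()
    laws[[tip]][[ang]] <- ContactLaw(tab$a[i], tab$b[i], noiseCV)
  }
  laws
}

#' Read ground-truth laws from a JSON or YAML file
#'
#' The file maps tip shape to angle to coefficients:
#' `{"flat": {"0": {"a": 2.685, "b": 7.782, "noise_cv": 0.08}, ...}, ...}`
#' (`noise_cv` optional, default 0).
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return nested named list `laws[[tip]][[angle]]` of
#'   [ContactLaw-class] objects.
#' @export
readLaws <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  else
    yaml::read_yaml(path)
  lapply(raw, function(byAngle) {
    lapply(byAngle, function(cf) {
      ContactLaw(cf$a, cf$b,
                 if (is.null(cf$noise_cv)) 0 else cf$noise_cv)
    })
  })
}

#' Write ground-truth laws to a JSON file
#'
#' @param laws nested list as returned by [defaultLaws()] or [readLaws()].
#' @param path output path ending in `.json`.
#' @return `path`, invisibly.
#' @export
writeLaws <- function(laws, path) {
  raw <- lapply(laws, function(byAngle) {
    lapply(byAngle, function(l)
      list(a = l@a, b = l@b, noise_cv = l@noiseCV))
  })
  jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
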