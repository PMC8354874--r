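#' Per-condition aggregation of replicate areas
#'
#' Mean and sample standard deviation (n-1 denominator) of the replicate
#' contact areas per (tip, angle, force), plus the mean percentage
#' contact area computed from the mean area and the tip electrode surface
#' area.  Conditions with a single replicate report SD 0 and are flagged.
#'
#' @param records data.frame with columns `tip`, `angle_deg`, `force_gf`,
#'   `replicate`, `area_mm2`.
#' @param tipAreas named numeric vector mapping tip shape to electrode
#'   surface area in mm^2; defaults to the published constants.
#' @return data.frame with columns `tip`, `angle_deg`, `force_gf`,
#'   `mean_area_mm2`, `sd_area_mm2`, `mean_pca_pct`, `n`,
#'   `single_replicate`.
#' @examples
#' rec <- data.frame(tip = "flat", angle_deg = 0, force_gf = 2,
#'                   replicate = 1:3, area_mm2 = c(1, 2, 3))
#' aggregateAreas(rec)   # mean 2, SD 1
#' @export
aggregateAreas <- function(records,
                           tipAreas = c(flat = tipSurfaceArea(flatTip()),
                                        round = tipSurfaceArea(roundTip()))) {
  need <- c("tip", "angle_deg", "force_gf", "replicate", "area_mm2")
  if (!is.data.frame(records) || nrow(records) == 0)
    stop("records must be a non-empty data.frame")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  key <- interaction(records$tip, records$angle_deg, records$force_gf,
                     drop = TRUE)
  parts <- split(records, key)
  out <- do.call(rbind, lapply(parts, function(g) {
    n <- nrow(g)
    m <- mean(g$area_mm2)
    s <- if (n > 1) stats::sd(g$area_mm2) else 0
    data.frame(tip = g$tip[1], angle_deg = g$angle_deg[1],
               force_gf = g$force_gf[1], mean_area_mm2 = m, sd_area_mm2 = s,
               mean_pca_pct = percentageContactArea(m, tipAreas[[g$tip[1]]]),
               n = n, single_replicate = n == 1,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$tip, out$angle_deg, out$force_gf), ]
  rownames(out) <- NULL
  out
}

#' Fit the logarithmic force-area model
#'
#' Ordinary least squares of contact area on the natural log of contact
#' force: `area = a * ln(force) + b`, with the coefficient of
#' determination `R^2 = 1 - SSres/SStot`.
#'
#' @param force contact forces in gf (> 0), or a data.frame with columns
#'   `force` (or `force_gf`) and `area` (or `area_mm2`).
#' @param area contact areas in mm^2 (ignored when `force` is a
#'   data.frame).
#' @return a [LogFit-class].
#' @examples
#' fitLogModel(c(2, 4, 8), 2 * log(c(2, 4, 8)) + 1)   # a = 2, b = 1
#' @export
fitLogModel <- function(force, area = NULL) {
  if (is.data.frame(force)) {
    df <- force
    fcol <- intersect(c("force", "force_gf"), names(df))[1]
    acol <- intersect(c("area", "area_mm2", "avg_area_mm2",
                        "mean_area_mm2"), names(df))[1]
    if (is.na(fcol) || is.na(acol))
      stop("data.frame input needs force and area columns")
    force <- df[[fcol]]; area <- df[[acol]]
  }
  if (length(force) != length(area))
    stop("force and area must have equal length")
  if (length(force) < 3)
    stop("at least 3 points are required")
  if (any(!is.finite(force)) || any(force <= 0))
    stop("all forces must be finite and > 0 gf")
  if (length(unique(force)) < 2)
    stop("forces must not all be identical")
  x <- log(force)
  fit <- stats::lm(area ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((area - mean(area))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  new("LogFit", a = unname(stats::coef(fit)[2]),
      b = unname(stats::coef(fit)[1]),
      r2 = min(max(r2, 0), 1), nPoints = length(force))
}

#' Predict contact area from a logarithmic fit
#'
#' @param fit a [LogFit-class].
#' @param force contact force in gf (> 0); vectorized.
#' @return predicted area `a * ln(force) + b`, mm^2.
#' @examples
#' predictArea(fitLogModel(c(2, 4, 8), 2 * log(c(2, 4, 8)) + 1), 1)  # b
#' @export
predictArea <- function(fit, force) {
  stopifnot(is(fit, "LogFit"))
  if (any(!is.finite(force)) || any(force <= 0))
    stop("force must be finite and > 0 gf")
  fit@a * log(force) + fit@b
}

#' Per-(tip, angle) logarithmic fits
#'
#' Fits `area = a * ln(force) + b` separately for every (tip, angle)
#' present in the records.  By default the fit uses the per-force mean
#' areas (how the published coefficients are reproduced); with
#' `onMeans = FALSE` every replicate point enters the fit.  Groups with
#' fewer than 3 distinct forces are reported without a fit and flagged.
#'
#' @param records data.frame with columns `tip`, `angle_deg`, `force_gf`,
#'   `area_mm2` (replicate-level) or `avg_area_mm2` / `mean_area_mm2`
#'   (condition means).
#' @param onMeans fit per-force mean areas (default) rather than all
#'   replicate points.
#' @return data.frame with columns `tip`, `angle_deg`, `a`, `b`, `r2`,
#'   `n_points`, `fitted` (FALSE where a fit was impossible, with `a`,
#'   `b`, `r2` set to `NA`).
#' @export
fitByCondition <- function(records, onMeans = TRUE) {
  acol <- intersect(c("area_mm2", "avg_area_mm2", "mean_area_mm2"),
                    names(records))[1]
  if (is.na(acol)) stop("records needs an area column")
  key <- interaction(records$tip, records$angle_deg, drop = TRUE)
  out <- do.call(rbind, lapply(split(records, key), function(g) {
    if (onMeans) {
      means <- tapply(g[[acol]], g$force_gf, mean)
      force <- as.numeric(names(means))
      area <- as.numeric(means)
    } else {
      force <- g$force_gf; area <- g[[acol]]
    }
    if (length(unique(force)) < 3) {
      return(data.frame(tip = g$tip[1], angle_deg = g$angle_deg[1],
                        a = NA_real_, b = NA_real_, r2 = NA_real_,
                        n_points = length(force), fitted = FALSE,
                        stringsAsFactors = FALSE))
    }
    f <- fitLogModel(force, area)
    data.frame(tip = g$tip[1], angle_deg = g$angle_deg[1],
               a = f@a, b = f@b, r2 = f@r2, n_points = f@nPoints,
               fitted = TRUE, stringsAsFactors = FALSE)
  }))
  out <- out[order(out$tip, out$angle_deg), ]
  rownames(out) <- NULL
  out
}
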