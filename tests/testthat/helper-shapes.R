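# Analytic shape rasterizers used as independent oracles: they draw by
# direct membership of pixel centers, sharing no code with the package's
# footprint renderer.

rasterEllipse <- function(a, b, thetaDeg = 0, rows = 400, cols = 400,
                          off = c(0, 0), pixelScale = 0.02) {
  cr <- (rows + 1) / 2 + off[1]; cc <- (cols + 1) / 2 + off[2]
  th <- thetaDeg * pi / 180
  dr <- seq_len(rows) - cr; dc <- seq_len(cols) - cc
  u <- outer(dr, dc, function(r, c)  cos(th) * r + sin(th) * c)
  v <- outer(dr, dc, function(r, c) -sin(th) * r + cos(th) * c)
  BinaryMask((u / a)^2 + (v / b)^2 <= 1, pixelScale)
}

rasterDisk <- function(r, rows = 400, cols = 400, off = c(0, 0),
                       pixelScale = 0.02) {
  rasterEllipse(r, r, 0, rows, cols, off, pixelScale)
}

rasterRect <- function(len, wid, thetaDeg = 0, rows = 400, cols = 400,
                       off = c(0, 0), pixelScale = 0.02) {
  cr <- (rows + 1) / 2 + off[1]; cc <- (cols + 1) / 2 + off[2]
  th <- thetaDeg * pi / 180
  dr <- seq_len(rows) - cr; dc <- seq_len(cols) - cc
  u <- outer(dr, dc, function(r, c)  cos(th) * r + sin(th) * c)
  v <- outer(dr, dc, function(r, c) -sin(th) * r + cos(th) * c)
  BinaryMask(abs(u) <= len / 2 & abs(v) <= wid / 2, pixelScale)
}

# half-ellipse: flat cut at the bottom, elliptical cap pointing up;
# a = full extent perpendicular to the cut, b = semi-axis along the cut
rasterHalfEllipse <- function(a, b, rows = 400, cols = 400,
                              pixelScale = 0.02) {
  cr <- (rows + 1) / 2; cc <- (cols + 1) / 2
  dr <- seq_len(rows) - cr; dc <- seq_len(cols) - cc
  u <- outer(dr, dc, function(r_, c_) r_)
  v <- outer(dr, dc, function(r_, c_) c_)
  up <- a / 2 - u
  BinaryMask(up >= 0 & (up / a)^2 + (v / b)^2 <= 1, pixelScale)
}

rasterHalfDisk <- function(r, rows = 400, cols = 400, pixelScale = 0.02) {
  rasterHalfEllipse(r, r, rows, cols, pixelScale)
}

# Brute-force SSE minimization of area = a*ln(force) + b over an (a, b)
# grid with 0.001 step, centred on a coarse pre-scan.
bruteForceLogFit <- function(force, area, center = NULL, halfWidth = 0.05) {
  x <- log(force)
  if (is.null(center)) {
    aa <- seq(-10, 10, by = 0.1)
    sse <- vapply(aa, function(a) {
      b <- mean(area) - a * mean(x)
      sum((area - a * x - b)^2)
    }, numeric(1))
    a0 <- aa[which.min(sse)]
    center <- c(a0, mean(area) - a0 * mean(x))
  }
  aa <- seq(center[1] - halfWidth, center[1] + halfWidth, by = 0.001)
  bb <- seq(center[2] - halfWidth, center[2] + halfWidth, by = 0.001)
  best <- c(NA, NA); bestSSE <- Inf
  for (a in aa) {
    for (b in bb) {
      s <- sum((area - a * x - b)^2)
      if (s < bestSSE) { bestSSE <- s; best <- c(a, b) }
    }
  }
  list(a = best[1], b = best[2], sse = bestSSE)
}

# Exhaustive 256-candidate between-class-variance scan, computed directly
# from the pixel partition (independent of the package's histogram route).
exhaustiveOtsu <- function(gray) {
  v <- as.numeric(gray)
  best <- NA_real_; bestVar <- -Inf
  for (k in 1:256) {
    t <- k / 256
    lo <- v <= t
    n0 <- sum(lo); n1 <- length(v) - n0
    if (n0 == 0 || n1 == 0) next
    w0 <- n0 / length(v); w1 <- 1 - w0
    sigmaB <- w0 * w1 * (mean(v[lo]) - mean(v[!lo]))^2
    if (sigmaB > bestVar + 1e-15) { bestVar <- sigmaB; best <- t }
  }
  best
}

studyTips <- function() list(flat = flatTip(), round = roundTip())
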