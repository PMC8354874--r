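test_that("grayscale conversion applies luminance weights", {
  m <- matrix(runif(20), 4, 5)
  expect_identical(toGrayscale(m), m)
  rgb <- array(1, dim = c(3, 3, 3))
  expect_equal(toGrayscale(rgb), matrix(1, 3, 3))
  red <- array(0, dim = c(3, 3, 3)); red[, , 1] <- 1
  expect_equal(toGrayscale(red), matrix(0.299, 3, 3))
  expect_error(toGrayscale(array(0, dim = c(3, 3, 4))), "channel")
})

test_that("Otsu binarization matches an exhaustive variance scan", {
  # constructed two-level image: foreground is exactly the bright 10%
  v <- c(rep(0.1, 900), rep(0.9, 100))
  img <- matrix(sample(v), 25, 40)
  mask <- binarize(img, keepLargest = FALSE)
  expect_equal(sum(maskPixels(mask)), 100)
  expect_equal(otsuThreshold(img), exhaustiveOtsu(img))
  # randomized noisy bimodal images
  set.seed(31)
  for (i in 1:8) {
    n <- 40 * 50
    frac <- runif(1, 0.05, 0.5)
    x <- c(rnorm(round(n * frac), 0.8, 0.07),
           rnorm(n - round(n * frac), 0.2, 0.07))
    img <- matrix(pmin(pmax(sample(x), 0), 1), 40, 50)
    expect_equal(otsuThreshold(img), exhaustiveOtsu(img))
  }
})

test_that("degenerate and fixed-threshold binarization behave as specified", {
  expect_warning(m <- binarize(matrix(0.4, 10, 10)), "constant")
  expect_equal(sum(maskPixels(m)), 0)
  img <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(maskPixels(binarize(img, method = "fixed", threshold = 0.5,
                                   keepLargest = FALSE)),
               img > 0.5)
  expect_error(binarize(img, method = "fixed"), "threshold")
})

test_that("only the largest connected component survives binarization", {
  img <- matrix(0.1, 60, 60)
  img[10:40, 10:20] <- 0.9   # 31 x 11 block
  img[50:52, 50:52] <- 0.9   # small distractor blob
  mask <- binarize(img, pixelScale = 1)
  expect_equal(sum(maskPixels(mask)), 31 * 11)
})

test_that("area measurement is pixel count times scale squared", {
  m <- BinaryMask(matrix(FALSE, 5, 5), 0.5)
  expect_equal(measureArea(m), 0)
  px <- matrix(FALSE, 5, 5); px[2:3, 2:3] <- TRUE
  expect_equal(measureArea(BinaryMask(px, 0.5)), 1.0)
  # analytic circle oracle: radius 50 px at 0.02 mm/px -> pi mm^2
  disk <- rasterDisk(50, rows = 200, cols = 200)
  expect_equal(measureArea(disk), pi, tolerance = 0.02)
})

test_that("rasterized analytic shapes measure within 2% of closed form", {
  shapes <- list(
    list(m = rasterRect(200, 80, 25), a = 200 * 80 * 0.02^2),
    list(m = rasterEllipse(120, 55, -40), a = pi * 120 * 55 * 0.02^2),
    list(m = rasterDisk(90), a = pi * 90^2 * 0.02^2),
    list(m = rasterHalfDisk(120), a = pi * 120^2 / 2 * 0.02^2))
  for (s in shapes)
    expect_equal(measureArea(s$m), s$a, tolerance = 0.02)
})

test_that("principal orientation recovers known axes", {
  disk <- rasterDisk(80)
  po <- principalOrientation(disk)
  expect_lt(po$eccentricity, 0.1)
  expect_equal(po$orientation, 0)

  vert <- rasterEllipse(100, 50, 0)
  expect_equal(principalOrientation(vert)$orientation, 0, tolerance = 1)

  tilted <- rasterEllipse(100, 50, 30)
  po <- principalOrientation(tilted)
  expect_equal(po$orientation, 30, tolerance = 1)
  # analytic moment-ellipse eccentricity for a 2:1 ellipse
  expect_equal(po$eccentricity, sqrt(1 - 0.25), tolerance = 0.01)

  neg <- rasterEllipse(100, 50, -55)
  expect_equal(principalOrientation(neg)$orientation, -55, tolerance = 1)
  expect_error(principalOrientation(BinaryMask(matrix(FALSE, 4, 4), 1)),
               "2 foreground")
})

test_that("alignment centers, verticalizes, conserves area, idempotent", {
  # translation-only case: offset circle comes back centered
  disk <- rasterDisk(60, off = c(30, -40))
  al <- alignMask(disk)
  cen <- unname(colMeans(which(maskPixels(al), arr.ind = TRUE)))
  expect_equal(cen, c(200.5, 200.5), tolerance = 1)
  expect_equal(sum(maskPixels(al)), sum(maskPixels(disk)),
               tolerance = 0.02 * sum(maskPixels(disk)))

  # already-aligned vertical ellipse is a near no-op
  vert <- rasterEllipse(100, 50, 0)
  al <- alignMask(vert)
  expect_lt(sum(xor(maskPixels(al), maskPixels(vert))) /
            sum(maskPixels(vert)), 0.01)

  # randomized sweep: conservation <= 2%, residual <= 1 deg,
  # idempotence <= 1% of foreground pixels
  set.seed(17)
  for (i in 1:12) {
    a <- runif(1, 40, 110); b <- runif(1, 20, a * 0.9)
    th <- runif(1, -85, 85)
    m <- rasterEllipse(a, b, th, off = runif(2, -25, 25))
    al <- alignMask(m)
    expect_lt(abs(measureArea(al) - measureArea(m)) / measureArea(m), 0.02)
    expect_lt(abs(principalOrientation(al)$orientation), 1)
    al2 <- alignMask(al)
    expect_lt(sum(xor(maskPixels(al), maskPixels(al2))) /
              sum(maskPixels(al)), 0.01)
  }
  expect_error(alignMask(rasterEllipse(150, 40, 45), canvas = c(60, 60)),
               "canvas too small")
})

test_that("asymmetric prints are canonically posed larger-half down", {
  half <- rasterHalfEllipse(150, 50)
  al <- alignMask(half)
  px <- maskPixels(al)
  rows <- which(px, arr.ind = TRUE)[, 1]
  expect_gt(sum(rows > nrow(px) / 2), sum(rows < nrow(px) / 2))
  # and the pose is stable under re-alignment
  al2 <- alignMask(al)
  expect_lt(sum(xor(maskPixels(al), maskPixels(al2))) / sum(px), 0.01)
})

test_that("occupancy averaging and the consensus tie rule", {
  vert <- rasterEllipse(80, 40, 0, rows = 300, cols = 300)
  prof <- averageMorphology(rep(list(vert), 6))
  expect_true(all(occupancy(prof) %in% c(0, 1)))
  expect_equal(sum(maskPixels(consensusMask(prof))),
               sum(maskPixels(vert)), tolerance = 0.01 * sum(maskPixels(vert)))

  # 3-of-6 pixels sit on the tie and stay inside the consensus,
  # 2-of-6 fall outside (concentric disks need no alignment, so the
  # occupancy ring is exactly the big-minus-small annulus)
  big <- rasterDisk(60, rows = 301, cols = 301)
  small <- rasterDisk(40, rows = 301, cols = 301)
  prof <- averageMorphology(c(rep(list(big), 3), rep(list(small), 3)),
                            canvas = c(301, 301))
  occ <- occupancy(prof)
  ring <- maskPixels(big) & !maskPixels(small)
  expect_equal(unique(occ[ring]), 0.5)
  expect_true(all(maskPixels(consensusMask(prof))[ring]))
  prof2 <- averageMorphology(c(rep(list(big), 2), rep(list(small), 4)),
                             canvas = c(301, 301))
  expect_equal(unique(occupancy(prof2)[ring]), 1 / 3, tolerance = 1e-9)
  expect_false(any(maskPixels(consensusMask(prof2))[ring]))

  expect_error(averageMorphology(list()), "at least one")
  expect_error(averageMorphology(list(big, BinaryMask(maskPixels(small), 0.5))),
               "pixel scale")
})

test_that("the four reference shapes classify into their own types", {
  expect_equal(classifyMask(rasterRect(200, 90, 10)), "T1")
  expect_equal(classifyMask(rasterDisk(80)), "T3")
  expect_equal(classifyMask(rasterHalfEllipse(160, 55)), "T2")
  expect_equal(classifyMask(rasterEllipse(100, 45, -20)), "T4")
  # exactly one class for a sweep of random shapes
  set.seed(23)
  for (i in 1:10) {
    m <- rasterEllipse(runif(1, 30, 100), runif(1, 20, 100),
                       runif(1, -90, 90))
    expect_true(classifyMask(m) %in% c("T1", "T2", "T3", "T4"))
  }
})
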