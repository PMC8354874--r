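test_that("tip shape and contact angle determine the footprint class", {
  expect_equal(footprintClass("flat", 0), "T1")
  expect_equal(footprintClass("round", 0), "T2")
  expect_equal(footprintClass("flat", 90), "T3")
  expect_equal(footprintClass("round", 90), "T3")
  expect_equal(footprintClass("flat", 45), "T4")
  expect_equal(footprintClass("round", 30), "T4")
  expect_equal(footprintClass(flatTip(), 60), "T4")
  expect_error(footprintClass("flat", -1), "angle")
  expect_error(footprintClass("flat", 91), "angle")
})

test_that("rendered noiseless footprints match their analytic area", {
  # circle: analytic disk vs rasterized pixel count
  p <- renderFootprint(ContactCondition(roundTip(), 90, 10),
                       ContactLaw(0, 10), seed = 3,
                       jitterRotation = 0, jitterOffset = 0,
                       intensityNoise = 0)
  m <- binarize(p)
  expect_equal(truthArea(p), 10)
  expect_true(measureArea(m) >= 9.8 && measureArea(m) <= 10.2)

  # rectangle geometry: width fixed at the tip diameter, length solved
  p <- renderFootprint(ContactCondition(flatTip(), 0, 2),
                       ContactLaw(0, 11.424), seed = 3,
                       jitterRotation = 0, jitterOffset = 0,
                       intensityNoise = 0)
  m <- maskPixels(binarize(p))
  rows <- range(which(apply(m, 1, any)))
  cols <- range(which(apply(m, 2, any)))
  expect_equal((diff(rows) + 1) * 0.02, 11.424 / 2.33, tolerance = 0.01)
  expect_equal((diff(cols) + 1) * 0.02, 2.33, tolerance = 0.01)
})

test_that("identical seeds give bit-identical prints", {
  cond <- ContactCondition(flatTip(), 45, 20)
  law <- ContactLaw(3.689, 2.952, 0.08)
  p1 <- renderFootprint(cond, law, seed = 42)
  p2 <- renderFootprint(cond, law, seed = 42)
  expect_identical(maskPixels(p1), maskPixels(p2))
  expect_identical(truthArea(p1), truthArea(p2))
  p3 <- renderFootprint(cond, law, seed = 43)
  expect_false(identical(maskPixels(p1), maskPixels(p3)))
})

test_that("rendering does not disturb the caller's RNG stream", {
  set.seed(7); before <- runif(3)
  set.seed(7); invisible(runif(1))
  invisible(renderFootprint(ContactCondition(roundTip(), 90, 10),
                            ContactLaw(0, 10), seed = 99))
  after <- runif(2)
  expect_identical(before[2:3], after)
})

test_that("dataset generation covers the requested grid with a manifest", {
  laws <- defaultLaws(noiseCV = 0)
  ds <- generateDataset(laws, tips = list(flatTip()), angles = 0,
                        replicates = 1, seed = 1, render = FALSE)
  expect_equal(nrow(ds$manifest), 8)   # 1 tip x 1 angle x 8 forces
  # noiseless truth areas equal the law evaluated at each force
  expect_equal(ds$manifest$truth_area_mm2,
               targetArea(laws$flat[["0"]], ds$manifest$force_gf))
  # full grid arithmetic: 2 tips x 5 angles x 8 forces x 6 replicates
  ds6 <- generateDataset(laws, replicates = 6, seed = 1, render = FALSE)
  expect_equal(nrow(ds6$manifest), 480)
  expect_error(
    generateDataset(list(flat = laws$flat), replicates = 1, render = FALSE),
    "no ground-truth law")
})

test_that("datasets are deterministic and render mode matches manifest", {
  laws <- defaultLaws(noiseCV = 0.08)
  a <- generateDataset(laws, tips = list(roundTip()), angles = 90,
                       forces = c(2, 40), replicates = 2, seed = 9)
  b <- generateDataset(laws, tips = list(roundTip()), angles = 90,
                       forces = c(2, 40), replicates = 2, seed = 9)
  expect_identical(a$manifest, b$manifest)
  expect_identical(maskPixels(a$prints[[3]]), maskPixels(b$prints[[3]]))
  # the unrendered manifest draws the same replicate areas
  c <- generateDataset(laws, tips = list(roundTip()), angles = 90,
                       forces = c(2, 40), replicates = 2, seed = 9,
                       render = FALSE)
  expect_identical(a$manifest, c$manifest)
})

test_that("noiseless dataset refits recover every generating law", {
  laws <- defaultLaws(noiseCV = 0)
  ds <- generateDataset(laws, replicates = 2, seed = 4, render = FALSE)
  rec <- transform(ds$manifest, area_mm2 = truth_area_mm2)
  f <- fitByCondition(rec)
  ref <- paperFitTable()
  mg <- merge(f, ref, by = c("tip", "angle_deg"))
  expect_equal(nrow(mg), 10)
  expect_true(all(abs(mg$a.x - mg$a.y) / mg$a.y < 0.01))
  expect_true(all(abs(mg$b.x - mg$b.y) <= pmax(0.01 * abs(mg$b.y), 1e-8)))
  expect_true(all(mg$r2.x >= 0.999))
})

test_that("PNG export writes a readable dataset with manifest", {
  dir <- withr::local_tempdir()
  laws <- defaultLaws(noiseCV = 0)
  ds <- generateDataset(laws, tips = list(roundTip()), angles = 90,
                        forces = c(2, 10), replicates = 1, seed = 2,
                        outDir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 2)
  img <- readContactImage(file.path(dir, man$file[1]))
  # 8-bit quantization: intensities within half a gray level
  expect_equal(dim(img), c(512, 512))
  expect_lt(max(abs(img - maskPixels(ds$prints[[1]]))), 1 / 255)
})
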