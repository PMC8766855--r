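test_that("patch grid tiling arithmetic and ordering", {
  expect_equal(nPatches(buildPatchGrid(c(512, 512), 32)), 256L)
  expect_equal(nPatches(buildPatchGrid(c(512, 512), 128)), 16L)
  expect_equal(nPatches(buildPatchGrid(c(512, 512), 32, 16)), 961L)
  g <- buildPatchGrid(c(64, 96), 32)
  expect_equal(nPatches(g), 2L * 3L)
  # row-major ordering, centers at the arithmetic mean of the corners
  ctr <- patchCenters(g)
  expect_equal(ctr$x[1:3], c(15.5, 47.5, 79.5))
  expect_equal(ctr$y[1:3], rep(15.5, 3))
  expect_error(buildPatchGrid(c(64, 64), 128), "exceeds")
  expect_error(buildPatchGrid(c(64, 64), 7), "8 pixels")
})

test_that("power-law cutoff finds the background/Pareto junction", {
  cuts <- vapply(1:20, function(s) {
    set.seed(s)
    v <- c(rnorm(5000, 100, 5), 130 * runif(200)^(-1 / 2.5))
    powerLawCutoff(v)
  }, numeric(1))
  expect_gte(mean(cuts >= 115 & cuts <= 145), 0.8)
  expect_true(median(cuts) >= 115 && median(cuts) <= 145)
})

test_that("power-law cutoff leaves pure-normal samples essentially intact", {
  qs <- vapply(1:20, function(s) {
    set.seed(100 + s)
    v <- rnorm(1024, 140, 12)
    mean(v <= powerLawCutoff(v))
  }, numeric(1))
  expect_true(all(qs >= 0.9))
})

test_that("a lone outlier sits above the cutoff of a constant sample", {
  v <- c(rep(50, 200), 5000)
  cut <- powerLawCutoff(v)
  expect_equal(cut, 50)
  expect_gt(5000, cut)
})

test_that("cutoff input validation", {
  expect_error(powerLawCutoff(rnorm(5, 100, 5)), ">= 20")
  expect_error(powerLawCutoff(rep(3, 100)), "all values equal")
})

test_that("clean normal samples pass the normality gate immediately", {
  for (s in 1:10) {
    set.seed(200 + s)
    tr <- trimToNormality(rnorm(800, 100, 5))
    expect_true(tr$converged)
    expect_gte(tr$swStatistic, 0.98)
    expect_lte(tr$iterations, 2L)
  }
})

test_that("balanced bimodal samples fail the normality gate", {
  cfg <- trimConfig(maxTrimFraction = 0.2)
  for (s in 1:5) {
    set.seed(300 + s)
    v <- c(rnorm(400, 100, 5), rnorm(400, 160, 5))
    tr <- trimToNormality(v, cfg)
    expect_false(tr$converged)
  }
})

test_that("trimming never removes more than twice the per-side budget", {
  cfg <- trimConfig(maxTrimFraction = 0.25)
  for (s in 1:10) {
    set.seed(400 + s)
    v <- contaminatedPatch(400 + s, runif(1, 0, 0.35))
    cut <- powerLawCutoff(v)
    kept <- v[v <= cut]
    tr <- trimToNormality(kept, cfg)
    expect_gte(length(tr$values), length(kept) * (1 - 2 * cfg$maxTrimFraction))
  }
})

test_that("constant patch with one outlier yields B = c, zero contrast, invalid", {
  sp <- estimateSupportPoint(c(rep(7, 500), 900))
  expect_equal(sp$B, 7)
  expect_equal(sp$C, 0)
  expect_false(sp$valid)
})

test_that("clean background patches estimate B and C accurately", {
  for (s in 1:10) {
    set.seed(500 + s)
    px <- rnorm(1024, 120, 10.5)
    sp <- estimateSupportPoint(px)
    expect_true(sp$valid)
    expect_lt(abs(sp$B - 120), 3 * 10.5 / sqrt(sp$n_used))
    expect_lt(abs(sp$C - 10.5) / 10.5, 0.10)
  }
})

test_that("disk contamination is excluded by the tail cut and trimming", {
  errSE <- vapply(1:20, function(s) {
    sp <- estimateSupportPoint(contaminatedPatch(600 + s, 0.3))
    (sp$B - 120) / (10.5 / sqrt(sp$n_used))
  }, numeric(1))
  expect_lte(median(abs(errSE)), 3)
  expect_gte(mean(abs(errSE) <= 3), 0.8)
})

test_that("B and C respond correctly to affine changes of the pixel values", {
  set.seed(42)
  px <- rnorm(1024, 120, 10.5)
  base <- estimateSupportPoint(px)
  shifted <- estimateSupportPoint(px + 37)
  expect_equal(shifted$B, base$B + 37, tolerance = 1e-8)
  expect_equal(shifted$C, base$C, tolerance = 1e-8)
  # scaling: the whole pipeline is scale-equivariant, including the cutoff
  cont <- contaminatedPatch(43, 0.15)
  b1 <- estimateSupportPoint(cont)
  b2 <- estimateSupportPoint(cont * 2.5)
  expect_equal(b2$B, 2.5 * b1$B, tolerance = 1e-8)
  expect_equal(b2$C, 2.5 * b1$C, tolerance = 1e-8)
})

test_that("support-point maps track the true fields on a phantom slice", {
  ph <- generatePhantom(phantomSpec(nSlices = 1, seed = 21))
  grid <- buildPatchGrid(c(512, 512), 32)
  sp <- estimateSupportPoints(getSlice(observedStack(ph), 1), grid)
  expect_equal(nrow(sp), 256L)
  ok <- sp[sp$valid, ]
  expect_gt(nrow(ok), 170)  # enough valid support points for the fit
  tB <- evalSurface(ph@brightnessField, ok$x, ok$y)
  expect_gte(cor(ok$B, tB), 0.95)
})

test_that("degenerate slices produce no valid support points", {
  g <- buildPatchGrid(c(64, 64), 32)
  sp <- estimateSupportPoints(matrix(5, 64, 64), g)
  expect_equal(sum(sp$valid), 0L)
})

test_that("pure-noise slices are almost entirely valid", {
  for (s in 1:3) {
    set.seed(700 + s)
    img <- matrix(rnorm(256 * 256, 100, 8), 256, 256)
    sp <- estimateSupportPoints(img, buildPatchGrid(c(256, 256), 32))
    expect_gte(mean(sp$valid), 0.95)
  }
})
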