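test_that("surface evaluation honors peak, one-sigma point and symmetry", {
  g <- GaussianSurface(50, c(256, 256), c(300, 280), 10)
  expect_equal(evalSurface(g, 256, 256), 60)
  expect_equal(evalSurface(g, 256 + 300, 256), 50 * exp(-0.5) + 10)
  expect_equal(evalSurface(g, 256 - 37, 256), evalSurface(g, 256 + 37, 256))
  m <- surfaceMatrix(g, c(512, 512))
  expect_equal(m[257, 257], 60)  # 0-based (256,256) is element [257,257]
})

test_that("noise-free surface fits recover the generating parameters", {
  truth <- GaussianSurface(50, c(256, 256), c(300, 280), 10)
  set.seed(1)
  pts <- data.frame(x = runif(100, 0, 511), y = runif(100, 0, 511))
  pts$value <- evalSurface(truth, pts$x, pts$y)
  fit <- fitSurface(pts)
  p <- surfaceParams(fit)
  expect_lt(abs(p["A"] - 50) / 50, 0.01)
  expect_lt(abs(p["x0"] - 256) / 256, 0.01)
  expect_lt(abs(p["y0"] - 256) / 256, 0.01)
  expect_lt(abs(p["sx"] - 300) / 300, 0.01)
  expect_lt(abs(p["sy"] - 280) / 280, 0.01)
  expect_lt(abs(p["b"] - 10), 0.5)
  expect_gt(rSquared(fit), 0.999)
})

test_that("noisy surface fits stay close to the generating center", {
  truth <- GaussianSurface(50, c(256, 256), c(300, 280), 10)
  for (s in 1:20) {
    set.seed(s)
    pts <- data.frame(x = runif(100, 0, 511), y = runif(100, 0, 511))
    pts$value <- evalSurface(truth, pts$x, pts$y) + rnorm(100)
    fit <- fitSurface(pts)
    p <- surfaceParams(fit)
    expect_lt(sqrt((p["x0"] - 256)^2 + (p["y0"] - 256)^2), 15)
    expect_gte(rSquared(fit), 0.9)
  }
})

test_that("degenerate fit inputs raise errors", {
  pts <- data.frame(x = runif(30, 0, 100), y = runif(30, 0, 100), value = 5)
  expect_error(fitSurface(pts), "flat surface")
  few <- data.frame(x = 1:10, y = 1:10, value = rnorm(10))
  expect_error(fitSurface(few), ">= 15")
})

test_that("identity and cancellation cases of the full correction", {
  img <- matrix(rnorm(64 * 64, 100, 5), 64, 64)
  zero <- GaussianSurface(0, c(31.5, 31.5), 10, 0)
  one <- GaussianSurface(0, c(31.5, 31.5), 10, 1)
  out <- correctFull(img, zero, one, CorrectionConstants(0, 1))
  expect_equal(out, img)
  # constant image c with M_B == c collapses to B_T everywhere
  cimg <- matrix(42, 32, 32)
  cB <- GaussianSurface(0, c(15.5, 15.5), 10, 42)
  out2 <- correctFull(cimg, cB, one, CorrectionConstants(7, 1))
  expect_true(all(out2 == 7))
})

test_that("a contrast field below the floor is refused with a location", {
  img <- matrix(1, 16, 16)
  zero <- GaussianSurface(0, c(7.5, 7.5), 10, 0)
  dip <- GaussianSurface(-1, c(7.5, 7.5), 50, 1.0000001) # near-zero at center
  expect_error(correctFull(img, zero, dip, CorrectionConstants(0, 1)),
               "floor")
})

test_that("brightness-only correction is an exact additive shift per pixel", {
  img <- matrix(rnorm(32 * 32, 50, 4), 32, 32)
  mb <- GaussianSurface(0, c(15.5, 15.5), 10, 20)  # constant 20
  out <- correctBrightness(img, mb, bT = 5)
  expect_equal(out, img - 20 + 5)
  expect_equal(sd(out), sd(img))  # sd untouched by a constant M_B
})

test_that("contrast-only correction: uniform gain is the identity, M_B is a fixed point", {
  img <- matrix(rnorm(32 * 32, 80, 6), 32, 32)
  mb <- GaussianSurface(10, c(15.5, 15.5), 20, 60)
  mcU <- GaussianSurface(0, c(15.5, 15.5), 10, 4)  # constant gain 4
  expect_equal(correctContrast(img, mb, mcU, cT = 4), img)
  # pixels equal to M_B map to M_B under any gain
  mbMat <- surfaceMatrix(mb, c(32, 32))
  mc <- GaussianSurface(3, c(15.5, 15.5), 20, 4)
  out <- correctContrast(mbMat, mb, mc, cT = 5)
  expect_equal(out, mbMat)
})

test_that("contrast-only correction composes algebraically into the full one", {
  ph <- generatePhantom(phantomSpec(width = 96, height = 96, nSlices = 1,
                                    neuronsPerSlice = 10, seed = 31))
  img <- getSlice(observedStack(ph), 1)
  mb <- ph@brightnessField
  mc <- ph@contrastField
  k <- CorrectionConstants(100, 10)
  viaContrast <- correctContrast(img, mb, mc, k@cT) -
    surfaceMatrix(mb, dim(img)) + k@bT
  expect_equal(viaContrast, correctFull(img, mb, mc, k), tolerance = 1e-12)
})

test_that("constants pool as the mean of valid support points", {
  one <- data.frame(x = 0, y = 0, B = 100, C = 5, sw = 0.99,
                    n_used = 500L, valid = TRUE)
  expect_equal(chooseConstants(one)@bT, 100)
  expect_equal(chooseConstants(one)@cT, 5)
  two <- rbind(one, transform(one, B = 110, C = 6))
  two$B[1] <- 90; two$C[1] <- 4
  k <- chooseConstants(two)
  expect_equal(k@bT, 100)
  expect_equal(k@cT, 5)
  none <- transform(one, valid = FALSE)
  expect_error(chooseConstants(none), "no valid")
})

test_that("constants from an undistorted phantom match the scene constants", {
  ph <- generatePhantom(identitySpec(width = 256, neurons = 40, seed = 17))
  flds <- estimateFields(observedStack(ph))
  k <- chooseConstants(flds[[1]]$supportPoints)
  expect_lt(abs(k@bT - 100), 1)
  expect_lt(abs(k@cT - 10) / 10, 0.1)
})

test_that("brightness-only correction leaves the contrast falloff in place", {
  ph <- generatePhantom(phantomSpec(width = 256, height = 256, nSlices = 1,
                                    seed = 23))
  flds <- estimateFields(observedStack(ph))
  k <- chooseConstants(flds[[1]]$supportPoints)
  grid <- buildPatchGrid(c(256, 256), 32)

  bOnly <- correctStack(observedStack(ph), flds, k, "brightness")
  spB <- estimateSupportPoints(getSlice(bOnly, 1), grid)
  okB <- spB[spB$valid, ]
  tC <- evalSurface(ph@contrastField, okB$x, okB$y)
  expect_gte(cor(okB$C, tC), 0.9)

  cOnly <- correctStack(observedStack(ph), flds, k, "contrast")
  spC <- estimateSupportPoints(getSlice(cOnly, 1), grid)
  okC <- spC[spC$valid, ]
  tB <- evalSurface(ph@brightnessField, okC$x, okC$y)
  expect_gte(cor(okC$B, tB), 0.9)
  expect_lt(sd(okC$C) / mean(okC$C), 0.1)  # gain equalized
})
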