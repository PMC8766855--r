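test_that("region partition labels and counts follow the 4x4 layout", {
  g <- buildRegionGrid(c(512, 512))
  lab <- regionLabels(g)
  expect_equal(dim(lab), c(4L, 4L))
  expect_equal(substr(lab[1, 1], 1, 1), "A")
  expect_equal(substr(lab[2, 2], 1, 1), "C")
  expect_equal(substr(lab[1, 2], 1, 1), "E")
  ty <- table(substr(lab, 1, 1))
  expect_equal(as.integer(ty[c("C", "E", "A")]), c(4L, 8L, 4L))
  # deterministic row-major numbering
  expect_equal(lab[1, ], c("A1", "E1", "E2", "A2"))
  expect_equal(lab[4, ], c("A3", "E7", "E8", "A4"))
  expect_error(buildRegionGrid(c(3, 3)), "4 x 4")
})

test_that("region pair counts match the combinatorial accounting", {
  nc <- regionPairCounts(buildRegionGrid(c(512, 512)))
  expect_equal(nc[["C-C"]], 6L)
  expect_equal(nc[["E-E"]], 28L)
  expect_equal(nc[["A-A"]], 6L)
  expect_equal(nc[["C-E"]], 32L)
  expect_equal(nc[["E-A"]], 32L)
  expect_equal(nc[["C-A"]], 16L)
  expect_equal(sum(nc), 120L)  # C(16, 2)
})

test_that("points map to regions with remainder pixels in the last cells", {
  g <- buildRegionGrid(c(510, 510))  # 127-px cells, remainder to the last
  expect_equal(regionOfPoint(g, 0, 0), "A1")
  expect_equal(regionOfPoint(g, 509, 509), "A4")
  expect_equal(regionOfPoint(g, 255, 255), "C4")
  expect_equal(regionOfPoint(g, 255, 0), "E2")
  expect_error(regionOfPoint(g, 510, 0), "outside")
})

test_that("activity readout takes the center pixel and validates positions", {
  img <- ImageStack(matrix(42, 16, 16))
  centers <- data.frame(neuron_id = 0:2, x = c(0, 5, 15), y = c(0, 7, 15),
                        slice = 0L)
  expect_equal(readActivity(img, centers), c(42, 42, 42))
  bad <- data.frame(neuron_id = 9L, x = 16, y = 0, slice = 0L)
  expect_error(readActivity(img, bad), "9")
})

test_that("raw/true activity ratios follow the generative gain field", {
  ph <- generatePhantom(phantomSpec(width = 192, height = 192, nSlices = 1,
                                    neuronsPerSlice = 25, seed = 41))
  nt <- neuronTable(ph)
  xRaw <- readActivity(observedStack(ph, 0), nt)
  xTrue <- readActivity(trueScene(ph, 0), nt)
  mc <- evalSurface(ph@contrastField, nt$x, nt$y)
  mb <- evalSurface(ph@brightnessField, nt$x, nt$y)
  expect_equal(xRaw, (xTrue - 100) / 10 * mc + mb, tolerance = 1e-12)
})

test_that("absolute and relative activity changes derive from the printed formulas", {
  tab <- data.frame(activity_day0 = c(10, 0, 30, 0),
                    activity_day1 = c(10, 20, 10, 0))
  out <- deriveChanges(tab)
  expect_equal(out$deltaX, c(0, 20, -20, 0))
  expect_equal(out$deltaXRel[1:3], c(0, 1, -0.5))
  expect_true(is.na(out$deltaXRel[4]))  # zero denominator is flagged
})

test_that("pairwise region tests cover all 120 pairs with Welch + Bonferroni", {
  g <- buildRegionGrid(c(160, 160))
  set.seed(51)
  # two neurons per region minimum; identical samples in two regions
  pts <- expand.grid(cx = c(20, 60, 100, 140), cy = c(20, 60, 100, 140))
  tab <- do.call(rbind, lapply(seq_len(16), function(i) {
    data.frame(neuron_id = (i - 1) * 10 + 1:10,
               x = pts$cx[i] + 0:9 %% 3, y = pts$cy[i] + 0:9 %/% 3,
               activity_day0 = rnorm(10, 100, 5))
  }))
  rep_ <- pairwiseRegionTests(tab, g, "activity_day0")
  expect_equal(nrow(rep_), 120L)
  expect_true(all(rep_$testable))
  expect_true(all(rep_$p_corrected >= rep_$p_raw - 1e-12))
  expect_true(all(rep_$p_corrected <= 1))
  expect_equal(sort(unique(rep_$type_pair)),
               sort(c("C-C", "C-E", "C-A", "E-E", "E-A", "A-A")))

  # identical samples: corrected p = 1 and delta_std = 0
  tab2 <- tab
  a1 <- tab2$x < 40 & tab2$y < 40      # region A1 block
  c1 <- tab2$x > 40 & tab2$x < 80 & tab2$y > 40 & tab2$y < 80
  tab2$activity_day0[c1] <- tab2$activity_day0[a1]
  rep2 <- pairwiseRegionTests(tab2, g, "activity_day0")
  row <- rep2[rep2$region_a == "C1" & rep2$region_b == "A1" |
              rep2$region_a == "A1" & rep2$region_b == "C1", ]
  expect_equal(row$p_corrected, 1)
  expect_equal(row$delta_std, 0)
})

test_that("the t-test flags large mean differences and delta_std is scale-free", {
  set.seed(61)
  a <- rnorm(200, 100, 10); b <- rnorm(200, 130, 10)
  p <- min(1, t.test(a, b)$p.value * 120)
  expect_lt(p, 0.01)
  # |10 - 30| / mean(10, 30) = 1
  g <- buildRegionGrid(c(160, 160))
  tab <- data.frame(
    neuron_id = 1:40,
    x = c(rep(10, 20), rep(60, 20)), y = c(rep(10, 20), rep(60, 20)),
    activity_day0 = c(scale(rnorm(20)) * 10 + 100, scale(rnorm(20)) * 30 + 100))
  rep_ <- pairwiseRegionTests(tab, g, "activity_day0")
  row <- rep_[rep_$testable & rep_$region_a %in% c("A1", "C1") &
              rep_$region_b %in% c("A1", "C1"), ]
  expect_equal(row$delta_std, 1, tolerance = 1e-10)
})

test_that("regions with fewer than two neurons are flagged untestable", {
  g <- buildRegionGrid(c(160, 160))
  tab <- data.frame(neuron_id = 1:3, x = c(10, 11, 60), y = c(10, 11, 60),
                    activity_day0 = c(1, 2, 3))
  rep_ <- pairwiseRegionTests(tab, g, "activity_day0")
  expect_equal(sum(rep_$testable), 0L)  # single region pairings lack data
  expect_true(all(is.na(rep_$p_corrected[!rep_$testable])))
})

test_that("bias summary normalizes by the within-type mean", {
  # synthetic report: everything non-significant -> every deltaC is 1
  rep0 <- data.frame(
    type_pair = rep(c("C-C", "C-E", "C-A", "E-E", "E-A", "A-A"),
                    times = c(6, 32, 16, 28, 32, 6)),
    p_corrected = 1, delta_std = 0.2, testable = TRUE)
  s0 <- summarizeBias(rep0)
  expect_equal(s0$cp, rep(1, 6))
  expect_equal(s0$deltaC, rep(1, 6))
  expect_equal(s0$deltaStdRatio, rep(1, 6))

  # printed-formula arithmetic: cp(C-A) = 0.25 with within-type mean 0.75
  rep1 <- rep0
  rep1$p_corrected[rep1$type_pair == "C-A"] <-
    rep(c(0.001, 1), times = c(12, 4))         # cp = 0.25
  rep1$p_corrected[rep1$type_pair == "C-C"] <-
    rep(c(0.001, 1), times = c(3, 3))          # cp = 0.5  within
  rep1$p_corrected[rep1$type_pair == "E-E"] <-
    rep(c(0.001, 1), times = c(7, 21))         # cp = 0.75 within
  # A-A stays 1: within-type mean = (0.5 + 0.75 + 1) / 3 = 0.75
  s1 <- summarizeBias(rep1)
  expect_equal(s1$cp[s1$type_pair == "C-A"], 0.25)
  expect_equal(s1$deltaC[s1$type_pair == "C-A"], 1 / 3)
})

test_that("highly active cells exceed mean + 3 sd of the relative change", {
  tab <- data.frame(neuron_id = 1:5, deltaXRel = rep(0.2, 5))
  expect_length(highlyActiveCells(tab), 0)
  set.seed(71)
  tab2 <- data.frame(neuron_id = seq_len(1001),
                     deltaXRel = c(rnorm(1000, 0, 0.1), 0.9))
  expect_true(1001 %in% highlyActiveCells(tab2))
  # normal tail calibration: about 0.135% of cells exceed the rule
  set.seed(72)
  tab3 <- data.frame(neuron_id = seq_len(40000),
                     deltaXRel = rnorm(40000))
  frac <- length(highlyActiveCells(tab3)) / 40000
  expect_gt(frac, 0.0002)
  expect_lt(frac, 0.004)
})

test_that("overlap rate is the reference-normalized intersection", {
  expect_equal(overlapRate(1:4, 1:4), 1)
  expect_equal(overlapRate(1:4, 5:8), 0)
  expect_equal(overlapRate(c(1, 2, 3, 4), c(3, 4, 5)), 0.5)
  expect_warning(r <- overlapRate(integer(0), 1:3), "empty")
  expect_true(is.na(r))
})
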