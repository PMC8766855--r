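# fixtures shared across test files; everything is generated in code

# flat (constant) fields that encode "no distortion" for a scene with
# background N(mu, sg): brightness == mu, contrast == sg
flatFields <- function(w, h = w, mu = 100, sg = 10) {
  ctr <- c((w - 1) / 2, (h - 1) / 2)
  list(B = GaussianSurface(0, ctr, w, mu),
       C = GaussianSurface(0, ctr, w, sg))
}

# small distortion-free phantom spec
identitySpec <- function(width = 128L, nSlices = 1L, neurons = 15L,
                         seed = 1L, ...) {
  f <- flatFields(width)
  phantomSpec(width = width, height = width, nSlices = nSlices,
              brightnessField = f$B, contrastField = f$C,
              neuronsPerSlice = neurons, seed = seed, ...)
}

# a single synthetic 32x32 patch: Normal background plus hard neuron
# disks covering ~coreFrac of the pixels (radius 3, amplitudes as in the
# phantom defaults scaled by `gain`)
contaminatedPatch <- function(seed, coreFrac, mu = 120, sg = 10.5,
                              gain = 1.05, ampRange = c(40, 120),
                              side = 32L, radius = 3) {
  set.seed(seed)
  m <- matrix(rnorm(side^2, mu, sg), side, side)
  nd <- round(coreFrac * side^2 / (pi * radius^2 + radius))
  if (nd > 0) {
    xs <- runif(nd, 1, side); ys <- runif(nd, 1, side)
    a <- runif(nd, ampRange[1L], ampRange[2L]) * gain
    for (k in seq_len(nd)) {
      dx <- outer(rep(1, side), seq_len(side) - xs[k])
      dy <- outer(seq_len(side) - ys[k], rep(1, side))
      m <- m + a[k] * (sqrt(dx^2 + dy^2) <= radius)
    }
  }
  as.numeric(m)
}

# bias-analysis phantom: one laminar compartment pooled over slices
biasSpec <- function(seed, width = 256L, nSlices = 4L, ...) {
  phantomSpec(width = width, height = width, nSlices = nSlices,
              layers = rep("II/III", nSlices), seed = seed, ...)
}

neuronCenters <- function(ph)
  neuronTable(ph)[, c("neuron_id", "x", "y", "slice", "layer")]

# Fig-3-style per-seed bias summary: deltaC / deltaSTD gaps between C-A
# and E-E, averaged over the three activity measures
biasGaps <- function(tab, grid,
                     measures = c("activity_day0", "deltaX", "deltaXRel")) {
  gC <- gS <- 0
  for (ms in measures) {
    s <- summarizeBias(pairwiseRegionTests(tab, grid, ms))
    gC <- gC + (s$deltaC[s$type_pair == "E-E"] -
                s$deltaC[s$type_pair == "C-A"]) / length(measures)
    gS <- gS + (s$deltaStdRatio[s$type_pair == "C-A"] -
                s$deltaStdRatio[s$type_pair == "E-E"]) / length(measures)
  }
  c(gapC = gC, gapS = gS)
}

# estimate fields for both days of a phantom once; corrections reuse them
estimatePhantom <- function(ph) {
  f0 <- estimateFields(observedStack(ph, 0))
  f1 <- estimateFields(observedStack(ph, 1))
  kons <- chooseConstants(lapply(c(f0, f1), `[[`, "supportPoints"))
  list(f0 = f0, f1 = f1, constants = kons)
}

applyMode <- function(ph, est, mode) {
  list(day0 = correctStack(observedStack(ph, 0), est$f0, est$constants, mode),
       day1 = correctStack(observedStack(ph, 1), est$f1, est$constants, mode))
}
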