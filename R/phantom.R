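#' Construct a phantom specification
#'
#' Defaults emulate a single-channel 2-photon functional stack: 512 x 512
#' slices, a near-centered Gaussian falloff of both background brightness
#' (offset 50, peak +100, sigma = 0.75 x side) and contrast (offset 4,
#' peak +8, sigma = 0.55 x side — the gain falls off more steeply than
#' the brightness, center-to-corner gain ratio ~1.6), an undistorted scene
#' background of N(100, 10), and well-separated disk neurons (radius 3 px,
#' 150 per slice, amplitudes Uniform(40, 120) above background — at least
#' four background standard deviations bright, with a broad spread so
#' activity dispersion dominates region variance) whose day-1 amplitudes
#' correlate with day-0 at 0.6. Slices are split into four contiguous
#' laminar compartments II/III, IV, V, VI. The wide field keeps the
#' within-cell brightness gradient small relative to the activity spread,
#' so a vignetted phantom shows the center-periphery bias signature in
#' both the region means and the region dispersions.
#'
#' @param width,height frame size in pixels.
#' @param nSlices slices per day.
#' @param brightnessField,contrastField ground-truth [GaussianSurface]s;
#'   defaults scale with the frame size (centered, sigma = 0.75 and
#'   0.55 x side respectively).
#' @param backgroundMean,backgroundStd undistorted background Normal
#'   parameters (the scene-truth constants).
#' @param neuronsPerSlice,neuronRadius,amplitudeRange neuron layout.
#' @param dayCorrelation across-day amplitude correlation in [0, 1].
#' @param neuronShape "disk" (default) or "gaussian".
#' @param layers one label per slice; default splits slices into four
#'   contiguous compartments.
#' @param seed integer seed; the generator is deterministic given it.
#' @return a [PhantomSpec].
#' @examples
#' spec <- phantomSpec(width = 128, height = 128, nSlices = 2,
#'                     neuronsPerSlice = 20, seed = 7)
#' spec
#' @export
phantomSpec <- function(width = 512L, height = 512L, nSlices = 4L,
                        brightnessField = NULL, contrastField = NULL,
                        backgroundMean = 100, backgroundStd = 10,
                        neuronsPerSlice = 150L, neuronRadius = 3,
                        amplitudeRange = c(40, 120),
                        dayCorrelation = 0.6,
                        neuronShape = c("disk", "gaussian"),
                        layers = NULL, seed = 1L) {
  neuronShape <- match.arg(neuronShape)
  width <- as.integer(width); height <- as.integer(height)
  nSlices <- as.integer(nSlices)
  ctr <- c((width - 1) / 2, (height - 1) / 2)
  side <- max(width, height)
  if (is.null(brightnessField))
    brightnessField <- GaussianSurface(100, ctr, 0.75 * side, 50)
  if (is.null(contrastField))
    contrastField <- GaussianSurface(8, ctr, 0.55 * side, 4)
  if (is.null(layers)) {
    lab <- c("II/III", "IV", "V", "VI")
    layers <- lab[ceiling(seq_len(nSlices) / nSlices * min(4L, nSlices))]
  }
  new("PhantomSpec", width = width, height = height, nSlices = nSlices,
      brightnessField = brightnessField, contrastField = contrastField,
      backgroundMean = backgroundMean, backgroundStd = backgroundStd,
      neuronsPerSlice = as.integer(neuronsPerSlice),
      neuronRadius = neuronRadius,
      amplitudeRange = as.numeric(amplitudeRange),
      dayCorrelation = dayCorrelation, neuronShape = neuronShape,
      layers = layers, noiseModel = "gaussian", seed = as.integer(seed))
}

# derived sub-stream seed; fixed offsets per slice/purpose keep partial
# regeneration reproducible. Kept below 2^31 - 1.
.subSeed <- function(seed, slice, purpose) {
  (abs(seed) + 7919 * (slice - 1L) + 104729 * purpose) %% 2147483629L
}

# place n non-overlapping disk centers by rejection sampling
.placeNeurons <- function(n, width, height, radius, maxRetries = 1000L) {
  margin <- ceiling(radius)
  if (width - 1 - 2 * margin < 0 || height - 1 - 2 * margin < 0)
    stop("frame too small to contain a single neuron disk")
  xs <- ys <- numeric(0)
  minSep2 <- (2 * radius)^2
  for (k in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(maxRetries)) {
      cx <- sample.int(width - 2L * margin, 1L) - 1L + margin
      cy <- sample.int(height - 2L * margin, 1L) - 1L + margin
      if (length(xs) == 0L ||
          min((xs - cx)^2 + (ys - cy)^2) > minSep2) {
        xs <- c(xs, cx); ys <- c(ys, cy)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop(sprintf(
        "could not place neuron %d of %d without overlap (min separation %g px) after %d retries",
        k, n, 2 * radius, maxRetries))
  }
  data.frame(x = xs, y = ys)
}

#' Generate a two-day synthetic vignetting phantom
#'
#' For each slice and day the undistorted "true scene" is background noise
#' N(backgroundMean, backgroundStd) with neuron blobs added on top
#' (constant-amplitude disks by default; the disk-center pixel is stamped
#' to exactly backgroundMean + amplitude so the center-pixel activity
#' readout is unambiguous). The observed stack applies the
#' generative inverse of the full correction formula,
#' \deqn{I_0 = (I_{true} - B_T) / C_T \cdot M_C(x,y) + M_B(x,y),}
#' with B_T = backgroundMean and C_T = backgroundStd, so that
#' [correctFull()] with the ground-truth fields recovers the true scene
#' exactly. Day-1 amplitudes follow the mean-preserving correlated-pair
#' construction \code{a1 = mu + rho (a0 - mu) + sqrt(1 - rho^2) (eps - mu)}
#' with eps drawn from the amplitude distribution. Neuron positions are
#' shared across days (the same cells are imaged twice). Deterministic
#' given \code{spec@seed}.
#'
#' @param spec a [PhantomSpec].
#' @return a [Phantom].
#' @examples
#' ph <- generatePhantom(phantomSpec(width = 96, height = 96, nSlices = 1,
#'                                   neuronsPerSlice = 10, seed = 3))
#' ph
#' @export
generatePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  w <- spec@width; h <- spec@height
  MB <- surfaceMatrix(spec@brightnessField, c(h, w))
  MC <- surfaceMatrix(spec@contrastField, c(h, w))
  mu <- spec@backgroundMean; sg <- spec@backgroundStd
  rho <- spec@dayCorrelation
  ampMid <- mean(spec@amplitudeRange)

  if (exists(".Random.seed", envir = globalenv()))
    oldSeed <- get(".Random.seed", envir = globalenv())
  else oldSeed <- NULL
  on.exit({
    if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv())
  }, add = TRUE)

  # disk stencil offsets
  r <- spec@neuronRadius
  rr <- ceiling(r)
  off <- expand.grid(dx = -rr:rr, dy = -rr:rr)
  off <- off[off$dx^2 + off$dy^2 <= r^2, ]

  true0 <- true1 <- array(0, dim = c(h, w, spec@nSlices))
  tables <- vector("list", spec@nSlices)
  for (s in seq_len(spec@nSlices)) {
    set.seed(.subSeed(spec@seed, s, 0L))
    pos <- .placeNeurons(spec@neuronsPerSlice, w, h, r)
    n <- nrow(pos)
    a0 <- stats::runif(n, spec@amplitudeRange[1L], spec@amplitudeRange[2L])
    eps <- stats::runif(n, spec@amplitudeRange[1L], spec@amplitudeRange[2L])
    a1 <- pmax(ampMid + rho * (a0 - ampMid) + sqrt(1 - rho^2) * (eps - ampMid), 0)

    for (d in 0:1) {
      set.seed(.subSeed(spec@seed, s, 1L + d))
      scene <- matrix(stats::rnorm(h * w, mu, sg), h, w)
      a <- if (d == 0L) a0 else a1
      for (k in seq_len(n)) {
        rows <- pos$y[k] + off$dy + 1L
        cols <- pos$x[k] + off$dx + 1L
        if (spec@neuronShape == "disk") {
          scene[cbind(rows, cols)] <- scene[cbind(rows, cols)] + a[k]
        } else {
          bump <- a[k] * exp(-(off$dx^2 + off$dy^2) / (2 * (r / 2)^2))
          scene[cbind(rows, cols)] <- scene[cbind(rows, cols)] + bump
        }
        # stamp the exact value at the disk center so the center-pixel
        # activity readout is unambiguous
        scene[pos$y[k] + 1L, pos$x[k] + 1L] <- mu + a[k]
      }
      if (d == 0L) true0[, , s] <- scene else true1[, , s] <- scene
    }
    ctrIdx <- cbind(pos$y + 1L, pos$x + 1L)
    tables[[s]] <- data.frame(
      x = pos$x, y = pos$y,
      slice = rep(s - 1L, n),
      layer = rep(spec@layers[s], n),
      activity_day0 = true0[, , s][ctrIdx],
      activity_day1 = true1[, , s][ctrIdx])
  }
  nt <- do.call(rbind, tables)
  nt <- cbind(neuron_id = seq_len(nrow(nt)) - 1L, nt)

  distort <- function(a) {
    for (s in seq_len(dim(a)[3L]))
      a[, , s] <- (a[, , s] - mu) / sg * MC + MB
    a
  }
  obs0 <- distort(true0)
  obs1 <- distort(true1)

  new("Phantom",
      stackDay0 = ImageStack(obs0), stackDay1 = ImageStack(obs1),
      trueDay0 = ImageStack(true0), trueDay1 = ImageStack(true1),
      neuronTable = nt,
      brightnessField = spec@brightnessField,
      contrastField = spec@contrastField,
      spec = spec)
}
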