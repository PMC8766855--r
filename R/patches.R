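#' Build a rectangular patch grid over an image
#'
#' Returns every patch of the requested size fully contained in the image,
#' in row-major order. The default stride equals the patch size, i.e. a
#' non-overlapping tiling; for 512 x 512 slices the default 32 x 32 tiling
#' yields 256 patches, enough support points for the surface fit while
#' keeping each patch large enough (~1000 px) for the normality gate.
#'
#' @param shape integer(2) (rows, cols) of the image.
#' @param patchSize patch side length in pixels (square patches), >= 8.
#' @param stride grid stride in pixels (default \code{patchSize}).
#' @return a [PatchGrid].
#' @examples
#' nPatches(buildPatchGrid(c(512, 512), 32))        # 256
#' nPatches(buildPatchGrid(c(512, 512), 128))       # 16
#' nPatches(buildPatchGrid(c(512, 512), 32, 16))    # 961
#' @export
buildPatchGrid <- function(shape, patchSize, stride = patchSize) {
  shape <- as.integer(shape)
  patchSize <- as.integer(patchSize)
  stride <- as.integer(stride)
  stopifnot(length(shape) == 2L, stride >= 1L)
  if (patchSize > min(shape))
    stop(sprintf("patch size %d exceeds image shape %d x %d",
                 patchSize, shape[1L], shape[2L]))
  rows0 <- seq.int(0L, shape[1L] - patchSize, by = stride)
  cols0 <- seq.int(0L, shape[2L] - patchSize, by = stride)
  origins <- data.frame(
    row0 = rep(rows0, each = length(cols0)),
    col0 = rep(cols0, times = length(rows0)))
  half <- (patchSize - 1) / 2
  centers <- data.frame(x = origins$col0 + half, y = origins$row0 + half)
  new("PatchGrid", patchWidth = patchSize, patchHeight = patchSize,
      stride = stride, origins = origins, centers = centers,
      imageShape = shape)
}

#' Power-law cutoff for the bright (foreground) tail
#'
#' Finds the intensity above which pixel values are treated as foreground
#' (active neurons and other bright objects). Scanning xmin over the unique
#' sample values, a continuous power law is fitted by maximum likelihood to
#' each candidate tail \code{\{v >= xmin\}} and scored by the
#' Kolmogorov-Smirnov distance D between the empirical tail and the fit.
#' The cutoff is the smallest xmin whose tail is statistically consistent
#' with a long-tailed power law: \code{sqrt(m) * D <= ksCritical} (the
#' asymptotic 5\% KS band by default) with a fitted exponent
#' \code{alpha <= alphaMax}. If no candidate qualifies — a sample with no
#' separable foreground tail, e.g. pure background noise — the cutoff
#' falls back to the rightmost candidate, so that at most
#' \code{minTail - 1} points are removed. Values strictly above the cutoff
#' are discarded downstream.
#'
#' The smallest-acceptable-xmin rule is used instead of the global
#' KS-distance minimum: the unnormalized minimum systematically drifts
#' into the background bulk (large smooth tails score small absolute D) or
#' deep into a genuine power-law tail (small tails score small D by
#' chance), truncating the background sample that the normality gate
#' downstream needs intact.
#'
#' @param values numeric sample of pixel intensities (must contain positive
#'   values; non-positive values cannot start a power-law tail and are
#'   never selected as cutoff).
#' @param minPixels minimum sample size (default 20).
#' @param minTail smallest tail size considered in the scan (default 8).
#' @param ksCritical acceptance bound on \code{sqrt(m) * D} (default 1.0).
#' @param alphaMax largest exponent still counted as a long tail (default
#'   8).
#' @return the cutoff intensity (one of the sample values).
#' @examples
#' set.seed(1)
#' v <- c(rnorm(5000, 100, 5), 130 * runif(200)^(-1 / 2.5))
#' powerLawCutoff(v)  # lands at the normal / Pareto-tail junction (~130)
#' @export
powerLawCutoff <- function(values, minPixels = 20L, minTail = 8L,
                           ksCritical = 1.0, alphaMax = 8) {
  values <- values[is.finite(values)]
  if (length(values) < minPixels)
    stop(sprintf("need >= %d values for a tail fit, got %d",
                 minPixels, length(values)))
  if (length(unique(values)) < 2L)
    stop("degenerate sample: all values equal")
  v <- sort(values[values > 0])
  if (length(v) < minTail + 1L)
    stop("too few positive values for a power-law tail fit")
  n <- length(v)
  if (n - which(!duplicated(v))[1L] + 1L < minTail)
    stop("no candidate tail of sufficient size")
  out <- .powerLawScan(v, as.integer(minTail), ksCritical, alphaMax)
  if (is.na(out))
    stop("no candidate tail of sufficient size")
  out
}

#' Trimming configuration for the background-normality gate
#'
#' @param swThreshold Shapiro-Wilk statistic threshold above which a patch
#'   sample counts as normal background (default 0.98).
#' @param maxTrimFraction maximum fraction of the tail-cut sample removed
#'   per side by trimming, in [0, 0.5) (default 0.25; total removal is
#'   capped at twice this).
#' @param trimStep window-halfwidth decrement per iteration, in robust
#'   standard deviations (default 0.25; see [trimToNormality()]).
#' @param windowStart,windowMin first and smallest window halfwidth in
#'   robust standard deviations (defaults 3.5 and 1.75).
#' @param minPixels smallest sample allowed to continue (default 20).
#' @return a validated list of class \code{"TrimConfig"}.
#' @export
trimConfig <- function(swThreshold = 0.98, maxTrimFraction = 0.25,
                       trimStep = 0.25, windowStart = 3.5, windowMin = 1.75,
                       minPixels = 20L) {
  stopifnot(swThreshold > 0, swThreshold <= 1,
            maxTrimFraction >= 0, maxTrimFraction < 0.5,
            trimStep > 0, windowStart > windowMin, windowMin > 0,
            minPixels >= 20L)
  structure(list(swThreshold = swThreshold,
                 maxTrimFraction = maxTrimFraction,
                 trimStep = trimStep,
                 windowStart = windowStart, windowMin = windowMin,
                 minPixels = as.integer(minPixels)),
            class = "TrimConfig")
}

# Shapiro-Wilk statistic; deterministic thinning to <= maxN evenly spaced
# order statistics (the test implementation loses accuracy for very large
# n, and stats::shapiro.test caps at 5000). NA for degenerate samples.
.swStatistic <- function(values, maxN = 4000L) {
  n <- length(values)
  if (n < 3L) return(NA_real_)
  v <- sort(values)
  if (v[1L] == v[n]) return(NA_real_)
  if (n > maxN) v <- v[unique(as.integer(round(seq(1, n, length.out = maxN))))]
  out <- tryCatch(stats::shapiro.test(v)$statistic,
                  error = function(e) NA_real_)
  unname(out)
}

#' Iterative symmetric trimming to normality
#'
#' Isolates the central, normal background component of a tail-cut patch
#' sample by restricting it to a window that is symmetric in value around
#' the robust center: \code{median(v) +/- c * mad(v)}. The halfwidth
#' \code{c} starts at \code{windowStart} robust standard deviations and
#' shrinks by \code{trimStep} per iteration until the Shapiro-Wilk
#' statistic of the windowed sample reaches \code{swThreshold}, the window
#' would remove more than \code{2 * maxTrimFraction} of the input, or
#' \code{c} falls below \code{windowMin}.
#'
#' Trimming equal amounts in value (not in count) from both ends is what
#' removes residual one-sided bright-foreground contamination without
#' biasing the background location: count-symmetric quantile trimming
#' converts a right-side contaminant into a left truncation of the
#' background, which the Shapiro-Wilk gate then rejects.
#'
#' @param values numeric sample (already tail-cut, see [powerLawCutoff()]).
#' @param cfg a [trimConfig()].
#' @return list with \code{values} (trimmed sample), \code{swStatistic}
#'   (final statistic, NA if degenerate), \code{converged} (did the
#'   statistic reach the threshold), \code{iterations}.
#' @export
trimToNormality <- function(values, cfg = trimConfig()) {
  stopifnot(inherits(cfg, "TrimConfig"))
  v <- values[is.finite(values)]
  n0 <- length(v)
  if (n0 == 0L)
    return(list(values = v, swStatistic = NA_real_,
                converged = FALSE, iterations = 0L))
  ctr <- stats::median(v)
  sc <- stats::mad(v)
  if (sc == 0) {
    w <- v[v == ctr]  # dominant tied value: zero-contrast degenerate patch
    return(list(values = w, swStatistic = .swStatistic(w),
                converged = FALSE, iterations = 0L))
  }
  iter <- 0L
  w <- v
  sw <- NA_real_
  for (cc in seq(cfg$windowStart, cfg$windowMin, by = -cfg$trimStep)) {
    w2 <- v[v >= ctr - cc * sc & v <= ctr + cc * sc]
    if (length(w2) < cfg$minPixels ||
        (n0 - length(w2)) / n0 > 2 * cfg$maxTrimFraction)
      break
    w <- w2
    sw <- .swStatistic(w)
    iter <- iter + 1L
    if (!is.na(sw) && sw >= cfg$swThreshold)
      return(list(values = w, swStatistic = sw,
                  converged = TRUE, iterations = iter))
  }
  if (iter == 0L) sw <- .swStatistic(w)
  list(values = w, swStatistic = sw, converged = FALSE, iterations = iter)
}

#' Estimate local background brightness and contrast for one patch
#'
#' The full per-patch pipeline: power-law tail cutoff (foreground removal),
#' iterative symmetric trimming gated by the Shapiro-Wilk statistic, then a
#' maximum-likelihood normal fit of the surviving sample. Brightness B is
#' the fitted mean, contrast C the fitted (ML) standard deviation. The
#' patch is a valid support point only if the normality gate converged and
#' C > 0 (a zero contrast cannot be divided by in the correction).
#'
#' @param pixels numeric vector/matrix of the patch's pixel intensities.
#' @param cfg a [trimConfig()].
#' @param center optional numeric(2) patch center (x, y) recorded in the
#'   result.
#' @return one-row data.frame \code{x, y, B, C, sw, n_used, valid}.
#' @export
estimateSupportPoint <- function(pixels, cfg = trimConfig(),
                                 center = c(NA_real_, NA_real_)) {
  v <- as.numeric(pixels)
  v <- v[is.finite(v)]
  if (length(v) == 0L) stop("empty patch")
  cut <- tryCatch(powerLawCutoff(v, minPixels = cfg$minPixels),
                  error = function(e) NA_real_)
  if (!is.na(cut)) v <- v[v <= cut]  # discard values above the cutoff
  tr <- trimToNormality(v, cfg)
  B <- mean(tr$values)
  C <- sqrt(mean((tr$values - B)^2))  # ML sigma of the normal fit
  if (length(tr$values) == 0L) { B <- NA_real_; C <- NA_real_ }
  data.frame(x = center[1L], y = center[2L],
             B = B, C = C,
             sw = tr$swStatistic,
             n_used = length(tr$values),
             valid = isTRUE(tr$converged) && !is.na(C) && C > 0)
}

#' Estimate all support points of a slice
#'
#' Applies [estimateSupportPoint()] to every patch of the grid, in grid
#' (row-major) order.
#'
#' @param slice numeric matrix (one image slice).
#' @param grid a [PatchGrid] matching the slice shape.
#' @param cfg a [trimConfig()].
#' @param verbose log the valid/invalid counts via [message()].
#' @return data.frame with one row per patch: \code{x, y, B, C, sw, n_used,
#'   valid}.
#' @export
estimateSupportPoints <- function(slice, grid, cfg = trimConfig(),
                                  verbose = FALSE) {
  stopifnot(is.matrix(slice), is(grid, "PatchGrid"))
  if (!identical(dim(slice), as.integer(grid@imageShape)))
    stop("grid does not match the slice shape")
  org <- grid@origins
  out <- vector("list", nrow(org))
  for (i in seq_len(nrow(org))) {
    px <- slice[org$row0[i] + seq_len(grid@patchHeight),
                org$col0[i] + seq_len(grid@patchWidth)]
    out[[i]] <- estimateSupportPoint(px, cfg,
                                     center = c(grid@centers$x[i],
                                                grid@centers$y[i]))
  }
  sp <- do.call(rbind, out)
  rownames(sp) <- NULL
  if (verbose)
    message(sprintf("support points: %d valid / %d invalid of %d patches",
                    sum(sp$valid), sum(!sp$valid), nrow(sp)))
  sp
}

#' Estimate vignetting fields for every slice of a stack
#'
#' Runs STEP 1 (patch-based support-point estimation) and STEP 2 (Gaussian
#' surface fits to the valid support points' B and C values) per slice.
#' Slices with fewer than \code{minPoints} valid support points are flagged
#' uncorrectable (fits set to NULL) rather than fitted from too little
#' data.
#'
#' @param stack an [ImageStack].
#' @param patchSize patch side length (default 32).
#' @param stride grid stride (default \code{patchSize}).
#' @param cfg a [trimConfig()].
#' @param minPoints minimum valid support points per slice (default 15).
#' @param verbose log per-slice summaries.
#' @return list with one element per slice: \code{list(supportPoints,
#'   fitB, fitC, nValid, correctable)}.
#' @export
estimateFields <- function(stack, patchSize = 32L, stride = patchSize,
                           cfg = trimConfig(), minPoints = 15L,
                           verbose = FALSE) {
  stopifnot(is(stack, "ImageStack"))
  grid <- buildPatchGrid(frameShape(stack), patchSize, stride)
  lapply(seq_len(nSlices(stack)), function(i) {
    sp <- estimateSupportPoints(getSlice(stack, i), grid, cfg)
    ok <- sp[sp$valid, , drop = FALSE]
    correctable <- nrow(ok) >= minPoints
    fitB <- fitC <- NULL
    if (correctable) {
      fitB <- fitSurface(data.frame(x = ok$x, y = ok$y, value = ok$B),
                         minPoints = minPoints)
      fitC <- fitSurface(data.frame(x = ok$x, y = ok$y, value = ok$C),
                         minPoints = minPoints)
    }
    if (verbose)
      message(sprintf(
        "slice %d: %d/%d valid patches%s", i, nrow(ok), nrow(sp),
        if (correctable)
          sprintf(", R2(B) = %.3f, R2(C) = %.3f",
                  fitB@rSquared, fitC@rSquared)
        else " -- uncorrectable"))
    list(supportPoints = sp, fitB = fitB, fitC = fitC,
         nValid = nrow(ok), correctable = correctable)
  })
}

#' Correct a whole stack from per-slice field fits
#'
#' @param stack an [ImageStack].
#' @param fields per-slice fits from [estimateFields()] (ground-truth
#'   surfaces may be substituted by wrapping them in the same structure).
#' @param constants a [CorrectionConstants]; default pools them from the
#'   valid support points of all correctable slices ([chooseConstants()]).
#' @param mode "full", "brightness" or "contrast".
#' @return corrected [ImageStack]; uncorrectable slices are passed through
#'   unchanged with a warning.
#' @export
correctStack <- function(stack, fields,
                         constants = NULL,
                         mode = c("full", "brightness", "contrast")) {
  mode <- match.arg(mode)
  stopifnot(is(stack, "ImageStack"), length(fields) == nSlices(stack))
  if (is.null(constants)) {
    sps <- lapply(Filter(function(f) f$correctable, fields),
                  `[[`, "supportPoints")
    constants <- chooseConstants(sps)
  }
  out <- stack
  for (i in seq_len(nSlices(stack))) {
    f <- fields[[i]]
    if (!isTRUE(f$correctable)) {
      warning(sprintf("slice %d uncorrectable: passed through unchanged", i))
      next
    }
    sl <- getSlice(stack, i)
    corrected <- switch(mode,
      full = correctFull(sl, f$fitB, f$fitC, constants),
      brightness = correctBrightness(sl, f$fitB, constants@bT),
      contrast = correctContrast(sl, f$fitB, f$fitC, constants@cT))
    out@intensities[, , i] <- corrected
  }
  out
}
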