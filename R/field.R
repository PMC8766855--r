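#' Evaluate a Gaussian surface at pixel coordinates
#'
#' @param surface a [GaussianSurface].
#' @param x,y numeric vectors of 0-based pixel coordinates (recycled).
#' @return numeric vector of surface values.
#' @examples
#' g <- GaussianSurface(50, c(256, 256), c(300, 280), 10)
#' evalSurface(g, 256, 256)        # peak: A + b
#' evalSurface(g, 256 + 300, 256)  # one-sigma point: A exp(-1/2) + b
#' @export
evalSurface <- function(surface, x, y) {
  stopifnot(is(surface, "GaussianSurface"))
  p <- surface
  p@amplitude * exp(-((x - p@center[1L])^2 / (2 * p@sigma[1L]^2) +
                      (y - p@center[2L])^2 / (2 * p@sigma[2L]^2))) + p@offset
}

#' Evaluate a Gaussian surface over a full pixel grid
#'
#' @param surface a [GaussianSurface].
#' @param shape integer(2) (rows, cols).
#' @return matrix of surface values at 0-based pixel centers.
#' @export
surfaceMatrix <- function(surface, shape) {
  shape <- as.integer(shape)
  x <- seq_len(shape[2L]) - 1  # columns
  y <- seq_len(shape[1L]) - 1  # rows
  gx <- exp(-(x - surface@center[1L])^2 / (2 * surface@sigma[1L]^2))
  gy <- exp(-(y - surface@center[2L])^2 / (2 * surface@sigma[2L]^2))
  surface@amplitude * (gy %o% gx) + surface@offset
}

#' Fit a 2D Gaussian surface to scattered support points
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) over the six
#' parameters (A, x0, y0, sigma_x, sigma_y, b). Initialization: b0 = min
#' value, A0 = max - min, (x0, y0) = value-above-baseline weighted centroid,
#' sigma0 = half the point-cloud side. Bounds keep the widths within
#' \code{sigmaBounds} and the center within one side length of the domain,
#' preventing needle-shaped or runaway solutions; vignetting surfaces are
#' wide and near-centered, so the bounds are not normally active.
#'
#' @param points data.frame with columns \code{x}, \code{y}, \code{value}
#'   (support-point coordinates and local brightness/contrast estimates).
#' @param minPoints minimum number of points required (default 15,
#'   2.5x the free parameters); fewer raises an error.
#' @param sigmaBounds numeric(2) lower/upper bounds for sigma_x, sigma_y in
#'   pixels; default \code{c(side/16, 10*side)} where side is the larger
#'   extent of the point cloud.
#' @return a [SurfaceFit].
#' @examples
#' g <- GaussianSurface(50, c(256, 256), c(300, 280), 10)
#' set.seed(1)
#' pts <- data.frame(x = runif(100, 0, 511), y = runif(100, 0, 511))
#' pts$value <- evalSurface(g, pts$x, pts$y)
#' fit <- fitSurface(pts)
#' rSquared(fit)
#' @export
fitSurface <- function(points, minPoints = 15L, sigmaBounds = NULL) {
  stopifnot(is.data.frame(points),
            all(c("x", "y", "value") %in% names(points)))
  points <- points[is.finite(points$value), , drop = FALSE]
  n <- nrow(points)
  if (n < minPoints)
    stop(sprintf("fitSurface needs >= %d support points, got %d",
                 minPoints, n))
  v <- points$value
  ssTot <- sum((v - mean(v))^2)
  if (ssTot == 0)
    stop("all support values are equal: a flat surface has no Gaussian fit")

  side <- max(diff(range(points$x)), diff(range(points$y)), 1)
  if (is.null(sigmaBounds)) sigmaBounds <- c(side / 16, 10 * side)
  b0 <- min(v)
  A0 <- max(v) - b0
  w <- v - b0
  if (sum(w) <= 0) w <- rep(1, n)
  x00 <- sum(points$x * w) / sum(w)
  y00 <- sum(points$y * w) / sum(w)
  s0 <- min(max(side / 2, sigmaBounds[1L]), sigmaBounds[2L])

  start <- c(A = A0, x0 = x00, y0 = y00, sx = s0, sy = s0, b = b0)
  lower <- c(A = 0,
             x0 = min(points$x) - side, y0 = min(points$y) - side,
             sx = sigmaBounds[1L], sy = sigmaBounds[1L], b = -Inf)
  upper <- c(A = Inf,
             x0 = max(points$x) + side, y0 = max(points$y) + side,
             sx = sigmaBounds[2L], sy = sigmaBounds[2L], b = Inf)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      value ~ A * exp(-((x - x0)^2 / (2 * sx^2) +
                        (y - y0)^2 / (2 * sy^2))) + b,
      data = points, start = as.list(start),
      lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop(sprintf(
        "Gaussian surface fit failed (%s); initialization was A=%.4g, x0=%.4g, y0=%.4g, sigma=%.4g, b=%.4g",
        conditionMessage(e), A0, x00, y00, s0, b0), call. = FALSE))

  p <- stats::coef(fit)
  res <- stats::resid(fit)
  r2 <- 1 - sum(res^2) / ssTot
  new("SurfaceFit",
      surface = GaussianSurface(p[["A"]], c(p[["x0"]], p[["y0"]]),
                                c(p[["sx"]], p[["sy"]]), p[["b"]]),
      rSquared = r2, nPoints = as.integer(n),
      residualRMS = sqrt(mean(res^2)))
}

# resolve a field argument (GaussianSurface | SurfaceFit | matrix) to a
# matrix conformable with `shape`
.fieldMatrix <- function(field, shape) {
  if (is(field, "SurfaceFit")) field <- field@surface
  if (is(field, "GaussianSurface")) return(surfaceMatrix(field, shape))
  if (is.matrix(field)) {
    if (!identical(dim(field), as.integer(shape)))
      stop("field matrix shape does not match the image")
    return(field)
  }
  stop("field must be a GaussianSurface, SurfaceFit or matrix")
}

.checkContrastFloor <- function(mc, cT, floor = 1e-3) {
  bad <- which(mc < floor * cT, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf(
      "contrast field below floor (%.3g x C_T) at %d pixel(s), first at (x=%d, y=%d)",
      floor, nrow(bad), bad[1L, 2L] - 1L, bad[1L, 1L] - 1L))
  invisible(TRUE)
}

.applyPerSlice <- function(image, fun) {
  if (is(image, "ImageStack")) {
    a <- image@intensities
    for (i in seq_len(dim(a)[3L])) a[, , i] <- fun(a[, , i])
    out <- image
    out@intensities <- a
    out
  } else if (is.matrix(image)) {
    fun(image)
  } else stop("image must be an ImageStack or a matrix")
}

#' Vignetting correction formulas
#'
#' Pixelwise corrections of an observed image \code{I0} given the estimated
#' brightness field \code{M_B(x,y)} and contrast (gain) field
#' \code{M_C(x,y)}:
#' \itemize{
#'   \item full: \code{I = C_T (I0 - M_B) / M_C + B_T} (brightness and
#'     contrast equalized, background mapped to N(B_T, C_T));
#'   \item brightness-only: \code{I = I0 - M_B + B_T};
#'   \item contrast-only: \code{I = C_T (I0 - M_B) / M_C + M_B} (gain
#'     equalized, local brightness restored).
#' }
#' All arithmetic is floating point; the division raises an error if the
#' contrast field falls below \code{1e-3 * C_T} anywhere, rather than
#' silently amplifying noise.
#'
#' @param image an [ImageStack] or a single-slice matrix.
#' @param mB,mC brightness/contrast fields: [GaussianSurface], [SurfaceFit]
#'   or precomputed matrix of the slice shape.
#' @param constants a [CorrectionConstants] (B_T, C_T).
#' @param bT target brightness for the brightness-only correction.
#' @return corrected image of the same class as \code{image}.
#' @seealso [fitSurface()], [chooseConstants()], [correctStack()]
#' @examples
#' img <- matrix(rnorm(64, 100, 5), 8, 8)
#' ident <- correctFull(img, GaussianSurface(0, c(0, 0), c(1, 1), 0),
#'                      GaussianSurface(0, c(0, 0), c(1, 1), 1),
#'                      CorrectionConstants(0, 1))
#' all.equal(ident, img)
#' @export
correctFull <- function(image, mB, mC, constants) {
  stopifnot(is(constants, "CorrectionConstants"))
  .applyPerSlice(image, function(m) {
    MB <- .fieldMatrix(mB, dim(m))
    MC <- .fieldMatrix(mC, dim(m))
    .checkContrastFloor(MC, constants@cT)
    constants@cT * (m - MB) / MC + constants@bT
  })
}

#' @rdname correctFull
#' @export
correctBrightness <- function(image, mB, bT = 0) {
  .applyPerSlice(image, function(m) {
    MB <- .fieldMatrix(mB, dim(m))
    m - MB + bT
  })
}

#' @rdname correctFull
#' @export
correctContrast <- function(image, mB, mC, cT) {
  stopifnot(is.numeric(cT), length(cT) == 1L, cT > 0)
  .applyPerSlice(image, function(m) {
    MB <- .fieldMatrix(mB, dim(m))
    MC <- .fieldMatrix(mC, dim(m))
    .checkContrastFloor(MC, cT)
    cT * (m - MB) / MC + MB
  })
}

#' Pool correction constants from support points
#'
#' Default policy: B_T is the mean brightness and C_T the mean contrast of
#' all valid support points pooled over the supplied slices, held constant
#' for the whole stack so the corrected background statistics are unified
#' in the superior-inferior direction.
#'
#' @param supportPoints a support-point data.frame (see
#'   [estimateSupportPoints()]) or a list of them (one per slice).
#' @param policy "mean" (default) or "median".
#' @return a [CorrectionConstants].
#' @export
chooseConstants <- function(supportPoints, policy = c("mean", "median")) {
  policy <- match.arg(policy)
  if (is.data.frame(supportPoints)) supportPoints <- list(supportPoints)
  sp <- do.call(rbind, supportPoints)
  sp <- sp[sp$valid, , drop = FALSE]
  if (nrow(sp) == 0)
    stop("no valid support points to pool constants from")
  f <- if (policy == "mean") mean else stats::median
  CorrectionConstants(bT = f(sp$B), cT = f(sp$C))
}
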