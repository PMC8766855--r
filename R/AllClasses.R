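#' @import methods
NULL

#' ImageStack: a single-channel 3D image stack
#'
#' Container for a stack of same-sized grayscale slices, stored as a 3D
#' numeric array indexed \code{[row, col, slice]}. Public pixel coordinates
#' throughout the package are 0-based with \code{x} = column and
#' \code{y} = row, and pixel centers at integer coordinates; slice indices
#' in tables and file formats are 0-based as well.
#'
#' @slot intensities 3D numeric array \code{[row, col, slice]}, all finite.
#' @slot pixelSizeXY optional in-plane pixel edge length (length units).
#' @slot sliceSpacing optional z spacing between slices (length units).
#'
#' @examples
#' s <- ImageStack(matrix(rnorm(64, 100, 5), 8, 8))
#' nSlices(s)
#' dim(getSlice(s, 1))
#' @export
setClass("ImageStack",
  representation(
    intensities = "array",
    pixelSizeXY = "numeric",
    sliceSpacing = "numeric"
  ),
  prototype(
    pixelSizeXY = NA_real_,
    sliceSpacing = NA_real_
  )
)

setValidity("ImageStack", function(object) {
  a <- object@intensities
  if (length(dim(a)) != 3L)
    return("intensities must be a 3D array [row, col, slice]")
  if (any(dim(a) < 1L))
    return("all dimensions must be >= 1")
  if (!all(is.finite(a)))
    return("all intensities must be finite")
  TRUE
})

#' @rdname ImageStack-class
#' @param x a 3D array \code{[row, col, slice]}, a matrix (one slice), or a
#'   list of equally sized matrices.
#' @param pixelSizeXY,sliceSpacing optional physical metadata.
#' @export
ImageStack <- function(x, pixelSizeXY = NA_real_, sliceSpacing = NA_real_) {
  if (is.list(x)) {
    d <- dim(x[[1L]])
    if (!all(vapply(x, function(m) identical(dim(m), d), logical(1L))))
      stop("all slices must have identical shape")
    x <- array(unlist(x, use.names = FALSE), dim = c(d, length(x)))
  } else if (is.matrix(x)) {
    x <- array(x, dim = c(dim(x), 1L))
  }
  storage.mode(x) <- "double"
  new("ImageStack", intensities = x,
      pixelSizeXY = as.numeric(pixelSizeXY),
      sliceSpacing = as.numeric(sliceSpacing))
}

#' GaussianSurface: axis-aligned 2D Gaussian + offset
#'
#' Parameterization used for the vignetting brightness field M_B(x,y) and
#' contrast (gain) field M_C(x,y):
#' \deqn{f(x,y) = A \exp\{-[(x-x_0)^2/(2\sigma_x^2) +
#'   (y-y_0)^2/(2\sigma_y^2)]\} + b}
#'
#' @slot amplitude peak height A above the offset (intensity units).
#' @slot center numeric(2), (x0, y0) in 0-based pixel coordinates.
#' @slot sigma numeric(2), (sigma_x, sigma_y) > 0 in pixels.
#' @slot offset constant baseline b (intensity units).
#'
#' @examples
#' g <- GaussianSurface(50, c(255.5, 255.5), c(300, 300), 10)
#' evalSurface(g, 255.5, 255.5)  # A + b
#' @export
setClass("GaussianSurface",
  representation(
    amplitude = "numeric",
    center = "numeric",
    sigma = "numeric",
    offset = "numeric"
  )
)

setValidity("GaussianSurface", function(object) {
  if (length(object@amplitude) != 1L || length(object@offset) != 1L)
    return("amplitude and offset must be scalars")
  if (length(object@center) != 2L || length(object@sigma) != 2L)
    return("center and sigma must have length 2")
  if (!all(is.finite(c(object@amplitude, object@center, object@sigma,
                       object@offset))))
    return("all parameters must be finite")
  if (any(object@sigma <= 0))
    return("sigma_x and sigma_y must be > 0")
  TRUE
})

#' @rdname GaussianSurface-class
#' @param amplitude,center,sigma,offset surface parameters (see slots).
#' @export
GaussianSurface <- function(amplitude, center, sigma, offset = 0) {
  if (length(sigma) == 1L) sigma <- c(sigma, sigma)
  new("GaussianSurface", amplitude = as.numeric(amplitude),
      center = as.numeric(center), sigma = as.numeric(sigma),
      offset = as.numeric(offset))
}

#' SurfaceFit: a fitted Gaussian surface with diagnostics
#'
#' @slot surface the fitted [GaussianSurface].
#' @slot rSquared coefficient of determination over the support points.
#' @slot nPoints number of support points used.
#' @slot residualRMS root-mean-square residual (intensity units).
#' @export
setClass("SurfaceFit",
  representation(
    surface = "GaussianSurface",
    rSquared = "numeric",
    nPoints = "integer",
    residualRMS = "numeric"
  )
)

setValidity("SurfaceFit", function(object) {
  if (object@rSquared > 1) return("rSquared must be <= 1")
  if (object@nPoints < 6L) return("nPoints must be >= number of parameters")
  TRUE
})

#' PatchGrid: a rectangular grid of image patches
#'
#' Patch domains are half-open 0-based pixel index ranges
#' \code{[col0, col0+width) x [row0, row0+height)}; the patch center is the
#' arithmetic mean of the domain corner pixel centers, i.e.
#' \code{col0 + (width-1)/2}. Patches are ordered row-major.
#'
#' @slot patchWidth,patchHeight patch side lengths (pixels), >= 8.
#' @slot stride grid stride (pixels).
#' @slot origins data.frame with 0-based \code{col0}, \code{row0}.
#' @slot centers data.frame with patch centers \code{x}, \code{y}.
#' @slot imageShape integer(2) (rows, cols) of the parent image.
#' @export
setClass("PatchGrid",
  representation(
    patchWidth = "integer",
    patchHeight = "integer",
    stride = "integer",
    origins = "data.frame",
    centers = "data.frame",
    imageShape = "integer"
  )
)

setValidity("PatchGrid", function(object) {
  if (object@patchWidth < 8L || object@patchHeight < 8L)
    return("patch side lengths must be >= 8 pixels")
  if (nrow(object@origins) != nrow(object@centers))
    return("origins and centers must align")
  if (any(object@origins$col0 < 0L) || any(object@origins$row0 < 0L) ||
      any(object@origins$col0 + object@patchWidth > object@imageShape[2L]) ||
      any(object@origins$row0 + object@patchHeight > object@imageShape[1L]))
    return("every patch domain must lie inside the image")
  if (anyDuplicated(object@centers))
    return("patch centers must be unique")
  TRUE
})

#' RegionGrid: the 4x4 center/edge/corner partition of a slice
#'
#' The slice is divided into 4x4 cells (remainder pixels absorbed by the
#' last row/column of cells). Corner cells are labelled A1..A4 (row-major),
#' the central 2x2 cells C1..C4 (row-major), and the remaining non-corner
#' border cells E1..E8 (row-major).
#'
#' @slot rowBreaks,colBreaks integer(5) 0-based half-open cell boundaries.
#' @slot labels 4x4 character matrix of region labels.
#' @slot shape integer(2) (rows, cols).
#' @export
setClass("RegionGrid",
  representation(
    rowBreaks = "integer",
    colBreaks = "integer",
    labels = "matrix",
    shape = "integer"
  )
)

setValidity("RegionGrid", function(object) {
  lab <- object@labels
  if (!identical(dim(lab), c(4L, 4L)))
    return("labels must be a 4x4 matrix")
  ty <- substr(lab, 1L, 1L)
  if (sum(ty == "C") != 4L || sum(ty == "E") != 8L || sum(ty == "A") != 4L)
    return("partition must contain 4 C, 8 E and 4 A regions")
  if (anyDuplicated(as.vector(lab)))
    return("region labels must be unique")
  TRUE
})

#' CorrectionConstants: the target brightness/contrast of corrected images
#'
#' The additive constant B_T and multiplicative constant C_T that set the
#' value range of the corrected image; they are held fixed for a whole
#' stack so background statistics are unified across slices.
#'
#' @slot bT target background brightness (intensity units).
#' @slot cT target background contrast, > 0 (intensity units).
#' @export
setClass("CorrectionConstants",
  representation(bT = "numeric", cT = "numeric")
)

setValidity("CorrectionConstants", function(object) {
  if (length(object@bT) != 1L || length(object@cT) != 1L)
    return("bT and cT must be scalars")
  if (!is.finite(object@cT) || object@cT <= 0)
    return("cT must be finite and > 0")
  TRUE
})

#' @rdname CorrectionConstants-class
#' @param bT,cT target background brightness and contrast.
#' @export
CorrectionConstants <- function(bT, cT) {
  new("CorrectionConstants", bT = as.numeric(bT), cT = as.numeric(cT))
}

#' PhantomSpec: parameters of the synthetic vignetting phantom
#'
#' Describes a two-day synthetic stack pair: an undistorted scene of
#' Gaussian background noise plus disk-shaped neurons, observed through a
#' known vignetting distortion (the generative inverse of the correction
#' formula), so that every downstream stage can be validated against ground
#' truth.
#'
#' @slot width,height frame size in pixels.
#' @slot nSlices number of slices per day.
#' @slot brightnessField,contrastField ground-truth [GaussianSurface]s for
#'   M_B and M_C; the contrast field must be positive over the frame.
#' @slot backgroundMean,backgroundStd the undistorted scene's background
#'   Normal parameters (the scene-truth constants B_T, C_T).
#' @slot neuronsPerSlice,neuronRadius,amplitudeRange neuron blob layout:
#'   count per slice, disk radius (pixels), and Uniform(min, max) amplitude
#'   range above the background mean.
#' @slot dayCorrelation correlation of day-1 with day-0 amplitudes, in [0,1].
#' @slot neuronShape "disk" (constant disks, default) or "gaussian" (bumps).
#' @slot layers character vector, one layer label per slice.
#' @slot noiseModel background noise family; only "gaussian".
#' @slot seed integer seed driving all generator streams.
#' @export
setClass("PhantomSpec",
  representation(
    width = "integer",
    height = "integer",
    nSlices = "integer",
    brightnessField = "GaussianSurface",
    contrastField = "GaussianSurface",
    backgroundMean = "numeric",
    backgroundStd = "numeric",
    neuronsPerSlice = "integer",
    neuronRadius = "numeric",
    amplitudeRange = "numeric",
    dayCorrelation = "numeric",
    neuronShape = "character",
    layers = "character",
    noiseModel = "character",
    seed = "integer"
  )
)

setValidity("PhantomSpec", function(object) {
  if (object@width < 1L || object@height < 1L || object@nSlices < 1L)
    return("width, height and nSlices must be >= 1")
  if (object@neuronRadius < 1)
    return("neuronRadius must be >= 1 pixel")
  if (object@backgroundStd <= 0)
    return("backgroundStd must be > 0")
  if (object@dayCorrelation < 0 || object@dayCorrelation > 1)
    return("dayCorrelation must be in [0, 1]")
  if (!object@noiseModel %in% "gaussian")
    return("noiseModel must be 'gaussian'")
  if (!object@neuronShape %in% c("disk", "gaussian"))
    return("neuronShape must be 'disk' or 'gaussian'")
  if (length(object@layers) != object@nSlices)
    return("layers must have one label per slice")
  if (length(object@amplitudeRange) != 2L ||
      object@amplitudeRange[1L] > object@amplitudeRange[2L] ||
      any(object@amplitudeRange < 0))
    return("amplitudeRange must be an increasing non-negative pair")
  # contrast field must be positive everywhere on the frame; with an
  # axis-aligned Gaussian the extrema over a rectangle lie at the corners
  # or at the peak, all of which reduce to checking min(b, corners)
  xs <- c(0, object@width - 1)
  ys <- c(0, object@height - 1)
  corner <- outer(xs, ys, function(x, y) evalSurface(object@contrastField, x, y))
  lo <- min(corner, object@contrastField@offset +
              min(0, object@contrastField@amplitude))
  if (lo <= 0)
    return("contrastField must evaluate > 0 everywhere on the frame")
  TRUE
})

#' Phantom: a generated two-day synthetic stack pair with ground truth
#'
#' @slot stackDay0,stackDay1 observed (vignetted) [ImageStack]s.
#' @slot trueDay0,trueDay1 undistorted scene [ImageStack]s.
#' @slot neuronTable data.frame \code{neuron_id, x, y, slice, layer,
#'   activity_day0, activity_day1} (0-based x, y, slice; activities are the
#'   true-scene center-pixel values).
#' @slot brightnessField,contrastField the ground-truth fields.
#' @slot spec the generating [PhantomSpec].
#' @export
setClass("Phantom",
  representation(
    stackDay0 = "ImageStack",
    stackDay1 = "ImageStack",
    trueDay0 = "ImageStack",
    trueDay1 = "ImageStack",
    neuronTable = "data.frame",
    brightnessField = "GaussianSurface",
    contrastField = "GaussianSurface",
    spec = "PhantomSpec"
  )
)

setValidity("Phantom", function(object) {
  d <- dim(object@stackDay0@intensities)
  if (!identical(d, dim(object@stackDay1@intensities)) ||
      !identical(d, dim(object@trueDay0@intensities)) ||
      !identical(d, dim(object@trueDay1@intensities)))
    return("stacks and true scenes must have identical shapes")
  nt <- object@neuronTable
  need <- c("neuron_id", "x", "y", "slice", "layer",
            "activity_day0", "activity_day1")
  if (!all(need %in% names(nt)))
    return(paste("neuronTable must contain columns:",
                 paste(need, collapse = ", ")))
  if (nrow(nt) > 0 &&
      (any(nt$x < 0) || any(nt$x > d[2L] - 1) ||
       any(nt$y < 0) || any(nt$y > d[1L] - 1) ||
       any(nt$slice < 0) || any(nt$slice > d[3L] - 1)))
    return("every neuron center must lie inside the image domain")
  TRUE
})
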