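#' @name accessors
#' @title Accessors for vigncorr classes
#' @param x,object an object of the documented class.
#' @param i slice index (1-based, as usual for R containers).
#' @description Slot access for the package's S4 containers. Slices are
#'   addressed 1-based through \code{getSlice} (R indexing); pixel
#'   coordinates inside tables remain 0-based.
NULL

#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname accessors
#' @export
setMethod("intensities", "ImageStack", function(x) x@intensities)

#' @rdname accessors
#' @export
setGeneric("nSlices", function(x) standardGeneric("nSlices"))

#' @rdname accessors
#' @export
setMethod("nSlices", "ImageStack", function(x) dim(x@intensities)[3L])

#' @rdname accessors
#' @export
setGeneric("frameShape", function(x) standardGeneric("frameShape"))

#' @rdname accessors
#' @export
setMethod("frameShape", "ImageStack", function(x) dim(x@intensities)[1:2])

#' @rdname accessors
#' @export
setGeneric("getSlice", function(x, i) standardGeneric("getSlice"))

#' @rdname accessors
#' @export
setMethod("getSlice", "ImageStack", function(x, i) {
  stopifnot(length(i) == 1L, i >= 1L, i <= nSlices(x))
  x@intensities[, , i]
})

#' @rdname accessors
#' @export
setGeneric("surfaceParams", function(x) standardGeneric("surfaceParams"))

#' @rdname accessors
#' @export
setMethod("surfaceParams", "GaussianSurface", function(x) {
  c(A = x@amplitude, x0 = x@center[1L], y0 = x@center[2L],
    sx = x@sigma[1L], sy = x@sigma[2L], b = x@offset)
})

#' @rdname accessors
#' @export
setMethod("surfaceParams", "SurfaceFit", function(x) surfaceParams(x@surface))

#' @rdname accessors
#' @export
setGeneric("fittedSurface", function(x) standardGeneric("fittedSurface"))

#' @rdname accessors
#' @export
setMethod("fittedSurface", "SurfaceFit", function(x) x@surface)

#' @rdname accessors
#' @export
setGeneric("rSquared", function(x) standardGeneric("rSquared"))

#' @rdname accessors
#' @export
setMethod("rSquared", "SurfaceFit", function(x) x@rSquared)

#' @rdname accessors
#' @export
setGeneric("patchCenters", function(x) standardGeneric("patchCenters"))

#' @rdname accessors
#' @export
setMethod("patchCenters", "PatchGrid", function(x) x@centers)

#' @rdname accessors
#' @export
setGeneric("nPatches", function(x) standardGeneric("nPatches"))

#' @rdname accessors
#' @export
setMethod("nPatches", "PatchGrid", function(x) nrow(x@origins))

#' @rdname accessors
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))

#' @rdname accessors
#' @export
setMethod("regionLabels", "RegionGrid", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("neuronTable", function(x) standardGeneric("neuronTable"))

#' @rdname accessors
#' @export
setMethod("neuronTable", "Phantom", function(x) x@neuronTable)

#' @rdname accessors
#' @export
setGeneric("trueFields", function(x) standardGeneric("trueFields"))

#' @rdname accessors
#' @export
setMethod("trueFields", "Phantom", function(x)
  list(brightness = x@brightnessField, contrast = x@contrastField))

#' @rdname accessors
#' @export
setGeneric("observedStack", function(x, day = 0L) standardGeneric("observedStack"))

#' @rdname accessors
#' @param day 0 or 1, which imaging day.
#' @export
setMethod("observedStack", "Phantom", function(x, day = 0L) {
  if (day == 0L) x@stackDay0 else if (day == 1L) x@stackDay1
  else stop("day must be 0 or 1")
})

#' @rdname accessors
#' @export
setGeneric("trueScene", function(x, day = 0L) standardGeneric("trueScene"))

#' @rdname accessors
#' @export
setMethod("trueScene", "Phantom", function(x, day = 0L) {
  if (day == 0L) x@trueDay0 else if (day == 1L) x@trueDay1
  else stop("day must be 0 or 1")
})

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@intensities)
  cat(sprintf("ImageStack: %d x %d pixels, %d slice(s)\n", d[1L], d[2L], d[3L]))
  cat(sprintf("  intensity range: [%.4g, %.4g]\n",
              min(object@intensities), max(object@intensities)))
})

setMethod("show", "GaussianSurface", function(object) {
  p <- surfaceParams(object)
  cat("GaussianSurface: f(x,y) = A exp(-[(x-x0)^2/2sx^2 + (y-y0)^2/2sy^2]) + b\n")
  cat(sprintf("  A = %.4g, center = (%.4g, %.4g), sigma = (%.4g, %.4g), b = %.4g\n",
              p["A"], p["x0"], p["y0"], p["sx"], p["sy"], p["b"]))
})

setMethod("show", "SurfaceFit", function(object) {
  show(object@surface)
  cat(sprintf("  fit: R^2 = %.4f on %d support points (residual RMS %.4g)\n",
              object@rSquared, object@nPoints, object@residualRMS))
})

setMethod("show", "PatchGrid", function(object) {
  cat(sprintf("PatchGrid: %d patches of %d x %d px (stride %d) on a %d x %d image\n",
              nPatches(object), object@patchWidth, object@patchHeight,
              object@stride, object@imageShape[1L], object@imageShape[2L]))
})

setMethod("show", "RegionGrid", function(object) {
  cat(sprintf("RegionGrid: 4 x 4 partition of a %d x %d slice\n",
              object@shape[1L], object@shape[2L]))
  print(object@labels, quote = FALSE)
})

setMethod("show", "CorrectionConstants", function(object) {
  cat(sprintf("CorrectionConstants: B_T = %.4g, C_T = %.4g\n",
              object@bT, object@cT))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %d x %d x %d, %d neurons/slice (r = %g px), seed %d\n",
              object@height, object@width, object@nSlices,
              object@neuronsPerSlice, object@neuronRadius, object@seed))
  cat(sprintf("  background N(%.4g, %.4g); day correlation %.2f; layers: %s\n",
              object@backgroundMean, object@backgroundStd,
              object@dayCorrelation,
              paste(unique(object@layers), collapse = ", ")))
})

setMethod("show", "Phantom", function(object) {
  d <- dim(object@stackDay0@intensities)
  cat(sprintf("Phantom: two-day stack pair, %d x %d x %d, %d neurons\n",
              d[1L], d[2L], d[3L], nrow(object@neuronTable)))
})
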