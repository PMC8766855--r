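#' Read and write multi-page grayscale TIFF stacks
#'
#' Stacks are written as little-endian multi-page grayscale TIFF, either
#' 16-bit unsigned (default; values clipped to [0, 65535] and rounded,
#' exact for integer-valued data) or 32-bit IEEE float. The TIFF float
#' path stores values scaled into [0, 1] by \code{scale}; the same scale
#' must be supplied on read (both default to 65535), so a
#' write-then-read round trip needs no sidecar.
#'
#' @param stack an [ImageStack].
#' @param path file path.
#' @param bitsPerSample 16 (unsigned int) or 32 (float).
#' @param scale full-scale value used to map intensities into [0, 1].
#' @return \code{readStack}: an [ImageStack]; \code{writeStack}: the path,
#'   invisibly.
#' @export
writeStack <- function(stack, path, bitsPerSample = 16L, scale = 65535) {
  stopifnot(is(stack, "ImageStack"), bitsPerSample %in% c(16L, 32L))
  a <- stack@intensities
  slices <- lapply(seq_len(dim(a)[3L]), function(i) a[, , i])
  if (bitsPerSample == 16L) {
    slices <- lapply(slices, function(m)
      pmin(pmax(round(m), 0), 65535) / 65535)
  } else {
    if (min(a) < 0 || max(a) > scale)
      stop(sprintf("float TIFF requires intensities within [0, %g]; rescale or raise `scale`", scale))
    slices <- lapply(slices, function(m) m / scale)
  }
  tiff::writeTIFF(slices, path, bits.per.sample = bitsPerSample)
  invisible(path)
}

#' @rdname writeStack
#' @export
readStack <- function(path, scale = 65535) {
  slices <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(slices)) slices <- list(slices)
  slices <- lapply(slices, function(m) {
    bps <- attr(m, "bits.per.sample")
    if (is.null(bps)) bps <- 16L
    # 32 bits per sample is IEEE float (the only 32-bit layout this
    # package writes); 8/16 are unsigned integer
    if (bps == 32L) m * scale else m * (2^bps - 1)
  })
  slices <- lapply(slices, function(m) { attributes(m) <- list(dim = dim(m)); m })
  ImageStack(slices)
}

.surfaceToList <- function(x) {
  if (is.null(x)) return(NULL)
  if (is(x, "SurfaceFit")) {
    p <- surfaceParams(x)
    list(A = unname(p["A"]), x0 = unname(p["x0"]), y0 = unname(p["y0"]),
         sx = unname(p["sx"]), sy = unname(p["sy"]), b = unname(p["b"]),
         r2 = x@rSquared, n_points = x@nPoints,
         residual_rms = x@residualRMS)
  } else {
    p <- surfaceParams(x)
    list(A = unname(p["A"]), x0 = unname(p["x0"]), y0 = unname(p["y0"]),
         sx = unname(p["sx"]), sy = unname(p["sy"]), b = unname(p["b"]))
  }
}

.surfaceFromList <- function(l) {
  if (is.null(l)) return(NULL)
  surf <- GaussianSurface(l$A, c(l$x0, l$y0), c(l$sx, l$sy), l$b)
  if (!is.null(l$r2))
    new("SurfaceFit", surface = surf, rSquared = l$r2,
        nPoints = as.integer(l$n_points),
        residualRMS = if (is.null(l$residual_rms)) NA_real_
                      else l$residual_rms)
  else surf
}

#' Serialize per-slice field fits to JSON
#'
#' One record per slice with the brightness and contrast surface
#' parameters \code{\{A, x0, y0, sx, sy, b, r2, n_points\}} plus the
#' valid-support-point count.
#'
#' @param fields output of [estimateFields()].
#' @param path JSON file path.
#' @return \code{readFields}: a fields list usable by [correctStack()]
#'   (support points are not round-tripped); \code{writeFields}: the path,
#'   invisibly.
#' @export
writeFields <- function(fields, path) {
  recs <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    list(slice = i - 1L,
         n_valid = f$nValid,
         correctable = f$correctable,
         B = .surfaceToList(f$fitB),
         C = .surfaceToList(f$fitC))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname writeFields
#' @export
readFields <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(recs, function(r)
    list(supportPoints = NULL,
         fitB = .surfaceFromList(r$B),
         fitC = .surfaceFromList(r$C),
         nValid = as.integer(r$n_valid),
         correctable = isTRUE(r$correctable)))
}

#' Serialize support points
#'
#' CSV columns \code{x, y, B, C, sw, valid} (plus \code{n_used}).
#'
#' @param sp support-point data.frame (see [estimateSupportPoints()]).
#' @param path CSV file path.
#' @return \code{readSupportPoints}: the data.frame;
#'   \code{writeSupportPoints}: the path, invisibly.
#' @export
writeSupportPoints <- function(sp, path) {
  utils::write.csv(sp[, c("x", "y", "B", "C", "sw", "n_used", "valid")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSupportPoints
#' @export
readSupportPoints <- function(path) {
  utils::read.csv(path)
}

#' Write a neuron activity table as CSV
#'
#' Header \code{neuron_id,x,y,slice,layer,activity_day0,activity_day1}
#' (derived change columns are appended if present).
#'
#' @param table a neuron table.
#' @param path CSV file path.
#' @return \code{readNeuronTable}: the data.frame; \code{writeNeuronTable}:
#'   the path, invisibly.
#' @export
writeNeuronTable <- function(table, path) {
  lead <- c("neuron_id", "x", "y", "slice", "layer",
            "activity_day0", "activity_day1")
  rest <- setdiff(names(table), lead)
  utils::write.csv(table[, c(lead, rest)], path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeNeuronTable
#' @export
readNeuronTable <- function(path) {
  utils::read.csv(path)
}

#' Write a phantom to disk
#'
#' Writes the observed and true stacks of both days as multi-page TIFF,
#' the neuron table as CSV and the ground-truth fields plus scene
#' constants as JSON into \code{dir}.
#'
#' @param phantom a [Phantom].
#' @param dir output directory (created if missing).
#' @param bitsPerSample TIFF sample depth (see [writeStack()]).
#' @return the directory, invisibly.
#' @export
writePhantom <- function(phantom, dir, bitsPerSample = 16L) {
  stopifnot(is(phantom, "Phantom"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeStack(phantom@stackDay0, file.path(dir, "stack_day0.tif"), bitsPerSample)
  writeStack(phantom@stackDay1, file.path(dir, "stack_day1.tif"), bitsPerSample)
  writeStack(phantom@trueDay0, file.path(dir, "true_day0.tif"), bitsPerSample)
  writeStack(phantom@trueDay1, file.path(dir, "true_day1.tif"), bitsPerSample)
  writeNeuronTable(phantom@neuronTable, file.path(dir, "neurons.csv"))
  truth <- list(
    brightness_field = .surfaceToList(phantom@brightnessField),
    contrast_field = .surfaceToList(phantom@contrastField),
    scene_background_mean = phantom@spec@backgroundMean,
    scene_background_std = phantom@spec@backgroundStd,
    seed = phantom@spec@seed,
    width = phantom@spec@width, height = phantom@spec@height,
    n_slices = phantom@spec@nSlices)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
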