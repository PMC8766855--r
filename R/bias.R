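.REGION_ORDER <- c(paste0("C", 1:4), paste0("E", 1:8), paste0("A", 1:4))
.TYPE_PAIRS <- c("C-C", "C-E", "C-A", "E-E", "E-A", "A-A")

#' Build the 4x4 center/edge/corner region partition
#'
#' Divides a slice into 4x4 equally sized cells (remainder pixels go to the
#' last row/column of cells) and labels them deterministically: corner
#' cells A1..A4 (row-major), central 2x2 cells C1..C4 (row-major), the
#' remaining non-corner border cells E1..E8 (row-major).
#'
#' @param shape integer(2) (rows, cols), each >= 4.
#' @return a [RegionGrid].
#' @examples
#' g <- buildRegionGrid(c(512, 512))
#' regionLabels(g)
#' table(substr(regionLabels(g), 1, 1))  # A 4, C 4, E 8
#' @export
buildRegionGrid <- function(shape) {
  shape <- as.integer(shape)
  if (any(shape < 4L)) stop("slice must be at least 4 x 4 pixels")
  cell <- shape %/% 4L
  rowBreaks <- c(0L, cell[1L] * 1:3, shape[1L])
  colBreaks <- c(0L, cell[2L] * 1:3, shape[2L])
  type <- matrix("E", 4L, 4L)
  type[2:3, 2:3] <- "C"
  type[c(1L, 4L), c(1L, 4L)] <- "A"
  lab <- matrix("", 4L, 4L)
  counts <- c(A = 0L, C = 0L, E = 0L)
  for (r in 1:4) for (cc in 1:4) {  # row-major numbering within each type
    ty <- type[r, cc]
    counts[ty] <- counts[ty] + 1L
    lab[r, cc] <- paste0(ty, counts[ty])
  }
  new("RegionGrid", rowBreaks = rowBreaks, colBreaks = colBreaks,
      labels = lab, shape = shape)
}

#' Map pixel coordinates to region labels
#'
#' @param grid a [RegionGrid].
#' @param x,y numeric vectors of 0-based pixel coordinates.
#' @return character vector of region labels (e.g. "C1", "E5", "A4").
#' @export
regionOfPoint <- function(grid, x, y) {
  stopifnot(is(grid, "RegionGrid"))
  if (any(x < 0 | x >= grid@shape[2L] | y < 0 | y >= grid@shape[1L]))
    stop("coordinates outside the slice")
  ci <- findInterval(x, grid@colBreaks, rightmost.closed = FALSE)
  ri <- findInterval(y, grid@rowBreaks, rightmost.closed = FALSE)
  grid@labels[cbind(ri, ci)]
}

#' Count region pairs by type pair
#'
#' Unordered pairs: within-type k(k-1)/2, cross-type k_a x k_b. For the
#' 4/8/4 partition this gives C-C 6, E-E 28, A-A 6, C-E 32, E-A 32,
#' C-A 16 — 120 pairs in total.
#'
#' @param grid a [RegionGrid].
#' @return named integer vector over the six type pairs.
#' @export
regionPairCounts <- function(grid) {
  k <- table(factor(substr(regionLabels(grid), 1L, 1L),
                    levels = c("C", "E", "A")))
  out <- c("C-C" = unname(k["C"] * (k["C"] - 1) / 2),
           "C-E" = unname(k["C"] * k["E"]),
           "C-A" = unname(k["C"] * k["A"]),
           "E-E" = unname(k["E"] * (k["E"] - 1) / 2),
           "E-A" = unname(k["E"] * k["A"]),
           "A-A" = unname(k["A"] * (k["A"] - 1) / 2))
  storage.mode(out) <- "integer"
  out[.TYPE_PAIRS]
}

#' Read neuron activities from a stack
#'
#' Activity of a neuron is the intensity of the center pixel of its
#' segmentation mask; the same (uncorrected-image) centers are used before
#' and after correction so positions never shift between the raw and the
#' corrected readout.
#'
#' @param stack an [ImageStack].
#' @param centers data.frame with 0-based \code{x}, \code{y}, \code{slice}
#'   (and optionally \code{neuron_id} for error reporting).
#' @return numeric vector of center-pixel intensities, one per row.
#' @export
readActivity <- function(stack, centers) {
  stopifnot(is(stack, "ImageStack"), is.data.frame(centers),
            all(c("x", "y", "slice") %in% names(centers)))
  d <- dim(stack@intensities)
  bad <- centers$x < 0 | centers$x > d[2L] - 1 |
         centers$y < 0 | centers$y > d[1L] - 1 |
         centers$slice < 0 | centers$slice > d[3L] - 1
  if (any(bad)) {
    ids <- if ("neuron_id" %in% names(centers))
      centers$neuron_id[bad] else which(bad) - 1L
    stop(sprintf("neuron center(s) outside the image: %s",
                 paste(utils::head(ids, 10L), collapse = ", ")))
  }
  stack@intensities[cbind(centers$y + 1L, centers$x + 1L,
                          centers$slice + 1L)]
}

#' Build a two-day neuron activity table
#'
#' @param stackDay0,stackDay1 [ImageStack]s for the two imaging days.
#' @param centers data.frame with \code{neuron_id, x, y, slice} and
#'   optionally \code{layer}.
#' @return the centers with \code{activity_day0}, \code{activity_day1},
#'   \code{deltaX} and \code{deltaXRel} columns (see [deriveChanges()]).
#' @export
activityTable <- function(stackDay0, stackDay1, centers) {
  centers$activity_day0 <- readActivity(stackDay0, centers)
  centers$activity_day1 <- readActivity(stackDay1, centers)
  deriveChanges(centers)
}

#' Derive absolute and relative activity changes
#'
#' Adds \code{deltaX = X(day1) - X(day0)} and \code{deltaXRel =
#' [X(day1) - X(day0)] / [X(day1) + X(day0)]} to an activity table. The
#' relative change is NA (flagged, not an error) where the denominator is
#' zero; otherwise it lies in [-1, 1] whenever both activities are
#' non-negative.
#'
#' @param table data.frame with \code{activity_day0}, \code{activity_day1}.
#' @return the table with \code{deltaX}, \code{deltaXRel} columns.
#' @export
deriveChanges <- function(table) {
  stopifnot(all(c("activity_day0", "activity_day1") %in% names(table)))
  d0 <- table$activity_day0; d1 <- table$activity_day1
  table$deltaX <- d1 - d0
  denom <- d1 + d0
  table$deltaXRel <- ifelse(denom == 0, NA_real_, (d1 - d0) / denom)
  table
}

# Welch t-test p-value robust to constant samples
.welchP <- function(a, b) {
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (sa == 0 && sb == 0)
    return(if (mean(a) == mean(b)) 1 else 0)
  stats::t.test(a, b)$p.value
}

#' Pairwise region comparisons of an activity measure
#'
#' For each of the 120 unordered pairs of the 16 regions: a Welch
#' two-sample t-test on the measure (Bonferroni-corrected over the
#' \code{bonferroniFamily} comparisons of one layer x measure family,
#' capped at 1) and the relative standard-deviation difference
#' \code{delta_std = |s_a - s_b| / ((s_a + s_b) / 2)}. Welch's
#' unequal-variance variant is used because vignetting induces
#' heteroscedasticity between regions by construction. Pairs where either
#' region has fewer than 2 neurons with a defined measure are flagged
#' untestable (NA statistics).
#'
#' @param table activity table with \code{x}, \code{y} and the measure
#'   column (see [activityTable()]); optionally \code{layer}.
#' @param grid a [RegionGrid].
#' @param measure column name: "activity_day0", "activity_day1", "deltaX"
#'   or "deltaXRel".
#' @param layer optional layer label to subset on.
#' @param bonferroniFamily size of the correction family (default 120).
#' @return data.frame with one row per region pair: \code{region_a,
#'   region_b, type_pair, n_a, n_b, p_raw, p_corrected, delta_std,
#'   testable}.
#' @export
pairwiseRegionTests <- function(table, grid, measure = "activity_day0",
                                layer = NULL, bonferroniFamily = 120L) {
  stopifnot(measure %in% names(table))
  if (!is.null(layer)) {
    stopifnot("layer" %in% names(table))
    table <- table[table$layer == layer, , drop = FALSE]
  }
  v <- table[[measure]]
  keep <- is.finite(v)
  table <- table[keep, , drop = FALSE]
  v <- v[keep]
  region <- regionOfPoint(grid, table$x, table$y)
  groups <- split(v, factor(region, levels = .REGION_ORDER))

  pairs <- utils::combn(.REGION_ORDER, 2L)
  typeRank <- c(C = 1L, E = 2L, A = 3L)
  out <- data.frame(region_a = pairs[1L, ], region_b = pairs[2L, ])
  ta <- substr(out$region_a, 1L, 1L); tb <- substr(out$region_b, 1L, 1L)
  swap <- typeRank[ta] > typeRank[tb]
  out$type_pair <- ifelse(swap, paste(tb, ta, sep = "-"),
                          paste(ta, tb, sep = "-"))
  out$n_a <- vapply(out$region_a, function(r) length(groups[[r]]), integer(1L))
  out$n_b <- vapply(out$region_b, function(r) length(groups[[r]]), integer(1L))
  out$testable <- out$n_a >= 2L & out$n_b >= 2L
  out$p_raw <- out$p_corrected <- out$delta_std <- NA_real_
  for (i in which(out$testable)) {
    a <- groups[[out$region_a[i]]]; b <- groups[[out$region_b[i]]]
    out$p_raw[i] <- .welchP(a, b)
    sa <- stats::sd(a); sb <- stats::sd(b)
    out$delta_std[i] <- if (sa + sb == 0) 0 else abs(sa - sb) / ((sa + sb) / 2)
  }
  out$p_corrected <- pmin(1, out$p_raw * bonferroniFamily)
  out
}

#' Summarize center-periphery bias by region type pair
#'
#' For each of the six type pairs (C-C, C-E, C-A, E-E, E-A, A-A):
#' \itemize{
#'   \item \code{cp}: fraction of (testable) pairs with non-significant
#'     Bonferroni-corrected differences (\code{p >= pThreshold});
#'   \item \code{deltaC = cp / <cp>_same}, normalizing by the unweighted
#'     mean of the within-type values (C-C, E-E, A-A);
#'   \item \code{deltaStdMean}: mean \code{delta_std} over the pairs;
#'   \item \code{deltaStdRatio = deltaStdMean / <deltaStdMean>_same}.
#' }
#' Values near 1 for the cross-type pairs indicate absence of a
#' center-periphery bias; under vignetting, C-A shows deltaC well below 1
#' and deltaStdRatio well above 1.
#'
#' @param report output of [pairwiseRegionTests()].
#' @param pThreshold significance threshold on corrected p (default 0.01).
#' @return data.frame with one row per type pair: \code{type_pair,
#'   n_pairs, cp, deltaC, deltaStdMean, deltaStdRatio}; the normalized
#'   columns are NA (flagged) if the within-type normalizer is zero.
#' @export
summarizeBias <- function(report, pThreshold = 0.01) {
  rep_ <- report[report$testable, , drop = FALSE]
  out <- data.frame(type_pair = .TYPE_PAIRS)
  out$n_pairs <- vapply(out$type_pair, function(tp)
    sum(rep_$type_pair == tp), integer(1L))
  out$cp <- vapply(out$type_pair, function(tp) {
    p <- rep_$p_corrected[rep_$type_pair == tp]
    if (length(p) == 0L) NA_real_ else mean(p >= pThreshold)
  }, numeric(1L))
  out$deltaStdMean <- vapply(out$type_pair, function(tp) {
    d <- rep_$delta_std[rep_$type_pair == tp]
    if (length(d) == 0L) NA_real_ else mean(d)
  }, numeric(1L))
  same <- c("C-C", "E-E", "A-A")
  cpSame <- mean(out$cp[out$type_pair %in% same])
  dsSame <- mean(out$deltaStdMean[out$type_pair %in% same])
  out$deltaC <- if (!is.na(cpSame) && cpSame > 0) out$cp / cpSame
                else NA_real_
  out$deltaStdRatio <- if (!is.na(dsSame) && dsSame > 0)
    out$deltaStdMean / dsSame else NA_real_
  out[, c("type_pair", "n_pairs", "cp", "deltaC",
          "deltaStdMean", "deltaStdRatio")]
}

#' Identify highly active cells
#'
#' Cells whose relative activity change exceeds the mean plus three times
#' the standard deviation of the measure within the (optional) layer —
#' the memory-trace candidate rule.
#'
#' @param table activity table (see [activityTable()]).
#' @param layer optional layer label to subset on.
#' @param measure column to threshold (default "deltaXRel").
#' @return vector of \code{neuron_id}s in the highly active set H.
#' @export
highlyActiveCells <- function(table, layer = NULL, measure = "deltaXRel") {
  stopifnot(measure %in% names(table), "neuron_id" %in% names(table))
  if (!is.null(layer)) table <- table[table$layer == layer, , drop = FALSE]
  v <- table[[measure]]
  keep <- is.finite(v)
  v <- v[keep]; ids <- table$neuron_id[keep]
  if (length(v) < 2L)
    stop("need >= 2 defined measure values to threshold")
  thr <- mean(v) + 3 * stats::sd(v)
  ids[v > thr]
}

#' Overlap rate of two highly active sets
#'
#' \code{|H_i intersect H_j| / |H_i|}; asymmetric in the reference set
#' H_i. NA (with a warning) if the reference set is empty.
#'
#' @param hi reference set of neuron ids.
#' @param hj comparison set of neuron ids.
#' @return unitless overlap rate in [0, 1], or NA.
#' @export
overlapRate <- function(hi, hj) {
  if (length(hi) == 0L) {
    warning("empty reference set: overlap rate undefined")
    return(NA_real_)
  }
  length(intersect(hi, hj)) / length(unique(hi))
}
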