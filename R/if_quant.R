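#' Automated Otsu threshold for a fluorescence channel
#'
#' Computes the 256-bin histogram threshold that maximizes the between-class
#' variance (Otsu's criterion, the method behind MATLAB's `graythresh`).
#' Intensities are binned by `round(x * 255)`; for the optimal cut after bin
#' `k`, the returned threshold is the midpoint `(k + 0.5) / 255`, which lies
#' strictly between the two classes so that `channel > threshold` reproduces
#' the optimal split exactly. Ties between equally optimal cuts are resolved
#' by their mean, matching `graythresh`'s tie convention.
#'
#' @param channel Numeric matrix with values in `[0, 1]` and at least two
#'   distinct values.
#' @return Threshold in `[0, 1]`.
#' @export
#' @examples
#' x <- matrix(c(rep(0.2, 60), rep(0.8, 40)), 10, 10)
#' auto_threshold(x)  # strictly between 0.2 and 0.8
auto_threshold <- function(channel) {
  if (!is.numeric(channel)) stopf("'channel' must be numeric")
  v <- as.vector(channel)
  if (any(v < 0 | v > 1)) stopf("channel intensities must be in [0, 1]")
  bins <- as.integer(round(v * 255))
  if (length(unique(bins)) < 2L) {
    stopf("constant channel: histogram is degenerate, no threshold exists")
  }
  counts <- tabulate(bins + 1L, nbins = 256L)
  p <- counts / sum(counts)
  levels <- 0:255
  w0 <- cumsum(p)                      # class 0 = bins 0..k
  mu <- cumsum(p * levels)
  mu_t <- mu[256]
  k <- 1:255                           # cut after bin k-1 .. consider 0..254
  w0k <- w0[k]; muk <- mu[k]
  valid <- w0k > 0 & w0k < 1
  sigma_b <- rep(-Inf, 255)
  sigma_b[valid] <- (mu_t * w0k[valid] - muk[valid])^2 /
    (w0k[valid] * (1 - w0k[valid]))
  best <- which(sigma_b == max(sigma_b))
  cut <- mean(best) - 1                # bin index k: class 0 is bins 0..k
  (cut + 0.5) / 255
}

#' Binarize a channel at a fixed threshold
#'
#' Strict comparison: `mask = channel > threshold`, so a pixel exactly at the
#' threshold is background. The threshold is recorded as an attribute for
#' provenance.
#'
#' @param channel Numeric matrix in `[0, 1]`.
#' @param threshold Fixed threshold in `(0, 1)`; default 0.3, the consistent
#'   marker threshold applied to all images of one stain.
#' @return Logical matrix with attribute `threshold`.
#' @export
binarize_fixed <- function(channel, threshold = 0.3) {
  if (threshold <= 0 || threshold >= 1) stopf("'threshold' must be in (0, 1)")
  structure(channel > threshold, threshold = threshold)
}

#' Count nuclei in a binary DAPI mask
#'
#' Labels connected components (8-connected by default) and counts those
#' whose pixel area is at least `min_area`; the inclusive rule means a
#' component of exactly `min_area` pixels is counted. Smaller components
#' (debris) are tallied separately, not silently dropped.
#'
#' @param dapi_mask Logical matrix.
#' @param min_area Minimum component area in pixels (default 15).
#' @param connectivity 4 or 8 (default 8).
#' @return List with `count`, `components` (a [label_components()] result
#'   restricted to retained components), and `n_discarded`.
#' @export
count_nuclei <- function(dapi_mask, min_area = 15, connectivity = 8) {
  comp <- label_components(dapi_mask, connectivity = connectivity)
  keep <- comp$areas >= min_area
  list(count = sum(keep),
       components = filter_components(comp, keep),
       n_discarded = sum(!keep))
}

#' Marker stain area per cell
#'
#' Normalizes a marker mask's positive-pixel area by the nucleus count.
#' Undefined for zero nuclei: that is an error, never a silent zero.
#'
#' @param marker_mask Logical matrix (binarized marker channel).
#' @param nucleus_count Positive integer.
#' @return Pixels per cell (real).
#' @export
stain_area_per_cell <- function(marker_mask, nucleus_count) {
  marker_mask <- assert_binary(marker_mask, "marker_mask")
  if (nucleus_count <= 0) {
    stopf("nucleus_count must be > 0: area per cell is undefined without cells")
  }
  sum(marker_mask) / nucleus_count
}

#' Relative GFP-positive cell count
#'
#' Counts size-filtered connected objects in the GFP and DAPI masks and
#' returns their ratio (GFP over DAPI), the relative number of GFP+ cells
#' normalized to all nuclei. The same size filter is applied to both
#' channels for symmetric debris rejection.
#'
#' @param gfp_mask,dapi_mask Logical matrices of identical shape.
#' @param min_area Minimum object area in pixels (default 15).
#' @param connectivity 4 or 8 (default 8).
#' @return List with `gfp_count`, `dapi_count`, `ratio`.
#' @export
relative_gfp_count <- function(gfp_mask, dapi_mask, min_area = 15,
                               connectivity = 8) {
  gfp_mask <- assert_binary(gfp_mask, "gfp_mask")
  dapi_mask <- assert_binary(dapi_mask, "dapi_mask")
  if (!all(dim(gfp_mask) == dim(dapi_mask))) {
    stopf("gfp_mask and dapi_mask must have identical shape")
  }
  ng <- count_nuclei(gfp_mask, min_area, connectivity)$count
  nd <- count_nuclei(dapi_mask, min_area, connectivity)$count
  if (nd == 0L) stopf("zero DAPI objects: relative count undefined")
  list(gfp_count = ng, dapi_count = nd, ratio = ng / nd)
}

#' Quantify one immunofluorescence image
#'
#' Runs the full per-image IF pipeline on an RGB composite: the blue (DAPI)
#' channel is binarized at an image-specific automated Otsu threshold and
#' size-filtered nuclei are counted; the red and green marker channels are
#' binarized at a fixed consistent threshold and their areas normalized per
#' cell.
#'
#' @param image h x w x 3 array in `[0, 1]` (channels R, G, B = marker_red,
#'   marker_green, dapi).
#' @param marker_threshold Fixed marker threshold (default 0.3).
#' @param min_nucleus_area Size filter in pixels (default 15).
#' @param connectivity 4 or 8.
#' @return List (`quant_result`) with `nucleus_count`, per-marker `*_area`
#'   and `*_area_per_cell`, and the thresholds used.
#' @export
quantify_if <- function(image, marker_threshold = 0.3, min_nucleus_area = 15,
                        connectivity = 8) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L) stopf("'image' must be h x w x 3")
  dapi_thr <- auto_threshold(image[, , 3])
  dapi_mask <- image[, , 3] > dapi_thr
  nuc <- count_nuclei(dapi_mask, min_nucleus_area, connectivity)
  red_mask <- binarize_fixed(image[, , 1], marker_threshold)
  green_mask <- binarize_fixed(image[, , 2], marker_threshold)
  red_area <- sum(red_mask); green_area <- sum(green_mask)
  per_cell <- function(a) if (nuc$count > 0) a / nuc$count else NA_real_
  structure(list(nucleus_count = nuc$count,
                 n_discarded = nuc$n_discarded,
                 red_area = as.integer(red_area),
                 green_area = as.integer(green_area),
                 red_area_per_cell = per_cell(red_area),
                 green_area_per_cell = per_cell(green_area),
                 dapi_threshold = dapi_thr,
                 marker_threshold = marker_threshold),
            class = "quant_result")
}
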