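#' Convert an RGB image to optical density
#'
#' Applies the Beer-Lambert absorbance transform per channel:
#' `OD_c = -log10((I_c + eps) / (i0_c + eps))`. The small offset `eps`
#' (default 1 intensity count) guards the logarithm at zero intensity in
#' quantized acquisitions; set `eps = 0` for continuous synthetic intensities
#' where the exact inverse of the forward model is wanted. OD is 0 at
#' `I = i0` and capped at `log10(i0 + eps)` (reached at `I = 0` when
#' `eps = 1`).
#'
#' @param image Height x width x 3 array of transmitted intensities, in the
#'   same units as `i0` (counts for 8-bit data).
#' @param i0 Incident (background) intensity per channel; scalar or length-3.
#'   Defaults to 255, the 8-bit channel maximum.
#' @param eps Log-guard offset in intensity counts (default 1).
#' @return An `od_image`: list with `od` (h x w x 3 array of optical
#'   densities), `i0` and `eps`.
#' @export
#' @examples
#' img <- array(255, dim = c(2, 2, 3))
#' range(rgb_to_od(img)$od)  # blank field: OD 0
rgb_to_od <- function(image, i0 = 255, eps = 1) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L) stopf("'image' must be a h x w x 3 array")
  if (any(i0 <= 0)) stopf("'i0' must be positive")
  if (length(i0) == 1L) i0 <- rep(i0, 3L)
  if (length(i0) != 3L) stopf("'i0' must be scalar or length 3")
  if (eps < 0) stopf("'eps' must be >= 0")
  if (eps == 0 && any(image <= 0)) {
    stopf("zero or negative intensities need eps > 0")
  }
  od <- image
  for (c in 1:3) od[, , c] <- -log10((image[, , c] + eps) / (i0[c] + eps))
  od[od < 0] <- 0  # intensities above i0 (specular noise) clamp to OD 0
  structure(list(od = od, i0 = i0, eps = eps), class = "od_image")
}

#' Unmix an optical-density image into per-stain density maps
#'
#' Solves, for every pixel, the square linear system `o = t(C) %*% d` where
#' `C` is the stain matrix and `o` the pixel's OD vector, by exact 3x3
#' inversion. Negative solutions (pixels outside the stain simplex, e.g.
#' noise) are clipped to zero; the fraction of pixels with any clipped
#' component is reported as `clip_fraction`, never hidden.
#'
#' @param od An `od_image` from [rgb_to_od()], or a bare h x w x 3 OD array.
#' @param stains A [stain_matrix()]; defaults to [trichrome_stain_matrix()].
#' @return A `density_map`: list with `density` (h x w x 3 array, one plane
#'   per stain, all values >= 0), `stain_names`, and `clip_fraction`.
#' @export
deconvolve <- function(od, stains = trichrome_stain_matrix()) {
  if (inherits(od, "od_image")) od <- od$od
  d <- dim(od)
  if (length(d) != 3L || d[3] != 3L) stopf("'od' must be a h x w x 3 array")
  if (!inherits(stains, "stain_matrix")) stains <- stain_matrix(stains)
  C <- stains$values
  ## o = t(C) d  =>  d = solve(t(C)) o ; vectorized over pixels
  inv <- solve(t(C))
  n <- d[1] * d[2]
  odm <- matrix(od, nrow = n, ncol = 3L)     # pixels x channels
  dens <- odm %*% t(inv)                     # pixels x stains
  clipped <- rowSums(dens < -1e-12) > 0
  dens[dens < 0] <- 0
  out <- array(dens, dim = d)
  dimnames(out) <- list(NULL, NULL, stains$stain_names)
  structure(list(density = out,
                 stain_names = stains$stain_names,
                 clip_fraction = mean(clipped)),
            class = "density_map")
}

#' Collagen content of a trichrome section
#'
#' Measures collagen from the blue-stain density plane of a deconvolved
#' trichrome image. A tissue pixel is collagen-positive when its blue-stain
#' density exceeds `density_threshold` *and* blue is the dominant (arg-max)
#' stain at that pixel; the second condition prevents red/blue bleed-through
#' from being double-counted. Reports the area fraction (the headline
#' metric), plus the mean blue density over tissue and integrated density,
#' since the relative merits of the three summaries depend on staining
#' consistency.
#'
#' @param d A `density_map` from [deconvolve()].
#' @param tissue_mask Logical matrix marking tissue pixels (same h x w).
#'   Default: pixels whose total stain density is positive. See
#'   [tissue_mask_od()] for the OD-based default used by the pipeline.
#' @param density_threshold Minimum blue-stain density for positivity
#'   (default 0.15, dimensionless concentration units).
#' @param blue_stain Name or index of the collagen stain plane (default
#'   `"trichrome_blue"`).
#' @return A `collagen_result`: list with `tissue_px`, `collagen_px`,
#'   `fraction`, `mean_density`, `integrated_density`, `clip_fraction`.
#' @export
collagen_content <- function(d, tissue_mask = NULL, density_threshold = 0.15,
                             blue_stain = "trichrome_blue") {
  if (!inherits(d, "density_map")) stopf("'d' must be a density_map")
  if (density_threshold < 0) stopf("'density_threshold' must be >= 0")
  dens <- d$density
  if (is.character(blue_stain)) {
    blue <- match(blue_stain, d$stain_names)
    if (is.na(blue)) stopf("no stain named '%s'", blue_stain)
  } else blue <- as.integer(blue_stain)
  total <- dens[, , 1] + dens[, , 2] + dens[, , 3]
  if (is.null(tissue_mask)) tissue_mask <- total > 0
  tissue_mask <- assert_binary(tissue_mask, "tissue_mask")
  if (!all(dim(tissue_mask) == dim(dens)[1:2])) {
    stopf("tissue_mask shape does not match density map")
  }
  tissue_px <- sum(tissue_mask)
  if (tissue_px == 0L) stopf("empty tissue mask: collagen fraction undefined")
  b <- dens[, , blue]
  argmax_blue <- b >= dens[, , 1] & b >= dens[, , 2] & b >= dens[, , 3]
  pos <- tissue_mask & (b > density_threshold) & argmax_blue
  collagen_px <- sum(pos)
  structure(list(tissue_px = as.integer(tissue_px),
                 collagen_px = as.integer(collagen_px),
                 fraction = collagen_px / tissue_px,
                 mean_density = mean(b[tissue_mask]),
                 integrated_density = sum(b[tissue_mask]),
                 clip_fraction = d$clip_fraction),
            class = "collagen_result")
}

#' Default OD-based tissue mask
#'
#' Marks pixels with total optical density (summed over channels) above
#' `min_od`, excluding blank background. The default 0.05 is well below the
#' OD of any visibly stained pixel.
#'
#' @param od An `od_image` or h x w x 3 OD array.
#' @param min_od Total-OD cutoff (default 0.05).
#' @return Logical matrix.
#' @export
tissue_mask_od <- function(od, min_od = 0.05) {
  if (inherits(od, "od_image")) od <- od$od
  (od[, , 1] + od[, , 2] + od[, , 3]) > min_od
}
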