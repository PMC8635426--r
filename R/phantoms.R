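## Seeded phantom generators. Every generator returns list(image, truth):
## the rendered image plus machine-readable ground truth computed from the
## realized layout (not the request), so recovery tests compare against what
## was actually drawn.

check_phantom_dims <- function(width, height) {
  if (width < 32 || height < 32) stopf("phantom dimensions must be >= 32")
  c(as.integer(height), as.integer(width))
}

## pixel-centre disk rasterization: TRUE where (r-cr)^2+(c-cc)^2 <= radius^2
disk_pixels <- function(nr, nc, cr, cc, radius) {
  r0 <- max(1L, floor(cr - radius)); r1 <- min(nr, ceiling(cr + radius))
  c0 <- max(1L, floor(cc - radius)); c1 <- min(nc, ceiling(cc + radius))
  if (r0 > r1 || c0 > c1) return(cbind(integer(0), integer(0)))
  rr <- r0:r1; cc2 <- c0:c1
  g <- expand.grid(r = rr, c = cc2)
  keep <- (g$r - cr)^2 + (g$c - cc)^2 <= radius^2
  as.matrix(g[keep, , drop = FALSE])
}

## rejection placement of disjoint disks with a clearance gap (pixels)
place_disks <- function(nr, nc, n, radius_range, gap = 2,
                        max_attempts = 10000L) {
  centers <- matrix(numeric(0), ncol = 2)
  radii <- numeric(0)
  attempts <- 0L
  while (length(radii) < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stopf("placed only %d of %d disks in %d attempts (field too crowded)",
            length(radii), n, max_attempts)
    }
    r <- runif(1, radius_range[1], radius_range[2])
    cr <- runif(1, 1 + r, nr - r)
    cc <- runif(1, 1 + r, nc - r)
    if (length(radii)) {
      dmin <- sqrt((centers[, 1] - cr)^2 + (centers[, 2] - cc)^2)
      if (any(dmin < radii + r + gap)) next
    }
    centers <- rbind(centers, c(cr, cc))
    radii <- c(radii, r)
  }
  list(centers = centers, radii = radii)
}

#' Beer-Lambert forward model
#'
#' Renders transmitted intensities from per-pixel stain densities:
#' `I_c = i0 * 10^(-sum_s d_s * C[s, c])`, so that the optical density of the
#' rendered image is exactly the linear stain mixture `t(C) %*% d`.
#'
#' @param density h x w x 3 array of non-negative stain densities (one plane
#'   per stain, in stain-matrix row order).
#' @param stains A [stain_matrix()].
#' @param i0 Incident intensity (default 255).
#' @return h x w x 3 array of transmitted intensities in `[0, i0]`.
#' @export
beer_lambert_forward <- function(density, stains = trichrome_stain_matrix(),
                                 i0 = 255) {
  if (any(density < 0)) stopf("stain densities must be non-negative")
  if (!inherits(stains, "stain_matrix")) stains <- stain_matrix(stains)
  d <- dim(density)
  if (length(d) != 3L || d[3] != 3L) stopf("'density' must be h x w x 3")
  C <- stains$values
  n <- d[1] * d[2]
  dm <- matrix(density, nrow = n, ncol = 3L)
  od <- dm %*% C                      # pixels x channels: o = t(C) d
  array(i0 * 10^(-od), dim = d)
}

#' Trichrome phantom with known stain densities
#'
#' Generates a synthetic Masson's-trichrome-like field through the
#' Beer-Lambert forward model: a uniform "tissue" plane of red-stain density
#' with randomly placed collagen blobs of blue-stain density covering
#' approximately `collagen_fraction` of the field. Intensities are continuous
#' (unquantized) so that deconvolution recovers the density planes exactly;
#' set `quantize = TRUE` to emulate an 8-bit acquisition.
#'
#' @param width,height Field size in pixels (>= 32).
#' @param seed Integer seed; fully determines the output.
#' @param collagen_fraction Target fraction of pixels carrying blue stain
#'   (blobs are added until coverage reaches it; the realized fraction is in
#'   the ground truth).
#' @param blue_density,red_density Stain densities of collagen blobs and of
#'   the tissue background.
#' @param density Optional h x w x 3 array of densities overriding the blob
#'   layout entirely (constant fields, custom layouts).
#' @param stains A [stain_matrix()].
#' @param i0 Incident intensity (default 255).
#' @param blob_radius Radius range (pixels) for collagen blobs.
#' @param quantize Round intensities to integer counts (default FALSE).
#' @return `list(image, truth)`; `truth` holds the density planes, the
#'   realized `collagen_fraction`, the collagen mask, `i0` and the stain
#'   matrix used.
#' @export
make_trichrome_phantom <- function(width = 192, height = 192, seed = 1,
                                   collagen_fraction = 0.3,
                                   blue_density = 1.0, red_density = 0.4,
                                   density = NULL,
                                   stains = trichrome_stain_matrix(),
                                   i0 = 255, blob_radius = c(8, 16),
                                   quantize = FALSE) {
  hw <- check_phantom_dims(width, height)
  nr <- hw[1]; nc <- hw[2]
  if (!inherits(stains, "stain_matrix")) stains <- stain_matrix(stains)
  withr::with_seed(seed, {
    if (is.null(density)) {
      if (blue_density < 0 || red_density < 0) {
        stopf("stain densities must be non-negative")
      }
      collagen <- matrix(FALSE, nr, nc)
      target <- collagen_fraction * nr * nc
      attempts <- 0L
      while (sum(collagen) < target && attempts < 10000L) {
        attempts <- attempts + 1L
        r <- runif(1, blob_radius[1], blob_radius[2])
        px <- disk_pixels(nr, nc, runif(1, 1, nr), runif(1, 1, nc), r)
        if (nrow(px)) collagen[px] <- TRUE
      }
      density <- array(0, dim = c(nr, nc, 3L))
      density[, , 1] <- red_density * !collagen
      density[, , 2] <- blue_density * collagen
    } else {
      if (any(density < 0)) stopf("stain densities must be non-negative")
      collagen <- density[, , 2] > 0
    }
    img <- beer_lambert_forward(density, stains, i0)
    if (quantize) img <- round(img)
    list(image = img,
         truth = list(kind = "trichrome",
                      density = density,
                      collagen_mask = collagen,
                      collagen_fraction = mean(collagen),
                      i0 = i0,
                      stains = stains))
  })
}

#' Immunofluorescence phantom with known counts and areas
#'
#' Renders a three-channel IF-like field: disjoint DAPI nuclei (disks) in the
#' blue channel and marker blobs in the red and green channels. Foreground
#' objects are rasterized at pixel centres (hard edges), so ground-truth
#' counts and areas are exact integers; optional Gaussian noise emulates
#' detector noise without crossing the thresholds used downstream.
#'
#' @param width,height Field size in pixels (>= 32).
#' @param seed Integer seed.
#' @param n_nuclei Number of DAPI nuclei to place.
#' @param nucleus_radius Radius range (pixels) of nuclei.
#' @param n_red_blobs,n_green_blobs Marker blob counts per channel.
#' @param marker_radius Radius range of marker blobs.
#' @param background,foreground Channel intensity levels in `[0, 1]`.
#' @param noise_sd Gaussian noise standard deviation (default 0.02).
#' @param gap Minimum clearance between objects within a channel (pixels).
#' @return `list(image, truth)`; `truth` holds nucleus count/centres/radii,
#'   per-channel masks, exact pixel areas, and blob counts.
#' @export
make_if_phantom <- function(width = 192, height = 192, seed = 1,
                            n_nuclei = 12, nucleus_radius = c(3, 6),
                            n_red_blobs = 6, n_green_blobs = 4,
                            marker_radius = c(2, 5),
                            background = 0.05, foreground = 0.9,
                            noise_sd = 0.02, gap = 2) {
  hw <- check_phantom_dims(width, height)
  nr <- hw[1]; nc <- hw[2]
  withr::with_seed(seed, {
    render <- function(n, radius_range) {
      mask <- matrix(FALSE, nr, nc)
      if (n == 0) {
        return(list(mask = mask, centers = matrix(numeric(0), ncol = 2),
                    radii = numeric(0), areas = integer(0)))
      }
      pl <- place_disks(nr, nc, n, radius_range, gap = gap)
      areas <- integer(n)
      for (i in seq_len(n)) {
        px <- disk_pixels(nr, nc, pl$centers[i, 1], pl$centers[i, 2],
                          pl$radii[i])
        mask[px] <- TRUE
        areas[i] <- nrow(px)
      }
      list(mask = mask, centers = pl$centers, radii = pl$radii, areas = areas)
    }
    dapi <- render(n_nuclei, nucleus_radius)
    red <- render(n_red_blobs, marker_radius)
    green <- render(n_green_blobs, marker_radius)
    chan <- function(obj) {
      x <- matrix(background, nr, nc)
      x[obj$mask] <- foreground
      if (noise_sd > 0) x <- x + rnorm(nr * nc, 0, noise_sd)
      pmin(pmax(x, 0), 1)
    }
    img <- array(0, dim = c(nr, nc, 3L))
    img[, , 1] <- chan(red)
    img[, , 2] <- chan(green)
    img[, , 3] <- chan(dapi)
    list(image = img,
         truth = list(kind = "if_field",
                      n_nuclei = n_nuclei,
                      nucleus_centers = dapi$centers,
                      nucleus_radii = dapi$radii,
                      nucleus_mask = dapi$mask,
                      nucleus_area = sum(dapi$areas),
                      red_mask = red$mask, green_mask = green$mask,
                      red_area = sum(red$areas),
                      green_area = sum(green$areas),
                      n_red_blobs = n_red_blobs,
                      n_green_blobs = n_green_blobs))
  })
}

## one connected (even 4-connected) component of exactly `area` pixels:
## a rectangle with a partial last row
component_footprint <- function(area) {
  w <- max(1L, floor(sqrt(area)))
  h <- ceiling(area / w)
  full <- h - 1L
  rem <- area - full * w
  rows <- c(rep(seq_len(full), each = w), rep(h, rem))
  cols <- c(rep(seq_len(w), full), seq_len(rem))
  cbind(r = rows, c = cols)
}

#' Multicolour clone-field phantom with known component areas
#'
#' Places mutually non-touching connected components of exact requested pixel
#' areas into colour channels, emulating multicolour (Brainbow-style)
#' reporter fields where contiguous same-colour regions are clones or single
#' cells. Component areas are realized exactly, so the clone/singleton split
#' at any threshold is known.
#'
#' @param width,height Field size in pixels (>= 32).
#' @param seed Integer seed.
#' @param areas Named list of numeric vectors of requested component areas,
#'   names among `"red"`, `"green"`, `"blue"`.
#' @param background,foreground Channel intensity levels.
#' @param clone_min_area Threshold used to record the true clone/singleton
#'   split in the ground truth (default 2000 px).
#' @param max_attempts Placement attempts per component before erroring.
#' @return `list(image, truth)`; `truth` holds per-channel realized areas,
#'   masks, and the true clone/singleton counts at `clone_min_area`.
#' @export
make_clone_phantom <- function(width = 256, height = 256, seed = 1,
                               areas = list(red = c(2500, 1500),
                                            green = c(3000, 120)),
                               background = 0.02, foreground = 0.9,
                               clone_min_area = 2000,
                               max_attempts = 10000L) {
  hw <- check_phantom_dims(width, height)
  nr <- hw[1]; nc <- hw[2]
  chans <- c("red", "green", "blue")
  if (!all(names(areas) %in% chans)) stopf("area channels must be red/green/blue")
  withr::with_seed(seed, {
    occupied <- matrix(FALSE, nr, nc)  # includes 1-px clearance margin
    masks <- list()
    realized <- list()
    for (ch in chans) {
      mask <- matrix(FALSE, nr, nc)
      got <- integer(0)
      for (a in areas[[ch]] %||% numeric(0)) {
        a <- as.integer(a)
        if (a < 1) stopf("component areas must be >= 1")
        fp <- component_footprint(a)
        fh <- max(fp[, "r"]); fw <- max(fp[, "c"])
        if (fh > nr - 2L || fw > nc - 2L) {
          stopf("component of area %d does not fit in a %dx%d field", a, nr, nc)
        }
        placed <- FALSE
        for (att in seq_len(max_attempts)) {
          r0 <- sample.int(nr - fh - 1L, 1L) + 1L
          c0 <- sample.int(nc - fw - 1L, 1L) + 1L
          box <- occupied[(r0 - 1L):(r0 + fh), (c0 - 1L):(c0 + fw)]
          if (any(box)) next
          px <- cbind(fp[, "r"] + r0 - 1L, fp[, "c"] + c0 - 1L)
          mask[px] <- TRUE
          occupied[(r0 - 1L):(r0 + fh), (c0 - 1L):(c0 + fw)] <- TRUE
          placed <- TRUE
          break
        }
        if (!placed) {
          stopf("could not place component of area %d after %d attempts (placed %d so far)",
                a, max_attempts, length(got))
        }
        got <- c(got, a)
      }
      masks[[ch]] <- mask
      realized[[ch]] <- got
    }
    img <- array(background, dim = c(nr, nc, 3L))
    for (i in 1:3) {
      m <- masks[[chans[i]]]
      plane <- img[, , i]
      plane[m] <- foreground
      img[, , i] <- plane
    }
    all_areas <- unlist(realized, use.names = FALSE)
    list(image = img,
         truth = list(kind = "clone_field",
                      areas = realized,
                      masks = masks,
                      clone_min_area = clone_min_area,
                      n_clones = sum(all_areas >= clone_min_area),
                      n_singletons = sum(all_areas < clone_min_area)))
  })
}

#' Sample from the von Mises distribution
#'
#' Best-Fisher rejection sampler. `kappa = 0` gives the uniform circular
#' distribution; `kappa` above the implementation cap `1e6` is treated as the
#' degenerate point mass at `mu`.
#'
#' @param n Number of draws.
#' @param mu Mean direction (radians).
#' @param kappa Concentration parameter, >= 0.
#' @return Numeric vector of angles in `[-pi, pi) + mu`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 0) stopf("'kappa' must be >= 0")
  if (kappa == 0) return(runif(n, -pi, pi) + mu)
  if (kappa >= 1e6) return(rep(mu, n))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(16L, 2L * (n - length(out)))
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    th <- sign(u3[ok] - 0.5) * acos(pmin(pmax(f[ok], -1), 1))
    out <- c(out, th)
  }
  out[seq_len(n)] + mu
}

#' Fibre-texture phantom with von Mises axial orientations
#'
#' Renders anti-aliased line segments whose axial angles follow a von Mises
#' law on the doubled circle: `2*theta ~ vonMises(2*mu, kappa)`, the standard
#' treatment for undirected (axial) data. Ground truth stores the drawn
#' angles, so both distributional and per-image recovery can be tested.
#'
#' @param width,height Field size in pixels (>= 32).
#' @param seed Integer seed.
#' @param n_fibers Number of segments.
#' @param fiber_length,fiber_width Segment geometry in pixels.
#' @param mu Mean axial angle in `[0, pi)`.
#' @param kappa von Mises concentration on doubled angles, >= 0
#'   (0 = isotropic; values above `1e6` collapse to all angles equal to
#'   `mu`).
#' @param background Background intensity.
#' @return `list(image, truth)`; `truth` holds the drawn `angles` (in
#'   `[0, pi)`), `mu`, `kappa`, and the 0.5-coverage fibre mask.
#' @export
make_fiber_phantom <- function(width = 512, height = 512, seed = 1,
                               n_fibers = 600, fiber_length = 40,
                               fiber_width = 2, mu = pi / 3, kappa = 4,
                               background = 0.05) {
  hw <- check_phantom_dims(width, height)
  nr <- hw[1]; nc <- hw[2]
  if (kappa < 0) stopf("'kappa' must be >= 0")
  withr::with_seed(seed, {
    angles <- (mu + rvonmises(n_fibers, 0, kappa) / 2) %% pi
    img <- matrix(background, nr, nc)
    half <- fiber_length / 2
    wr <- fiber_width / 2 + 0.5
    for (i in seq_len(n_fibers)) {
      th <- angles[i]
      ux <- cos(th); uy <- sin(th)          # x = column, y = row
      cx <- runif(1, 1, nc); cy <- runif(1, 1, nr)
      x0 <- cx - half * ux; x1 <- cx + half * ux
      y0 <- cy - half * uy; y1 <- cy + half * uy
      rlo <- max(1L, floor(min(y0, y1) - wr)); rhi <- min(nr, ceiling(max(y0, y1) + wr))
      clo <- max(1L, floor(min(x0, x1) - wr)); chi <- min(nc, ceiling(max(x0, x1) + wr))
      if (rlo > rhi || clo > chi) next
      rows <- rlo:rhi; cols <- clo:chi
      py <- matrix(rows, length(rows), length(cols))
      px <- matrix(cols, length(rows), length(cols), byrow = TRUE)
      t <- pmin(pmax((px - cx) * ux + (py - cy) * uy, -half), half)
      dist <- sqrt((px - cx - t * ux)^2 + (py - cy - t * uy)^2)
      val <- pmin(pmax(fiber_width / 2 + 0.5 - dist, 0), 1)
      img[rows, cols] <- pmax(img[rows, cols], background + (1 - background) * val)
    }
    list(image = img,
         truth = list(kind = "fiber_texture",
                      angles = angles, mu = mu, kappa = kappa,
                      mask = img >= background + (1 - background) * 0.5))
  })
}

#' Binary patterns of known fractal dimension
#'
#' Exact deterministic patterns with analytic box-counting dimension: a
#' filled square (D = 2), a one-pixel horizontal line (D = 1), and the
#' Sierpinski triangle built by the Pascal-mod-2 rule on a `2^depth` grid
#' (D = log 3 / log 2 ~ 1.585). For the Sierpinski pattern the box counts at
#' dyadic sizes are exactly `N(2^k) = 3^(depth - k)`.
#'
#' @param pattern One of `"filled_square"`, `"line"`, `"sierpinski"`.
#' @param depth Grid is `2^depth` on a side (default 7, i.e. 128); depths
#'   above 12 (4096 px) are rejected.
#' @return `list(mask, truth)` with `truth$dimension` the analytic value.
#' @export
make_fractal_phantom <- function(pattern = c("filled_square", "line",
                                             "sierpinski"),
                                 depth = 7) {
  pattern <- match.arg(pattern)
  if (depth < 2 || depth > 12) stopf("'depth' must be in [2, 12]")
  n <- 2L^depth
  mask <- switch(pattern,
    filled_square = matrix(TRUE, n, n),
    line = {
      m <- matrix(FALSE, n, n)
      m[n %/% 2L, ] <- TRUE
      m
    },
    sierpinski = outer(0:(n - 1L), 0:(n - 1L),
                       function(i, j) bitwAnd(i, j) == 0L)
  )
  dimension <- switch(pattern,
    filled_square = 2.0,
    line = 1.0,
    sierpinski = log(3) / log(2)
  )
  list(mask = mask,
       truth = list(kind = "fractal", pattern = pattern, depth = depth,
                    dimension = dimension))
}

#' Generate any phantom kind from a parameter record
#'
#' Thin dispatcher used by the command-line interface: forwards `params` to
#' the kind-specific generator.
#'
#' @param kind One of `"trichrome"`, `"if_field"`, `"clone_field"`,
#'   `"fiber_texture"`, `"fractal"`.
#' @param width,height,seed Passed to the generator (ignored for
#'   `"fractal"`, whose size is set by `params$depth`).
#' @param params Named list of kind-specific arguments.
#' @return The generator's `list(image|mask, truth)`.
#' @export
make_phantom <- function(kind, width = 192, height = 192, seed = 1,
                         params = list()) {
  switch(kind,
    trichrome = do.call(make_trichrome_phantom,
                        c(list(width = width, height = height, seed = seed), params)),
    if_field = do.call(make_if_phantom,
                       c(list(width = width, height = height, seed = seed), params)),
    clone_field = do.call(make_clone_phantom,
                          c(list(width = width, height = height, seed = seed), params)),
    fiber_texture = do.call(make_fiber_phantom,
                            c(list(width = width, height = height, seed = seed), params)),
    fractal = do.call(make_fractal_phantom, params),
    stopf("unknown phantom kind '%s'", kind)
  )
}
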