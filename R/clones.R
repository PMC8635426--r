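#' Label connected components of a binary mask
#'
#' Standard connected-component labelling (8-connected by default; 4
#' available). Labels are contiguous from 1 in raster-scan order of each
#' component's first pixel, so results are deterministic.
#'
#' @param mask Logical (or 0/1) matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return A `labeled_components` list: `labels` (integer matrix), `n`,
#'   `areas` (pixel count per label), `centroids` (n x 2, row/col), and
#'   `connectivity`.
#' @export
label_components <- function(mask, connectivity = 8) {
  mask <- assert_binary(mask)
  connectivity <- as.integer(connectivity)
  labels <- .label_cc(mask, connectivity)
  n <- max(labels)
  if (n == 0L) {
    return(structure(list(labels = labels, n = 0L, areas = integer(0),
                          centroids = matrix(numeric(0), ncol = 2,
                                             dimnames = list(NULL, c("row", "col"))),
                          connectivity = connectivity),
                     class = "labeled_components"))
  }
  idx <- which(labels > 0, arr.ind = TRUE)
  lab <- labels[labels > 0]
  areas <- tabulate(lab, nbins = n)
  centroids <- cbind(row = as.vector(tapply(idx[, 1], lab, mean)),
                     col = as.vector(tapply(idx[, 2], lab, mean)))
  structure(list(labels = labels, n = n, areas = as.integer(areas),
                 centroids = centroids, connectivity = connectivity),
            class = "labeled_components")
}

## keep a logical subset of components (relabelled contiguously)
filter_components <- function(comp, keep) {
  stopifnot(inherits(comp, "labeled_components"), length(keep) == comp$n)
  map <- integer(comp$n)
  map[keep] <- seq_len(sum(keep))
  labels <- comp$labels
  pos <- labels > 0
  labels[pos] <- map[labels[pos]]
  structure(list(labels = labels, n = sum(keep),
                 areas = comp$areas[keep],
                 centroids = comp$centroids[keep, , drop = FALSE],
                 connectivity = comp$connectivity),
            class = "labeled_components")
}

#' Classify components into clones and single cells by area
#'
#' Components with area at or above `clone_min_area` are clones; the rest
#' are single cells (singletons). The 2000-px default delineates contiguous
#' same-colour cell clusters (clones) from single labelled cells in
#' multicolour reporter images; the boundary is inclusive, so a component of
#' exactly `clone_min_area` pixels is a clone.
#'
#' @param components A `labeled_components` from [label_components()], or a
#'   bare numeric vector of areas.
#' @param clone_min_area Area threshold in pixels (default 2000, > 0).
#' @return A `clone_report`: `clone_count`, `singleton_count`,
#'   `clone_areas` (descending), `total_clone_area`, `n_components`.
#' @export
classify_clones <- function(components, clone_min_area = 2000) {
  if (clone_min_area <= 0) stopf("'clone_min_area' must be > 0")
  areas <- if (inherits(components, "labeled_components")) {
    components$areas
  } else {
    as.numeric(components)
  }
  is_clone <- areas >= clone_min_area
  clone_areas <- sort(areas[is_clone], decreasing = TRUE)
  structure(list(clone_count = sum(is_clone),
                 singleton_count = sum(!is_clone),
                 clone_areas = clone_areas,
                 total_clone_area = sum(clone_areas),
                 n_components = length(areas),
                 clone_min_area = clone_min_area),
            class = "clone_report")
}

#' Quantify clones in a multicolour reporter image
#'
#' Each colour channel is binarized at a fixed threshold and labelled
#' independently — in multicolour reporter constructs the colour itself is
#' the clone identity — then the per-channel components are pooled and
#' classified by area.
#'
#' @param image h x w x 3 array in `[0, 1]`.
#' @param threshold Fixed channel threshold (default 0.3).
#' @param clone_min_area Clone area threshold (default 2000 px).
#' @param connectivity 4 or 8.
#' @param channels Channel indices to analyse (default all three).
#' @return A `clone_report` with an extra `per_channel` list of per-channel
#'   reports.
#' @export
quantify_clones <- function(image, threshold = 0.3, clone_min_area = 2000,
                            connectivity = 8, channels = 1:3) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L) stopf("'image' must be h x w x 3")
  comps <- lapply(channels, function(ch) {
    label_components(binarize_fixed(image[, , ch], threshold),
                     connectivity = connectivity)
  })
  per <- lapply(comps, classify_clones, clone_min_area = clone_min_area)
  names(per) <- c("red", "green", "blue")[channels]
  pooled <- classify_clones(unlist(lapply(comps, `[[`, "areas")),
                            clone_min_area)
  pooled$per_channel <- per
  pooled
}

#' Compare clone metrics between groups
#'
#' Per-group mean and SEM of a clone metric with one-way ANOVA and pairwise
#' post hoc comparisons; see [compare_groups()].
#'
#' @param reports Named list of groups, each a list of `clone_report`s
#'   (>= 2 per group).
#' @param metric Which scalar to compare: `"clone_count"`,
#'   `"total_clone_area"`, or `"singleton_count"`.
#' @param posthoc `"tukey"` (default) or `"bh"`.
#' @return A `group_comparison`; see [compare_groups()].
#' @export
compare_clone_groups <- function(reports, metric = "clone_count",
                                 posthoc = c("tukey", "bh")) {
  if (length(reports) < 2L) stopf("need >= 2 groups")
  values <- unlist(lapply(reports, function(g)
    vapply(g, function(r) as.numeric(r[[metric]]), numeric(1))))
  groups <- rep(names(reports), times = vapply(reports, length, integer(1)))
  compare_groups(values, groups, posthoc = match.arg(posthoc))
}
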