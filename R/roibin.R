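## ROI construction: R2 thresholding, group-overlap masks, eccentricity
## binning, stimulus-representation and peripheral V1 ROIs.

#' Threshold a map of R2 values
#'
#' Voxels with R2 strictly greater than `threshold` (the study convention
#' is R2 > 0.1 in the independent localizer).
#'
#' @param r2 Numeric array of coefficients of determination in [0, 1].
#' @param threshold Fraction (default 0.1).
#' @return Logical mask.
#' @export
threshold_by_r2 <- function(r2, threshold = 0.1) {
  if (any(r2 < 0 | r2 > 1, na.rm = TRUE))
    stopf("R2 values must lie in [0, 1]")
  !is.na(r2) & r2 > threshold
}

#' Group-overlap mask
#'
#' Voxels present in at least `ceil(min_fraction * n_subjects)` of the
#' per-subject masks (the study uses one third of the participants).
#'
#' @param masks List of logical arrays on a common grid.
#' @param min_fraction Fraction of subjects required (default 1/3).
#' @return Logical mask.
#' @export
group_overlap_mask <- function(masks, min_fraction = 1/3) {
  if (length(masks) < 1L) stopf("need at least one subject mask")
  dims <- lapply(masks, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stopf("subject masks are not on a common grid")
  count <- Reduce(`+`, lapply(masks, function(m) m * 1))
  need <- ceiling(min_fraction * length(masks))
  count >= need
}

#' Bin an eccentricity map
#'
#' Half-open bins `[e_i, e_{i+1})`, with the last bin closed at the outer
#' edge. Voxels outside all bins (or outside the validity mask) are
#' unlabeled (`NA`).
#'
#' @param map An `eccentricity_map` (list with `values`, `mask`) or a
#'   plain numeric array.
#' @param edges Strictly increasing bin edges in degrees (>= 2 values);
#'   the study's default outer edge is 88 deg.
#' @return list with `bin` (integer array, 1-based, NA unlabeled) and
#'   `masks` (list of per-bin logical arrays).
#' @export
bin_by_eccentricity <- function(map, edges = c(0.5, 2, 2.5, 6, 20, 88)) {
  if (length(edges) < 2L || is.unsorted(edges, strictly = TRUE))
    stopf("edges must be >= 2 strictly increasing values")
  vals <- if (is.list(map)) map$values else map
  valid <- if (is.list(map)) map$mask else !is.na(vals)
  nb <- length(edges) - 1L
  bin <- array(NA_integer_, dim(vals) %||% length(vals))
  for (i in seq_len(nb)) {
    hit <- valid & vals >= edges[i] &
      (vals < edges[i + 1L] | (i == nb & vals <= edges[i + 1L]))
    bin[hit] <- i
  }
  masks <- lapply(seq_len(nb), function(i) !is.na(bin) & bin == i)
  names(masks) <- sprintf("[%g,%g%s", edges[-length(edges)], edges[-1],
                          c(rep(")", nb - 1L), "]"))
  list(bin = bin, masks = masks)
}

#' Stimulus-representation and peripheral V1 ROIs
#'
#' The central ROI contains the V1 voxels whose eccentricity is at most
#' the stimulus half-extent (default 2 deg, the representation of a
#' 4 x 6 deg foveal face ellipse); the peripheral ROI extends from beyond
#' the stimulus representation plus a guard band out to `max_ecc`
#' (default 88 deg).
#'
#' @param map An `eccentricity_map` or numeric array.
#' @param v1_mask Logical array selecting V1 voxels.
#' @param stimulus_extent Stimulus half-extent in degrees (default 2).
#' @param guard Guard band in degrees between the ROIs (default 0.5).
#' @param max_ecc Outer eccentricity limit (default 88).
#' @return list with `central` and `peripheral` logical masks (disjoint).
#' @export
define_stimulus_and_peripheral_v1 <- function(map, v1_mask,
                                              stimulus_extent = 2,
                                              guard = 0.5, max_ecc = 88) {
  vals <- if (is.list(map)) map$values else map
  valid <- if (is.list(map)) map$mask else !is.na(vals)
  if (stimulus_extent >= max(vals[valid & v1_mask]))
    stopf("stimulus extent exceeds the eccentricity range of the map")
  central <- v1_mask & valid & vals <= stimulus_extent
  peripheral <- v1_mask & valid & vals > stimulus_extent + guard &
    vals <= max_ecc
  if (!any(central)) stopf("central ROI is empty")
  if (!any(peripheral)) stopf("peripheral ROI is empty")
  list(central = central, peripheral = peripheral)
}

#' Summarize a set of ROI masks
#'
#' @param masks Named list of logical arrays.
#' @param map Optional eccentricity map for mean eccentricity.
#' @return data.frame with `name`, `n_voxels`, `mean_ecc`.
#' @export
roi_summary_table <- function(masks, map = NULL) {
  vals <- if (is.list(map) && !is.null(map$values)) map$values else map
  data.frame(
    name = names(masks),
    n_voxels = vapply(masks, sum, integer(1)),
    mean_ecc = vapply(masks, function(m)
      if (is.null(vals)) NA_real_ else mean(vals[m]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}
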