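## Cortical-depth ("layer") analysis: in-plane upsampling, equidistant
## growth of cortical depths between the WM and CSF boundaries, depth
## profile extraction around the peak-R2 axial slice, and
## uncertainty-weighted spline smoothing of cross-layer profiles.

#' Upsample a volume in the in-plane (x, y) dimensions
#'
#' The z dimension is untouched. Masks (logical or `method = "nearest"`)
#' are replicated voxel-wise; data volumes are interpolated with separable
#' natural cubic splines aligned on voxel centers. Averaging over the
#' upsampled voxels of a layer ROI defined on the fine grid is then
#' equivalent to a volume-weighted average over the original voxels.
#'
#' @param volume 2-D or 3-D array.
#' @param factor Integer upsampling factor (>= 1); the study convention
#'   is 4.
#' @param method `"cubic"` for data, `"nearest"` for masks; defaults to
#'   `"nearest"` for logical input and `"cubic"` otherwise.
#' @return Upsampled array; logical in, logical out.
#' @export
upsample_inplane <- function(volume, factor,
                             method = if (is.logical(volume)) "nearest" else "cubic") {
  if (factor < 1 || factor != round(factor))
    stopf("upsampling factor must be a positive integer")
  factor <- as.integer(factor)
  method <- match.arg(method, c("cubic", "nearest"))
  if (factor == 1L) return(volume)
  was_2d <- length(dim(volume)) == 2L
  v <- if (was_2d) array(volume, c(dim(volume), 1L)) else volume
  d <- dim(v)
  if (method == "nearest") {
    out <- array(if (is.logical(v)) FALSE else 0,
                 c(d[1] * factor, d[2] * factor, d[3]))
    rep_idx <- function(n) rep(seq_len(n), each = factor)
    for (z in seq_len(d[3]))
      out[, , z] <- v[rep_idx(d[1]), rep_idx(d[2]), z]
  } else {
    ## voxel centers: coarse i at i - 0.5 (voxel units); fine j at
    ## (j - 0.5) / factor
    fine <- function(n) (seq_len(n * factor) - 0.5) / factor
    out <- array(0, c(d[1] * factor, d[2] * factor, d[3]))
    for (z in seq_len(d[3])) {
      sl <- v[, , z, drop = TRUE]
      step1 <- apply(sl, 2, function(col)
        stats::spline(seq_len(d[1]) - 0.5, col, xout = fine(d[1]),
                      method = "natural")$y)
      out[, , z] <- t(apply(step1, 1, function(row)
        stats::spline(seq_len(d[2]) - 0.5, row, xout = fine(d[2]),
                      method = "natural")$y))
    }
  }
  if (was_2d) out <- out[, , 1L]
  out
}

#' Grow cortical depths between the WM and CSF boundaries
#'
#' Assigns every gray-matter voxel an equidistant depth fraction
#' `d_wm / (d_wm + d_csf)`, where `d_wm` and `d_csf` are Euclidean
#' distances (in voxel units, computed within each axial slice) to the
#' nearest white-matter and CSF boundary voxel, and a depth bin
#' `min(K - 1, floor(K * fraction))` (half-open bins, last bin closed).
#' Depth fraction 0 lies on the WM boundary, 1 on the CSF boundary.
#'
#' @param wm_boundary,csf_boundary Logical 3-D arrays marking boundary
#'   voxels (non-intersecting).
#' @param K Number of depth bins (default 21). `K` is a visualization
#'   grid, not a count of independent measurements.
#' @param gray_mask Optional logical array of gray-matter voxels;
#'   defaults to all voxels between the boundaries (neither boundary).
#' @return A `cortical_ribbon`: boundaries, `gray_mask`,
#'   `depth_fraction`, `depth_bin` (0-based, NA outside gray matter),
#'   `K`, and `excluded` (voxels unreachable from a boundary, flagged and
#'   dropped from the gray mask).
#' @export
grow_depths <- function(wm_boundary, csf_boundary, K = 21L,
                        gray_mask = NULL) {
  if (any(wm_boundary & csf_boundary))
    stopf("WM and CSF boundaries intersect")
  if (K < 1L) stopf("K must be >= 1")
  d <- dim(wm_boundary)
  if (!identical(d, dim(csf_boundary)))
    stopf("boundary masks must share a grid")
  if (is.null(gray_mask)) gray_mask <- !(wm_boundary | csf_boundary)
  depth_fraction <- array(NA_real_, d)
  excluded <- array(FALSE, d)
  for (z in seq_len(d[3])) {
    g <- which(gray_mask[, , z], arr.ind = TRUE)
    if (nrow(g) == 0L) next
    wm <- which(wm_boundary[, , z], arr.ind = TRUE)
    csf <- which(csf_boundary[, , z], arr.ind = TRUE)
    if (nrow(wm) == 0L || nrow(csf) == 0L) {
      excluded[, , z] <- gray_mask[, , z]
      next
    }
    d_wm <- min_dist2d(g, wm)
    d_csf <- min_dist2d(g, csf)
    fr <- d_wm / (d_wm + d_csf)
    ## which(..., arr.ind) enumerates voxels in column-major order, the
    ## same order as logical subsetting, so direct assignment is aligned
    sl <- depth_fraction[, , z]
    sl[gray_mask[, , z]] <- fr
    depth_fraction[, , z] <- sl
  }
  gray_mask <- gray_mask & !excluded
  depth_bin <- array(NA_integer_, d)
  gm <- which(gray_mask)
  depth_bin[gm] <- as.integer(pmin(K - 1L, floor(K * depth_fraction[gm])))
  structure(list(wm_boundary = wm_boundary, csf_boundary = csf_boundary,
                 gray_mask = gray_mask, depth_fraction = depth_fraction,
                 depth_bin = depth_bin, K = as.integer(K),
                 excluded = excluded),
            class = "cortical_ribbon")
}

## minimum Euclidean distance from each row of `a` to the rows of `b`
## (2-D integer coordinates)
min_dist2d <- function(a, b) {
  dx <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  sqrt(apply(dx^2 + dy^2, 1, min))
}

#' @export
print.cortical_ribbon <- function(x, ...) {
  cat(sprintf("<cortical_ribbon> %s grid, %d gray voxels, %d depth bins\n",
              paste(dim(x$gray_mask), collapse = "x"),
              sum(x$gray_mask), x$K))
  invisible(x)
}

#' Extract a cortical depth profile around the peak-R2 axial slice
#'
#' Selects the axial (z) slice with the highest mean R2 inside the ROI,
#' takes that slice together with the slice above and below, and averages
#' the response per depth bin across the voxels of the three slices. The
#' per-bin standard error is the across-voxel standard error.
#'
#' @param response 3-D array of response amplitudes (e.g. percent CBV
#'   change).
#' @param r2 3-D array of GLM R2 values on the same grid.
#' @param ribbon A `cortical_ribbon`.
#' @param roi Logical array restricting the profile (defaults to all gray
#'   matter).
#' @return A `depth_profile` data.frame: `bin` (0-based),
#'   `depth_fraction` (bin center), `mean`, `se`, `n_voxels`; empty bins
#'   are `NA` and flagged in the `missing_bins` attribute. The selected
#'   slices are stored in the `slices` attribute.
#' @export
extract_depth_profile <- function(response, r2, ribbon, roi = NULL) {
  d <- dim(response)
  if (!identical(d, dim(ribbon$gray_mask)))
    stopf("response grid does not match ribbon grid")
  if (is.null(roi)) roi <- ribbon$gray_mask
  use <- roi & ribbon$gray_mask
  zs <- which(apply(use, 3, any))
  if (length(zs) < 3L)
    stopf("ROI must intersect at least 3 axial slices")
  mean_r2 <- vapply(zs, function(z) mean(r2[, , z][use[, , z]]), numeric(1))
  k <- zs[which.max(mean_r2)]
  k <- min(max(k, min(zs) + 1L), max(zs) - 1L)  # keep k-1..k+1 inside
  slices <- (k - 1L):(k + 1L)
  sel <- array(FALSE, d); sel[, , slices] <- TRUE
  sel <- sel & use
  K <- ribbon$K
  bins <- ribbon$depth_bin[sel]
  vals <- response[sel]
  out <- data.frame(bin = 0:(K - 1L),
                    depth_fraction = (0:(K - 1L) + 0.5) / K,
                    mean = NA_real_, se = NA_real_, n_voxels = 0L)
  for (b in 0:(K - 1L)) {
    v <- vals[bins == b]
    v <- v[!is.na(v)]
    if (length(v) > 0L) {
      out$mean[b + 1L] <- mean(v)
      out$se[b + 1L] <- if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else 0
      out$n_voxels[b + 1L] <- length(v)
    }
  }
  attr(out, "missing_bins") <- out$bin[is.na(out$mean)]
  attr(out, "slices") <- slices
  class(out) <- c("depth_profile", "data.frame")
  out
}

#' Smooth a cross-layer profile with uncertainty-weighted splines
#'
#' Fits a penalized thin-plate regression spline to the per-bin means
#' with weights proportional to `1 / se^2`, smoothing parameter chosen by
#' REML. The returned band is plus/minus one standard error of the fitted
#' curve. The 21-bin grid oversamples the cortical thickness, so the
#' spline models the smoothness that neighbouring bins share instead of
#' treating bins as independent samples.
#'
#' @param profile A `depth_profile` from [extract_depth_profile()].
#' @param k Spline basis dimension (default `min(10, bins - 1)`).
#' @return The profile with columns `fit`, `band_lo`, `band_hi` added.
#' @export
smooth_profile <- function(profile, k = NULL) {
  ok <- !is.na(profile$mean)
  if (sum(ok) < 5L) stopf("need at least 5 non-missing bins to smooth")
  df <- profile[ok, ]
  if (all(df$se == 0)) {
    warning("all per-bin standard errors are zero; fitting unweighted")
    w <- rep(1, nrow(df))
  } else {
    se <- pmax(df$se, 1e-8)
    w <- 1 / se^2
    w <- w / mean(w)
  }
  k <- k %||% min(10L, sum(ok) - 1L)
  fit <- mgcv::gam(mean ~ s(depth_fraction, bs = "tp", k = k),
                   weights = w, data = df, method = "REML")
  pr <- mgcv::predict.gam(fit, newdata = profile, se.fit = TRUE)
  profile$fit <- as.numeric(pr$fit)
  profile$band_lo <- profile$fit - as.numeric(pr$se.fit)
  profile$band_hi <- profile$fit + as.numeric(pr$se.fit)
  attr(profile, "gam") <- fit
  profile
}
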