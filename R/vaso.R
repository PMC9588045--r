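## VASO processing: split interleaved acquisitions, align in time, remove
## BOLD contamination by frame-wise division, and compute the T1-EPI
## ("VASO anatomy") contrast.

#' Split an interleaved VASO acquisition into its two groups
#'
#' The scanner alternates blood-nulled and blood-not-nulled readouts
#' within each effective TR; this separates the frames into the two
#' groups, each keeping its own acquisition timestamps.
#'
#' @param series An interleaved [run_series()] with an even frame count.
#' @param nulled_first Logical; the first frame of each pair is the
#'   blood-nulled readout (default `TRUE`).
#' @return A `vaso_pair`: list with `nulled` and `notnulled` run series
#'   and `effective_tr`.
#' @export
split_interleaved <- function(series, nulled_first = TRUE) {
  n <- nrow(series$data)
  if (n == 0L) stopf("series has no frames")
  if (n %% 2L != 0L)
    stopf("interleaved series must have an even frame count (got %d)", n)
  first <- seq(1L, n, by = 2L); second <- seq(2L, n, by = 2L)
  idx_nulled <- if (nulled_first) first else second
  idx_not <- if (nulled_first) second else first
  eff_tr <- if (n >= 3L) series$times[3L] - series$times[1L] else 2 * series$tr
  structure(list(
    nulled = run_series(series$data[idx_nulled, , drop = FALSE], eff_tr,
                        "nulled", series$design, series$times[idx_nulled]),
    notnulled = run_series(series$data[idx_not, , drop = FALSE], eff_tr,
                           "not-nulled", series$design, series$times[idx_not]),
    effective_tr = eff_tr), class = "vaso_pair")
}

#' Re-interleave a VASO pair into acquisition order
#'
#' Inverse of [split_interleaved()].
#' @param pair A `vaso_pair`.
#' @return An interleaved [run_series()].
#' @export
interleave_pair <- function(pair) {
  times <- c(pair$nulled$times, pair$notnulled$times)
  data <- rbind(pair$nulled$data, pair$notnulled$data)
  ord <- order(times)
  run_series(data[ord, , drop = FALSE], pair$nulled$tr / 2, "interleaved",
             pair$nulled$design, times[ord])
}

#' Align a VASO pair onto a common uniform timebase
#'
#' Both groups are cubic-spline interpolated onto a uniform grid with
#' spacing `effective_tr / 2` spanning the overlap of their acquisition
#' times, after which the first and last two frames are removed to discard
#' interpolation edge effects.
#'
#' @param pair A `vaso_pair` from [split_interleaved()] or
#'   [simulate_vaso_run()].
#' @return A `vaso_pair` on the common timebase (equal frame counts and
#'   identical times in both groups).
#' @export
align_and_trim <- function(pair) {
  if (nrow(pair$nulled$data) < 8L || nrow(pair$notnulled$data) < 8L)
    stopf("need at least 8 frames per group to align")
  step <- pair$effective_tr / 2
  t0 <- max(pair$nulled$times[1], pair$notnulled$times[1])
  t1 <- min(max(pair$nulled$times), max(pair$notnulled$times))
  grid <- seq(t0, t1, by = step)
  interp <- function(rs) {
    out <- apply(rs$data, 2, function(yy)
      stats::spline(rs$times, yy, xout = grid, method = "fmm")$y)
    out[3:(length(grid) - 2L), , drop = FALSE]
  }
  kept <- grid[3:(length(grid) - 2L)]
  structure(list(
    nulled = run_series(interp(pair$nulled), step, "nulled",
                        pair$nulled$design, kept),
    notnulled = run_series(interp(pair$notnulled), step, "not-nulled",
                           pair$notnulled$design, kept),
    effective_tr = pair$effective_tr), class = "vaso_pair")
}

fixation_frames <- function(design, times) {
  ev <- design$events[design$events$condition == "fixation", , drop = FALSE]
  keep <- rep(FALSE, length(times))
  for (i in seq_len(nrow(ev)))
    keep <- keep | (times >= ev$onset[i] - 1e-9 &
                    times < ev$onset[i] + ev$duration[i] - 1e-9)
  keep
}

#' Remove BOLD contamination from an aligned VASO pair
#'
#' The CBV-weighted series is the blood-nulled series divided by the
#' blood-not-nulled series at each time frame (cancelling any
#' multiplicative BOLD component) and multiplied by -1, so that a CBV
#' increase appears as a positive response. The result is expressed as
#' percent change against the series' fixation-epoch baseline.
#'
#' @param pair An aligned `vaso_pair` (see [align_and_trim()]).
#' @return A [run_series()] with modality `"vaso"`, percent-change units.
#' @export
bold_correct <- function(pair) {
  if (!isTRUE(all.equal(pair$nulled$times, pair$notnulled$times)))
    stopf("pair is not aligned; run align_and_trim() first")
  if (any(pair$notnulled$data <= 0))
    stopf("not-nulled series has nonpositive values; division is unsafe")
  vaso <- -pair$nulled$data / pair$notnulled$data
  design <- pair$nulled$design
  base_idx <- fixation_frames(design, pair$nulled$times)
  if (!any(base_idx))
    stopf("no fixation frames available for the percent-change baseline")
  base <- colMeans(vaso[base_idx, , drop = FALSE])
  if (any(abs(base) < 1e-12)) stopf("degenerate zero baseline")
  pct <- 100 * sweep(sweep(vaso, 2, base), 2, abs(base), "/")
  run_series(pct, pair$nulled$tr, "vaso", design, pair$nulled$times)
}

#' T1-EPI anatomical contrast from the VASO time series ("VASO anatomy")
#'
#' Computed per voxel from all frames of both groups. The default contrast
#' is the inverse signal variability divided by the mean signal,
#' `(1/sd) / mean`; the tSNR-style alternative `mean / sd` is available
#' behind the `type` switch (the two differ only by the square of the
#' mean). Standard deviations are population (divide by n) statistics.
#' Zero-variance voxels receive `NA` and are reported in the
#' `flagged` attribute rather than raising an error.
#'
#' @param pair A `vaso_pair`.
#' @param type `"inv-sd-over-mean"` (default) or `"mean-over-sd"`.
#' @return Numeric vector (one value per voxel) with attribute `flagged`.
#' @export
vaso_anatomy <- function(pair, type = c("inv-sd-over-mean", "mean-over-sd")) {
  type <- match.arg(type)
  if (nrow(pair$nulled$data) < 2L || nrow(pair$notnulled$data) < 2L)
    stopf("need at least 2 frames per group")
  X <- rbind(pair$nulled$data, pair$notnulled$data)
  mu <- colMeans(X)
  sd_pop <- sqrt(colMeans(sweep(X, 2, mu)^2))
  out <- rep(NA_real_, ncol(X))
  ok <- sd_pop > 0
  out[ok] <- if (type == "inv-sd-over-mean")
    (1 / sd_pop[ok]) / mu[ok] else mu[ok] / sd_pop[ok]
  attr(out, "flagged") <- which(!ok)
  attr(out, "type") <- type
  out
}
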