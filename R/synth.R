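## Synthetic block-design fMRI generator.
##
## Emulates the three-condition (fearful / neutral / happy) face protocols:
## a 3T BOLD variant (20 s face blocks, 10 s fixation), a 7T BOLD variant
## (18 s / 9 s) and a 7T VASO variant (19.3 s / 9.65 s with interleaved
## blood-nulled and not-nulled readouts). Every generator is seeded and
## byte-reproducible.

FACE_CONDITIONS <- c("fearful", "neutral", "happy")

protocol_spec <- function(protocol) {
  switch(protocol,
    "3T-BOLD" = list(face_dur = 20,   fix_dur = 10,   reps = 3L, n_fix = 10L,
                     tr = 2),
    "7T-BOLD" = list(face_dur = 18,   fix_dur = 9,    reps = 3L, n_fix = 10L,
                     tr = 1.5),
    "7T-VASO" = list(face_dur = 19.3, fix_dur = 9.65, reps = 6L, n_fix = 19L,
                     tr = 4.825),
    stopf("unknown protocol '%s'; expected one of 3T-BOLD, 7T-BOLD, 7T-VASO",
          protocol)
  )
}

#' Generate a pseudo-randomized block design
#'
#' Builds the stimulus timing of one run of the gender-judgment protocol:
#' face blocks of the three expression conditions alternate with fixation
#' blocks, starting and ending on fixation, so that every face block is
#' followed by a fixation block. The condition order is a seeded
#' permutation with the per-condition block counts fixed by the protocol
#' (3 repeats per condition at 3T/7T BOLD, 6 at 7T VASO).
#'
#' @param protocol One of `"3T-BOLD"` (20 s face / 10 s fixation blocks,
#'   run length 280 s), `"7T-BOLD"` (18 s / 9 s, 252 s) or `"7T-VASO"`
#'   (19.3 s / 9.65 s, 530.75 s, effective volume TR 4.825 s).
#' @param seed Integer seed controlling the condition permutation.
#' @return A `block_design`: list with `events` (data.frame of
#'   `condition`, `onset`, `duration` in seconds, sorted, non-overlapping),
#'   `conditions`, `run_duration`, `tr` and `protocol`.
#' @export
make_block_design <- function(protocol, seed = 1L) {
  sp <- protocol_spec(protocol)
  order <- with_seed(seed, sample(rep(FACE_CONDITIONS, sp$reps)))
  n_face <- length(order)
  stopifnot(sp$n_fix == n_face + 1L)
  cond <- character(2L * n_face + 1L)
  cond[seq(1L, length(cond), by = 2L)] <- "fixation"
  cond[seq(2L, length(cond), by = 2L)] <- order
  dur <- ifelse(cond == "fixation", sp$fix_dur, sp$face_dur)
  onset <- cumsum(c(0, dur[-length(dur)]))
  design <- structure(list(
    events = data.frame(condition = cond, onset = onset, duration = dur,
                        stringsAsFactors = FALSE),
    conditions = c(FACE_CONDITIONS, "fixation"),
    run_duration = sum(dur),
    tr = sp$tr,
    protocol = protocol
  ), class = "block_design")
  validate_block_design(design)
}

validate_block_design <- function(design) {
  ev <- design$events
  if (is.unsorted(ev$onset, strictly = TRUE))
    stopf("block design events must be sorted by onset")
  ends <- ev$onset + ev$duration
  if (any(ends[-length(ends)] > ev$onset[-1] + 1e-9))
    stopf("block design events overlap")
  if (max(ends) > design$run_duration + 1e-9)
    stopf("events extend past run_duration")
  face <- which(ev$condition != "fixation")
  follows_fix <- face < nrow(ev) & ev$condition[pmin(face + 1L, nrow(ev))] == "fixation"
  if (!all(follows_fix))
    stopf("every face block must be followed by a fixation block")
  design
}

#' @export
print.block_design <- function(x, ...) {
  cat(sprintf("<block_design> %s: %d events, %.4g s, TR %.4g s\n",
              x$protocol, nrow(x$events), x$run_duration, x$tr))
  invisible(x)
}

#' Synthetic-data configuration
#'
#' Collects every tunable of the synthetic generators: the scan protocol,
#' ROI labels, per-(ROI, condition) evoked amplitudes (percent signal),
#' per-(ROI, condition) loadings of the condition-gated shared latent
#' fluctuation, AR(1) noise parameters, the depth-dependent CBV response
#' bands for the VASO generator, and the multiplicative BOLD-contamination
#' amplitude.
#'
#' The shared latent signal is a unit-variance AR(1) process, one per
#' condition, added to each ROI with the given loading but only during the
#' epochs (face block plus its following fixation block) of its condition;
#' two ROIs with loadings `c1`, `c2` and innovation noise standard
#' deviation `noise_sd` then share an epoch correlation of
#' `c1*c2 / sqrt((c1^2 + v)(c2^2 + v))` with `v = noise_sd^2/(1 - ar1_coef^2)`.
#'
#' @param seed Integer seed; identical configs give byte-identical output.
#' @param protocol Scan protocol tag (see [make_block_design()]).
#' @param roi_names Character vector of ROI labels.
#' @param evoked_amplitude ROI x condition matrix of evoked-response peak
#'   amplitudes in percent signal change.
#' @param coupling ROI x condition matrix of shared-latent loadings.
#' @param noise_sd AR(1) innovation standard deviation, percent signal.
#' @param ar1_coef AR(1) coefficient, absolute value < 1.
#' @param layer_effect data.frame with columns `lo`, `hi`, `condition`,
#'   `amplitude` giving additive CBV responses (percent, i.e. ml per
#'   100 ml) applied where the cortical depth fraction falls in `[lo, hi)`
#'   (`hi = 1` closed). Rows are additive.
#' @param bold_contamination_amplitude Peak amplitude of the multiplicative
#'   BOLD-like contamination of the VASO acquisition (fraction, e.g. 0.01).
#' @param tr_nulled,tr_notnulled Readout durations of the blood-nulled and
#'   not-nulled VASO acquisitions in seconds (defaults 2.088 s and 2.737 s,
#'   effective pair TR 4.825 s).
#' @param nulled_first Logical; blood-nulled frame acquired first in each
#'   interleaved pair.
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1L,
                         protocol = "7T-BOLD",
                         roi_names = c("amygdala", "V1", "V2", "V3", "hV4"),
                         evoked_amplitude = NULL,
                         coupling = NULL,
                         noise_sd = 0.5,
                         ar1_coef = 0.3,
                         layer_effect = default_layer_effect(),
                         bold_contamination_amplitude = 0.01,
                         tr_nulled = 2.088,
                         tr_notnulled = 2.737,
                         nulled_first = TRUE) {
  protocol_spec(protocol)  # validates tag
  if (abs(ar1_coef) >= 1) stopf("ar1_coef must have absolute value < 1")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (is.null(evoked_amplitude))
    evoked_amplitude <- default_evoked_amplitude(roi_names)
  if (is.null(coupling))
    coupling <- default_coupling(roi_names)
  evoked_amplitude <- as_roi_condition_matrix(evoked_amplitude, roi_names,
                                              "evoked_amplitude")
  coupling <- as_roi_condition_matrix(coupling, roi_names, "coupling")
  structure(list(seed = as.integer(seed), protocol = protocol,
                 roi_names = roi_names,
                 evoked_amplitude = evoked_amplitude, coupling = coupling,
                 noise_sd = noise_sd, ar1_coef = ar1_coef,
                 layer_effect = layer_effect,
                 bold_contamination_amplitude = bold_contamination_amplitude,
                 tr_nulled = tr_nulled, tr_notnulled = tr_notnulled,
                 nulled_first = nulled_first),
            class = "synth_config")
}

as_roi_condition_matrix <- function(m, roi_names, what) {
  m <- as.matrix(m)
  if (nrow(m) != length(roi_names) || ncol(m) != length(FACE_CONDITIONS))
    stopf("'%s' must be a %d x %d (ROI x condition) matrix",
          what, length(roi_names), length(FACE_CONDITIONS))
  rownames(m) <- roi_names
  colnames(m) <- FACE_CONDITIONS
  m
}

## Study-condition defaults: a clear visual response in every area, larger
## for expressive faces (the valence effect), with the amygdala weaker than
## cortex; fearful-gated shared fluctuation between amygdala and cortex.
default_evoked_amplitude <- function(roi_names) {
  base <- ifelse(roi_names == "amygdala", 0.5, 1.5)
  m <- cbind(fearful = base * 1.25, neutral = base, happy = base * 1.15)
  rownames(m) <- roi_names
  m
}

default_coupling <- function(roi_names) {
  m <- matrix(0, length(roi_names), 3,
              dimnames = list(roi_names, FACE_CONDITIONS))
  ## fearful-gated fluctuation sourced in the amygdala: strong amygdala
  ## loading, weak cortical loadings, so the pairwise correlation
  ## increment is first-order for amygdala-cortex pairs and only
  ## second-order for cortico-cortical pairs
  m[, "fearful"] <- 0.3
  m[roi_names == "amygdala", "fearful"] <- 0.8
  m
}

## Mid-depth stimulus-driven CBV peak for every condition plus a
## superficial-only increment for expressive faces (fearful strongest).
default_layer_effect <- function() {
  data.frame(
    lo = c(0.35, 0.35, 0.35, 2/3, 2/3),
    hi = c(0.65, 0.65, 0.65, 1.0, 1.0),
    condition = c("fearful", "neutral", "happy", "fearful", "happy"),
    amplitude = c(2.0, 2.0, 2.0, 0.8, 0.4),
    stringsAsFactors = FALSE
  )
}

#' Construct a run-series container
#'
#' @param data time x unit numeric matrix (percent signal).
#' @param tr Sampling interval in seconds (frame spacing for uniformly
#'   sampled modalities).
#' @param modality One of `"BOLD"`, `"nulled"`, `"not-nulled"`, `"vaso"`,
#'   `"interleaved"`.
#' @param design The generating [make_block_design()] object.
#' @param times Optional explicit frame times (seconds); defaults to
#'   `(0:(n-1)) * tr`.
#' @return A `run_series` object.
#' @export
run_series <- function(data, tr, modality, design, times = NULL) {
  data <- as.matrix(data)
  if (!all(is.finite(data))) stopf("run series values must be finite")
  if (is.null(times)) times <- (seq_len(nrow(data)) - 1) * tr
  if (length(times) != nrow(data))
    stopf("times length must match frame count")
  structure(list(data = data, tr = tr, modality = modality,
                 design = design, times = times),
            class = "run_series")
}

#' @export
print.run_series <- function(x, ...) {
  cat(sprintf("<run_series> %s: %d frames x %d units, TR %.4g s\n",
              x$modality, nrow(x$data), ncol(x$data), x$tr))
  invisible(x)
}

## Unit-variance AR(1) latent, gated to the epochs of one condition.
ar1_series <- function(n, phi, innov_sd) {
  eps <- rnorm(n, 0, innov_sd)
  as.numeric(stats::filter(eps, phi, method = "recursive"))
}

condition_epoch_gate <- function(design, condition, times) {
  ev <- design$events
  idx <- which(ev$condition == condition)
  gate <- rep(FALSE, length(times))
  for (i in idx) {
    fix_dur <- if (i < nrow(ev) && ev$condition[i + 1L] == "fixation")
      ev$duration[i + 1L] else 0
    gate <- gate | (times >= ev$onset[i] - 1e-9 &
                    times < ev$onset[i] + ev$duration[i] + fix_dur - 1e-9)
  }
  gate
}

#' Simulate BOLD run series for a set of ROIs
#'
#' Each ROI time series is the sum of (i) HRF-convolved condition boxcars
#' scaled by the configured evoked amplitudes (the evoked responses
#' superpose exactly, i.e. the generator is a shift-invariant linear
#' system), (ii) condition-gated unit-variance shared latent AR(1) signals
#' scaled by the ROI's loading, and (iii) independent AR(1) noise.
#'
#' @param design A [make_block_design()] object.
#' @param cfg A [synth_config()]; its protocol must match the design.
#' @return A [run_series()] with one column per ROI, percent-signal units.
#' @export
simulate_bold_runs <- function(design, cfg) {
  if (cfg$protocol != design$protocol)
    stopf("config protocol (%s) does not match design protocol (%s)",
          cfg$protocol, design$protocol)
  n <- round(design$run_duration / design$tr)
  times <- (seq_len(n) - 1) * design$tr
  n_roi <- length(cfg$roi_names)
  evoked <- matrix(0, n, n_roi)
  for (cond in FACE_CONDITIONS) {
    reg <- convolved_regressor(design, cond, times)
    evoked <- evoked + outer(reg, cfg$evoked_amplitude[, cond])
  }
  with_seed(cfg$seed, {
    shared <- matrix(0, n, n_roi)
    for (ci in seq_along(FACE_CONDITIONS)) {
      cond <- FACE_CONDITIONS[ci]
      latent <- ar1_series(n, cfg$ar1_coef, sqrt(1 - cfg$ar1_coef^2)) *
        condition_epoch_gate(design, cond, times)
      shared <- shared + outer(latent, cfg$coupling[, cond])
    }
    noise <- vapply(seq_len(n_roi),
                    function(i) ar1_series(n, cfg$ar1_coef, cfg$noise_sd),
                    numeric(n))
    out <- evoked + shared + noise
  })
  colnames(out) <- cfg$roi_names
  run_series(out, design$tr, "BOLD", design, times)
}

#' Build a flat cortical ribbon and matching eccentricity map
#'
#' The ribbon is a slab in a 3-D grid: along the y axis the first ribbon
#' row is the white-matter (WM) boundary, the last is the CSF boundary,
#' and `thickness` gray-matter tiers lie between them. Cortical depths are
#' grown with the equidistant metric (see [grow_depths()]), depth fraction
#' 0 at the WM boundary and 1 at the CSF boundary. Eccentricity increases
#' monotonically along the x axis from 0.5 deg to `max_ecc` deg.
#'
#' @param shape Integer grid dimensions `c(nx, ny, nz)`; `ny` must hold the
#'   ribbon (`thickness + 2` rows).
#' @param thickness Number of gray-matter voxel tiers (>= 3).
#' @param max_ecc Maximum eccentricity in degrees of visual angle
#'   (default 88, the far edge of peripheral V1).
#' @param n_depth_bins Number of cortical depth bins (default 21).
#' @return list with `ribbon` (a `cortical_ribbon`) and `eccentricity`
#'   (an `eccentricity_map`).
#' @export
make_ribbon_and_eccentricity <- function(shape = c(20L, 23L, 5L),
                                         thickness = 21L,
                                         max_ecc = 88,
                                         n_depth_bins = 21L) {
  if (thickness < 3L) stopf("ribbon thickness must be >= 3 voxels")
  if (shape[2] < thickness + 2L)
    stopf("grid y-dimension too small for ribbon of thickness %d", thickness)
  wm <- array(FALSE, shape); csf <- array(FALSE, shape)
  wm[, 1L, ] <- TRUE
  csf[, thickness + 2L, ] <- TRUE
  ribbon <- grow_depths(wm, csf, K = n_depth_bins)
  ecc_vals <- seq(0.5, max_ecc, length.out = shape[1])
  ecc <- array(rep(ecc_vals, times = prod(shape[2:3])), shape)
  emap <- structure(list(values = ecc, mask = array(TRUE, shape)),
                    class = "eccentricity_map")
  list(ribbon = ribbon, eccentricity = emap)
}

#' Simulate an interleaved VASO acquisition pair
#'
#' Generates blood-nulled and blood-not-nulled voxel time series on the
#' ribbon grid. The not-nulled series carries a positive multiplicative
#' BOLD-like response `b(t)`; the nulled series is
#' `b(t) * (1 - v(x, t))` where `v` is the planted CBV response whose
#' depth profile follows `cfg$layer_effect`. Dividing nulled by not-nulled
#' therefore cancels the contamination and recovers `1 - v`, so the
#' corrected series ([bold_correct()]) has the opposite response sign from
#' BOLD. The two series are sampled at their own staggered acquisition
#' times within each effective TR.
#'
#' @param design A `7T-VASO` [make_block_design()].
#' @param cfg A [synth_config()] with protocol `"7T-VASO"`.
#' @param ribbon A `cortical_ribbon` from [make_ribbon_and_eccentricity()]
#'   or [grow_depths()].
#' @return list with elements `nulled` and `notnulled`, both [run_series()]
#'   over the ribbon's gray-matter voxels (columns) with explicit frame
#'   times, plus `voxels` (index of gray-matter voxels in the grid).
#' @export
simulate_vaso_run <- function(design, cfg, ribbon) {
  if (cfg$protocol != "7T-VASO" || design$protocol != "7T-VASO")
    stopf("simulate_vaso_run requires the 7T-VASO protocol")
  if (!inherits(ribbon, "cortical_ribbon"))
    stopf("'ribbon' must be a cortical_ribbon")
  eff_tr <- cfg$tr_nulled + cfg$tr_notnulled
  n_pairs <- floor(design$run_duration / eff_tr + 1e-9)
  t_first <- (seq_len(n_pairs) - 1) * eff_tr
  t_second <- t_first + if (cfg$nulled_first) cfg$tr_nulled else cfg$tr_notnulled
  t_nulled <- if (cfg$nulled_first) t_first else t_second
  t_notnulled <- if (cfg$nulled_first) t_second else t_first
  gray <- which(ribbon$gray_mask)
  depth <- ribbon$depth_fraction[gray]
  ## per-voxel CBV amplitude (fraction) per condition from the band table
  amp <- matrix(0, length(gray), length(FACE_CONDITIONS),
                dimnames = list(NULL, FACE_CONDITIONS))
  le <- cfg$layer_effect
  for (i in seq_len(nrow(le))) {
    inband <- depth >= le$lo[i] &
      (depth < le$hi[i] | (le$hi[i] >= 1 & depth <= 1))
    amp[inband, le$condition[i]] <- amp[inband, le$condition[i]] +
      le$amplitude[i] / 100
  }
  resp_at <- function(times) {
    sapply(FACE_CONDITIONS, function(cond)
      convolved_regressor(design, cond, times))
  }
  v_nulled <- resp_at(t_nulled) %*% t(amp)        # n_pairs x voxels
  bold_n <- 1 + cfg$bold_contamination_amplitude *
    rowSums(resp_at(t_nulled))
  bold_nn <- 1 + cfg$bold_contamination_amplitude *
    rowSums(resp_at(t_notnulled))
  with_seed(derive_seed(cfg$seed, 7L), {
    noise_scale <- cfg$noise_sd / 100
    nulled <- bold_n * (1 - v_nulled) *
      (1 + matrix(rnorm(length(v_nulled), 0, noise_scale), nrow(v_nulled)))
    notnulled <- matrix(bold_nn, n_pairs, length(gray)) *
      (1 + matrix(rnorm(length(v_nulled), 0, noise_scale), nrow(v_nulled)))
  })
  structure(list(
    nulled = run_series(nulled, eff_tr, "nulled", design, t_nulled),
    notnulled = run_series(notnulled, eff_tr, "not-nulled", design, t_notnulled),
    effective_tr = eff_tr,
    voxels = gray
  ), class = "vaso_pair")
}

#' Write a block design as a 3-column event file
#'
#' Tab-separated columns `onset`, `duration`, `condition`.
#' @param design A `block_design`.
#' @param path Output path.
#' @export
write_events <- function(design, path) {
  ev <- design$events[, c("onset", "duration", "condition")]
  utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a 3-column event file written by [write_events()]
#' @param path Event file path.
#' @param tr,run_duration,protocol Metadata not stored in the event file.
#' @return A `block_design`.
#' @export
read_events <- function(path, tr, run_duration = NULL, protocol = "custom") {
  ev <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  ev <- ev[order(ev$onset), c("condition", "onset", "duration")]
  validate_block_design(structure(list(
    events = ev,
    conditions = unique(ev$condition),
    run_duration = run_duration %||% max(ev$onset + ev$duration),
    tr = tr, protocol = protocol), class = "block_design"))
}
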