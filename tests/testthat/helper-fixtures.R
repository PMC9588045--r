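## Shared fixtures: tiny designs, phantoms and configs built in code.

## A block design with explicit events (bypasses the protocol presets);
## used for periodic and degenerate timing cases.
manual_design <- function(conditions, face_dur, fix_dur, tr,
                          protocol = "custom") {
  n <- length(conditions)
  cond <- character(2L * n + 1L)
  cond[seq(1L, length(cond), 2L)] <- "fixation"
  if (n > 0L) cond[seq(2L, length(cond), 2L)] <- conditions
  dur <- ifelse(cond == "fixation", fix_dur, face_dur)
  onset <- cumsum(c(0, dur[-length(dur)]))
  structure(list(
    events = data.frame(condition = cond, onset = onset, duration = dur,
                        stringsAsFactors = FALSE),
    conditions = unique(c(conditions, "fixation")),
    run_duration = sum(dur), tr = tr, protocol = protocol),
    class = "block_design")
}

## Flat ribbon of given thickness; x = nx columns, z slices.
flat_ribbon <- function(thickness, nx = 6L, nz = 3L, K = 21L) {
  shape <- c(nx, thickness + 2L, nz)
  wm <- array(FALSE, shape); csf <- array(FALSE, shape)
  wm[, 1L, ] <- TRUE; csf[, thickness + 2L, ] <- TRUE
  grow_depths(wm, csf, K = K)
}

## Independent brute-force depth assignment for flat ribbons: per gray
## voxel, scan all boundary voxels in its slice and use plain euclidean
## distances (the oracle the implementation is checked against).
brute_force_depth <- function(wm, csf, K) {
  d <- dim(wm)
  gray <- !(wm | csf)
  frac <- array(NA_real_, d); bin <- array(NA_integer_, d)
  for (z in seq_len(d[3])) {
    wmc <- which(wm[, , z], arr.ind = TRUE)
    csfc <- which(csf[, , z], arr.ind = TRUE)
    for (x in seq_len(d[1])) for (y in seq_len(d[2])) {
      if (!gray[x, y, z]) next
      dwm <- min(sqrt((wmc[, 1] - x)^2 + (wmc[, 2] - y)^2))
      dcsf <- min(sqrt((csfc[, 1] - x)^2 + (csfc[, 2] - y)^2))
      fr <- dwm / (dwm + dcsf)
      frac[x, y, z] <- fr
      bin[x, y, z] <- as.integer(min(K - 1L, floor(K * fr)))
    }
  }
  list(fraction = frac, bin = bin)
}

## Analytic VASO pair: nulled = b(t) * (1 - v(t)), notnulled = b(t),
## aligned on a common timebase (v = 0 on fixation frames by design of
## the caller). `v` and `b` are time x voxel matrices.
analytic_pair <- function(v, b, design, tr) {
  times <- (seq_len(nrow(v)) - 1) * tr
  structure(list(
    nulled = run_series(b * (1 - v), tr, "nulled", design, times),
    notnulled = run_series(b, tr, "not-nulled", design, times),
    effective_tr = 2 * tr), class = "vaso_pair")
}

expect_all_finite <- function(x) expect_true(all(is.finite(x)))
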