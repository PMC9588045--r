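## Design matrices, OLS GLM, FIR deconvolution.

#' Canonical double-gamma haemodynamic response function
#'
#' Standard parameterization: a positive gamma peaking near 5 s minus an
#' undershoot gamma peaking near 15 s with 1/6 relative amplitude, scaled
#' to unit area over the positive lobe so that sustained blocks plateau
#' near the underlying neural amplitude.
#'
#' @param t Time in seconds (>= 0).
#' @return HRF values at `t`.
#' @export
canonical_hrf <- function(t) {
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / (1 - 1/6)   # unit net area
}

## Boxcar for one condition convolved with the canonical HRF, evaluated at
## arbitrary times. Discrete convolution on a fine grid (dt = 0.1 s).
convolved_regressor <- function(design, condition, times, dt = 0.1) {
  ev <- design$events[design$events$condition == condition, , drop = FALSE]
  if (nrow(ev) == 0L) return(numeric(length(times)))
  t_max <- max(times) + dt
  grid <- seq(0, t_max + 32, by = dt)
  box <- numeric(length(grid))
  for (i in seq_len(nrow(ev)))
    box[grid >= ev$onset[i] - 1e-9 &
        grid < ev$onset[i] + ev$duration[i] - 1e-9] <- 1
  kern <- canonical_hrf(seq(0, 32, by = dt)) * dt
  conv <- stats::convolve(box, rev(kern), type = "open")[seq_along(grid)]
  stats::approx(grid, conv, xout = times, rule = 2)$y
}

#' Build a GLM design matrix for a block design
#'
#' With the canonical basis, one column per face condition (condition
#' boxcar convolved with [canonical_hrf()]) plus a constant and a linear
#' drift column. With the FIR basis, one delta column per (condition, lag)
#' pair covering `fir_window` seconds after block onset, plus constant and
#' drift; the FIR estimates are the deconvolved mean evoked responses.
#'
#' @param design A [make_block_design()] object.
#' @param n_timepoints Number of frames in the series.
#' @param tr Frame interval, seconds.
#' @param basis `"canonical-hrf"` or `"fir"`.
#' @param fir_window FIR window length in seconds (default 30, covering
#'   a face block plus the post-stimulus undershoot).
#' @return A `design_matrix`: list with `matrix`, `labels`, `basis`,
#'   `fir_window`, `conditions`.
#' @export
build_design_matrix <- function(design, n_timepoints, tr,
                                basis = c("canonical-hrf", "fir"),
                                fir_window = 30) {
  basis <- match.arg(basis)
  times <- (seq_len(n_timepoints) - 1) * tr
  conds <- intersect(FACE_CONDITIONS,
                     unique(design$events$condition))
  cols <- list(); labels <- character(0)
  if (basis == "canonical-hrf") {
    for (cond in conds) {
      cols[[length(cols) + 1L]] <- convolved_regressor(design, cond, times)
      labels <- c(labels, cond)
    }
  } else {
    n_lags <- floor(fir_window / tr + 1e-9)
    if (n_lags < 1L) stopf("fir_window must cover at least one TR")
    for (cond in conds) {
      ev <- design$events[design$events$condition == cond, , drop = FALSE]
      onset_bins <- round(ev$onset / tr)
      for (lag in seq_len(n_lags) - 1L) {
        col <- numeric(n_timepoints)
        idx <- onset_bins + lag + 1L
        idx <- idx[idx >= 1L & idx <= n_timepoints]
        col[idx] <- 1
        cols[[length(cols) + 1L]] <- col
        labels <- c(labels, sprintf("%s:lag%02d", cond, lag))
      }
    }
  }
  cols[[length(cols) + 1L]] <- rep(1, n_timepoints); labels <- c(labels, "constant")
  cols[[length(cols) + 1L]] <- seq(-0.5, 0.5, length.out = n_timepoints)
  labels <- c(labels, "drift")
  X <- do.call(cbind, cols)
  colnames(X) <- labels
  if (qr(X)$rank < ncol(X))
    stopf("design matrix is rank deficient (%d columns, rank %d)",
          ncol(X), qr(X)$rank)
  structure(list(matrix = X, labels = labels, basis = basis,
                 fir_window = if (basis == "fir") fir_window else NULL,
                 conditions = conds, tr = tr),
            class = "design_matrix")
}

#' Fit an ordinary-least-squares GLM
#'
#' @param series A [run_series()] (or a plain time x unit matrix).
#' @param X A [build_design_matrix()] object (or plain matrix).
#' @return A `glm_fit`: `betas` (regressor x unit), `yhat`, `residual`
#'   (`residual + yhat` reconstructs the input exactly), and `r2`
#'   (per-unit coefficient of determination about the series mean).
#' @export
fit_glm <- function(series, X) {
  y <- if (inherits(series, "run_series")) series$data else as.matrix(series)
  Xm <- if (inherits(X, "design_matrix")) X$matrix else as.matrix(X)
  if (nrow(Xm) != nrow(y))
    stopf("design matrix rows (%d) must equal series length (%d)",
          nrow(Xm), nrow(y))
  qrX <- qr(Xm)
  if (qrX$rank < ncol(Xm))
    stopf("design matrix is rank deficient; drop collinear regressors")
  betas <- qr.coef(qrX, y)
  yhat <- Xm %*% betas
  resid <- y - yhat
  ss_res <- colSums(resid^2)
  ss_tot <- colSums(sweep(y, 2, colMeans(y))^2)
  r2 <- ifelse(ss_tot > 0, pmax(0, pmin(1, 1 - ss_res / ss_tot)), NA_real_)
  rownames(betas) <- colnames(Xm)
  structure(list(betas = betas, yhat = yhat, residual = resid, r2 = r2,
                 design_matrix = Xm, labels = colnames(Xm)),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("<glm_fit> %d regressors x %d units; mean R2 %.3f\n",
              nrow(x$betas), ncol(x$betas), mean(x$r2, na.rm = TRUE)))
  invisible(x)
}

#' Deconvolve mean evoked responses with an FIR model
#'
#' Estimates the lag-indexed mean evoked response of each condition by
#' least squares on a finite-impulse-response design. Because the solver
#' inverts the full linear system, responses that overlap across blocks
#' (short fixation blocks, post-stimulus undershoot running into the next
#' block) are handled exactly. Residuals are `y - yhat` with `yhat` the
#' FIR-predicted series; these are the inputs of the inter-area
#' correlation analysis.
#'
#' @inheritParams fit_glm
#' @param design The generating block design.
#' @param fir_window FIR window, seconds. For a strictly periodic block
#'   design the response is only identifiable up to the block period
#'   (face block + fixation), so the default is that period; longer
#'   windows on periodic timing make the FIR system rank deficient and
#'   are rejected. Irregular designs default to 30 s.
#' @return list with `evoked` (per condition: lag x unit matrix),
#'   `lag_times`, and `fit` (the underlying `glm_fit`).
#' @export
deconvolve_evoked <- function(series, design, fir_window = NULL) {
  if (is.null(fir_window)) fir_window <- default_fir_window(design)
  y <- if (inherits(series, "run_series")) series$data else as.matrix(series)
  tr <- if (inherits(series, "run_series")) series$tr else design$tr
  X <- build_design_matrix(design, nrow(y), tr, basis = "fir",
                           fir_window = fir_window)
  fit <- fit_glm(y, X)
  n_lags <- floor(fir_window / tr + 1e-9)
  evoked <- lapply(X$conditions, function(cond) {
    rows <- grep(sprintf("^%s:lag", cond), rownames(fit$betas))
    m <- fit$betas[rows, , drop = FALSE]
    rownames(m) <- sprintf("lag%02d", seq_len(n_lags) - 1L)
    m
  })
  names(evoked) <- X$conditions
  list(evoked = evoked, lag_times = (seq_len(n_lags) - 1L) * tr, fit = fit)
}

## identifiable FIR window for a design: the block period (face block +
## following fixation) when the timing is uniform, 30 s otherwise
default_fir_window <- function(design) {
  ev <- design$events
  face <- unique(ev$duration[ev$condition != "fixation"])
  fix <- unique(ev$duration[ev$condition == "fixation"])
  if (length(face) == 1L && length(fix) == 1L) face + fix else 30
}
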