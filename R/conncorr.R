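## Residual inter-area correlation analysis: per-condition epoch
## extraction, ROI x ROI correlation matrices, valence contrasts
## (fearful - neutral, happy - neutral) and their significance tests.

#' Extract per-condition residual epochs
#'
#' For each block of `condition`, takes the residual samples from block
#' onset through the end of the following fixation block, and
#' concatenates them across blocks and runs.
#'
#' @param residuals A residual time x ROI matrix, a `glm_fit`, or a list
#'   of either (one per run).
#' @param design A block design, or a list of designs matching `residuals`.
#' @param condition Condition label (must appear in the design).
#' @param tr Frame interval; taken from the design if omitted.
#' @return A samples x ROI matrix of concatenated epochs
#'   (`condition_epochs`), with a `n_per_block` attribute.
#' @export
extract_condition_epochs <- function(residuals, design, condition, tr = NULL) {
  get_resid <- function(r) {
    if (inherits(r, "glm_fit")) r$residual
    else if (inherits(r, "run_series")) r$data
    else as.matrix(r)
  }
  runs <- if (is.list(residuals) && !inherits(residuals, c("glm_fit", "run_series")))
    lapply(residuals, get_resid) else list(get_resid(residuals))
  designs <- if (inherits(design, "block_design"))
    rep(list(design), length(runs)) else design
  if (length(designs) != length(runs))
    stopf("number of designs (%d) must match number of runs (%d)",
          length(designs), length(runs))
  pieces <- list(); counts <- integer(0)
  for (i in seq_along(runs)) {
    dsg <- designs[[i]]
    ev <- dsg$events
    blocks <- which(ev$condition == condition)
    if (length(blocks) == 0L)
      stopf("condition '%s' is absent from the design", condition)
    tri <- tr %||% dsg$tr
    times <- (seq_len(nrow(runs[[i]])) - 1) * tri
    for (b in blocks) {
      if (b >= nrow(ev) && ev$condition[b] != "fixation")
        stopf("block of '%s' at %.4g s has no following fixation block",
              condition, ev$onset[b])
      stopifnot(ev$condition[b + 1L] == "fixation")
      t0 <- ev$onset[b]
      t1 <- ev$onset[b + 1L] + ev$duration[b + 1L]
      idx <- which(times >= t0 - 1e-9 & times < t1 - 1e-9)
      pieces[[length(pieces) + 1L]] <- runs[[i]][idx, , drop = FALSE]
      counts <- c(counts, length(idx))
    }
  }
  out <- do.call(rbind, pieces)
  attr(out, "n_per_block") <- counts
  out
}

#' Per-condition ROI correlation matrices and valence contrasts
#'
#' Pairwise correlation of the concatenated residual epochs of each
#' condition, plus contrast matrices against the `baseline` condition
#' (fearful - neutral and happy - neutral in the study protocol).
#'
#' @param epochs_by_condition Named list (condition -> samples x ROI
#'   matrix, as from [extract_condition_epochs()]).
#' @param method `"pearson"` (field default) or `"spearman"`.
#' @param baseline Condition subtracted in the contrasts
#'   (default `"neutral"`).
#' @return A `corr_matrix_set`: `r` (list of ROI x ROI matrices, unit
#'   diagonal), `contrast` (list named `"<cond>-<baseline>"`), `method`.
#'   Zero-variance ROI series give `NA` cells (flagged via warning
#'   suppression-free `cor`).
#' @export
correlation_matrices <- function(epochs_by_condition,
                                 method = c("pearson", "spearman"),
                                 baseline = "neutral") {
  method <- match.arg(method)
  if (any(vapply(epochs_by_condition, nrow, 1L) < 3L))
    stopf("need at least 3 samples per condition")
  r <- lapply(epochs_by_condition, function(m) {
    zv <- apply(m, 2, stats::sd) == 0
    cc <- suppressWarnings(stats::cor(m, method = method))
    cc[zv, ] <- NA; cc[, zv] <- NA
    diag(cc) <- 1
    cc
  })
  contrast <- list()
  if (baseline %in% names(r)) {
    for (cond in setdiff(names(r), baseline))
      contrast[[paste0(cond, "-", baseline)]] <- r[[cond]] - r[[baseline]]
  }
  structure(list(r = r, contrast = contrast, method = method),
            class = "corr_matrix_set")
}

#' Average correlation matrices across sessions
#'
#' Plain averaging of correlation coefficients by default; Fisher
#' z-transform averaging behind a flag.
#'
#' @param mats List of ROI x ROI matrices.
#' @param fisher Average in the Fisher-z domain.
#' @return Averaged matrix.
#' @export
average_corr_matrices <- function(mats, fisher = FALSE) {
  if (fisher) {
    z <- Reduce(`+`, lapply(mats, atanh)) / length(mats)
    out <- tanh(z)
    diag(out) <- 1
    out
  } else {
    Reduce(`+`, mats) / length(mats)
  }
}

#' Test whether baseline correlations exceed zero
#'
#' One-sided Wilcoxon signed-rank test of the per-subject correlation
#' values of one ROI-pair cell against zero, Bonferroni-corrected for the
#' number of tests. Zeros are discarded (the standard convention); an
#' all-zero vector is undefined and returns `NA` with a flag.
#'
#' @param r Per-subject correlation values for one cell.
#' @param m Number of tests in the Bonferroni family.
#' @return list with `statistic`, `p`, `p_adj`, `n`, `flagged`.
#' @export
test_baseline_correlations <- function(r, m = 1L) {
  r <- r[!is.na(r)]
  nonzero <- r[r != 0]
  if (length(nonzero) == 0L)
    return(list(statistic = NA_real_, p = NA_real_, p_adj = NA_real_,
                n = 0L, flagged = TRUE))
  wt <- stats::wilcox.test(nonzero, alternative = "greater", exact = TRUE)
  list(statistic = unname(wt$statistic), p = wt$p.value,
       p_adj = min(1, m * wt$p.value), n = length(nonzero), flagged = FALSE)
}

#' Test a correlation contrast with a one-sample t test
#'
#' Two-tailed one-sample t test of the per-subject correlation
#' differences of one cell against zero, Bonferroni-corrected.
#'
#' @param delta Per-subject correlation differences for one cell.
#' @param m Number of tests in the Bonferroni family.
#' @return list with `statistic` (t), `df`, `p`, `p_adj`, `flagged`
#'   (zero-variance input).
#' @export
test_contrast <- function(delta, m = 1L) {
  delta <- delta[!is.na(delta)]
  n <- length(delta)
  if (n < 3L) stopf("need at least 3 subjects")
  s <- stats::sd(delta)
  if (s == 0) {
    if (mean(delta) == 0)
      return(list(statistic = NA_real_, df = n - 1L, p = NA_real_,
                  p_adj = NA_real_, flagged = TRUE))
    return(list(statistic = sign(mean(delta)) * Inf, df = n - 1L, p = 0,
                p_adj = 0, flagged = TRUE))
  }
  tt <- stats::t.test(delta)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, p_adj = min(1, m * tt$p.value), flagged = FALSE)
}

#' Cell-wise tests over a stack of per-subject matrices
#'
#' Applies [test_baseline_correlations()] (for a condition matrix) or
#' [test_contrast()] (for a contrast matrix) to every upper-triangle cell
#' of a subjects-stack of ROI x ROI matrices and returns a long-format
#' table. The Bonferroni family size defaults to the number of tested
#' cells; `family = "rois"` uses the number of ROIs instead.
#'
#' @param mats List (one ROI x ROI matrix per subject).
#' @param type `"baseline"` or `"contrast"`.
#' @param family `"cells"` (default) or `"rois"`.
#' @return data.frame with columns `roi_i`, `roi_j`, `statistic`, `p`,
#'   `p_adj`.
#' @export
correlation_cell_tests <- function(mats, type = c("baseline", "contrast"),
                                   family = c("cells", "rois")) {
  type <- match.arg(type); family <- match.arg(family)
  rois <- rownames(mats[[1]]) %||% paste0("roi", seq_len(nrow(mats[[1]])))
  n_roi <- length(rois)
  cells <- which(upper.tri(mats[[1]]), arr.ind = TRUE)
  m <- if (family == "cells") nrow(cells) else n_roi
  rows <- lapply(seq_len(nrow(cells)), function(k) {
    i <- cells[k, 1]; j <- cells[k, 2]
    v <- vapply(mats, function(mm) mm[i, j], numeric(1))
    res <- if (type == "baseline") test_baseline_correlations(v, m)
           else test_contrast(v, m)
    data.frame(roi_i = rois[i], roi_j = rois[j],
               statistic = res$statistic, p = res$p, p_adj = res$p_adj,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
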