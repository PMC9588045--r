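## Region-based Bayesian multilevel model: data container, simulation
## from the generative model, and the fitting front-end.

#' Assemble data for the Bayesian multilevel model
#'
#' One response per (condition, region, subject) cell: typically GLM beta
#' weights in percent signal change, or percent CBV change per depth bin.
#'
#' @param condition,region,subject Cell labels (coercible to factor).
#' @param y Response amplitudes.
#' @return A `bml_data` data.frame; the complete crossed design is
#'   required (exactly one row per cell).
#' @export
bml_data <- function(condition, region, subject, y) {
  df <- data.frame(condition = as.factor(condition),
                   region = as.factor(region),
                   subject = as.factor(subject),
                   y = as.numeric(y))
  if (!all(is.finite(df$y))) stopf("responses must be finite")
  C <- nlevels(df$condition); R <- nlevels(df$region); S <- nlevels(df$subject)
  if (nrow(df) != C * R * S ||
      anyDuplicated(df[, c("condition", "region", "subject")]))
    stopf("need exactly one observation per (condition, region, subject) cell")
  if (!C %in% c(2L, 3L))
    stopf("the model supports 2 or 3 conditions (got %d)", C)
  class(df) <- c("bml_data", "data.frame")
  df
}

bml_data_array <- function(data) {
  C <- nlevels(data$condition); R <- nlevels(data$region)
  S <- nlevels(data$subject)
  y <- array(NA_real_, c(C, R, S))
  y[cbind(as.integer(data$condition), as.integer(data$region),
          as.integer(data$subject))] <- data$y
  y
}

#' Simulate data from the multilevel model
#'
#' Draws one dataset from the generative model: population condition
#' effects `b`, crossed varying effects for subject-by-condition
#' (covariance `Theta`), region-by-condition (covariance `Omega`) and
#' region-by-subject (`lambda^2`), and Student-t residuals with `nu`
#' degrees of freedom and scale `sigma`.
#'
#' @param C,R,S Numbers of conditions, regions, subjects.
#' @param b Population condition effects (length `C`).
#' @param Theta,Omega `C x C` covariance matrices (default `0.01 * I`).
#' @param lambda Region-by-subject effect standard deviation.
#' @param nu Student-t degrees of freedom.
#' @param sigma Residual scale.
#' @param seed Integer seed.
#' @return A [bml_data()] with the simulated truth in the `truth`
#'   attribute.
#' @export
simulate_bml_data <- function(C = 3L, R = 15L, S = 15L,
                              b = c(0.2, 0.5, 0.8),
                              Theta = diag(0.01, C), Omega = diag(0.01, C),
                              lambda = 0.05, nu = 30, sigma = 0.1,
                              seed = 1L) {
  stopifnot(length(b) == C)
  with_seed(seed, {
    Ls <- t(chol(Theta)); Lr <- t(chol(Omega))
    xi <- Ls %*% matrix(stats::rnorm(C * S), C, S)
    eta <- Lr %*% matrix(stats::rnorm(C * R), C, R)
    gam <- matrix(stats::rnorm(R * S, 0, lambda), R, S)
    grid <- expand.grid(condition = seq_len(C), region = seq_len(R),
                        subject = seq_len(S))
    y <- b[grid$condition] + xi[cbind(grid$condition, grid$subject)] +
      eta[cbind(grid$condition, grid$region)] +
      gam[cbind(grid$region, grid$subject)] +
      sigma * stats::rt(nrow(grid), df = nu)
  })
  out <- bml_data(condition = sprintf("c%d", grid$condition),
                  region = sprintf("r%02d", grid$region),
                  subject = sprintf("s%02d", grid$subject), y = y)
  attr(out, "truth") <- list(b = b, Theta = Theta, Omega = Omega,
                             lambda = lambda, nu = nu, sigma = sigma,
                             xi = xi, eta = eta, gam = gam)
  out
}

#' Fit the Bayesian multilevel model
#'
#' Fits the Student-t multilevel model with crossed condition/region/
#' subject varying effects by MCMC (see the package vignette for the
#' sampler). `iterations` counts post-adaptation iterations per chain, of
#' which the first `warmup` are discarded.
#'
#' Convergence is assessed on every sampled parameter with the split
#' R-hat statistic; a maximum above `rhat_warn` triggers a prominent
#' warning (the fit is still returned, never silently).
#'
#' @param data A [bml_data()].
#' @param chains Number of chains (>= 2).
#' @param iterations Iterations per chain (default 1000).
#' @param warmup Warmup iterations discarded per chain (default half).
#' @param seed Integer seed; chains use derived sub-seeds.
#' @param rhat_warn Split R-hat warning threshold (default 1.05).
#' @return A `bml_fit`: `draws` (iterations x chains x parameters array),
#'   `labels`, `data`, and sampler metadata.
#' @export
fit_bml <- function(data, chains = 4L, iterations = 1000L,
                    warmup = floor(iterations / 2), seed = 1L,
                    rhat_warn = 1.05) {
  if (!inherits(data, "bml_data")) stopf("'data' must be a bml_data object")
  if (chains < 2L) stopf("need at least 2 chains for convergence diagnostics")
  if (warmup >= iterations) stopf("warmup must be smaller than iterations")
  if (nlevels(data$subject) < 2L)
    stopf("varying effects are unidentifiable with a single subject")
  if (nlevels(data$region) < 2L)
    stopf("varying effects are unidentifiable with a single region")
  y <- bml_data_array(data)
  labels <- list(condition = levels(data$condition),
                 region = levels(data$region),
                 subject = levels(data$subject))
  t0 <- Sys.time()
  chain_draws <- lapply(seq_len(chains), function(ch)
    bml_chain(y, iterations, warmup, derive_seed(seed, ch), labels))
  draws <- array(NA_real_,
                 c(iterations - warmup, chains, ncol(chain_draws[[1]])),
                 dimnames = list(NULL, NULL, colnames(chain_draws[[1]])))
  for (ch in seq_len(chains)) draws[, ch, ] <- chain_draws[[ch]]
  fit <- structure(list(
    draws = draws, labels = labels, data = data,
    chains = chains, iterations = iterations, warmup = warmup,
    seed = seed, sd_y = stats::sd(data$y),
    runtime_s = as.numeric(Sys.time() - t0, units = "secs")),
    class = "bml_fit")
  dg <- diagnostics(fit)
  fit$diagnostics <- dg
  max_rhat <- max(dg$rhat, na.rm = TRUE)
  if (is.finite(max_rhat) && max_rhat > rhat_warn)
    warning(sprintf(
      "MCMC has not converged: max split R-hat = %.3f (> %.2f) for '%s'; increase iterations",
      max_rhat, rhat_warn, dg$parameter[which.max(dg$rhat)]), call. = FALSE)
  fit
}

#' @export
print.bml_fit <- function(x, ...) {
  cat(sprintf(
    "<bml_fit> C=%d conditions, R=%d regions, S=%d subjects; %d chains x %d kept draws (%.1f s)\n",
    length(x$labels$condition), length(x$labels$region),
    length(x$labels$subject), x$chains, x$iterations - x$warmup,
    x$runtime_s))
  dg <- x$diagnostics
  cat(sprintf("  max split R-hat %.3f, min ESS %.0f (over %d parameters)\n",
              max(dg$rhat, na.rm = TRUE), min(dg$ess, na.rm = TRUE),
              nrow(dg)))
  invisible(x)
}

#' Extract draws of one or more parameters
#'
#' @param fit A `bml_fit`.
#' @param pars Parameter names (as in `dimnames(fit$draws)[[3]]`) or a
#'   regular expression when `regex = TRUE`.
#' @param regex Treat `pars` as a regular expression.
#' @return Matrix of pooled draws (all chains concatenated) x parameters.
#' @export
bml_draws <- function(fit, pars, regex = FALSE) {
  all_pars <- dimnames(fit$draws)[[3]]
  sel <- if (regex) grep(pars, all_pars, value = TRUE) else pars
  miss <- setdiff(sel, all_pars)
  if (length(miss)) stopf("unknown parameter(s): %s", paste(miss, collapse = ", "))
  out <- apply(fit$draws[, , sel, drop = FALSE], 3, as.vector)
  colnames(out) <- sel
  out
}

#' Per-region condition-effect draws
#'
#' Draws of `b_c + eta_cr`, the region-level effect of a condition, used
#' for ridgeline-style posterior displays and region-wise indices.
#'
#' @param fit A `bml_fit`.
#' @param condition Condition label.
#' @return Matrix of pooled draws x regions.
#' @export
condition_region_draws <- function(fit, condition) {
  if (!condition %in% fit$labels$condition)
    stopf("unknown condition '%s'", condition)
  bdr <- bml_draws(fit, sprintf("b[%s]", condition))
  eta <- bml_draws(fit, sprintf("eta[%s,%s]", condition, fit$labels$region))
  out <- sweep(eta, 1, bdr, "+")
  colnames(out) <- fit$labels$region
  out
}
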