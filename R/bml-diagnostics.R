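## MCMC convergence diagnostics: split R-hat and effective sample size.

## split each chain in half, returning an iterations x (2 * chains) matrix
split_chains <- function(x) {
  n <- nrow(x)
  half <- floor(n / 2)
  x <- x[seq_len(2 * half), , drop = FALSE]
  cbind(x[seq_len(half), , drop = FALSE],
        x[half + seq_len(half), , drop = FALSE])
}

#' Split R-hat for one parameter
#'
#' The between/within-chain variance ratio computed on split chains:
#' each chain is halved, and R-hat is
#' `sqrt(((n-1)/n * W + B/n) / W)` over the resulting half-chains.
#' Values near 1 indicate convergence; the study's criterion is < 1.05.
#'
#' @param x Draws, iterations x chains matrix.
#' @return Split R-hat (NA for constant draws).
#' @export
split_rhat <- function(x) {
  x <- split_chains(as.matrix(x))
  n <- nrow(x)
  if (n < 2L) return(NA_real_)
  means <- colMeans(x)
  vars <- apply(x, 2, stats::var)
  W <- mean(vars)
  if (W == 0) return(NA_real_)
  B <- n * stats::var(means)
  sqrt(((n - 1) / n * W + B / n) / W)
}

## per-sequence autocovariances (biased, lag 0..n-1) via FFT
acov_fft <- function(v) {
  n <- length(v)
  v <- v - mean(v)
  M <- stats::nextn(2L * n)
  f <- stats::fft(c(v, rep(0, M - n)))
  ## inverse FFT in R is unnormalized; divide by M, then by n for the
  ## biased autocovariance estimate
  Re(stats::fft(f * Conj(f), inverse = TRUE))[seq_len(n)] / M / n
}

#' Effective sample size for one parameter
#'
#' Multi-chain effective sample size from split chains: combined
#' autocorrelations are formed from the within-chain autocovariances and
#' the pooled variance estimate, summed with Geyer's initial monotone
#' positive sequence.
#'
#' @param x Draws, iterations x chains matrix.
#' @return Effective sample size (capped at the total draw count times
#'   `log10` overcount guard of 1; NA for constant draws).
#' @export
ess_draws <- function(x) {
  x <- split_chains(as.matrix(x))
  n <- nrow(x); m <- ncol(x)
  if (n < 3L) return(NA_real_)
  vars <- apply(x, 2, stats::var)
  W <- mean(vars)
  if (W == 0) return(NA_real_)
  B <- n * stats::var(colMeans(x))
  var_plus <- (n - 1) / n * W + B / n
  ac <- vapply(seq_len(m), function(j) acov_fft(x[, j]), numeric(n))
  mean_ac <- rowMeans(ac)
  rho <- 1 - (W - mean_ac) / var_plus
  rho[1] <- 1
  ## Geyer initial positive monotone sequence on paired sums
  max_pairs <- floor((n - 1) / 2)
  psum <- numeric(max_pairs)
  for (k in seq_len(max_pairs))
    psum[k] <- rho[2 * k] + rho[2 * k + 1]
  pos <- which(psum <= 0)
  K <- if (length(pos)) pos[1] - 1L else max_pairs
  if (K > 1L) psum[seq_len(K)] <- cummin(psum[seq_len(K)])
  tau <- if (K >= 1L) 1 + 2 * sum(psum[seq_len(K)]) else 1
  tau <- max(tau, 1e-3)
  min(n * m / tau, n * m)
}

#' Convergence diagnostics for a fitted multilevel model
#'
#' Split R-hat and effective sample size for every sampled parameter
#' (population effects, scales, degrees of freedom, correlations and all
#' varying effects).
#'
#' @param fit A `bml_fit`.
#' @param pars Optional subset (names or regex with `regex = TRUE`).
#' @param regex Treat `pars` as a regular expression.
#' @return data.frame with `parameter`, `rhat`, `ess`.
#' @export
diagnostics <- function(fit, pars = NULL, regex = FALSE) {
  if (fit$chains < 2L)
    stopf("R-hat is undefined for a single chain")
  all_pars <- dimnames(fit$draws)[[3]]
  sel <- if (is.null(pars)) all_pars
         else if (regex) grep(pars, all_pars, value = TRUE)
         else pars
  res <- data.frame(
    parameter = sel,
    rhat = vapply(sel, function(p) split_rhat(fit$draws[, , p]), numeric(1)),
    ess = vapply(sel, function(p) ess_draws(fit$draws[, , p]), numeric(1)),
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

## parameters reported as "population-level" in summaries: everything
## except the varying-effect draws
population_parameters <- function(fit) {
  grep("^(xi|eta|gam)\\[", dimnames(fit$draws)[[3]],
       invert = TRUE, value = TRUE)
}
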