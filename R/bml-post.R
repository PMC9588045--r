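## Posterior summaries: valence modulation index, P+, posterior
## predictive checks.

#' Dimensionless modulation index
#'
#' Per-draw index `(C1 - C2) / (|C1| + |C2|)`, bounded in [-1, 1] and
#' antisymmetric in its arguments; the study's negative valence index is
#' fearful vs neutral, the positive valence index happy vs neutral.
#' Draws with both arguments zero return 0 by convention and are counted
#' in the `n_zero_zero` attribute.
#'
#' @param draws_c1,draws_c2 Equal-length draw vectors of the two
#'   condition effects.
#' @return Vector of index draws.
#' @export
modulation_index <- function(draws_c1, draws_c2) {
  if (length(draws_c1) != length(draws_c2))
    stopf("draw counts differ (%d vs %d)",
          length(draws_c1), length(draws_c2))
  den <- abs(draws_c1) + abs(draws_c2)
  zz <- den == 0
  out <- ifelse(zz, 0, (draws_c1 - draws_c2) / ifelse(zz, 1, den))
  attr(out, "n_zero_zero") <- sum(zz)
  out
}

#' Posterior probability of a positive effect (P+)
#'
#' Fraction of posterior draws strictly greater than zero.
#'
#' @param draws Draw vector (>= 100 draws).
#' @return P+ in [0, 1].
#' @export
posterior_positive_prob <- function(draws) {
  if (length(draws) < 100L)
    stopf("need at least 100 draws for a stable P+ estimate")
  mean(draws > 0)
}

#' Region-wise modulation-index posterior table
#'
#' For every region, forms the modulation index between the region-level
#' effects (`b_c + eta_cr`) of two conditions and summarizes its
#' posterior: mean, 95% quantile interval, and P+.
#'
#' @param fit A `bml_fit`.
#' @param c1,c2 Condition labels (index is `c1` vs `c2`).
#' @return data.frame with one row per region; the full index draws are
#'   attached as the `draws` attribute (draws x regions).
#' @export
valence_index_table <- function(fit, c1, c2) {
  d1 <- condition_region_draws(fit, c1)
  d2 <- condition_region_draws(fit, c2)
  idx <- vapply(seq_len(ncol(d1)),
                function(r) modulation_index(d1[, r], d2[, r]),
                numeric(nrow(d1)))
  colnames(idx) <- fit$labels$region
  out <- data.frame(
    region = fit$labels$region,
    mean = colMeans(idx),
    q2.5 = apply(idx, 2, stats::quantile, 0.025),
    q97.5 = apply(idx, 2, stats::quantile, 0.975),
    p_plus = apply(idx, 2, posterior_positive_prob),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "draws") <- idx
  out
}

#' Region-wise contrast posterior table
#'
#' Posterior of the plain difference `(b_c1 + eta_c1,r) - (b_c2 + eta_c2,r)`
#' per region, with 95% quantile intervals and P+.
#'
#' @inheritParams valence_index_table
#' @return data.frame with one row per region, draws in the `draws`
#'   attribute.
#' @export
contrast_table <- function(fit, c1, c2) {
  d <- condition_region_draws(fit, c1) - condition_region_draws(fit, c2)
  out <- data.frame(
    region = fit$labels$region,
    mean = colMeans(d),
    q2.5 = apply(d, 2, stats::quantile, 0.025),
    q97.5 = apply(d, 2, stats::quantile, 0.975),
    p_plus = apply(d, 2, posterior_positive_prob),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "draws") <- d
  out
}

#' Posterior predictive check
#'
#' Simulates replicate datasets from the fitted model (plugging in the
#' posterior draws of all parameters, including the varying effects) and
#' compares observed per-condition means with their replicated
#' distribution, plus a per-observation two-sided predictive tail
#' probability for outlier detection.
#'
#' @param fit A `bml_fit`.
#' @param n_rep Number of replicate datasets (>= 1; default 200).
#' @param seed Seed for the replicate simulation.
#' @return A `bml_ppc`: `rep_cond_means` (n_rep x C), `obs_cond_means`,
#'   `cond_mean_quantile` (where the observed mean falls among
#'   replicates), and `tail_prob` per observation.
#' @export
posterior_predictive_check <- function(fit, n_rep = 200L, seed = 1L) {
  if (n_rep < 1L) stopf("n_rep must be >= 1")
  data <- fit$data
  labels <- fit$labels
  C <- length(labels$condition)
  ci <- as.integer(data$condition); ri <- as.integer(data$region)
  si <- as.integer(data$subject)
  total <- dim(fit$draws)[1] * dim(fit$draws)[2]
  pick <- with_seed(seed, sample(total, min(n_rep, total)))
  b <- bml_draws(fit, "^b\\[", regex = TRUE)
  xi <- bml_draws(fit, "^xi\\[", regex = TRUE)
  eta <- bml_draws(fit, "^eta\\[", regex = TRUE)
  gam <- bml_draws(fit, "^gam\\[", regex = TRUE)
  sigma <- bml_draws(fit, "sigma")[, 1]
  nu <- bml_draws(fit, "nu")[, 1]
  S <- length(labels$subject); R <- length(labels$region)
  idx_xi <- (si - 1L) * C + ci
  idx_eta <- (ri - 1L) * C + ci
  idx_gam <- (si - 1L) * R + ri
  n_obs <- nrow(data)
  rep_means <- matrix(NA_real_, length(pick), C,
                      dimnames = list(NULL, labels$condition))
  tail_count <- numeric(n_obs)
  with_seed(derive_seed(seed, 2L), {
    for (k in seq_along(pick)) {
      dr <- pick[k]
      mu <- b[dr, ci] + xi[dr, idx_xi] + eta[dr, idx_eta] + gam[dr, idx_gam]
      yrep <- mu + sigma[dr] * stats::rt(n_obs, df = nu[dr])
      rep_means[k, ] <- tapply(yrep, ci, mean)
      tail_count <- tail_count + (yrep >= data$y)
    }
  })
  frac_ge <- tail_count / length(pick)
  obs_means <- tapply(data$y, ci, mean)
  structure(list(
    rep_cond_means = rep_means,
    obs_cond_means = stats::setNames(as.numeric(obs_means), labels$condition),
    cond_mean_quantile = vapply(seq_len(C), function(cc)
      mean(rep_means[, cc] <= obs_means[cc]), numeric(1)),
    tail_prob = 2 * pmin(frac_ge, 1 - frac_ge),
    n_rep = length(pick)), class = "bml_ppc")
}

#' @export
print.bml_ppc <- function(x, ...) {
  cat(sprintf("<bml_ppc> %d replicates\n", x$n_rep))
  q <- x$cond_mean_quantile
  for (i in seq_along(x$obs_cond_means))
    cat(sprintf("  %s: observed mean %.3f at replicate quantile %.2f\n",
                names(x$obs_cond_means)[i], x$obs_cond_means[i], q[i]))
  invisible(x)
}
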