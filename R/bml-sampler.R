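## Blocked Gibbs sampler for the region-based Bayesian multilevel model
##
##   y_crs ~ T(b_c + xi_cs + eta_cr + gam_rs, nu, sigma^2)
##   (xi_1s..xi_Cs)' ~ N(0, Theta),  (eta_1r..eta_Cr)' ~ N(0, Omega),
##   gam_rs ~ N(0, lambda^2)
##
## Priors: flat on b_c; LKJ(1) (jointly uniform) on the Theta/Omega
## correlations, realized exactly through the C-vine partial-correlation
## construction; half-t(3,0,1) on lambda and on the Theta/Omega standard
## deviations; Gamma(2, 0.1) on nu; half-Cauchy(0, sd(y)) on sigma.
##
## The Student-t likelihood is handled through its normal scale-mixture
## representation (per-observation weights w ~ Gamma(nu/2, nu/2)), giving
## conjugate Gaussian updates for every location block. Three additional
## ingredients make the chain mix at the paper's iteration counts, where
## plain single-site Gibbs does not:
##   * exact recentering ("sweep") moves that jointly translate b_c
##     against the means of xi, eta and gam -- the flat directions of the
##     crossed-intercept posterior;
##   * partially collapsed slice updates for nu and sigma with the
##     mixture weights integrated out (the marginal Student-t likelihood),
##     removing the nu <-> w coupling;
##   * a partially collapsed slice update for lambda with gam integrated
##     out (rank-one Gaussian marginalization per region-subject cell).

## ---- scalar slice sampler (Neal 2003, stepping out + shrinkage) ----
slice_sample1 <- function(x0, logf, w = 1, m = 30L,
                          lower = -Inf, upper = Inf) {
  f0 <- logf(x0)
  if (!is.finite(f0)) stopf("slice sampler started outside support")
  z <- f0 - stats::rexp(1)
  u <- stats::runif(1)
  L <- x0 - w * u
  R <- L + w
  j <- floor(m * stats::runif(1)); k <- m - 1L - j
  while (j > 0L && L > lower && logf(L) > z) { L <- L - w; j <- j - 1L }
  while (k > 0L && R < upper && logf(R) > z) { R <- R + w; k <- k - 1L }
  L <- max(L, lower); R <- min(R, upper)
  repeat {
    x1 <- stats::runif(1, L, R)
    if (logf(x1) > z) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
  }
}

## ---- LKJ(1) via C-vine partial correlations ----
## For dimension d, the canonical partial correlations at vine level k
## are independent Beta(a_k, a_k) rescaled to (-1, 1) with
## a_k = 1 + (d - 1 - k)/2; the implied correlation matrix is jointly
## uniform (LKJ shape 1).
vine_beta_shapes <- function(C) {
  if (C == 2L) return(1)
  if (C == 3L) return(c(1.5, 1.5, 1))
  stopf("the model supports C in {2, 3} conditions")
}

vine_to_corr <- function(p, C) {
  if (C == 2L) return(matrix(c(1, p, p, 1), 2, 2))
  r12 <- p[1]; r13 <- p[2]
  r23 <- r12 * r13 + p[3] * sqrt((1 - r12^2) * (1 - r13^2))
  matrix(c(1, r12, r13, r12, 1, r23, r13, r23, 1), 3, 3)
}

vine_logprior <- function(p, C) {
  if (any(abs(p) >= 1)) return(-Inf)
  a <- vine_beta_shapes(C)
  sum(stats::dbeta((p + 1) / 2, a, a, log = TRUE))
}

log_half_t3 <- function(x) {
  if (x <= 0) return(-Inf)
  stats::dt(x, df = 3, log = TRUE)
}

## log N(0, Sigma) likelihood of the rows of X (n x C), -Inf if Sigma is
## not positive definite
mvn0_loglik <- function(X, Sigma) {
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  -nrow(X) * sum(log(diag(ch))) -
    0.5 * sum(backsolve(ch, t(X), transpose = TRUE)^2)
}

## One MCMC chain. y: C x R x S array. Returns kept draws as a matrix
## (iterations x parameters) plus the parameter naming used throughout.
bml_chain <- function(y, n_iter, warmup, chain_seed, labels) {
  set.seed(chain_seed)
  dC <- dim(y)[1]; dR <- dim(y)[2]; dS <- dim(y)[3]
  N <- dC * dR * dS
  RS <- dR * dS
  npc <- dC * (dC - 1L) / 2L
  sd_y <- stats::sd(y)
  ymat <- matrix(y, dC, RS)            # column (r, s): r fast
  rrep <- rep(seq_len(dR), times = dS) # column -> region index
  srep <- rep(seq_len(dS), each = dR)  # column -> subject index

  ## overdispersed seeded initialization; varying effects start away from
  ## zero so the scale updates do not see a degenerate configuration
  b <- apply(y, 1, mean) + stats::rnorm(dC, 0, 0.3 * sd_y)
  xi <- matrix(stats::rnorm(dC * dS, 0, 0.2 * sd_y), dC, dS)
  eta <- matrix(stats::rnorm(dC * dR, 0, 0.2 * sd_y), dC, dR)
  gam <- matrix(stats::rnorm(dR * dS, 0, 0.1 * sd_y), dR, dS)
  sigma <- sd_y * exp(stats::rnorm(1, 0, 0.4))
  nu <- exp(stats::rnorm(1, log(20), 0.5))
  lambda <- 0.3 * sd_y * exp(stats::rnorm(1, 0, 0.4))
  tau_s <- rep(0.3 * sd_y, dC) * exp(stats::rnorm(dC, 0, 0.4))
  tau_r <- rep(0.3 * sd_y, dC) * exp(stats::rnorm(dC, 0, 0.4))
  p_s <- rep(0, npc); p_r <- rep(0, npc)

  ## numeric guard rails for the log/atanh-scale slice updates
  lsc_lo <- log(1e-7 * sd_y); lsc_hi <- log(100 * sd_y)
  z_lim <- 6  # |rho| <= tanh(6) ~ 1 - 1e-5

  mu_mat <- function()
    b + eta[, rrep, drop = FALSE] + xi[, srep, drop = FALSE] +
      rep(as.vector(gam), each = dC)

  draw_mvn_block <- function(Q, Pdiag, rhs) {
    ## sample from N(A^-1 rhs, A^-1), A = Q + diag(Pdiag)
    A <- Q; diag(A) <- diag(A) + Pdiag
    ch <- chol(A)
    mvec <- backsolve(ch, backsolve(ch, rhs, transpose = TRUE))
    mvec + backsolve(ch, stats::rnorm(length(rhs)))
  }

  n_keep <- n_iter - warmup
  par_names <- bml_par_names(labels)
  keep <- matrix(NA_real_, n_keep, length(par_names),
                 dimnames = list(NULL, par_names))

  for (it in seq_len(n_iter)) {
    ## --- mixture weights w | rest
    E <- ymat - mu_mat()
    w <- matrix(stats::rgamma(N, (nu + 1) / 2,
                              rate = (nu + (E / sigma)^2) / 2), dC, RS)
    P <- w / sigma^2

    ## --- b | rest (flat prior)
    Eb <- E + b                       # y - (mu - b)
    prec_b <- rowSums(P)
    b <- stats::rnorm(dC, rowSums(P * Eb) / prec_b, 1 / sqrt(prec_b))

    ## --- lambda | rest with gam collapsed, then gam | lambda, rest
    E3 <- ymat - (mu_mat() - rep(as.vector(gam), each = dC))
    s_cell <- colSums(P)              # RS: sum_c p
    q_cell <- colSums(P * E3)         # RS: sum_c p * e
    lambda <- exp(slice_sample1(log(lambda), function(lt) {
      l2 <- exp(2 * lt)
      -0.5 * sum(log1p(l2 * s_cell)) +
        0.5 * l2 * sum(q_cell^2 / (1 + l2 * s_cell)) +
        log_half_t3(exp(lt)) + lt
    }, w = 0.5, lower = lsc_lo, upper = lsc_hi))
    prec_cell <- s_cell + 1 / lambda^2
    gam <- matrix(stats::rnorm(RS, q_cell / prec_cell, 1 / sqrt(prec_cell)),
                  dR, dS)

    ## --- (tau_s, p_s) | xi, then xi | rest
    for (c0 in seq_len(dC)) {
      tau_s[c0] <- exp(slice_sample1(log(tau_s[c0]), function(lt) {
        tt <- tau_s; tt[c0] <- exp(lt)
        mvn0_loglik(t(xi), tt * t(tt * vine_to_corr(p_s, dC))) +
          log_half_t3(exp(lt)) + lt
      }, w = 0.7, lower = lsc_lo, upper = lsc_hi))
    }
    for (k0 in seq_len(npc)) {
      p_s[k0] <- tanh(slice_sample1(atanh(p_s[k0]), function(zt) {
        q <- p_s; q[k0] <- tanh(zt)
        mvn0_loglik(t(xi), tau_s * t(tau_s * vine_to_corr(q, dC))) +
          vine_logprior(q, dC) + log(1 - tanh(zt)^2)
      }, w = 0.7, lower = -z_lim, upper = z_lim))
    }
    Sig_s <- tau_s * t(tau_s * vine_to_corr(p_s, dC))
    Qs <- chol2inv(chol(Sig_s))
    Ex <- ymat - (mu_mat() - xi[, srep, drop = FALSE])
    PEx <- P * Ex
    for (s0 in seq_len(dS)) {
      cols <- which(srep == s0)
      xi[, s0] <- draw_mvn_block(Qs, rowSums(P[, cols, drop = FALSE]),
                                 rowSums(PEx[, cols, drop = FALSE]))
    }

    ## --- (tau_r, p_r) | eta, then eta | rest
    for (c0 in seq_len(dC)) {
      tau_r[c0] <- exp(slice_sample1(log(tau_r[c0]), function(lt) {
        tt <- tau_r; tt[c0] <- exp(lt)
        mvn0_loglik(t(eta), tt * t(tt * vine_to_corr(p_r, dC))) +
          log_half_t3(exp(lt)) + lt
      }, w = 0.7, lower = lsc_lo, upper = lsc_hi))
    }
    for (k0 in seq_len(npc)) {
      p_r[k0] <- tanh(slice_sample1(atanh(p_r[k0]), function(zt) {
        q <- p_r; q[k0] <- tanh(zt)
        mvn0_loglik(t(eta), tau_r * t(tau_r * vine_to_corr(q, dC))) +
          vine_logprior(q, dC) + log(1 - tanh(zt)^2)
      }, w = 0.7, lower = -z_lim, upper = z_lim))
    }
    Sig_r <- tau_r * t(tau_r * vine_to_corr(p_r, dC))
    Qr <- chol2inv(chol(Sig_r))
    Ee <- ymat - (mu_mat() - eta[, rrep, drop = FALSE])
    PEe <- P * Ee
    for (r0 in seq_len(dR)) {
      cols <- which(rrep == r0)
      eta[, r0] <- draw_mvn_block(Qr, rowSums(P[, cols, drop = FALSE]),
                                  rowSums(PEe[, cols, drop = FALSE]))
    }

    ## --- recentering sweeps (exact Gibbs along the flat translation
    ## directions; likelihood-invariant, flat prior on b)
    d1 <- rowMeans(xi) + drop(t(chol(Sig_s)) %*% stats::rnorm(dC)) / sqrt(dS)
    xi <- xi - d1; b <- b + d1
    d2 <- rowMeans(eta) + drop(t(chol(Sig_r)) %*% stats::rnorm(dC)) / sqrt(dR)
    eta <- eta - d2; b <- b + d2
    a0 <- stats::rnorm(1, mean(gam), lambda / sqrt(RS))
    gam <- gam - a0; b <- b + a0

    ## --- nu, sigma | rest with w collapsed (marginal Student-t)
    e <- as.vector(ymat - mu_mat())
    nu <- exp(slice_sample1(log(nu), function(lt) {
      v <- exp(lt)
      sum(stats::dt(e / sigma, v, log = TRUE)) +
        stats::dgamma(v, 2, rate = 0.1, log = TRUE) + lt
    }, w = 0.7, lower = log(0.05), upper = log(5000)))
    sigma <- exp(slice_sample1(log(sigma), function(ls) {
      sg <- exp(ls)
      sum(stats::dt(e / sg, nu, log = TRUE)) - length(e) * ls +
        stats::dcauchy(sg, 0, sd_y, log = TRUE) + ls
    }, w = 0.5, lower = lsc_lo, upper = lsc_hi))

    if (it > warmup) {
      rho_s <- corr_upper(vine_to_corr(p_s, dC))
      rho_r <- corr_upper(vine_to_corr(p_r, dC))
      keep[it - warmup, ] <- c(b, sigma, nu, lambda, tau_s, tau_r,
                               rho_s, rho_r,
                               as.vector(xi), as.vector(eta), as.vector(gam))
    }
  }
  keep
}

corr_upper <- function(R) R[upper.tri(R)]

## canonical parameter naming shared by the sampler, diagnostics and
## posterior summaries
bml_par_names <- function(labels) {
  C <- length(labels$condition); R <- length(labels$region)
  S <- length(labels$subject)
  pairs <- which(upper.tri(diag(C)), arr.ind = TRUE)
  pair_lab <- paste0(pairs[, 1], ",", pairs[, 2])
  c(paste0("b[", labels$condition, "]"),
    "sigma", "nu", "lambda",
    paste0("tau_subj[", labels$condition, "]"),
    paste0("tau_region[", labels$condition, "]"),
    paste0("rho_subj[", pair_lab, "]"),
    paste0("rho_region[", pair_lab, "]"),
    paste0("xi[", rep(labels$condition, times = S), ",",
           rep(labels$subject, each = C), "]"),
    paste0("eta[", rep(labels$condition, times = R), ",",
           rep(labels$region, each = C), "]"),
    paste0("gam[", rep(labels$region, times = S), ",",
           rep(labels$subject, each = R), "]"))
}
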