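test_that("modulation index obeys its formula, bounds and antisymmetry", {
  expect_equal(as.numeric(modulation_index(1.0, 0.5)), 1/3, tolerance = 1e-12)
  expect_equal(as.numeric(modulation_index(0.7, 0.7)), 0)
  expect_equal(as.numeric(modulation_index(1, -1)), 1)
  expect_equal(as.numeric(modulation_index(-1, 1)), -1)
  ## both-zero convention
  mz <- modulation_index(c(0, 1), c(0, 2))
  expect_equal(as.numeric(mz), c(0, -1/3))
  expect_equal(attr(mz, "n_zero_zero"), 1L)
  expect_error(modulation_index(1:3, 1:2), "draw counts differ")
  ## property: antisymmetric and bounded on random draws
  set.seed(1)
  a <- rnorm(500); b <- rnorm(500)
  idx <- modulation_index(a, b)
  expect_true(all(idx >= -1 & idx <= 1))
  expect_equal(as.numeric(idx), -as.numeric(modulation_index(b, a)))
})

test_that("P+ matches its analytic value for a unit normal at mean 1", {
  expect_equal(posterior_positive_prob(rep(1, 200)), 1)
  set.seed(4)
  expect_equal(posterior_positive_prob(rnorm(2000)), 0.5, tolerance = 0.05)
  draws <- with(list(), { set.seed(123); rnorm(1e5, mean = 1) })
  expect_equal(posterior_positive_prob(draws), pnorm(1), tolerance = 0.004)
  expect_error(posterior_positive_prob(rnorm(50)), "at least 100")
})

test_that("split R-hat and ESS behave on independent and disjoint chains", {
  set.seed(11)
  iid <- matrix(rnorm(4000), 1000, 4)
  expect_lt(split_rhat(iid), 1.01)
  expect_equal(ess_draws(iid), 4000, tolerance = 0.2)
  ## chains with disjoint means
  bad <- cbind(rnorm(500, 10), rnorm(500, -10))
  expect_gt(split_rhat(bad), 3)
  ## a within-chain trend is caught by splitting
  trend <- matrix(rep(seq(0, 1, length.out = 500), 4), 500, 4) +
    matrix(rnorm(2000, 0, 0.05), 500, 4)
  expect_gt(split_rhat(trend), 1.05)
  ## AR(1) chains: ESS ratio close to (1 - phi) / (1 + phi)
  phi <- 0.6
  ar <- vapply(1:4, function(k) {
    set.seed(k)
    as.numeric(stats::filter(rnorm(2000, 0, sqrt(1 - phi^2)), phi,
                             method = "recursive"))
  }, numeric(2000))
  ratio <- ess_draws(ar) / (2000 * 4)
  expect_equal(ratio, (1 - phi) / (1 + phi), tolerance = 0.35)
})

test_that("the data container enforces the complete crossed design", {
  g <- expand.grid(condition = c("c1", "c2"), region = c("r1", "r2"),
                   subject = c("s1", "s2", "s3"))
  d <- bml_data(g$condition, g$region, g$subject, rnorm(nrow(g)))
  expect_s3_class(d, "bml_data")
  expect_error(bml_data(g$condition[-1], g$region[-1], g$subject[-1],
                        rnorm(nrow(g) - 1)), "one observation per")
  g4 <- expand.grid(condition = paste0("c", 1:4), region = "r1",
                    subject = c("s1", "s2"))
  expect_error(bml_data(g4$condition, g4$region, g4$subject,
                        rnorm(nrow(g4))), "2 or 3 conditions")
  ## degenerate single subject rejected at fit time
  g1 <- expand.grid(condition = c("c1", "c2"), region = c("r1", "r2"),
                    subject = "s1")
  d1 <- bml_data(g1$condition, g1$region, g1$subject, rnorm(nrow(g1)))
  expect_error(fit_bml(d1), "single subject")
  expect_error(fit_bml(d, chains = 1), "at least 2 chains")
})

test_that("the sampler recovers planted effects on a small design", {
  dat <- simulate_bml_data(C = 2, R = 6, S = 10, b = c(0.2, 0.6),
                           Theta = diag(0.01, 2), Omega = diag(0.01, 2),
                           lambda = 0.05, nu = 30, sigma = 0.1, seed = 5)
  fit <- suppressWarnings(fit_bml(dat, chains = 2, iterations = 600, seed = 9))
  b_draws <- bml_draws(fit, "^b\\[", regex = TRUE)
  pm <- colMeans(b_draws)
  expect_equal(unname(pm), c(0.2, 0.6), tolerance = 0.25)
  ## draws are reproducible given the seed
  fit2 <- suppressWarnings(fit_bml(dat, chains = 2, iterations = 600, seed = 9))
  expect_identical(fit$draws, fit2$draws)
  ## diagnostics table covers every sampled parameter
  expect_equal(nrow(fit$diagnostics), dim(fit$draws)[3])
})

test_that("posterior means agree with an independent MCMC implementation", {
  skip_if_not_installed("rjags")
  ## small dataset; our blocked Gibbs vs a JAGS formulation of the same
  ## model (long run to tame JAGS's slower mixing)
  dat <- simulate_bml_data(C = 2, R = 5, S = 8, b = c(0.3, 0.7),
                           Theta = diag(0.02, 2), Omega = diag(0.02, 2),
                           lambda = 0.05, nu = 25, sigma = 0.12, seed = 31)
  fit <- suppressWarnings(fit_bml(dat, chains = 2, iterations = 1500, seed = 17))
  ours <- colMeans(bml_draws(fit, "^b\\[|^sigma$", regex = TRUE))

  model_str <- "
  model {
    for (i in 1:N) {
      w[i] ~ dgamma(nu / 2, nu / 2)
      y[i] ~ dnorm(b[cond[i]] + xi[cond[i], subj[i]] + eta[cond[i], region[i]]
                   + gam[region[i], subj[i]], w[i] / sigma^2)
    }
    for (s in 1:S) { xi[1:2, s] ~ dmnorm(zero2, inverse(Sig_s)) }
    for (r in 1:R) { eta[1:2, r] ~ dmnorm(zero2, inverse(Sig_r)) }
    for (r in 1:R) { for (s in 1:S) { gam[r, s] ~ dnorm(0, pow(lambda, -2)) } }
    lambda ~ dt(0, 1, 3) T(0,)
    nu ~ dgamma(2, 0.1)
    sigma ~ dt(0, pow(sd_y, -2), 1) T(0,)
    for (c in 1:2) {
      b[c] ~ dnorm(0, pow(100 * sd_y, -2))
      tau_s[c] ~ dt(0, 1, 3) T(0,)
      tau_r[c] ~ dt(0, 1, 3) T(0,)
    }
    ps ~ dunif(-1, 1); pr ~ dunif(-1, 1)
    Sig_s[1,1] <- tau_s[1]^2; Sig_s[2,2] <- tau_s[2]^2
    Sig_s[1,2] <- tau_s[1]*tau_s[2]*ps; Sig_s[2,1] <- Sig_s[1,2]
    Sig_r[1,1] <- tau_r[1]^2; Sig_r[2,2] <- tau_r[2]^2
    Sig_r[1,2] <- tau_r[1]*tau_r[2]*pr; Sig_r[2,1] <- Sig_r[1,2]
  }"
  jd <- list(y = dat$y, cond = as.integer(dat$condition),
             region = as.integer(dat$region),
             subject = as.integer(dat$subject), N = nrow(dat),
             S = nlevels(dat$subject), R = nlevels(dat$region),
             zero2 = c(0, 0), sd_y = sd(dat$y))
  names(jd)[names(jd) == "subject"] <- "subj"
  jm <- rjags::jags.model(textConnection(model_str), data = jd,
                          inits = list(.RNG.name = "base::Mersenne-Twister",
                                       .RNG.seed = 100),
                          n.chains = 1, n.adapt = 1000, quiet = TRUE)
  stats::update(jm, 2000)
  samp <- rjags::coda.samples(jm, c("b", "sigma"), n.iter = 8000)
  jags_means <- colMeans(as.matrix(samp))
  ## population effects agree within combined Monte-Carlo error
  expect_equal(unname(ours[1:2]), unname(jags_means[c("b[1]", "b[2]")]),
               tolerance = 0.05)
  expect_equal(unname(ours["sigma"]), unname(jags_means["sigma"]),
               tolerance = 0.15)
})

test_that("with large fixed-ish nu the posterior approaches a Gaussian fit", {
  ## data generated with essentially Gaussian noise: the t model's b
  ## estimates match ordinary cell-mean estimates closely
  dat <- simulate_bml_data(C = 2, R = 8, S = 10, b = c(0.1, 0.5),
                           lambda = 0.03, nu = 1000, sigma = 0.05,
                           Theta = diag(0.005, 2), Omega = diag(0.005, 2),
                           seed = 8)
  fit <- suppressWarnings(fit_bml(dat, chains = 2, iterations = 600, seed = 2))
  pm <- colMeans(bml_draws(fit, "^b\\[", regex = TRUE))
  cell_means <- tapply(dat$y, dat$condition, mean)
  expect_equal(unname(pm), unname(as.numeric(cell_means)), tolerance = 0.08)
})

test_that("posterior predictive checks are self-consistent and catch outliers", {
  dat <- simulate_bml_data(C = 2, R = 6, S = 8, b = c(0.2, 0.5),
                           lambda = 0.05, nu = 30, sigma = 0.1, seed = 3)
  fit <- suppressWarnings(fit_bml(dat, chains = 2, iterations = 500, seed = 5))
  ppc <- posterior_predictive_check(fit, n_rep = 200, seed = 1)
  ## observed per-condition means inside the central 95% of replicates
  expect_true(all(ppc$cond_mean_quantile > 0.025 &
                  ppc$cond_mean_quantile < 0.975))
  expect_error(posterior_predictive_check(fit, n_rep = 0), "n_rep")

  ## gross outlier: flagged by the predictive tail and nu shifts low
  dat_out <- dat
  dat_out$y[7] <- 100 * sd(dat$y)
  fit_out <- suppressWarnings(fit_bml(dat_out, chains = 2, iterations = 500,
                                      seed = 5))
  ppc_out <- posterior_predictive_check(fit_out, n_rep = 300, seed = 2)
  expect_lt(ppc_out$tail_prob[7], 0.01)
  expect_lt(mean(bml_draws(fit_out, "nu")), mean(bml_draws(fit, "nu")))
})

test_that("region-level draws and index tables have coherent shapes", {
  dat <- simulate_bml_data(C = 3, R = 4, S = 6, b = c(0.2, 0.4, 0.6),
                           lambda = 0.05, nu = 30, sigma = 0.1, seed = 12)
  fit <- suppressWarnings(fit_bml(dat, chains = 2, iterations = 400, seed = 3))
  dr <- condition_region_draws(fit, "c2")
  expect_equal(ncol(dr), 4L)
  expect_equal(nrow(dr), 2 * 200)
  vit <- valence_index_table(fit, "c3", "c1")
  expect_equal(nrow(vit), 4L)
  expect_true(all(vit$p_plus >= 0 & vit$p_plus <= 1))
  expect_true(all(attr(vit, "draws") >= -1 & attr(vit, "draws") <= 1))
  expect_error(condition_region_draws(fit, "nope"), "unknown condition")
})
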