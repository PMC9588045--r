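test_that("protocol presets reproduce the published run structure", {
  d3 <- make_block_design("3T-BOLD", seed = 1)
  expect_equal(d3$run_duration, 280)          # 4 min 40 s
  ev <- d3$events
  expect_equal(sum(ev$condition != "fixation"), 9L)
  expect_equal(sum(ev$condition == "fixation"), 10L)
  expect_equal(unique(ev$duration[ev$condition != "fixation"]), 20)
  expect_equal(unique(ev$duration[ev$condition == "fixation"]), 10)
  expect_equal(unname(table(ev$condition)[c("fearful", "neutral", "happy")]),
               rep(3L, 3), ignore_attr = TRUE)

  d7 <- make_block_design("7T-BOLD", seed = 2)
  expect_equal(d7$run_duration, 252)          # 4 min 12 s
  expect_equal(unique(d7$events$duration[d7$events$condition != "fixation"]), 18)

  dv <- make_block_design("7T-VASO", seed = 3)
  ## block arithmetic: 18 x 19.3 + 19 x 9.65
  expect_equal(dv$run_duration, 530.75)
  expect_equal(sum(dv$events$condition != "fixation"), 18L)
  expect_equal(sum(dv$events$condition == "fixation"), 19L)
  expect_equal(unname(table(dv$events$condition)[c("fearful", "neutral", "happy")]),
               rep(6L, 3), ignore_attr = TRUE)

  expect_error(make_block_design("9T-MRI", 1), "unknown protocol")
})

test_that("every face block is followed by fixation and events are disjoint", {
  for (seed in 1:5) {
    d <- make_block_design("7T-BOLD", seed)
    ev <- d$events
    expect_true(all(diff(ev$onset) > 0))
    expect_true(all(ev$onset + ev$duration <= d$run_duration + 1e-9))
    face <- which(ev$condition != "fixation")
    expect_true(all(ev$condition[face + 1L] == "fixation"))
  }
})

test_that("generators are byte-deterministic given the config seed", {
  d <- make_block_design("3T-BOLD", 7)
  cfg <- synth_config(seed = 42, protocol = "3T-BOLD")
  expect_identical(simulate_bold_runs(d, cfg), simulate_bold_runs(d, cfg))
  expect_identical(make_block_design("7T-VASO", 9),
                   make_block_design("7T-VASO", 9))
  rb <- make_ribbon_and_eccentricity(c(8, 12, 3), 10)
  cfgv <- synth_config(seed = 13, protocol = "7T-VASO")
  dv <- make_block_design("7T-VASO", 13)
  expect_identical(simulate_vaso_run(dv, cfgv, rb$ribbon),
                   simulate_vaso_run(dv, cfgv, rb$ribbon))
})

test_that("null generator yields constant-zero series", {
  d <- make_block_design("3T-BOLD", 1)
  cfg <- synth_config(seed = 1, protocol = "3T-BOLD",
                      evoked_amplitude = matrix(0, 5, 3),
                      coupling = matrix(0, 5, 3), noise_sd = 0)
  rs <- simulate_bold_runs(d, cfg)
  expect_equal(max(abs(rs$data)), 0)
})

test_that("noiseless generated responses superpose and deconvolve exactly", {
  d <- make_block_design("7T-BOLD", 4)
  amp <- matrix(c(1.2, 0.8, 0.4), 5, 3, byrow = TRUE)
  cfg0 <- synth_config(seed = 1, protocol = "7T-BOLD",
                       evoked_amplitude = amp,
                       coupling = matrix(0, 5, 3), noise_sd = 0)
  rs <- simulate_bold_runs(d, cfg0)
  ## linearity: sum of single-condition generators equals the full one
  single <- lapply(1:3, function(k) {
    a <- matrix(0, 5, 3); a[, k] <- amp[, k]
    simulate_bold_runs(d, synth_config(seed = 1, protocol = "7T-BOLD",
                                       evoked_amplitude = a,
                                       coupling = matrix(0, 5, 3),
                                       noise_sd = 0))$data
  })
  expect_equal(Reduce(`+`, single), rs$data, tolerance = 1e-12)
  ## FIR deconvolution of the noiseless series reconstructs it exactly
  ## once the window spans the full response (18 s block + 32 s kernel)
  dec <- deconvolve_evoked(rs, d, fir_window = 51)
  expect_lt(max(abs(dec$fit$residual)), 1e-8)
})

test_that("AR(1) noise variance matches noise_sd^2 / (1 - phi^2)", {
  phi <- 0.3; sdv <- 0.5
  x <- with(list(), {
    set.seed(99)
    lamina:::ar1_series(2e4, phi, sdv)
  })
  x <- x[-(1:100)]  # discard transient from the zero start
  expect_equal(stats::var(x), sdv^2 / (1 - phi^2), tolerance = 0.05)
})

test_that("condition-gated shared latent plants the expected epoch correlation", {
  ## coupling c into amygdala and V1 under the fearful condition only;
  ## expected epoch correlation c^2 / (c^2 + noise_var)
  cpl <- 0.8; noise_sd <- 0.3; phi <- 0.3
  noise_var <- noise_sd^2 / (1 - phi^2)
  expected <- cpl^2 / (cpl^2 + noise_var)
  coupling <- matrix(0, 5, 3); coupling[1:2, 1] <- cpl
  r_hat <- vapply(1:100, function(seed) {
    d <- make_block_design("7T-BOLD", seed)
    cfg <- synth_config(seed = seed, protocol = "7T-BOLD",
                        evoked_amplitude = matrix(0, 5, 3),
                        coupling = coupling, noise_sd = noise_sd,
                        ar1_coef = phi)
    rs <- simulate_bold_runs(d, cfg)
    ep <- extract_condition_epochs(rs$data, d, "fearful")
    stats::cor(ep[, 1], ep[, 2])
  }, numeric(1))
  mc_se <- stats::sd(r_hat) / sqrt(length(r_hat))
  expect_lt(abs(mean(r_hat) - expected), 3 * mc_se + 0.02)
  ## and the planted contrast: fearful epochs correlate more than neutral
  expect_gt(mean(r_hat), 0.3)
})

test_that("ribbon construction assigns distinct bins to distinct tiers", {
  rb <- make_ribbon_and_eccentricity(c(6, 23, 3), 21)$ribbon
  ## thickness 21 with 21 bins: bijection tier -> bin
  bins_by_tier <- vapply(2:22, function(yy)
    unique(rb$depth_bin[, yy, ])[1], integer(1))
  expect_equal(sort(bins_by_tier), 0:20)
  ## boundaries excluded from gray matter
  expect_false(any(rb$gray_mask & (rb$wm_boundary | rb$csf_boundary)))
})

test_that("eccentricity map spans 0.5 to max_ecc monotonically", {
  out <- make_ribbon_and_eccentricity(c(12, 13, 3), 10, max_ecc = 88)
  ecc <- out$eccentricity$values
  expect_equal(max(ecc), 88)
  expect_equal(min(ecc), 0.5)
  expect_true(all(diff(ecc[, 1, 1]) > 0))
  expect_error(make_ribbon_and_eccentricity(c(6, 13, 3), 2), "thickness")
})

test_that("vaso pair generator honours its null and antiphase contracts", {
  rb <- make_ribbon_and_eccentricity(c(6, 12, 3), 10)$ribbon
  d <- make_block_design("7T-VASO", 5)
  ## no contamination, no layer effect, no noise: nulled == notnulled
  cfg0 <- synth_config(seed = 2, protocol = "7T-VASO", noise_sd = 0,
                       layer_effect = data.frame(lo = 0, hi = 1,
                                                 condition = "fearful",
                                                 amplitude = 0),
                       bold_contamination_amplitude = 0)
  p0 <- simulate_vaso_run(d, cfg0, rb)
  ## same planted content sampled at different times; compare via the
  ## ratio at shared support: both identically 1
  expect_equal(max(abs(p0$nulled$data - 1)), 0, tolerance = 1e-12)
  expect_equal(max(abs(p0$notnulled$data - 1)), 0, tolerance = 1e-12)

  ## planted CBV response: nulled ratio dips where the not-nulled
  ## contamination peaks (opposite response phase)
  cfg1 <- synth_config(seed = 2, protocol = "7T-VASO", noise_sd = 0,
                       layer_effect = data.frame(
                         lo = 0, hi = 1,
                         condition = c("fearful", "neutral", "happy"),
                         amplitude = 2),
                       bold_contamination_amplitude = 0.01)
  p1 <- simulate_vaso_run(d, cfg1, rb)
  ratio <- p1$nulled$data[, 1] / p1$notnulled$data[, 1]
  bold <- p1$notnulled$data[, 1]
  ## the ratio extremum is a minimum while the BOLD extremum is a maximum
  expect_lt(min(ratio), 1 - 0.01)
  expect_gt(max(bold), 1 + 0.005)
  expect_gt(stats::cor(1 - ratio, bold - 1), 0.8)
})
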