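test_that("interleaved splitting and re-interleaving are inverse operations", {
  d <- manual_design(c("fearful", "neutral"), 19.3, 9.65, 4.825)
  times <- cumsum(c(0, rep(c(2.088, 2.737), 5)))[1:10]
  dat <- matrix(seq_len(20), 10, 2)
  il <- run_series(dat, 2.4125, "interleaved", d, times)
  pair <- split_interleaved(il, nulled_first = TRUE)
  ## frames 0, 2, 4, 6, 8 (0-based) are blood-nulled
  expect_equal(pair$nulled$data[, 1], c(1, 3, 5, 7, 9))
  expect_equal(pair$notnulled$data[, 1], c(2, 4, 6, 8, 10))
  expect_equal(pair$effective_tr, 2.088 + 2.737)
  back <- interleave_pair(pair)
  expect_equal(back$data, il$data)
  expect_equal(back$times, il$times)
  ## error contracts
  expect_error(split_interleaved(run_series(dat[1:3, ], 1, "interleaved",
                                            d, times[1:3])), "even")
  expect_error(split_interleaved(run_series(dat[0, , drop = FALSE], 1,
                                            "interleaved", d, numeric(0))),
               "no frames")
})

test_that("alignment preserves constants, straight lines, and sinusoids", {
  d <- manual_design(rep("fearful", 5), 19.3, 9.65, 4.825)
  n <- 24L
  tn <- (seq_len(n) - 1) * 4.825
  tb <- tn + 2.088
  mk_pair <- function(f) {
    structure(list(
      nulled = run_series(cbind(f(tn)), 4.825, "nulled", d, tn),
      notnulled = run_series(cbind(f(tb)), 4.825, "not-nulled", d, tb),
      effective_tr = 4.825), class = "vaso_pair")
  }
  al_const <- align_and_trim(mk_pair(function(t) rep(2.5, length(t))))
  expect_equal(max(abs(al_const$nulled$data - 2.5)), 0, tolerance = 1e-12)
  al_lin <- align_and_trim(mk_pair(function(t) 0.3 * t - 1))
  expect_equal(al_lin$nulled$data[, 1], 0.3 * al_lin$nulled$times - 1,
               tolerance = 1e-10)
  expect_equal(al_lin$nulled$times, al_lin$notnulled$times)
  expect_equal(nrow(al_lin$nulled$data), nrow(al_lin$notnulled$data))
  ## sinusoid with >= 10 samples per cycle: amplitude error < 1%
  per <- 11 * 4.825
  f <- function(t) sin(2 * pi * t / per)
  al_sin <- align_and_trim(mk_pair(f))
  expect_lt(max(abs(al_sin$nulled$data[, 1] - f(al_sin$nulled$times))),
            0.01)
  short <- mk_pair(f)
  short$nulled$data <- short$nulled$data[1:5, , drop = FALSE]
  short$nulled$times <- short$nulled$times[1:5]
  expect_error(align_and_trim(short), "at least 8 frames")
})

test_that("BOLD correction recovers a planted CBV response algebraically", {
  ## v(t) nonzero only inside face blocks, b(t) an arbitrary positive
  ## contamination: the ratio must return exactly 100 * v percent change
  d <- manual_design(rep("fearful", 3), 20, 10, 2)
  n <- round(d$run_duration / d$tr)
  times <- (seq_len(n) - 1) * 2
  ev <- d$events
  inblock <- rep(FALSE, n)
  for (i in which(ev$condition == "fearful"))
    inblock <- inblock | (times >= ev$onset[i] &
                          times < ev$onset[i] + ev$duration[i])
  v <- cbind(ifelse(inblock, 0.02, 0))            # 2 percent CBV response
  b <- cbind(1 + 0.01 * sin(times / 7))           # 1 percent contamination
  pair <- analytic_pair(v, b, d, 2)
  vz <- bold_correct(pair)
  expect_equal(vz$data, 100 * v, tolerance = 1e-6, ignore_attr = TRUE)

  ## nulled == notnulled -> ratio 1, percent change 0
  pair0 <- analytic_pair(v * 0, b, d, 2)
  expect_lt(max(abs(bold_correct(pair0)$data)), 1e-10)

  ## contamination invariance: output does not depend on b at all
  b2 <- cbind(exp(0.008 * cos(times / 3)) * 1.5)
  expect_equal(bold_correct(analytic_pair(v, b2, d, 2))$data,
               vz$data, tolerance = 1e-9)

  ## division hazard rejected
  bad <- analytic_pair(v, b, d, 2)
  bad$notnulled$data[3, 1] <- 0
  expect_error(bold_correct(bad), "nonpositive")
})

test_that("planted CBV increases come out positive and antiphase to BOLD", {
  ## periodic single-condition design through the full simulate ->
  ## interleave -> split -> align -> correct chain
  rb <- make_ribbon_and_eccentricity(c(6, 12, 3), 10)$ribbon
  d <- make_block_design("7T-VASO", 11)
  cfg <- synth_config(seed = 4, protocol = "7T-VASO", noise_sd = 0,
                      layer_effect = data.frame(lo = 0, hi = 1,
                                                condition = c("fearful", "neutral", "happy"),
                                                amplitude = 2),
                      bold_contamination_amplitude = 0.01)
  pair <- simulate_vaso_run(d, cfg, rb)
  corrected <- bold_correct(align_and_trim(
    split_interleaved(interleave_pair(pair))))
  ## sign convention: planted CBV increase -> positive percent change,
  ## tracking the task time course
  expect_gt(max(corrected$data), 1.5)
  reg_c <- rowSums(sapply(c("fearful", "neutral", "happy"), function(cc)
    lamina:::convolved_regressor(d, cc, corrected$times)))
  expect_gt(stats::cor(corrected$data[, 1], reg_c), 0.8)
  ## antiphase: project both modalities on the task fundamental
  al <- align_and_trim(split_interleaved(interleave_pair(pair)))
  t_al <- al$notnulled$times
  reg <- rowSums(sapply(c("fearful", "neutral", "happy"), function(cc)
    lamina:::convolved_regressor(d, cc, t_al)))
  ## opposite response phase: correlation with the task regressor has
  ## opposite sign in the two modalities
  bold_r <- stats::cor(al$notnulled$data[, 1], reg)
  vaso_raw_r <- stats::cor(-al$nulled$data[, 1] / al$notnulled$data[, 1], reg)
  expect_gt(bold_r, 0.5)
  expect_gt(vaso_raw_r, 0.5)  # after the -1 flip, aligned with the task
  nulled_ratio_r <- stats::cor(al$nulled$data[, 1] / al$notnulled$data[, 1], reg)
  expect_lt(nulled_ratio_r, -0.5)  # raw ratio is antiphase to BOLD
})

test_that("vaso anatomy contrast follows its closed form and flags zero variance", {
  d <- manual_design("fearful", 20, 10, 2)
  mk <- function(vals) {
    m <- matrix(vals, ncol = length(vals) / 4, byrow = FALSE)
    structure(list(
      nulled = run_series(m[1:2, , drop = FALSE], 2, "nulled", d, c(0, 2)),
      notnulled = run_series(m[3:4, , drop = FALSE], 2, "not-nulled", d,
                             c(1, 3)),
      effective_tr = 2), class = "vaso_pair")
  }
  ## frames {1, 3, 1, 3}: population sd 1, mean 2 -> (1/sd)/mean = 0.5
  pair <- mk(c(1, 3, 1, 3))
  an <- vaso_anatomy(pair)
  expect_equal(as.numeric(an), 0.5)
  expect_equal(as.numeric(vaso_anatomy(pair, type = "mean-over-sd")), 2)
  ## all frames equal -> sentinel
  an0 <- vaso_anatomy(mk(c(2, 2, 2, 2)))
  expect_true(is.na(an0[1]))
  expect_equal(attr(an0, "flagged"), 1L)
})

test_that("tissue classes order correctly under the anatomy contrast", {
  ## 3-tissue phantom: gray has a large nulled/not-nulled difference,
  ## CSF a small difference with a high mean, WM intermediate-low mean
  d <- manual_design("fearful", 20, 10, 2)
  n <- 40
  set.seed(21)
  mk_tissue <- function(base, diff) {
    nulled <- matrix(base - diff / 2 + rnorm(n, 0, 0.001), n, 1)
    notnulled <- matrix(base + diff / 2 + rnorm(n, 0, 0.001), n, 1)
    list(nulled = nulled, notnulled = notnulled)
  }
  gm <- mk_tissue(1.0, 0.5); wm <- mk_tissue(0.8, 0.05); csf <- mk_tissue(1.6, 0.02)
  pair <- structure(list(
    nulled = run_series(cbind(gm$nulled, wm$nulled, csf$nulled), 2,
                        "nulled", d, (1:n - 1) * 2),
    notnulled = run_series(cbind(gm$notnulled, wm$notnulled, csf$notnulled),
                           2, "not-nulled", d, (1:n - 1) * 2 + 1),
    effective_tr = 2), class = "vaso_pair")
  an <- vaso_anatomy(pair)
  ## brute-force oracle per voxel
  oracle <- vapply(1:3, function(j) {
    x <- c(pair$nulled$data[, j], pair$notnulled$data[, j])
    (1 / sqrt(mean((x - mean(x))^2))) / mean(x)
  }, numeric(1))
  expect_equal(as.numeric(an), oracle, tolerance = 1e-12)
  ## gray (large difference) ranks below CSF (small difference, high mean)
  expect_lt(an[1], an[3])
})
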