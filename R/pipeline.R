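## End-to-end orchestration on synthetic data: simulate -> GLM ->
## {residual connectivity; VASO -> laminar} -> multilevel model ->
## eccentricity analysis, with tab-separated outputs and a JSON index.

#' Pipeline configuration
#'
#' Collects the problem sizes, module parameters and output location of
#' one end-to-end run. The defaults are deliberately compact (a small
#' cohort on small grids) so that a full run completes within minutes;
#' every size is a plain field that can be raised.
#'
#' @param seed Global seed; stages derive independent sub-seeds from it,
#'   so a stage can be re-run without reusing another stage's stream.
#' @param out_dir Output directory (created if missing).
#' @param n_subjects BOLD cohort size.
#' @param n_runs Runs per subject.
#' @param protocol BOLD protocol tag.
#' @param roi_names ROI labels; must include `amygdala`, `V1` and
#'   `neutral`-condition baselines are taken from the standard condition
#'   set.
#' @param n_vaso_subjects VASO cohort size.
#' @param ribbon_shape,ribbon_thickness Base grid of the simulated
#'   cortical slab.
#' @param upsample_factor In-plane upsampling before layering.
#' @param n_depth_bins Cortical depth bins (21 in the study convention).
#' @param n_ecc_voxels Voxels in the simulated V1 eccentricity strip.
#' @param ecc_edges Eccentricity bin edges (degrees).
#' @param bml_chains,bml_iterations MCMC settings for the multilevel fits.
#' @param synth Optional list of [synth_config()] overrides.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("lamina-"),
                            n_subjects = 8L, n_runs = 2L,
                            protocol = "7T-BOLD",
                            roi_names = c("amygdala", "V1", "V2", "V3", "hV4"),
                            n_vaso_subjects = 4L,
                            ribbon_shape = c(8L, 14L, 5L),
                            ribbon_thickness = 10L,
                            upsample_factor = 4L,
                            n_depth_bins = 21L,
                            n_ecc_voxels = 60L,
                            ecc_edges = c(0.5, 2, 2.5, 6, 20, 88),
                            bml_chains = 2L, bml_iterations = 400L,
                            synth = list()) {
  structure(as.list(environment()), class = "pipeline_config")
}

pipeline_synth_config <- function(cfg, seed, protocol = NULL) {
  args <- c(list(seed = seed, protocol = protocol %||% cfg$protocol,
                 roi_names = cfg$roi_names), cfg$synth)
  do.call(synth_config, args)
}

log_stage <- function(fmt, ...) message(sprintf(paste0("[lamina] ", fmt), ...))

#' Run the full analysis pipeline on synthetic data
#'
#' Executes, in order: (1) seeded simulation of a BOLD cohort; (2) GLM
#' and FIR deconvolution per subject/run; (3) residual inter-area
#' correlation matrices, valence contrasts and their tests; (4) the
#' Bayesian multilevel model on the per-ROI condition betas with
#' region-wise modulation-index posteriors; (5) a VASO cohort with
#' splitting, BOLD correction, in-plane upsampling, 21-depth layering,
#' depth profiles with spline smoothing and per-depth contrast
#' posteriors; (6) an eccentricity-resolved analysis with binning and
#' per-bin contrast posteriors. All tables are written to
#' `config$out_dir` together with a machine-readable JSON index.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of the report tables and output paths.
#' @export
run_end_to_end <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  save_tsv <- function(df, name) {
    p <- file.path(config$out_dir, name)
    write_tsv(df, p)
    paths[[name]] <<- p
    p
  }
  report <- list()

  ## ---- stage 1+2: BOLD cohort, GLM, residuals, betas -----------------
  log_stage("simulating %d subjects x %d runs (%s)",
            config$n_subjects, config$n_runs, config$protocol)
  subj_resid <- list(); subj_designs <- list()
  beta_rows <- list()
  for (s in seq_len(config$n_subjects)) {
    resid_runs <- list(); designs <- list(); betas_acc <- NULL
    for (r in seq_len(config$n_runs)) {
      run_seed <- derive_seed(config$seed, 100L * s + r)
      scfg <- pipeline_synth_config(config, run_seed)
      design <- make_block_design(config$protocol, run_seed)
      series <- simulate_bold_runs(design, scfg)
      dec <- deconvolve_evoked(series, design)
      resid_runs[[r]] <- dec$fit$residual
      designs[[r]] <- design
      X <- build_design_matrix(design, nrow(series$data), design$tr,
                               basis = "canonical-hrf")
      fit <- fit_glm(series, X)
      bc <- fit$betas[FACE_CONDITIONS, , drop = FALSE]
      betas_acc <- if (is.null(betas_acc)) bc else betas_acc + bc
    }
    subj_resid[[s]] <- resid_runs
    subj_designs[[s]] <- designs
    betas <- betas_acc / config$n_runs
    beta_rows[[s]] <- data.frame(
      condition = rep(rownames(betas), times = ncol(betas)),
      region = rep(colnames(betas), each = nrow(betas)),
      subject = sprintf("s%02d", s),
      y = as.vector(betas), stringsAsFactors = FALSE)
  }
  beta_tab <- do.call(rbind, beta_rows)
  save_tsv(beta_tab, "roi_condition_betas.tsv")

  ## ---- stage 3: residual inter-area correlation ----------------------
  log_stage("residual inter-area correlation analysis")
  subj_mats <- lapply(seq_len(config$n_subjects), function(s) {
    epochs <- lapply(stats::setNames(FACE_CONDITIONS, FACE_CONDITIONS),
                     function(cond) extract_condition_epochs(
                       subj_resid[[s]], subj_designs[[s]], cond))
    correlation_matrices(epochs)
  })
  conn <- list()
  for (cond in FACE_CONDITIONS) {
    mats <- lapply(subj_mats, function(m) m$r[[cond]])
    conn[[cond]] <- average_corr_matrices(mats)
    save_tsv(as.data.frame(conn[[cond]]),
             sprintf("corr_%s.tsv", cond))
  }
  contrast_tests <- list()
  for (ctr in names(subj_mats[[1]]$contrast)) {
    mats <- lapply(subj_mats, function(m) m$contrast[[ctr]])
    tab <- correlation_cell_tests(mats, type = "contrast")
    tab$contrast <- ctr
    contrast_tests[[ctr]] <- tab
    save_tsv(tab, sprintf("corr_contrast_tests_%s.tsv", ctr))
  }
  report$correlation <- conn
  report$correlation_tests <- contrast_tests

  ## ---- stage 4: multilevel model on ROI betas ------------------------
  log_stage("Bayesian multilevel model on ROI betas")
  bdat <- bml_data(beta_tab$condition, beta_tab$region, beta_tab$subject,
                   beta_tab$y)
  fit_roi <- fit_bml(bdat, chains = config$bml_chains,
                     iterations = config$bml_iterations,
                     seed = derive_seed(config$seed, 41L))
  vit <- valence_index_table(fit_roi, "fearful", "neutral")
  vit$index <- "fearful-neutral"
  vit2 <- valence_index_table(fit_roi, "happy", "neutral")
  vit2$index <- "happy-neutral"
  report$valence_index <- rbind(vit, vit2)
  save_tsv(report$valence_index, "roi_valence_index.tsv")

  ## ---- stage 5: VASO + laminar ---------------------------------------
  log_stage("VASO cohort (%d subjects) and laminar profiles",
            config$n_vaso_subjects)
  rib0 <- make_ribbon_and_eccentricity(
    shape = c(config$ribbon_shape[1],
              config$ribbon_thickness + 2L,
              config$ribbon_shape[3]),
    thickness = config$ribbon_thickness,
    n_depth_bins = config$n_depth_bins)$ribbon
  wm_up <- upsample_inplane(rib0$wm_boundary, config$upsample_factor)
  csf_up <- upsample_inplane(rib0$csf_boundary, config$upsample_factor)
  rib_up <- grow_depths(wm_up, csf_up, K = config$n_depth_bins)
  depth_rows <- list(); prof_acc <- NULL
  for (s in seq_len(config$n_vaso_subjects)) {
    vseed <- derive_seed(config$seed, 500L + s)
    vcfg <- pipeline_synth_config(config, vseed, protocol = "7T-VASO")
    vdesign <- make_block_design("7T-VASO", vseed)
    pair <- simulate_vaso_run(vdesign, vcfg, rib0)
    corrected <- bold_correct(align_and_trim(
      split_interleaved(interleave_pair(pair),
                        nulled_first = vcfg$nulled_first)))
    ## canonical design evaluated on the corrected series' timebase
    n_frames <- nrow(corrected$data)
    Xm_t <- cbind(
      vapply(FACE_CONDITIONS, function(cond)
        convolved_regressor(vdesign, cond, corrected$times),
        numeric(n_frames)),
      constant = rep(1, n_frames),
      drift = seq(-0.5, 0.5, length.out = n_frames))
    fit <- fit_glm(corrected$data, Xm_t)
    d <- dim(rib0$gray_mask)
    vol_of <- function(vals) {
      a <- array(0, d); a[pair$voxels] <- vals
      upsample_inplane(a, config$upsample_factor, method = "nearest")
    }
    r2_up <- vol_of(fit$r2)
    for (cond in FACE_CONDITIONS) {
      beta_up <- vol_of(fit$betas[cond, ])
      prof <- extract_depth_profile(beta_up, r2_up, rib_up)
      depth_rows[[length(depth_rows) + 1L]] <- data.frame(
        condition = cond, region = sprintf("bin%02d", prof$bin),
        subject = sprintf("v%02d", s), y = prof$mean,
        stringsAsFactors = FALSE)
      if (cond == "fearful") {
        pooled <- extract_depth_profile(
          vol_of(colMeans(fit$betas[FACE_CONDITIONS, , drop = FALSE])),
          r2_up, rib_up)
        prof_acc <- if (is.null(prof_acc)) pooled else {
          pooled$mean <- pooled$mean + prof_acc$mean
          pooled$se <- sqrt(pooled$se^2 + prof_acc$se^2)
          pooled
        }
      }
    }
  }
  prof_acc$mean <- prof_acc$mean / config$n_vaso_subjects
  prof_acc$se <- prof_acc$se / config$n_vaso_subjects
  report$depth_profile <- smooth_profile(prof_acc)
  save_tsv(as.data.frame(report$depth_profile), "vaso_depth_profile.tsv")
  depth_tab <- do.call(rbind, depth_rows)
  fit_depth <- fit_bml(bml_data(depth_tab$condition, depth_tab$region,
                                depth_tab$subject, depth_tab$y),
                       chains = config$bml_chains,
                       iterations = config$bml_iterations,
                       seed = derive_seed(config$seed, 42L))
  dtab <- contrast_table(fit_depth, "fearful", "neutral")
  dtab$contrast <- "fearful-neutral"
  dtab2 <- contrast_table(fit_depth, "happy", "neutral")
  dtab2$contrast <- "happy-neutral"
  report$depth_contrast <- rbind(dtab, dtab2)
  save_tsv(report$depth_contrast, "vaso_depth_contrast.tsv")

  ## ---- stage 6: eccentricity-resolved valence effect -----------------
  log_stage("eccentricity-binned analysis")
  ecc_tab <- simulate_eccentricity_betas(config)
  fit_ecc <- fit_bml(bml_data(ecc_tab$condition, ecc_tab$region,
                              ecc_tab$subject, ecc_tab$y),
                     chains = config$bml_chains,
                     iterations = config$bml_iterations,
                     seed = derive_seed(config$seed, 43L))
  etab <- contrast_table(fit_ecc, "fearful", "neutral")
  etab$contrast <- "fearful-neutral"
  report$eccentricity_contrast <- etab
  save_tsv(etab, "eccentricity_contrast.tsv")

  ## ---- index ---------------------------------------------------------
  index <- list(seed = config$seed,
                protocol = config$protocol,
                sizes = list(n_subjects = config$n_subjects,
                             n_runs = config$n_runs,
                             n_vaso_subjects = config$n_vaso_subjects,
                             n_depth_bins = config$n_depth_bins),
                outputs = as.list(paths))
  idx_path <- file.path(config$out_dir, "index.json")
  jsonlite::write_json(index, idx_path, auto_unbox = TRUE, pretty = TRUE)
  report$paths <- c(paths, index = idx_path)
  log_stage("done; %d output files in %s", length(report$paths),
            config$out_dir)
  invisible(report)
}

## Simulated V1 eccentricity strip: stimulus-driven "half-Mexican-hat"
## response (positive at the stimulus representation, negative penumbra,
## baseline beyond) plus an additive, eccentricity-flat valence increment
## for expressive faces; per-voxel GLM betas binned by eccentricity.
simulate_eccentricity_betas <- function(config) {
  n_vox <- config$n_ecc_voxels
  ecc <- exp(seq(log(0.5), log(88), length.out = n_vox))
  stim <- ifelse(ecc <= 2, 1, ifelse(ecc <= 6, -0.4, 0))
  valence_inc <- c(fearful = 0.25, neutral = 0, happy = 0.12)
  rows <- list()
  for (s in seq_len(config$n_subjects)) {
    seed <- derive_seed(config$seed, 700L + s)
    design <- make_block_design(config$protocol, seed)
    n <- round(design$run_duration / design$tr)
    times <- (seq_len(n) - 1) * design$tr
    evoked <- matrix(0, n, n_vox)
    for (cond in FACE_CONDITIONS) {
      reg <- convolved_regressor(design, cond, times)
      amp <- stim + valence_inc[[cond]]   # additive, flat across ecc
      evoked <- evoked + outer(reg, amp)
    }
    scfg <- pipeline_synth_config(config, seed)
    y <- evoked + with_seed(seed, matrix(
      stats::rnorm(n * n_vox, 0, scfg$noise_sd), n, n_vox))
    X <- build_design_matrix(design, n, design$tr, basis = "canonical-hrf")
    fit <- fit_glm(y, X)
    bins <- bin_by_eccentricity(array(ecc, c(n_vox, 1, 1)),
                                edges = config$ecc_edges)
    for (cond in FACE_CONDITIONS[FACE_CONDITIONS != "happy"]) {
      for (bi in seq_along(bins$masks)) {
        sel <- as.vector(bins$masks[[bi]])
        rows[[length(rows) + 1L]] <- data.frame(
          condition = cond, region = sprintf("ecc%d", bi),
          subject = sprintf("s%02d", s),
          y = mean(fit$betas[cond, sel]), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
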