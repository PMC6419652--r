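#' Default run configuration
#'
#' The study conditions for a synthetic cohort run: 4.07 mm voxels, 3.0 mm
#' PSF, a single hot lesion per subject on a warm background, cranio-caudal
#' Lujan-type motion of 15 mm over a 120 s acquisition (300 frames at 0.4 s),
#' a 35% duty cycle, the 40% SUVmax isocontour and 255-bin discretization.
#' Survival times follow an exponential baseline (lambda0 per week, median
#' around 46 weeks at HR 1) with a planted log hazard ratio on gated SUVmean
#' and 20% uniform censoring.
#'
#' @return Nested config list.
#' @export
default_config <- function() {
  list(
    phantom = list(
      grid_shape = c(28L, 28L, 36L),
      voxel_spacing_mm = c(4.07, 4.07, 4.07),
      background_suv = 1.0,
      lesion_radius_mm = c(12, 18),    # per-subject uniform range
      lesion_peak_suv_meanlog = log(8),
      lesion_peak_suv_sdlog = 0.25,
      heterogeneous = TRUE,            # uptake foci + necrotic core
      n_foci = 2L,
      focus_excess_suv = c(0.25, 0.6), # fraction of the main peak
      necrotic_core = TRUE,
      psf_fwhm_mm = 3.0,
      noise_scale = 10),
    motion = list(
      period_s = 4.0,
      amplitude_mm = 15,
      exponent_n = 2L,
      duration_s = 120,
      dt_s = 0.4,
      drift_mm_per_min = 0,
      jitter_frac = 0.05),
    duty = 0.35,
    isocontour_fraction = 0.40,
    n_bins = 255L,
    cohort = list(
      n_subjects = 50L,
      planted_effects = list(SUVmean = 0.5),
      lambda0 = 0.015,
      censor_frac = 0.2),
    seed = 1L)
}

# Counter-based seed fan-out: subject/stream substreams of one global seed,
# independent of cohort order. Kept below 2^31 - 1.
derive_seed <- function(seed, subject, stream = 0L) {
  as.integer((as.numeric(seed) * 48271 + subject * 100003 + stream * 7919) %%
               2147483629 + 1)
}

#' Simulate one synthetic subject through the full imaging chain
#'
#' Draws subject-level lesion size and peak uptake, renders the phantom,
#' simulates the respiratory-motion frame stack, forms the ungated (all
#' frames) and gated (optimal window at the configured duty cycle) images,
#' delineates the isocontour VOI on each, and extracts the 35-feature vector
#' from both reconstructions.
#'
#' @param config a config list (see \code{\link{default_config}}).
#' @param subject_seed integer seed for this subject's substreams.
#' @return List: \code{features_nonORG}, \code{features_ORG} (named length-35
#'   vectors), \code{window} (the resolved \code{gating_window}), \code{spec}.
#' @export
simulate_subject <- function(config, subject_seed) {
  ph <- config$phantom
  set.seed(subject_seed)
  radius <- stats::runif(1, ph$lesion_radius_mm[1], ph$lesion_radius_mm[2])
  peak <- max(exp(stats::rnorm(1, ph$lesion_peak_suv_meanlog,
                               ph$lesion_peak_suv_sdlog)),
              ph$background_suv + 2)
  dims <- ph$grid_shape
  sp <- ph$voxel_spacing_mm
  extent <- (dims - 1) * sp
  center <- c(extent[1] / 2, extent[2] / 2, 45)
  centers <- list(center)
  radii <- radius
  peaks <- peak
  if (isTRUE(ph$heterogeneous)) {
    # Intratumoral heterogeneity: a few hot foci superposed inside the main
    # lesion, at random positions within 0.4 r of the centre.
    for (f in seq_len(ph$n_foci)) {
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      off <- u * stats::runif(1, 0.15, 0.4) * radius
      excess <- stats::runif(1, ph$focus_excess_suv[1],
                             ph$focus_excess_suv[2]) * (peak - ph$background_suv)
      centers <- c(centers, list(center + off))
      radii <- c(radii, 0.45 * radius)
      peaks <- c(peaks, ph$background_suv + excess)
    }
  }
  core <- NULL
  if (isTRUE(ph$necrotic_core)) {
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    core <- list(center_mm = center + u * 0.35 * radius,
                 radius_mm = 0.3 * radius,
                 suv = ph$background_suv)
  }
  spec <- phantom_spec(grid_shape = dims, voxel_spacing_mm = sp,
                       background_suv = ph$background_suv,
                       lesion_centers_mm = centers,
                       lesion_radii_mm = radii,
                       lesion_peak_suv = peaks,
                       necrotic_core = core,
                       psf_fwhm_mm = ph$psf_fwhm_mm,
                       noise_scale = ph$noise_scale,
                       seed = subject_seed)
  truth <- make_phantom(spec)
  mo <- config$motion
  # Matched count statistics: the ungated reference image uses duration_s of
  # data; the gated image retains a duty-cycle fraction of a proportionally
  # longer acquisition, so both average the same amount of data.
  acq_s <- mo$duration_s / config$duty
  trace <- lujan_waveform(mo$period_s, mo$amplitude_mm, mo$exponent_n,
                          acq_s, mo$dt_s, mo$drift_mm_per_min,
                          mo$jitter_frac, seed = derive_seed(subject_seed, 1))
  stack <- simulate_acquisition(truth, trace, motion_axis = 3L,
                                noise_scale = ph$noise_scale,
                                seed = derive_seed(subject_seed, 2))
  ungated <- sum_frames(stack, which(trace$times_s < mo$duration_s))
  gated <- gated_image(stack, config$duty)
  seed_region <- lesion_seed_region(spec, margin_vox = 2L,
                                    motion_extra_mm = max(trace$amplitudes_mm))
  voi_u <- isocontour_voi(ungated, seed_region, config$isocontour_fraction)
  voi_g <- isocontour_voi(gated, seed_region, config$isocontour_fraction)
  list(features_nonORG = extract_all(ungated, voi_u, config$n_bins),
       features_ORG = extract_all(gated, voi_g, config$n_bins),
       window = attr(gated, "window"),
       spec = spec)
}

#' Run the full synthetic-cohort pipeline
#'
#' For each subject: phantom, frame simulation, ungated and gated image
#' formation, isocontour VOIs, 35-feature extraction; then the statistical
#' layer: paired Wilcoxon comparison per feature, survival simulation with
#' the configured planted effects on the gated features, and the per-feature
#' Cox/cutoff table. Fully deterministic for a fixed seed.
#'
#' @param config config list (see \code{\link{default_config}}); the seed
#'   inside it drives every substream.
#' @param output_dir optional directory; when given, writes features.csv,
#'   survival.csv, wilcoxon.csv, table2.csv, cutoffs.csv, windows.csv and a
#'   manifest.yaml recording the resolved config.
#' @return List: \code{features} (tidy data.frame, one row per subject x
#'   reconstruction), \code{survival}, \code{wilcoxon}, \code{table2} (list
#'   cox/cutoffs), \code{windows} (per-subject gating windows).
#' @export
run_pipeline <- function(config = default_config(), output_dir = NULL) {
  n <- config$cohort$n_subjects
  if (n < 1) stop("cohort must have at least 1 subject")
  feat_rows <- vector("list", 2 * n)
  win_rows <- vector("list", n)
  for (i in seq_len(n)) {
    subj <- tryCatch(
      simulate_subject(config, derive_seed(config$seed, i)),
      error = function(e)
        stop("pipeline failed at stage 'simulate_subject' for subject ", i,
             ": ", conditionMessage(e)))
    for (rc in c("nonORG", "ORG")) {
      fv <- if (rc == "ORG") subj$features_ORG else subj$features_nonORG
      row <- data.frame(subject_id = i, reconstruction = rc,
                        check.names = FALSE)
      row[names(fv)] <- as.list(unname(fv))
      feat_rows[[(i - 1) * 2 + (rc == "ORG") + 1]] <- row
    }
    w <- subj$window
    win_rows[[i]] <- data.frame(subject_id = i, lower_L_mm = w$lower_L_mm,
                                upper_U_mm = w$upper_U_mm,
                                width_W_mm = w$width_W_mm,
                                achieved_duty = w$achieved_duty)
  }
  features <- do.call(rbind, feat_rows)
  windows <- do.call(rbind, win_rows)

  # Paired comparison per feature (needs >= 6 subjects).
  wilcoxon <- NULL
  fnames <- table2_feature_names()
  if (n >= 6) {
    non <- features[features$reconstruction == "nonORG", ]
    org <- features[features$reconstruction == "ORG", ]
    wil_rows <- lapply(fnames, function(f) {
      wt <- wilcoxon_paired(non[[f]], org[[f]])
      data.frame(feature = f, statistic = wt$statistic, p = wt$p,
                 median_nonORG = stats::median(non[[f]]),
                 median_ORG = stats::median(org[[f]]),
                 flagged = wt$flagged)
    })
    wilcoxon <- do.call(rbind, wil_rows)
  }

  # Survival generated from the gated features named in planted_effects.
  survival_tab <- NULL; table2 <- NULL
  pe <- config$cohort$planted_effects
  if (n >= 2 && length(pe) > 0) {
    org <- features[features$reconstruction == "ORG", ]
    X <- sapply(names(pe), function(f) {
      sc <- standard_scale(org[[f]])
      if (isTRUE(attr(sc, "flagged"))) rep(0, n) else as.numeric(sc)
    })
    X <- matrix(X, nrow = n)
    survival_tab <- simulate_survival(X, unlist(pe),
                                      lambda0 = config$cohort$lambda0,
                                      censor_frac = config$cohort$censor_frac,
                                      seed = derive_seed(config$seed, 0, 3))
    if (n >= 6 && sum(survival_tab$event) >= 2)
      table2 <- table2_analysis(features, survival_tab,
                                cutoffs = n >= 20)
  }

  out <- list(features = features, survival = survival_tab,
              wilcoxon = wilcoxon, table2 = table2, windows = windows,
              config = config)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_table(features, file.path(output_dir, "features.csv"))
    write_table(windows, file.path(output_dir, "windows.csv"))
    if (!is.null(survival_tab))
      write_table(survival_tab, file.path(output_dir, "survival.csv"))
    if (!is.null(wilcoxon))
      write_table(wilcoxon, file.path(output_dir, "wilcoxon.csv"))
    if (!is.null(table2)) {
      write_table(table2$cox, file.path(output_dir, "table2.csv"))
      if (!is.null(table2$cutoffs))
        write_table(table2$cutoffs, file.path(output_dir, "cutoffs.csv"))
    }
    write_config(config, file.path(output_dir, "manifest.yaml"))
  }
  out
}
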