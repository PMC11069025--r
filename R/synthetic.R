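# Synthetic task-fMRI cohort generator: planted spatial networks,
# covariate-moderated activation, condition-modulated seed-voxel coupling,
# AR(1) + drift + thermal noise, and the on-disk BIDS-like layout.

#' Specify a synthetic odor-identification cohort
#'
#' Defaults mirror the acquisition and task this package models: two runs,
#' TR 2 s, eight odorants presented four times per run in 16-s
#' presentation/choice events with a 16-s baseline block after each set of
#' eight, covariates on the instruments' scales (odor-identification score
#' 0-8, mean odor familiarity 1-10, ApoE e4 carrier status 0/1), and a
#' logistic in-scanner hit-probability model in the identification score so
#' that identification ability and accuracy correlate.
#'
#' @param n_subjects number of subjects (default 36).
#' @param grid spatial grid dims, >= 12 voxels per axis (default 15x15x12).
#' @param n_runs runs per subject (default 2).
#' @param tr_s repetition time (default 2 s).
#' @param event_s stimulation + choice event duration (default 16 s).
#' @param n_odorants odorants per set (default 8).
#' @param reps_per_run presentations of each odorant per run (default 4).
#' @param baseline_s baseline block after each odorant set (default 16 s).
#' @param n_frames frames per run; defaults to exactly the schedule length.
#' @param apoe_frac ApoE e4 carrier fraction (default 16/36).
#' @param hit_intercept,hit_slope logistic hit-probability model
#'   `plogis(hit_intercept + hit_slope * (sdoit - 4))`.
#' @param ar1_phi,drift_sd,thermal_sd noise model: AR(1) coefficient,
#'   per-voxel linear drift amplitude SD, thermal (innovation) SD.
#' @param intrinsic_sd SD of each component's intrinsic (non-task) AR(1)
#'   time-course activity. Real network time courses fluctuate outside task
#'   events; this also keeps the gPPI design nonsingular (a purely
#'   task-locked seed would lie in the span of the hit/miss regressors).
#' @param spike_prob per-frame probability of a planted motion spike.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 36, grid = c(15, 15, 12), n_runs = 2,
                        tr_s = 2, event_s = 16, n_odorants = 8,
                        reps_per_run = 4, baseline_s = 16, n_frames = NULL,
                        apoe_frac = 16 / 36, hit_intercept = 0,
                        hit_slope = 0.35, ar1_phi = 0.3, drift_sd = 0.5,
                        thermal_sd = 1, intrinsic_sd = 1, spike_prob = 0.02) {
  schedule_s <- reps_per_run * (n_odorants * event_s + baseline_s)
  required <- ceiling(schedule_s / tr_s)
  if (is.null(n_frames)) n_frames <- required
  if (n_frames * tr_s < schedule_s)
    stop("run length insufficient for schedule: need ", required,
         " frames at TR ", tr_s, " s, got ", n_frames)
  stopifnot(n_subjects >= 1, length(grid) == 3, n_runs >= 1, tr_s > 0,
            apoe_frac >= 0, apoe_frac <= 1)
  structure(list(n_subjects = n_subjects, grid = as.integer(grid),
                 n_runs = n_runs, tr_s = tr_s, event_s = event_s,
                 n_odorants = n_odorants, reps_per_run = reps_per_run,
                 baseline_s = baseline_s, n_frames = as.integer(n_frames),
                 apoe_frac = apoe_frac, hit_intercept = hit_intercept,
                 hit_slope = hit_slope, ar1_phi = ar1_phi, drift_sd = drift_sd,
                 thermal_sd = thermal_sd, intrinsic_sd = intrinsic_sd,
                 spike_prob = spike_prob),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(paste0("<cohort_spec> %d subjects, grid %s, %d run(s) x %d frames",
                     " (TR %g s), %d odorants x %d reps\n"),
              x$n_subjects, paste(x$grid, collapse = "x"), x$n_runs, x$n_frames,
              x$tr_s, x$n_odorants, x$reps_per_run))
  invisible(x)
}

#' Plant spatially quasi-uncorrelated network maps
#'
#' Each map is a sum of 1-3 Gaussian blobs, standardized to zero mean and
#' unit SD over the grid. Maps are accepted only if their pairwise absolute
#' spatial correlation with all previously accepted maps is below 0.2
#' (rejection sampling), which keeps the planted sources identifiable.
#'
#' @param grid 3-vector of grid dims, each >= 12.
#' @param n_components number of maps (>= 2).
#' @param seed RNG seed; output is deterministic given the seed.
#' @param max_r pairwise absolute-correlation bound (default 0.2).
#' @param margin blob centers stay `margin` voxels away from the x = 1 face,
#'   which the generator reserves as the CSF-like noise slab.
#' @return array (x, y, z, n_components).
#' @export
plant_spatial_maps <- function(grid, n_components, seed, max_r = 0.2,
                               margin = 3) {
  ax <- c("x", "y", "z")
  small <- which(grid < 12)
  if (length(small))
    stop("grid too small to place non-overlapping blobs on axis ",
         paste(ax[small], collapse = ", "), " (need >= 12 voxels)")
  stopifnot(n_components >= 2)
  set.seed(seed)
  co <- expand.grid(x = seq_len(grid[1]), y = seq_len(grid[2]),
                    z = seq_len(grid[3]))
  maps <- array(0, c(grid, n_components))
  flat <- matrix(0, prod(grid), n_components)
  for (c_i in seq_len(n_components)) {
    for (try in seq_len(500)) {
      nb <- sample(1:3, 1)
      m <- numeric(prod(grid))
      for (b in seq_len(nb)) {
        ctr <- c(stats::runif(1, margin, grid[1] - 1),
                 stats::runif(1, 2, grid[2] - 1),
                 stats::runif(1, 2, grid[3] - 1))
        sd_b <- stats::runif(1, 1.2, 2.2)
        m <- m + exp(-((co$x - ctr[1])^2 + (co$y - ctr[2])^2 +
                         (co$z - ctr[3])^2) / (2 * sd_b^2))
      }
      m <- (m - mean(m)) / stats::sd(m)
      ok <- c_i == 1 ||
        max(abs(stats::cor(m, flat[, seq_len(c_i - 1), drop = FALSE]))) < max_r
      if (ok) { flat[, c_i] <- m; break }
      if (try == 500)
        stop("could not place component ", c_i,
             " with pairwise |r| < ", max_r)
    }
    maps[, , , c_i] <- flat[, c_i]
  }
  maps
}

#' Schedule one run of odor-identification events
#'
#' Per run: `reps_per_run` blocks, each with the `n_odorants` odorants in
#' random order as 16-s stimulation/choice events followed by a 16-s baseline
#' block. Each stimulation event is labeled hit or miss by an independent
#' Bernoulli(`subject_accuracy`) draw (drawn first in the RNG stream, so the
#' labels can be replayed from the seed).
#'
#' @param spec a [cohort_spec].
#' @param subject_accuracy hit probability in `[0, 1]`.
#' @param seed RNG seed.
#' @return event table data.frame: `onset`, `duration`, `trial_type`
#'   (stim/baseline), `odorant`, `outcome`.
#' @export
schedule_events <- function(spec, subject_accuracy, seed) {
  stopifnot(inherits(spec, "cohort_spec"),
            subject_accuracy >= 0, subject_accuracy <= 1)
  n_stim <- spec$n_odorants * spec$reps_per_run
  schedule_s <- spec$reps_per_run * (spec$n_odorants * spec$event_s + spec$baseline_s)
  if (spec$n_frames * spec$tr_s < schedule_s)
    stop("run length insufficient for schedule: need ",
         ceiling(schedule_s / spec$tr_s), " frames")
  set.seed(seed)
  hits <- stats::runif(n_stim) < subject_accuracy
  rows <- vector("list", n_stim + spec$reps_per_run)
  onset <- 0; i <- 1L; k <- 1L
  for (rep_i in seq_len(spec$reps_per_run)) {
    for (od in sample(spec$n_odorants)) {
      rows[[i]] <- data.frame(onset = onset, duration = spec$event_s,
                              trial_type = "stim", odorant = od,
                              outcome = if (hits[k]) "hit" else "miss")
      onset <- onset + spec$event_s; i <- i + 1L; k <- k + 1L
    }
    rows[[i]] <- data.frame(onset = onset, duration = spec$baseline_s,
                            trial_type = "baseline", odorant = NA_integer_,
                            outcome = NA_character_)
    onset <- onset + spec$baseline_s; i <- i + 1L
  }
  do.call(rbind, rows)
}

#' Simulate head-motion parameters
#'
#' Six mean-reverting bounded random walks (3 translations mm, 3 rotations
#' rad) whose frame-to-frame changes stay well below 1 mm FD; with
#' probability `spike_prob` a frame receives an additional translation jump
#' > 1 mm so that framewise-displacement spikes exist in fixtures.
#'
#' @param n_frames frames (>= 2).
#' @param spike_prob per-frame spike probability.
#' @param seed RNG seed.
#' @return n_frames x 6 matrix with columns `trans_x`...`rot_z`; planted
#'   spike frames in attribute `"spikes"`.
#' @export
simulate_motion <- function(n_frames, spike_prob, seed) {
  stopifnot(n_frames >= 2, spike_prob >= 0, spike_prob <= 1)
  set.seed(seed)
  spike_u <- stats::runif(n_frames)
  steps <- cbind(matrix(stats::rnorm(n_frames * 3, 0, 0.02), n_frames, 3),
                 matrix(stats::rnorm(n_frames * 3, 0, 4e-4), n_frames, 3))
  steps[, 1:3] <- pmin(pmax(steps[, 1:3], -0.08), 0.08)
  steps[, 4:6] <- pmin(pmax(steps[, 4:6], -1.6e-3), 1.6e-3)
  m <- matrix(0, n_frames, 6)
  for (t in 2:n_frames) m[t, ] <- 0.95 * m[t - 1, ] + steps[t, ]
  spikes <- which(spike_u < spike_prob)
  for (t in spikes)
    m[t, 1] <- m[t, 1] + (1.2 + 0.6 * spike_u[t] / max(spike_prob, 1e-12)) *
      sign(stats::rnorm(1))
  colnames(m) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  attr(m, "spikes") <- spikes
  m
}

#' Simulate one subject's BOLD runs
#'
#' The noiseless mean field is `sum_c map_c x timecourse_c + drift`, where
#' each component time course is the HRF-convolved hit/miss regressors scaled
#' by that subject's planted amplitudes. During hit events the seed
#' component's centered time course multiplied by the centered hit regressor
#' is added into the target voxel set with the subject's coupling gain (the
#' signal a psychophysiological-interaction GLM measures). Noise is AR(1)
#' with Gaussian innovations; with `thermal_sd = 0` the output equals the
#' deterministic mean field exactly.
#'
#' @param spec a [cohort_spec].
#' @param ground_truth ground-truth list (see [generate_cohort]); uses
#'   `planted_maps`, `tmfc$seed_component`, `tmfc$target_voxels`.
#' @param events_list list of per-run event tables.
#' @param amplitudes C x 2 matrix (columns hit, miss) for this subject.
#' @param tmfc_gain this subject's hit-specific coupling gain.
#' @param seed RNG seed.
#' @return list of [bold4d], one per run. Analysis mask excludes the x = 1
#'   noise slab; attribute `"noise_mask"` on each element holds the CSF-like
#'   slab used for aCompCor.
#' @export
simulate_subject_bold <- function(spec, ground_truth, events_list, amplitudes,
                                  tmfc_gain, seed) {
  maps <- ground_truth$planted_maps
  grid <- dim(maps)[1:3]
  if (!identical(as.integer(grid), spec$grid))
    stop("planted map grid (", paste(grid, collapse = "x"),
         ") does not match spec grid (", paste(spec$grid, collapse = "x"), ")")
  C <- dim(maps)[4]
  stopifnot(nrow(amplitudes) == C, ncol(amplitudes) == 2)
  V <- prod(grid)
  M <- matrix(maps, V, C)
  hrf <- canonical_hrf(10, spec$tr_s)
  mask <- array(TRUE, grid); mask[1, , ] <- FALSE
  noise_mask <- array(FALSE, grid); noise_mask[1, , ] <- TRUE
  affine <- diag(c(3, 3, 3, 1))
  set.seed(seed)
  out <- vector("list", length(events_list))
  for (r in seq_along(events_list)) {
    ev <- events_list[[r]]
    hit <- build_condition_regressor(ev, "hit", spec$n_frames, spec$tr_s, hrf)
    miss <- build_condition_regressor(ev, "miss", spec$n_frames, spec$tr_s, hrf)
    tc <- outer(hit, amplitudes[, 1]) + outer(miss, amplitudes[, 2])  # T x C
    if (spec$intrinsic_sd > 0) {
      icomp <- ground_truth$intrinsic_components %||% seq_len(C)
      intr <- apply_ar1(matrix(stats::rnorm(spec$n_frames * length(icomp), 0,
                                            spec$intrinsic_sd),
                               spec$n_frames, length(icomp)), spec$ar1_phi)
      tc[, icomp] <- tc[, icomp] + intr
    }
    y <- tc %*% t(M)                                                 # T x V
    tv <- ground_truth$tmfc$target_voxels
    if (length(tv) && tmfc_gain != 0) {
      seed_tc <- tc[, ground_truth$tmfc$seed_component]
      ppi <- (seed_tc - mean(seed_tc)) * (hit - mean(hit))
      y[, tv] <- y[, tv] + tmfc_gain * ppi
    }
    if (spec$drift_sd > 0) {
      slope <- stats::rnorm(V, 0, spec$drift_sd)
      tt <- seq_len(spec$n_frames)
      y <- y + outer((tt - mean(tt)) / spec$n_frames, slope)
    }
    if (spec$thermal_sd > 0) {
      eps <- matrix(stats::rnorm(spec$n_frames * V, 0, spec$thermal_sd),
                    spec$n_frames, V)
      y <- y + apply_ar1(eps, spec$ar1_phi)
    }
    out[[r]] <- bold4d(array(t(y), c(grid, spec$n_frames)), affine = affine,
                       tr_s = spec$tr_s, mask = mask)
    attr(out[[r]], "noise_mask") <- noise_mask
    attr(out[[r]], "timecourses") <- tc
  }
  out
}

apply_ar1 <- function(eps, phi) {
  if (phi == 0) return(eps)
  out <- stats::filter(eps, phi, method = "recursive")
  matrix(as.numeric(out), nrow(eps), ncol(eps))
}

#' Generate a complete synthetic cohort
#'
#' Draws covariates, plants spatial networks, computes per-subject task
#' amplitudes (with the designated component's hit amplitude moderated by the
#' centered covariates through the planted interaction coefficients),
#' simulates BOLD, events and motion for every subject/run, and optionally
#' writes the on-disk layout: `sub-XX/func/sub-XX_run-R_bold.nii.gz`,
#' `..._events.tsv`, `..._confounds.tsv`, `participants.tsv`,
#' `ground_truth.json` (+ `ground_truth_maps.nii.gz`).
#'
#' @param spec a [cohort_spec].
#' @param seed base RNG seed; every per-subject seed is derived from it and
#'   recorded, so the cohort is bit-reproducible.
#' @param dir output directory (created); `NULL` keeps the cohort in memory.
#' @param n_components planted networks (default 5).
#' @param moderation named planted coefficients applied to the designated
#'   component's hit amplitude: `apoe`, `sdoit`, `fam`, `apoe_sdoit`,
#'   `apoe_fam`, `sdoit_fam`, `three_way`.
#' @param moderated_component which component's hit amplitude is moderated
#'   (default: the last).
#' @param tmfc_gain hit-specific seed-target coupling gain (default 0.5).
#' @param tmfc_seed_component seed component for the planted coupling
#'   (default 1).
#' @param n_target_voxels size of the coupling target set (default 40; the
#'   in-mask voxels with the weakest planted loadings).
#' @param amplitude_jitter_sd subject-level SD of task amplitudes (default 0.1).
#' @param intrinsic_components which components carry intrinsic activity
#'   (default all).
#' @return invisible list: `spec`, `participants` (data.frame), `bold`
#'   (list\[subject\]\[run\]), `events`, `motion`, `timecourses` (the true
#'   per-run component time courses, T x C), `ground_truth`, `dir`.
#' @export
generate_cohort <- function(spec, seed, dir = NULL, n_components = 5,
                            moderation = c(apoe = -0.25, sdoit = 0.05,
                                           fam = 0.05, apoe_sdoit = -0.1,
                                           apoe_fam = 0.1, sdoit_fam = 0.02,
                                           three_way = 0.078),
                            moderated_component = n_components,
                            tmfc_gain = 0.5, tmfc_seed_component = 1,
                            n_target_voxels = 40, amplitude_jitter_sd = 0.1,
                            intrinsic_components = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  set.seed(seed)
  apoe_draws <- stats::runif(n)
  participants <- data.frame(
    subject = sprintf("sub-%02d", seq_len(n)),
    apoe4 = as.integer(apoe_draws < spec$apoe_frac),
    sdoit = stats::rbinom(n, 8, 0.55),
    familiarity = pmin(pmax(stats::rnorm(n, 4.75, 1.9), 1), 10),
    age = round(pmin(pmax(stats::rnorm(n, 76.6, 4.22), 68), 92), 1),
    sex = stats::rbinom(n, 1, 0.5))
  accuracy <- stats::plogis(spec$hit_intercept +
                              spec$hit_slope * (participants$sdoit - 4))
  maps <- plant_spatial_maps(spec$grid, n_components, derive_seed(seed, 1))
  # target set: in-mask voxels with the weakest planted loadings
  V <- prod(spec$grid)
  flat <- matrix(maps, V, n_components)
  mask_vec <- rep(TRUE, V); dim(mask_vec) <- spec$grid
  mask_vec[1, , ] <- FALSE
  load_mag <- apply(abs(flat), 1, max)
  cand <- which(as.vector(mask_vec))
  target_voxels <- cand[order(load_mag[cand])][seq_len(n_target_voxels)]
  # planted amplitudes: base 1 (hit) / 0.7 (miss) + subject jitter;
  # the designated component's hit amplitude is moderated by centered covariates
  amp <- array(0, c(n, n_components, 2),
               dimnames = list(NULL, NULL, c("hit", "miss")))
  amp[, , "hit"] <- 1 + matrix(stats::rnorm(n * n_components, 0,
                                            amplitude_jitter_sd), n)
  amp[, , "miss"] <- 0.7 + matrix(stats::rnorm(n * n_components, 0,
                                               amplitude_jitter_sd), n)
  sd_c <- participants$sdoit - mean(participants$sdoit)
  fm_c <- participants$familiarity - mean(participants$familiarity)
  ap <- participants$apoe4
  amp[, moderated_component, "hit"] <- amp[, moderated_component, "hit"] +
    moderation["apoe"] * ap + moderation["sdoit"] * sd_c +
    moderation["fam"] * fm_c + moderation["apoe_sdoit"] * ap * sd_c +
    moderation["apoe_fam"] * ap * fm_c + moderation["sdoit_fam"] * sd_c * fm_c +
    moderation["three_way"] * ap * sd_c * fm_c
  gains <- rep(tmfc_gain, n)
  subject_seeds <- vapply(seq_len(n), function(s) derive_seed(seed, 100 + s), 0L)
  gt <- list(planted_maps = maps, planted_task_amplitudes = amp,
             activation_moderation = as.list(moderation),
             moderated_component = moderated_component,
             tmfc = list(seed_component = tmfc_seed_component,
                         target_voxels = target_voxels, gains = gains),
             noise_model = list(ar1_phi = spec$ar1_phi, drift_sd = spec$drift_sd,
                                thermal_sd = spec$thermal_sd,
                                intrinsic_sd = spec$intrinsic_sd),
             intrinsic_components = intrinsic_components,
             seeds = subject_seeds, base_seed = seed)
  events <- motion <- bold <- vector("list", n)
  for (s in seq_len(n)) {
    events[[s]] <- lapply(seq_len(spec$n_runs), function(r)
      schedule_events(spec, accuracy[s], derive_seed(seed, 1000 + s * 10 + r)))
    motion[[s]] <- lapply(seq_len(spec$n_runs), function(r)
      simulate_motion(spec$n_frames, spec$spike_prob,
                      derive_seed(seed, 2000 + s * 10 + r)))
    bold[[s]] <- simulate_subject_bold(spec, gt, events[[s]],
                                       amp[s, , , drop = TRUE],
                                       gains[s], subject_seeds[s])
  }
  timecourses <- lapply(bold, function(runs) lapply(runs, attr, "timecourses"))
  bundle <- list(spec = spec, participants = participants, bold = bold,
                 events = events, motion = motion, timecourses = timecourses,
                 ground_truth = gt, accuracy = accuracy, dir = dir)
  if (!is.null(dir)) write_cohort(bundle, dir)
  invisible(bundle)
}

# On-disk layout writer (NIfTI + TSV + ground-truth manifest).
write_cohort <- function(bundle, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("output directory not writable: ", dir)
  spec <- bundle$spec
  for (s in seq_len(spec$n_subjects)) {
    sid <- bundle$participants$subject[s]
    fdir <- file.path(dir, sid, "func")
    dir.create(fdir, recursive = TRUE, showWarnings = FALSE)
    for (r in seq_len(spec$n_runs)) {
      stem <- file.path(fdir, sprintf("%s_run-%d", sid, r))
      save_bold(bundle$bold[[s]][[r]], paste0(stem, "_bold.nii.gz"))
      utils::write.table(bundle$events[[s]][[r]], paste0(stem, "_events.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      utils::write.table(as.data.frame(unclass(bundle$motion[[s]][[r]])),
                         paste0(stem, "_confounds.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  utils::write.table(bundle$participants, file.path(dir, "participants.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  gt <- bundle$ground_truth
  maps_img <- RNifti::asNifti(gt$planted_maps, datatype = "float")
  RNifti::writeNifti(maps_img, file.path(dir, "ground_truth_maps.nii.gz"))
  manifest <- gt[setdiff(names(gt), "planted_maps")]
  manifest$planted_task_amplitudes <- NULL  # large; kept in memory bundle
  jsonlite::write_json(manifest, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a cohort written by [generate_cohort] back into memory
#' @param dir cohort directory.
#' @param tr_s TR override passed to [load_bold].
#' @return list with `participants`, `bold`, `events`, `motion`.
#' @export
load_cohort <- function(dir, tr_s = NULL) {
  participants <- load_participants(file.path(dir, "participants.tsv"))
  n <- nrow(participants)
  bold <- events <- motion <- vector("list", n)
  for (s in seq_len(n)) {
    sid <- participants$subject[s]
    fdir <- file.path(dir, sid, "func")
    runs <- sort(Sys.glob(file.path(fdir, paste0(sid, "_run-*_bold.nii.gz"))))
    if (!length(runs)) stage_stop("load", sid, "no BOLD runs found")
    bold[[s]] <- lapply(runs, load_bold, tr_s = tr_s)
    events[[s]] <- lapply(seq_along(runs), function(r) {
      p <- file.path(fdir, sprintf("%s_run-%d_events.tsv", sid, r))
      if (!file.exists(p)) stage_stop("load", sid, paste("missing events file", p))
      load_events(p)
    })
    motion[[s]] <- lapply(seq_along(runs), function(r)
      load_confounds(file.path(fdir, sprintf("%s_run-%d_confounds.tsv", sid, r))))
    for (r in seq_along(runs)) {
      nm <- array(FALSE, dim(bold[[s]][[r]]$data)[1:3]); nm[1, , ] <- TRUE
      msk <- !nm
      bold[[s]][[r]]$mask <- msk
      attr(bold[[s]][[r]], "noise_mask") <- nm
    }
  }
  list(participants = participants, bold = bold, events = events,
       motion = motion)
}
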