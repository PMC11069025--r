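# Pipeline orchestration: configuration, staged execution, manifest.

#' Pipeline configuration
#'
#' Collects every tunable of the analysis with its default: 8-mm smoothing,
#' MDL-estimated ICA order with 10 ICASSO repetitions, the 10-s HRF, the
#' |r| > .2 retention rule, spike thresholds FD 1 mm / standardized DVARS 2,
#' 0.01-Hz high-pass, one-sample t-map thresholds p < .0001 / k >= 100 and
#' group-regression thresholds p < .001 / k >= 75 at 26-connectivity.
#'
#' @param data_dir cohort directory (layout of [generate_cohort]).
#' @param fwhm_mm smoothing kernel FWHM (default 8).
#' @param ica_order `"mdl"` or a fixed integer.
#' @param icasso_runs ICA repetitions (default 10).
#' @param retention_threshold task-correlation retention cut (default 0.2).
#' @param hrf_duration_s HRF kernel length (default 10).
#' @param fd_thresh,dvars_thresh spike thresholds (defaults 1.0, 2.0).
#' @param highpass_hz DCT cutoff (default 0.01).
#' @param tmap_p,tmap_k one-sample t-map thresholds (defaults 1e-4, 100).
#' @param reg_p,reg_k group-regression thresholds (defaults 1e-3, 75).
#' @param connectivity cluster connectivity (default 26).
#' @param seed RNG seed (default 1).
#' @param tr_s optional TR override for [load_bold].
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(data_dir = NULL, fwhm_mm = 8, ica_order = "mdl",
                            icasso_runs = 10, retention_threshold = 0.2,
                            hrf_duration_s = 10, fd_thresh = 1.0,
                            dvars_thresh = 2.0, highpass_hz = 0.01,
                            tmap_p = 1e-4, tmap_k = 100, reg_p = 1e-3,
                            reg_k = 75, connectivity = 26, seed = 1,
                            tr_s = NULL) {
  cfg <- list(data_dir = data_dir, fwhm_mm = fwhm_mm, ica_order = ica_order,
              icasso_runs = icasso_runs,
              retention_threshold = retention_threshold,
              hrf_duration_s = hrf_duration_s, fd_thresh = fd_thresh,
              dvars_thresh = dvars_thresh, highpass_hz = highpass_hz,
              tmap_p = tmap_p, tmap_k = tmap_k, reg_p = reg_p, reg_k = reg_k,
              connectivity = connectivity, seed = seed, tr_s = tr_s)
  num <- c("fwhm_mm", "icasso_runs", "retention_threshold", "hrf_duration_s",
           "fd_thresh", "dvars_thresh", "highpass_hz", "tmap_p", "tmap_k",
           "reg_p", "reg_k")
  for (f in num) if (cfg[[f]] < 0) stop("config field must be >= 0: ", f)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys mirror [pipeline_config] arguments.
#' @param ... overrides applied after the file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  over <- list(...)
  vals[names(over)] <- over
  do.call(pipeline_config, vals[names(vals) %in% names(formals(pipeline_config))])
}

#' Run the full odor-identification network pipeline
#'
#' Stages: load (or accept in-memory) cohort -> Gaussian smoothing -> group
#' spatial ICA (MDL + infomax + ICASSO + GICA3) -> temporal sorting and
#' |r| > threshold retention -> per-subject hit/miss condition betas ->
#' confound assembly -> per-component gPPI TMFC maps -> group statistics
#' (one-sample t maps of subject component maps; moderated regression of
#' condition betas and of TMFC maps with cluster-extent thresholding).
#'
#' @param config a `pipeline_config`.
#' @param cohort optional in-memory cohort bundle (as from [generate_cohort]
#'   or [load_cohort]); otherwise loaded from `config$data_dir`.
#' @return list with `components`, `relevance`, `retained`, `betas`,
#'   `activation_fits`, `tmfc` (per component x condition group `stat_map`s),
#'   `tmaps`, `manifest`.
#' @export
run_pipeline <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(cohort)) {
    if (is.null(config$data_dir)) stage_stop("load", msg = "no data_dir or cohort")
    cohort <- tryCatch(load_cohort(config$data_dir, tr_s = config$tr_s),
                       error = function(e) stage_stop("load", msg = conditionMessage(e)))
  }
  participants <- cohort$participants
  n <- nrow(participants)
  tr_s <- cohort$bold[[1]][[1]]$tr_s
  run_frames <- vapply(cohort$bold[[1]], function(b) dim(b$data)[4], 0L)
  hrf <- canonical_hrf(config$hrf_duration_s, tr_s)

  smoothed <- lapply(seq_len(n), function(s) {
    tryCatch(lapply(cohort$bold[[s]], smooth_gaussian, fwhm_mm = config$fwhm_mm),
             error = function(e)
               stage_stop("smooth", participants$subject[s], conditionMessage(e)))
  })

  # MDL effective sample size: resel count after smoothing (spatially
  # correlated noise otherwise inflates the estimated order)
  vox <- voxel_sizes(cohort$bold[[1]][[1]]$affine)
  n_eff <- round(sum(cohort$bold[[1]][[1]]$mask) /
                   max(1, prod(pmax(config$fwhm_mm / vox, 1))))
  comps <- tryCatch(
    group_ica(smoothed, order = config$ica_order, icasso_runs = config$icasso_runs,
              seed = config$seed, mdl_n_effective = n_eff),
    error = function(e) stage_stop("ica", msg = conditionMessage(e)))

  generic <- unlist(lapply(seq_along(run_frames), function(r)
    build_condition_regressor(cohort$events[[1]][[r]], "all_stim",
                              run_frames[r], tr_s, hrf)))
  relevance <- tryCatch(
    sort_by_task_correlation(comps$subject_timecourses, generic, run_frames),
    error = function(e) stage_stop("sort", msg = conditionMessage(e)))
  retained <- retain_task_components(relevance, config$retention_threshold)

  betas <- tryCatch(
    condition_betas(comps$subject_timecourses, cohort$events, tr_s, run_frames,
                    hrf = hrf, components = retained),
    error = function(e) stage_stop("betas", msg = conditionMessage(e)))

  confounds <- lapply(seq_len(n), function(s) {
    tryCatch({
      per_run <- lapply(seq_along(run_frames), function(r) {
        b <- smoothed[[s]][[r]]
        nm <- attr(cohort$bold[[s]][[r]], "noise_mask")
        if (is.null(nm)) { nm <- array(FALSE, dim(b$data)[1:3]); nm[1, , ] <- TRUE }
        b$mask <- b$mask & !nm
        cm <- build_confound_matrix(as.matrix(cohort$motion[[s]][[r]][, 1:6]), b,
                                    nm, fd_thresh = config$fd_thresh,
                                    dvars_thresh = config$dvars_thresh,
                                    cutoff_hz = config$highpass_hz)
        x <- cm$x
        colnames(x) <- paste0(colnames(x), "_run", r)
        x
      })
      # run-specific confounds enter block-diagonally over the concatenation
      total <- sum(run_frames)
      off <- c(0, cumsum(run_frames))
      do.call(cbind, lapply(seq_along(per_run), function(r) {
        out <- matrix(0, total, ncol(per_run[[r]]),
                      dimnames = list(NULL, colnames(per_run[[r]])))
        out[(off[r] + 1):off[r + 1], ] <- per_run[[r]]
        out
      }))
    }, error = function(e)
      stage_stop("confounds", participants$subject[s], conditionMessage(e)))
  })

  tmfc_res <- list()
  for (k in retained) {
    per_subj_hit <- matrix(NA_real_, n, sum(comps$mask))
    per_subj_miss <- matrix(NA_real_, n, sum(comps$mask))
    for (s in seq_len(n)) {
      seed_tc <- comps$subject_timecourses[[s]][, k]
      maps <- tryCatch(
        tmfc_subject(smoothed[[s]], cohort$events[[s]], seed_tc,
                     confounds = confounds[[s]], hrf = hrf),
        error = function(e)
          stage_stop("tmfc", participants$subject[s], conditionMessage(e)))
      if (!is.null(maps$hit)) per_subj_hit[s, ] <- maps$hit
      if (!is.null(maps$miss)) per_subj_miss[s, ] <- maps$miss
    }
    tmfc_res[[paste0("comp", k)]] <- list(hit = per_subj_hit,
                                          miss = per_subj_miss)
  }

  design <- tryCatch(group_design(participants),
                     error = function(e) stage_stop("groupstats", msg = conditionMessage(e)))
  activation_fits <- lapply(seq_along(retained), function(i) {
    list(hit = fit_group_regression(betas[, i, "hit"], design),
         miss = if (!all(is.na(betas[, i, "miss"])))
           fit_group_regression(betas[, i, "miss"], design) else NULL)
  })
  names(activation_fits) <- paste0("comp", retained)

  tmaps <- lapply(retained, function(k) {
    sm <- do.call(rbind, lapply(comps$subject_maps, function(m) m[k, ]))
    one_sample_tmap(sm, grid = comps$grid, mask = as.vector(comps$mask),
                    p_voxel = config$tmap_p, k_min = config$tmap_k,
                    connectivity = config$connectivity)
  })
  names(tmaps) <- paste0("comp", retained)

  tmfc_stats <- lapply(tmfc_res, function(tm) {
    lapply(tm, function(mm) {
      if (all(is.na(mm))) return(NULL)
      fit <- fit_group_regression(mm, design)
      lapply(c(apoe_x_sdoit = "apoe_x_sdoit", apoe_x_fam = "apoe_x_fam",
               three_way = "apoe_x_sdoit_x_fam"), function(cn)
        cluster_threshold(fit$t[cn, ], fit$p[cn, ], grid = comps$grid,
                          mask = as.vector(comps$mask), p_voxel = config$reg_p,
                          k_min = config$reg_k,
                          connectivity = config$connectivity, df = fit$df))
    })
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("odornets")),
    seed = config$seed, config = unclass(config)[!vapply(config, is.null, TRUE)],
    n_subjects = n, order = comps$order,
    stability_iq = comps$stability_iq,
    retained_components = retained,
    relevance = relevance$mean_abs_corr)

  list(components = comps, relevance = relevance, retained = retained,
       betas = betas, activation_fits = activation_fits, tmaps = tmaps,
       tmfc = tmfc_res, tmfc_stats = tmfc_stats, manifest = manifest,
       confounds = confounds, design = design)
}

#' Write a pipeline manifest as JSON
#' @param result result list from [run_pipeline].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_manifest <- function(result, path) {
  jsonlite::write_json(result$manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
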