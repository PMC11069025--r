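# Hybrid ICA/gPPI stage: per subject and retained component, build the PPI
# design and fit a voxelwise GLM producing condition-specific
# task-modulated-connectivity (interaction-beta) maps.

#' Build a generalized-PPI design matrix
#'
#' Columns: per-run intercepts, HRF-convolved hit and miss regressors
#' (centered per run), the seed component time course (centered per run),
#' the two psychophysiological interactions `hit_x_seed` and `miss_x_seed`
#' (elementwise products of the centered parents), and the nuisance block
#' (24-parameter motion, aCompCor, spikes, per-run DCT high-pass basis).
#' All-zero columns (e.g. the interaction of an empty condition) are dropped
#' with a message.
#'
#' @param seed_timecourse numeric vector, runs concatenated.
#' @param task_design `design_matrix` from [concat_run_designs] (per-run
#'   intercepts + hit + miss).
#' @param confounds T x K nuisance matrix (runs concatenated), or NULL.
#' @param run_frames per-run frame counts.
#' @return a `design_matrix` whose `types` distinguish task, seed,
#'   interaction and nuisance columns.
#' @export
build_ppi_design <- function(seed_timecourse, task_design, confounds = NULL,
                             run_frames = NULL) {
  stopifnot(inherits(task_design, "design_matrix"))
  x <- task_design$x
  total <- nrow(x)
  if (length(seed_timecourse) != total)
    stop("seed time course length (", length(seed_timecourse),
         ") does not match design frames (", total, ")")
  run_frames <- run_frames %||% total
  off <- c(0, cumsum(run_frames))
  center_by_run <- function(v) {
    for (r in seq_along(run_frames)) {
      idx <- (off[r] + 1):off[r + 1]
      v[idx] <- v[idx] - mean(v[idx])
    }
    v
  }
  seed_c <- center_by_run(seed_timecourse)
  hit_c <- center_by_run(x[, "hit"])
  miss_c <- center_by_run(x[, "miss"])
  intercepts <- x[, grep("^intercept", colnames(x)), drop = FALSE]
  task_block <- cbind(hit = hit_c, miss = miss_c, seed = seed_c,
                      hit_x_seed = hit_c * seed_c,
                      miss_x_seed = miss_c * seed_c)
  full <- cbind(intercepts, task_block)
  types <- c(rep("nuisance", ncol(intercepts)),
             "task", "task", "seed", "interaction", "interaction")
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    full <- cbind(full, confounds)
    types <- c(types, rep("nuisance", ncol(confounds)))
  }
  names(types) <- colnames(full)
  zero <- apply(full, 2, function(v) all(v == 0))
  if (any(zero)) {
    message("dropping all-zero design column(s): ",
            paste(colnames(full)[zero], collapse = ", "))
    full <- full[, !zero, drop = FALSE]
    types <- types[!zero]
  }
  tk <- full[, types %in% c("task", "seed", "interaction"), drop = FALSE]
  if (ncol(tk) && qr(tk)$rank < ncol(tk)) {
    cc <- abs(stats::cor(tk)); diag(cc) <- 0
    pair <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    stop("task/interaction block is rank deficient; collinear pair: ",
         colnames(tk)[pair[1]], " ~ ", colnames(tk)[pair[2]])
  }
  design_matrix(full, types = types, empty = task_design$empty)
}

#' Fit a voxelwise GLM
#'
#' Ordinary least squares at every mask voxel with a single pseudo-inverse
#' applied to all voxel time series at once. Voxels with non-finite series
#' are excluded from the mask with a warning.
#'
#' @param bold a [bold4d] object, or a T x V numeric matrix (runs
#'   concatenated; then `mask` gives voxel columns).
#' @param design a `design_matrix`.
#' @param mask logical vector selecting columns when `bold` is a matrix.
#' @return object of class `voxel_glm`: `beta` (columns x voxels), `sigma2`
#'   (residual variance per voxel), `df`, `design`, `mask`, `grid`.
#' @export
fit_voxelwise_glm <- function(bold, design, mask = NULL) {
  stopifnot(inherits(design, "design_matrix"))
  if (inherits(bold, "bold4d")) {
    d <- dim(bold$data)
    grid <- d[1:3]
    mask <- as.vector(bold$mask)
    y <- t(matrix(bold$data, prod(grid), d[4]))[, mask, drop = FALSE]
  } else {
    y <- as.matrix(bold)
    grid <- NULL
    mask <- mask %||% rep(TRUE, ncol(y))
    y <- y[, mask, drop = FALSE]
  }
  x <- design$x
  if (nrow(y) != nrow(x))
    stop("data frames (", nrow(y), ") do not match design frames (", nrow(x), ")")
  bad <- !apply(is.finite(y), 2, all)
  if (any(bad)) {
    warning(sum(bad), " voxel(s) with non-finite series excluded from mask")
    which_mask <- which(mask)
    mask[which_mask[bad]] <- FALSE
    y <- y[, !bad, drop = FALSE]
  }
  rank <- qr(x)$rank
  df <- nrow(x) - rank
  if (df <= 0) stop("nonpositive residual degrees of freedom")
  beta <- pinv(x) %*% y
  rownames(beta) <- colnames(x)
  resid <- y - x %*% beta
  sigma2 <- colSums(resid^2) / df
  structure(list(beta = beta, sigma2 = sigma2, df = df, design = design,
                 mask = mask, grid = grid),
            class = "voxel_glm")
}

#' Extract task-modulated-connectivity maps from a PPI fit
#'
#' Selects the `hit_x_seed` and `miss_x_seed` interaction-beta maps. A
#' condition whose interaction column was absent (no events) yields a
#' missing entry, not zeros.
#'
#' @param fit a `voxel_glm` from a PPI design.
#' @return object of class `tmfc_maps`: list with `hit`, `miss` (numeric
#'   vectors over mask voxels or NULL if missing), `missing` (character),
#'   `sigma2`, `df`, `mask`, `grid`.
#' @export
extract_tmfc <- function(fit) {
  stopifnot(inherits(fit, "voxel_glm"))
  pick <- function(cn) if (cn %in% rownames(fit$beta)) fit$beta[cn, ] else NULL
  hit <- pick("hit_x_seed"); miss <- pick("miss_x_seed")
  missing <- c(if (is.null(hit)) "hit", if (is.null(miss)) "miss")
  structure(list(hit = hit, miss = miss, missing = missing,
                 sigma2 = fit$sigma2, df = fit$df, mask = fit$mask,
                 grid = fit$grid),
            class = "tmfc_maps")
}

#' Per-subject TMFC maps for one seed component
#'
#' Convenience wrapper: concatenates the subject's runs, builds the task and
#' PPI designs, fits the voxelwise GLM and extracts the interaction maps.
#'
#' @param bold_runs list of [bold4d] runs for one subject.
#' @param events_runs list of event tables, one per run.
#' @param seed_timecourse concatenated component time course.
#' @param confounds optional concatenated nuisance matrix.
#' @param hrf HRF kernel (default 10-s canonical at the data's TR).
#' @return a `tmfc_maps` object.
#' @export
tmfc_subject <- function(bold_runs, events_runs, seed_timecourse,
                         confounds = NULL, hrf = NULL) {
  tr_s <- bold_runs[[1]]$tr_s
  hrf <- hrf %||% canonical_hrf(10, tr_s)
  run_frames <- vapply(bold_runs, function(b) dim(b$data)[4], 0L)
  designs <- lapply(seq_along(bold_runs), function(r)
    build_task_design(events_runs[[r]], tr_s, run_frames[r], hrf))
  task <- concat_run_designs(designs)
  ppi <- build_ppi_design(seed_timecourse, task, confounds, run_frames)
  mask <- as.vector(bold_runs[[1]]$mask)
  y <- do.call(rbind, lapply(bold_runs, function(b) {
    d <- dim(b$data)
    t(matrix(b$data, prod(d[1:3]), d[4]))
  }))
  fit <- fit_voxelwise_glm(y, ppi, mask = mask)
  out <- extract_tmfc(fit)
  out$grid <- dim(bold_runs[[1]]$data)[1:3]
  out
}
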