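# Canonical HRF and task design construction.

#' Canonical double-gamma hemodynamic response function
#'
#' Standard double-gamma kernel (response peak around 5-6 s, late undershoot,
#' undershoot ratio 1/6) sampled at `dt_s` and truncated at `duration_s`. The
#' default 10-s truncation keeps only the positive response lobe, the short
#' kernel that correlates best with the 16-s odor presentation/choice blocks.
#' The kernel is peak-normalized to 1 so that regression coefficients are
#' comparable across kernels; scale is absorbed by the betas.
#'
#' @param duration_s kernel length in seconds (default 10).
#' @param dt_s sampling step in seconds (default 2, the TR).
#' @param peak_shape,undershoot_shape gamma shape parameters for the response
#'   and undershoot lobes (defaults 6 and 16, unit rate: modes at 5 s / 15 s).
#' @param undershoot_ratio relative amplitude of the undershoot (default 1/6).
#' @return object of class `hrf_kernel`: list with `samples`, `dt_s`,
#'   `duration_s`.
#' @export
canonical_hrf <- function(duration_s = 10, dt_s = 2,
                          peak_shape = 6, undershoot_shape = 16,
                          undershoot_ratio = 1 / 6) {
  stopifnot(duration_s > 0, dt_s > 0)
  t <- seq(0, duration_s, by = dt_s)
  h <- stats::dgamma(t, shape = peak_shape, rate = 1) -
    undershoot_ratio * stats::dgamma(t, shape = undershoot_shape, rate = 1)
  peak <- max(h)
  if (peak <= 0) stop("degenerate HRF: nonpositive peak")
  out <- structure(list(samples = h / peak, dt_s = dt_s, duration_s = duration_s),
                   class = "hrf_kernel")
  if (duration_s < peak_shape - 1)  # truncated before the response mode
    warning("HRF truncated before its peak delay (", peak_shape - 1, " s)")
  out
}

#' @export
print.hrf_kernel <- function(x, ...) {
  cat(sprintf("<hrf_kernel> %g s at dt %g s (%d samples), peak %.3g\n",
              x$duration_s, x$dt_s, length(x$samples), max(x$samples)))
  invisible(x)
}

#' HRF-convolved condition regressor
#'
#' Builds a boxcar at the events of one condition sampled at the TR, convolves
#' it with the HRF kernel and truncates to the scan length. A frame is inside
#' the boxcar when its acquisition time falls in `[onset, onset + duration)`.
#'
#' @param events event table (see [load_events]).
#' @param condition one of `"all_stim"`, `"hit"`, `"miss"`, `"baseline"`.
#' @param n_frames number of frames in the run.
#' @param tr_s repetition time in seconds; must equal the kernel `dt_s`.
#' @param hrf an [canonical_hrf] kernel.
#' @return numeric vector of length `n_frames`; all-zero iff the condition
#'   has no events.
#' @export
build_condition_regressor <- function(events, condition, n_frames, tr_s, hrf) {
  stopifnot(inherits(hrf, "hrf_kernel"))
  if (abs(hrf$dt_s - tr_s) > 1e-9)
    stop("HRF kernel dt (", hrf$dt_s, ") must match TR (", tr_s, ")")
  condition <- match.arg(condition, c("all_stim", "hit", "miss", "baseline"))
  sel <- switch(condition,
    all_stim = events$trial_type == "stim",
    baseline = events$trial_type == "baseline",
    hit = events$trial_type == "stim" & events$outcome == "hit",
    miss = events$trial_type == "stim" & events$outcome == "miss")
  u <- numeric(n_frames)
  tt <- (seq_len(n_frames) - 1) * tr_s
  for (i in which(sel)) {
    if (events$onset[i] + events$duration[i] > n_frames * tr_s)
      warning("event at ", events$onset[i], " s extends past scan end; truncated")
    u[tt >= events$onset[i] & tt < events$onset[i] + events$duration[i]] <- 1
  }
  # direct (non-FFT) convolution: exact zeros where the boxcar is zero
  k <- hrf$samples
  x <- numeric(n_frames)
  for (j in seq_along(k)) {
    if (k[j] == 0) next
    x[j:n_frames] <- x[j:n_frames] + k[j] * u[seq_len(n_frames - j + 1)]
  }
  x
}

#' Task design matrix with hit and miss regressors
#'
#' @param events event table for one run.
#' @param tr_s repetition time.
#' @param n_frames frames in the run.
#' @param hrf HRF kernel.
#' @return object of class `design_matrix`: list with `x` (matrix with columns
#'   `intercept`, `hit`, `miss`), `types` (per-column role), `empty`
#'   (conditions present in the design but without events), `rank`.
#' @export
build_task_design <- function(events, tr_s, n_frames, hrf) {
  if (!any(events$trial_type == "stim"))
    stop("design requires at least one stim event")
  hit <- build_condition_regressor(events, "hit", n_frames, tr_s, hrf)
  miss <- build_condition_regressor(events, "miss", n_frames, tr_s, hrf)
  x <- cbind(intercept = 1, hit = hit, miss = miss)
  empty <- c("hit", "miss")[c(all(hit == 0), all(miss == 0))]
  design_matrix(x, types = c(intercept = "nuisance", hit = "task", miss = "task"),
                empty = empty)
}

design_matrix <- function(x, types, empty = character(0)) {
  stopifnot(!anyDuplicated(colnames(x)))
  structure(list(x = x, types = types, empty = empty, rank = qr(x)$rank),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> %d frames x %d columns, rank %d",
              nrow(x$x), ncol(x$x), x$rank))
  if (length(x$empty)) cat(" (empty: ", paste(x$empty, collapse = ", "), ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Concatenate per-run task designs with per-run intercepts
#'
#' Task columns are stacked over runs; the intercept becomes one indicator
#' column per run, so run-specific offsets never leak across run boundaries.
#'
#' @param designs list of `design_matrix` objects (one per run, same task
#'   columns).
#' @return a `design_matrix` over the concatenated frames.
#' @export
concat_run_designs <- function(designs) {
  n_runs <- length(designs)
  frames <- vapply(designs, function(d) nrow(d$x), 0L)
  total <- sum(frames)
  task_cols <- setdiff(colnames(designs[[1]]$x), "intercept")
  x <- matrix(0, total, n_runs + length(task_cols))
  colnames(x) <- c(paste0("intercept_run", seq_len(n_runs)), task_cols)
  off <- 0L
  for (r in seq_len(n_runs)) {
    idx <- off + seq_len(frames[r])
    x[idx, r] <- 1
    for (cn in task_cols) x[idx, cn] <- designs[[r]]$x[, cn]
    off <- off + frames[r]
  }
  types <- c(rep("nuisance", n_runs), rep("task", length(task_cols)))
  names(types) <- colnames(x)
  empty <- task_cols[vapply(task_cols, function(cn) all(x[, cn] == 0), TRUE)]
  design_matrix(x, types = types, empty = empty)
}
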