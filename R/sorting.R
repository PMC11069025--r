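# Temporal sorting of components against the generic task regressor,
# the |r| > .2 retention rule, and per-subject hit/miss condition betas.

#' Temporally sort components by task correlation
#'
#' For every component, computes the Pearson correlation between each
#' subject's component time course and the generic (subject-invariant)
#' HRF-convolved stimulus regressor, per run, and aggregates by the mean of
#' the absolute correlations over subjects and runs (retention operates on
#' absolute magnitude; `aggregate = "mean_r"` averages signed correlations
#' instead). Components are returned ranked by the aggregate, descending.
#'
#' @param subject_timecourses list (subjects) of T x C matrices with runs
#'   concatenated on the time axis.
#' @param generic_regressor numeric vector: the all-stim regressor for one
#'   run, or of full concatenated length.
#' @param run_frames integer vector of per-run frame counts; correlations are
#'   computed per run and then averaged.
#' @param aggregate `"mean_abs_r"` (default) or `"mean_r"`.
#' @return object of class `task_relevance`: data.frame with `component`,
#'   `mean_abs_corr`, `rank`, plus the per-subject-run correlation array in
#'   attribute `"per_run_r"`.
#' @export
sort_by_task_correlation <- function(subject_timecourses, generic_regressor,
                                     run_frames = NULL,
                                     aggregate = c("mean_abs_r", "mean_r")) {
  aggregate <- match.arg(aggregate)
  tc1 <- subject_timecourses[[1]]
  total <- nrow(tc1)
  run_frames <- run_frames %||% total
  if (length(generic_regressor) == run_frames[1] && length(run_frames) > 1)
    generic_regressor <- rep(generic_regressor, length(run_frames))
  if (length(generic_regressor) != sum(run_frames))
    stop("regressor length (", length(generic_regressor),
         ") does not match time courses (", sum(run_frames), ")")
  C <- ncol(tc1)
  n <- length(subject_timecourses)
  n_runs <- length(run_frames)
  rr <- array(NA_real_, c(n, n_runs, C))
  off <- c(0, cumsum(run_frames))
  for (s in seq_len(n)) {
    tc <- subject_timecourses[[s]]
    if (nrow(tc) != sum(run_frames))
      stop("subject ", s, " time course length mismatch")
    for (r in seq_len(n_runs)) {
      idx <- (off[r] + 1):off[r + 1]
      rr[s, r, ] <- stats::cor(tc[idx, , drop = FALSE], generic_regressor[idx])
    }
  }
  agg <- if (aggregate == "mean_abs_r") apply(abs(rr), 3, mean)
         else abs(apply(rr, 3, mean))
  out <- data.frame(component = seq_len(C), mean_abs_corr = agg)
  out <- out[order(-out$mean_abs_corr), ]
  out$rank <- seq_len(C)
  rownames(out) <- NULL
  structure(out, per_run_r = rr, class = c("task_relevance", "data.frame"))
}

#' Construct a task-relevance table from precomputed correlation magnitudes
#'
#' Convenience constructor for worked examples where only the aggregate
#' component-regressor correlation magnitudes are known.
#'
#' @param mean_abs_corr numeric vector of aggregate |r| values, one per
#'   component.
#' @param component optional component labels (default `seq_along`).
#' @return a `task_relevance` object.
#' @export
task_relevance <- function(mean_abs_corr, component = seq_along(mean_abs_corr)) {
  stopifnot(all(mean_abs_corr >= 0), all(mean_abs_corr <= 1))
  out <- data.frame(component = component, mean_abs_corr = mean_abs_corr)
  out <- out[order(-out$mean_abs_corr), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out, class = c("task_relevance", "data.frame"))
}

#' Retain task-relevant components
#'
#' A component is retained when its aggregate absolute correlation with the
#' generic task regressor is strictly greater than the threshold.
#'
#' @param relevance a `task_relevance` object.
#' @param threshold retention threshold (default 0.2).
#' @return integer vector of retained component indices (by original
#'   component label, ranked); `length()` of it is the retention count.
#' @export
retain_task_components <- function(relevance, threshold = 0.2) {
  stopifnot(inherits(relevance, "task_relevance"))
  relevance$component[relevance$mean_abs_corr > threshold]
}

#' Per-subject hit/miss condition betas for retained components
#'
#' Ordinary least squares of each retained component's concatenated time
#' course on the subject-specific task design (per-run intercepts plus the
#' HRF-convolved hit and miss regressors). A condition with no events is
#' dropped from the design and its beta marked missing.
#'
#' @param subject_timecourses list (subjects) of T x C matrices, runs
#'   concatenated.
#' @param subject_events list (subjects) of lists (runs) of event tables.
#' @param tr_s repetition time.
#' @param run_frames per-run frame counts.
#' @param hrf HRF kernel (default: 10-s canonical at `tr_s`).
#' @param components which components to fit (default: all).
#' @return array subjects x components x 2 (`hit`, `miss`), NA where a
#'   condition was empty; class `condition_betas`.
#' @export
condition_betas <- function(subject_timecourses, subject_events, tr_s,
                            run_frames, hrf = NULL, components = NULL) {
  hrf <- hrf %||% canonical_hrf(10, tr_s)
  n <- length(subject_timecourses)
  C <- ncol(subject_timecourses[[1]])
  components <- components %||% seq_len(C)
  out <- array(NA_real_, c(n, length(components), 2),
               dimnames = list(NULL, paste0("comp", components),
                               c("hit", "miss")))
  for (s in seq_len(n)) {
    designs <- lapply(seq_along(subject_events[[s]]), function(r)
      build_task_design(subject_events[[s]][[r]], tr_s, run_frames[r], hrf))
    d <- concat_run_designs(designs)
    x <- d$x
    keep <- setdiff(colnames(x), d$empty)
    x <- x[, keep, drop = FALSE]
    tc <- subject_timecourses[[s]]
    beta <- pinv(x) %*% tc[, components, drop = FALSE]
    rownames(beta) <- keep
    if ("hit" %in% keep) out[s, , "hit"] <- beta["hit", ]
    if ("miss" %in% keep) out[s, , "miss"] <- beta["miss", ]
  }
  structure(out, class = c("condition_betas", class(out)))
}
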