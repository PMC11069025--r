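# Motion / physiological nuisance model: FD, DVARS, 24-parameter motion
# expansion, aCompCor, spike regressors, DCT high-pass basis.

#' Framewise displacement (Power formulation)
#'
#' FD_t = sum |delta translation| + head_radius * sum |delta rotation|, with
#' FD_1 = 0. Rotations are converted to arc length on a 50-mm sphere, the
#' convention behind the common 1-mm spike threshold.
#'
#' @param motion matrix/data.frame with 6 columns: 3 translations (mm) then
#'   3 rotations (rad).
#' @param head_radius_mm sphere radius for rotations (default 50).
#' @return numeric FD series (mm), first element 0.
#' @export
framewise_displacement <- function(motion, head_radius_mm = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) stop("motion must have 6 columns, got ", ncol(motion))
  d <- apply(motion, 2, function(x) c(0, diff(x)))
  rowSums(abs(d[, 1:3, drop = FALSE])) +
    head_radius_mm * rowSums(abs(d[, 4:6, drop = FALSE]))
}

#' DVARS: RMS of the temporal derivative of voxel signals
#'
#' Raw DVARS_t is the spatial root-mean-square over the mask of the
#' frame-to-frame signal difference; the standardized series divides by the
#' median of the raw series over t >= 2, so its median is 1 and the
#' conventional spike threshold of 2 means "twice the typical frame change".
#'
#' @param bold a [bold4d] object.
#' @return list with `raw` and `std` series (first element 0 in both).
#' @export
dvars <- function(bold) {
  stopifnot(inherits(bold, "bold4d"))
  if (!any(bold$mask)) stop("empty mask")
  d <- dim(bold$data)
  y <- matrix(bold$data, prod(d[1:3]), d[4])[as.vector(bold$mask), , drop = FALSE]
  dif <- y[, -1, drop = FALSE] - y[, -ncol(y), drop = FALSE]
  raw <- c(0, sqrt(colMeans(dif^2)))
  med <- stats::median(raw[-1])
  std <- if (med > 0) raw / med else raw
  list(raw = raw, std = std)
}

#' 24-parameter motion expansion
#'
#' Columns `[m, dm, m^2, dm^2]`: the six rigid-body parameters, their backward
#' temporal differences (leading 0), and the squares of both.
#'
#' @param motion 6-column motion matrix.
#' @return numeric matrix with 24 named columns.
#' @export
motion_expansion <- function(motion) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) stop("motion must have 6 columns, got ", ncol(motion))
  base_names <- colnames(motion) %||% c("trans_x", "trans_y", "trans_z",
                                        "rot_x", "rot_y", "rot_z")
  if (is.null(colnames(motion))) colnames(motion) <- base_names
  d <- apply(motion, 2, function(x) c(0, diff(x)))
  out <- cbind(motion, d, motion^2, d^2)
  colnames(out) <- c(base_names, paste0(base_names, "_derivative1"),
                     paste0(base_names, "_power2"),
                     paste0(base_names, "_derivative1_power2"))
  out
}

#' aCompCor nuisance components
#'
#' Principal-component time series of voxel signals in a noise region
#' (CSF-like mask). Each noise voxel is detrended (mean + linear trend), then
#' the top principal components by explained variance are returned,
#' unit-normalized, in order of decreasing eigenvalue.
#'
#' @param bold a [bold4d] object.
#' @param noise_mask logical 3D array, disjoint from the analysis mask.
#' @param n_components number of components (default 5).
#' @return T x n_components matrix, columns `a_comp_cor_00`...
#' @export
acompcor <- function(bold, noise_mask, n_components = 5) {
  stopifnot(inherits(bold, "bold4d"))
  noise_mask <- array(as.logical(noise_mask), dim(bold$mask))
  if (any(noise_mask & bold$mask))
    stop("noise mask must be disjoint from the analysis mask")
  nv <- sum(noise_mask)
  if (nv < n_components)
    stop("noise mask has ", nv, " voxels; need at least ", n_components)
  d <- dim(bold$data)
  y <- t(matrix(bold$data, prod(d[1:3]), d[4])[as.vector(noise_mask), , drop = FALSE])
  tt <- seq_len(nrow(y))
  y <- stats::lm.fit(cbind(1, tt), y)$residuals  # mean + linear detrend
  s <- svd(y, nu = n_components, nv = 0)
  u <- s$u[, seq_len(n_components), drop = FALSE]
  u <- sweep(u, 2, sqrt(colSums(u^2)), "/")
  colnames(u) <- sprintf("a_comp_cor_%02d", seq_len(n_components) - 1L)
  u
}

#' Motion/artifact spike regressors
#'
#' One indicator column per frame where FD exceeds `fd_thresh` (mm) or
#' standardized DVARS exceeds `dvars_thresh`; a frame exceeding both gets a
#' single column.
#'
#' @param fd FD series (mm).
#' @param dvars standardized DVARS series, same length.
#' @param fd_thresh FD threshold (default 1 mm).
#' @param dvars_thresh DVARS threshold (default 2).
#' @return T x n_spikes matrix (0 columns if no exceedances), columns
#'   `motion_outlier_00`...
#' @export
spike_regressors <- function(fd, dvars, fd_thresh = 1.0, dvars_thresh = 2.0) {
  if (length(fd) != length(dvars)) stop("fd and dvars must have equal length")
  flag <- which(fd > fd_thresh | dvars > dvars_thresh)
  if (length(flag) == length(fd))
    stop("all frames flagged as spikes; design would be saturated")
  out <- matrix(0, length(fd), length(flag))
  if (length(flag)) {
    out[cbind(flag, seq_along(flag))] <- 1
    colnames(out) <- sprintf("motion_outlier_%02d", seq_along(flag) - 1L)
  }
  out
}

#' Discrete-cosine high-pass basis
#'
#' Orthonormal DCT columns spanning frequencies below `cutoff_hz`, excluding
#' the constant term (which belongs to the intercept). Including these as
#' nuisance regressors inside the GLM is equivalent to high-pass filtering at
#' the cutoff while keeping the residual degrees of freedom correct.
#'
#' @param n_frames frames in the run (>= 4).
#' @param tr_s repetition time (s).
#' @param cutoff_hz high-pass cutoff (default 0.01 Hz).
#' @return n_frames x K matrix, K = floor(2 * n_frames * tr_s * cutoff_hz);
#'   columns `cosine_00`...
#' @export
dct_highpass_basis <- function(n_frames, tr_s, cutoff_hz = 0.01) {
  stopifnot(n_frames >= 4)
  K <- floor(2 * n_frames * tr_s * cutoff_hz)
  if (K >= n_frames / 2)
    stop("cutoff too high: ", K, " DCT columns for ", n_frames, " frames")
  t <- seq_len(n_frames) - 1
  out <- matrix(0, n_frames, K)
  for (k in seq_len(K))
    out[, k] <- sqrt(2 / n_frames) * cos(pi * (2 * t + 1) * k / (2 * n_frames))
  if (K) colnames(out) <- sprintf("cosine_%02d", seq_len(K) - 1L)
  out
}

#' Assemble the full confound matrix for one run
#'
#' Combines the 24-parameter motion expansion, aCompCor components, spike
#' regressors and the DCT high-pass basis, with fMRIPrep-style column names,
#' plus the FD and standardized DVARS diagnostic series as attributes.
#'
#' @param motion 6-column motion matrix (translations mm, rotations rad).
#' @param bold a [bold4d] object (for DVARS and aCompCor).
#' @param noise_mask logical 3D noise-region mask for aCompCor.
#' @param fd_thresh,dvars_thresh spike thresholds (defaults 1 mm / 2).
#' @param cutoff_hz high-pass cutoff (default 0.01 Hz).
#' @param n_acompcor number of aCompCor components (default 5).
#' @return object of class `confound_matrix`: list with `x` (T x K matrix),
#'   `fd`, `dvars` series.
#' @export
build_confound_matrix <- function(motion, bold, noise_mask,
                                  fd_thresh = 1.0, dvars_thresh = 2.0,
                                  cutoff_hz = 0.01, n_acompcor = 5) {
  m24 <- motion_expansion(motion)
  fd <- framewise_displacement(motion)
  dv <- dvars(bold)
  cc <- acompcor(bold, noise_mask, n_acompcor)
  sp <- spike_regressors(fd, dv$std, fd_thresh, dvars_thresh)
  dct <- dct_highpass_basis(dim(bold$data)[4], bold$tr_s, cutoff_hz)
  x <- cbind(m24, cc, sp, dct)
  structure(list(x = x, fd = fd, dvars = dv$std), class = "confound_matrix")
}

#' Write a confound matrix as TSV
#' @param cm a `confound_matrix`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
save_confound_matrix <- function(cm, path) {
  df <- as.data.frame(cm$x)
  df$framewise_displacement <- cm$fd
  df$std_dvars <- cm$dvars
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
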