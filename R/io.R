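# NIfTI and TSV sidecar I/O, plus Gaussian smoothing.

#' Construct a 4D BOLD container
#'
#' Holds a 4D BOLD array together with its voxel-to-world affine, repetition
#' time and an analysis mask on the same grid.
#'
#' @param data 4D numeric array (x, y, z, t).
#' @param affine 4x4 voxel-to-world transform (NIfTI convention, 0-based
#'   voxel indices).
#' @param tr_s repetition time in seconds (> 0).
#' @param mask logical 3D array on the same grid; defaults to all-TRUE.
#' @return an object of class `bold4d`.
#' @export
bold4d <- function(data, affine = diag(4), tr_s, mask = NULL) {
  if (length(dim(data)) != 4L)
    stop("BOLD data must be 4-dimensional (x, y, z, t), got ",
         length(dim(data)), " dimensions")
  if (dim(data)[4] < 2L) stop("BOLD data must have at least 2 frames")
  if (!is.numeric(tr_s) || length(tr_s) != 1L || !is.finite(tr_s) || tr_s <= 0)
    stop("tr_s must be a single positive number; ",
         "if the NIfTI header lacks a TR, pass tr_s explicitly")
  grid <- dim(data)[1:3]
  if (is.null(mask)) mask <- array(TRUE, grid)
  if (!identical(dim(mask), as.integer(grid)))
    stop("mask grid does not match data grid")
  mask <- array(as.logical(mask), grid)
  if (any(!is.finite(data[rep(mask, dim(data)[4])])))
    stop("non-finite values inside mask")
  structure(list(data = data, affine = unname(affine), tr_s = tr_s, mask = mask),
            class = "bold4d")
}

#' @export
print.bold4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold4d> grid %dx%dx%d, %d frames, TR %.3g s, %d mask voxels\n",
              d[1], d[2], d[3], d[4], x$tr_s, sum(x$mask)))
  invisible(x)
}

#' Read a 4D BOLD NIfTI file
#'
#' @param path NIfTI-1 file (.nii or .nii.gz).
#' @param tr_s optional TR override in seconds; by default the header
#'   time-step field is used and must be positive.
#' @param mask optional logical 3D array.
#' @return a [bold4d] object.
#' @export
load_bold <- function(path, tr_s = NULL, mask = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    stop("expected a 4D BOLD image, got ", length(d), " dimensions: ", path)
  header_tr <- RNifti::pixdim(img)[4]
  if (is.null(tr_s)) {
    if (!is.finite(header_tr) || header_tr <= 0)
      stop("NIfTI header has missing/zero TR; pass tr_s explicitly: ", path)
    tr_s <- header_tr
  }
  bold4d(array(as.numeric(img), dim = d),
         affine = matrix(as.numeric(RNifti::xform(img)), 4, 4),
         tr_s = tr_s, mask = mask)
}

#' Write a 4D BOLD container as NIfTI
#'
#' Data are stored as float32; the affine goes to the qform and the TR to the
#' header time-step field, so `load_bold(save_bold(x))` round-trips.
#'
#' @param bold a [bold4d] object.
#' @param path output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
save_bold <- function(bold, path) {
  stopifnot(inherits(bold, "bold4d"))
  img <- RNifti::asNifti(bold$data)
  vox <- voxel_sizes(bold$affine)
  RNifti::`pixdim<-`(img, c(vox, bold$tr_s)) -> img
  RNifti::`qform<-`(img, structure(bold$affine, code = 2L)) -> img
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

# Voxel sizes (mm) from the affine's column norms; errors on shear.
voxel_sizes <- function(affine, tol = 1e-6) {
  m <- affine[1:3, 1:3]
  sizes <- sqrt(colSums(m^2))
  if (any(sizes <= 0)) stop("degenerate affine: zero-length voxel axis")
  g <- crossprod(m / rep(sizes, each = 3))
  if (max(abs(g - diag(3))) > tol)
    stop("affine has shear/oblique axes; smoothing supports orthogonal axes only")
  sizes
}

#' Read an event table
#'
#' Tab-separated with columns `onset`, `duration`, `trial_type` and, for
#' stimulation rows, `odorant` and `outcome` (hit/miss, case-insensitive).
#'
#' @param path events TSV.
#' @return validated data.frame (an event table); unknown columns preserved.
#' @export
load_events <- function(path) {
  ev <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  validate_events(ev, context = path)
}

validate_events <- function(ev, context = "events") {
  required <- c("onset", "duration", "trial_type")
  missing <- setdiff(required, names(ev))
  if (length(missing))
    stop("missing required column(s) in ", context, ": ",
         paste(missing, collapse = ", "))
  if (is.unsorted(ev$onset))
    stop("event onsets must be nondecreasing: ", context)
  if (any(ev$duration <= 0))
    stop("event durations must be positive: ", context)
  if ("outcome" %in% names(ev)) {
    ev$outcome <- tolower(as.character(ev$outcome))
    stim <- ev$trial_type == "stim"
    bad <- stim & !(ev$outcome %in% c("hit", "miss"))
    if (any(bad))
      stop("stim rows must have outcome hit/miss: ", context)
  } else if (any(ev$trial_type == "stim")) {
    stop("missing required column(s) in ", context, ": outcome")
  }
  ev
}

#' Read a confounds table (motion parameters)
#'
#' @param path TSV with at least the six rigid-body columns
#'   `trans_x`, `trans_y`, `trans_z`, `rot_x`, `rot_y`, `rot_z`
#'   (translations mm, rotations rad).
#' @return data.frame; unknown columns preserved.
#' @export
load_confounds <- function(path) {
  cf <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  required <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  missing <- setdiff(required, names(cf))
  if (length(missing))
    stop("missing required column(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  cf
}

#' Read the participants covariate table
#'
#' @param path TSV with columns `subject`, `apoe4` (0/1), `sdoit` (0-8),
#'   `familiarity` (1-10), `age`, `sex` (0/1).
#' @return data.frame.
#' @export
load_participants <- function(path) {
  pp <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  required <- c("subject", "apoe4", "sdoit", "familiarity", "age", "sex")
  missing <- setdiff(required, names(pp))
  if (length(missing))
    stop("missing required column(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  pp
}

#' Spatial Gaussian smoothing of a 4D BOLD image
#'
#' Per-frame separable 3D Gaussian smoothing with the kernel width given as
#' full width at half maximum in millimetres; per-axis sigma in voxels is
#' `fwhm / (2 sqrt(2 log 2)) / voxel_size`. Boundaries use nearest-neighbour
#' extension so constants are preserved exactly.
#'
#' @param bold a [bold4d] object.
#' @param fwhm_mm kernel FWHM in mm (>= 0); 0 is the identity.
#' @return a smoothed [bold4d].
#' @export
smooth_gaussian <- function(bold, fwhm_mm) {
  stopifnot(inherits(bold, "bold4d"), fwhm_mm >= 0)
  if (fwhm_mm == 0) return(bold)
  vox <- voxel_sizes(bold$affine)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / vox
  d <- dim(bold$data)
  mats <- lapply(1:3, function(ax) conv_matrix(d[ax], sigma[ax]))
  out <- bold$data
  # contract each spatial axis with its 1D kernel matrix
  for (ax in 1:3) {
    perm <- c(ax, setdiff(1:4, ax))
    x <- aperm(out, perm)
    dm <- dim(x)
    x <- mats[[ax]] %*% matrix(x, nrow = dm[1])
    dim(x) <- dm
    out <- aperm(x, order(perm))
  }
  bold4d(out, affine = bold$affine, tr_s = bold$tr_s, mask = bold$mask)
}

# n x n 1D Gaussian convolution matrix with nearest-neighbour padding:
# out-of-range taps are clamped to the boundary sample, so rows sum to 1.
conv_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- max(1L, ceiling(4 * sigma))
  w <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  w <- w / sum(w)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- pmin(pmax(i + seq(-r, r), 1L), n)
    for (k in seq_along(idx)) m[i, idx[k]] <- m[i, idx[k]] + w[k]
  }
  m
}
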