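# Group spatial ICA: MDL order estimation, two-stage PCA reduction, infomax
# unmixing, ICASSO stability selection, GICA3 back-reconstruction, z-scaling.

#' Estimate the number of components by minimum description length
#'
#' Classic MDL (Wax-Kailath) on the eigenvalues of the temporal covariance:
#' `MDL(k) = -N (p - k) log(g_k / a_k) + k (2p - k + 1)/2 log N`, where `g_k`
#' and `a_k` are the geometric and arithmetic means of the trailing
#' eigenvalues, `p` the number of time points and `N` the effective number of
#' samples (voxels by default). Returns the `k >= 1` minimizing the
#' criterion. Scale-invariant: rescaling the data leaves the estimate
#' unchanged.
#'
#' @param data_matrix T x V matrix (time x voxels), or a precomputed
#'   eigenvalue vector via `eigenvalues`.
#' @param n_samples_effective effective sample count N (default: V).
#' @param eigenvalues optional eigenvalues of the T x T covariance, sorted
#'   decreasing (bypasses `data_matrix`).
#' @return integer component count.
#' @export
estimate_order_mdl <- function(data_matrix = NULL, n_samples_effective = NULL,
                               eigenvalues = NULL) {
  if (is.null(eigenvalues)) {
    x <- data_matrix - rowMeans(data_matrix)
    N <- n_samples_effective %||% ncol(x)
    eigenvalues <- sort(eigen(tcrossprod(x) / ncol(x), symmetric = TRUE,
                              only.values = TRUE)$values, decreasing = TRUE)
  } else {
    N <- n_samples_effective %||% stop("n_samples_effective required with eigenvalues")
  }
  lam <- eigenvalues
  floor_val <- max(lam) * 1e-12
  if (any(lam <= floor_val)) {
    warning("near-zero trailing eigenvalues truncated for MDL")
    lam <- pmax(lam, floor_val)
  }
  p <- length(lam)
  mdl <- vapply(seq_len(p - 1), function(k) {
    tail_lam <- lam[(k + 1):p]
    g <- exp(mean(log(tail_lam)))
    a <- mean(tail_lam)
    -N * (p - k) * log(g / a) + 0.5 * k * (2 * p - k + 1) * log(N)
  }, 0)
  which.min(mdl)
}

#' Two-stage PCA reduction for group ICA
#'
#' Stage 1 reduces each subject's time dimension to the top `l1` principal
#' directions; the reduced data are concatenated across subjects on the time
#' axis and stage 2 reduces to `c` dimensions with whitening. All projection
#' matrices are retained for GICA3 back-reconstruction.
#'
#' @param subject_matrices list of T x V matrices (concatenated runs per
#'   subject); voxel count must agree.
#' @param l1 subject-level dimension (`>= c`, `<=` frames).
#' @param c group-level dimension.
#' @return object of class `ica_reduction`: `z` (c x V whitened group
#'   matrix, `z %*% t(z) / V = I`), `f` (subject projections, T x l1), `y`
#'   (reduced subject data, l1 x V each), `e` (group eigenvectors N*l1 x c),
#'   `lambda` (c group eigenvalues), `group_eigenvalues` (full spectrum).
#' @export
two_stage_pca <- function(subject_matrices, l1, c) {
  stopifnot(l1 >= c)
  n <- length(subject_matrices)
  f <- y <- vector("list", n)
  for (i in seq_len(n)) {
    x <- subject_matrices[[i]]
    if (nrow(x) < l1) stop("subject ", i, " has ", nrow(x),
                           " frames; l1 = ", l1, " too large")
    x <- x - matrix(colMeans(x), nrow(x), ncol(x), byrow = TRUE)  # center voxel ts
    s <- svd(x, nu = l1, nv = 0)
    f[[i]] <- s$u[, seq_len(l1), drop = FALSE]
    y[[i]] <- crossprod(f[[i]], x)          # l1 x V
  }
  ys <- do.call(rbind, y)                   # (n*l1) x V
  eg <- eigen(tcrossprod(ys), symmetric = TRUE)
  lambda <- eg$values[seq_len(c)]
  if (any(lambda <= 0)) stop("group covariance rank below requested order ", c)
  e <- eg$vectors[, seq_len(c), drop = FALSE]
  v_dim <- ncol(ys)
  z <- sqrt(v_dim) * (1 / sqrt(lambda)) * crossprod(e, ys) # c x V, z z'/V = I
  structure(list(z = z, f = f, y = y, e = e, lambda = lambda,
                 group_eigenvalues = eg$values, l1 = l1, c = c,
                 n_subjects = n),
            class = "ica_reduction")
}

#' Infomax independent components analysis
#'
#' Natural-gradient infomax with the logistic nonlinearity (super-Gaussian
#' sources, the standard choice for sparse spatial fMRI maps). The learning
#' rate anneals when successive update directions turn by more than 60
#' degrees; iteration stops when the Frobenius norm of the natural-gradient
#' factor drops below `tol` or at `max_steps`. On divergence the run
#' restarts with a halved rate (up to 3 restarts).
#'
#' @param whitened c x V whitened matrix (rows uncorrelated, unit scale).
#' @param seed RNG seed for the random orthonormal initial unmixing matrix.
#' @param lr initial learning rate.
#' @param max_steps iteration cap (default 512).
#' @param tol stopping tolerance on the natural-gradient norm (default 1e-6).
#' @return list with `w` (c x c unmixing), `s` (= `w %*% whitened` sources),
#'   `steps`, `converged`.
#' @export
infomax_ica <- function(whitened, seed, lr = 0.05, max_steps = 512,
                        tol = 1e-6) {
  c_dim <- nrow(whitened)
  v <- ncol(whitened)
  set.seed(seed)
  w0 <- qr.Q(qr(matrix(stats::rnorm(c_dim^2), c_dim)))
  for (restart in 0:3) {
    w <- w0
    rate <- lr / 2^restart
    prev_dir <- NULL
    converged <- FALSE
    steps <- 0L
    diverged <- FALSE
    repeat {
      steps <- steps + 1L
      u <- w %*% whitened
      g <- 1 / (1 + exp(-u))
      phi <- diag(c_dim) + ((1 - 2 * g) %*% t(u)) / v  # natural-gradient factor
      gnorm <- sqrt(sum(phi^2))
      if (gnorm < tol) { converged <- TRUE; break }
      dir <- phi %*% w
      # anneal when successive updates turn by more than 60 degrees
      if (!is.null(prev_dir)) {
        cosang <- sum(dir * prev_dir) /
          sqrt(sum(dir^2) * sum(prev_dir^2) + 1e-300)
        rate <- if (cosang < 0.5) rate * 0.9 else min(rate * 1.02, lr)
      }
      prev_dir <- dir
      w_new <- w + rate * dir
      if (!all(is.finite(w_new)) || max(abs(w_new)) > 1e6) {  # diverged
        diverged <- TRUE; break
      }
      w <- w_new
      if (steps >= max_steps) break
    }
    if (!diverged)
      return(list(w = w, s = w %*% whitened, steps = steps,
                  converged = converged))
  }
  stop("infomax diverged after 3 restarts")
}

#' ICASSO stability selection
#'
#' Runs infomax `n_runs` times from different random initializations, pools
#' all component estimates, clusters them by average-linkage agglomeration on
#' `1 - |correlation|`, and returns per cluster the centrotype (the estimate
#' with the largest within-cluster similarity sum) and the quality index
#' `Iq = mean within-cluster similarity - mean between-cluster similarity`.
#'
#' @param whitened c x V whitened group matrix.
#' @param c number of components.
#' @param n_runs number of ICA repetitions (default 10).
#' @param base_seed seed; run r uses `base_seed + r - 1`.
#' @param ... passed to [infomax_ica].
#' @return list with `s` (c x V centrotype sources), `w` (c x c assembled
#'   unmixing, rows are the centrotypes' unmixing rows), `iq` (c quality
#'   indices), `cluster` (pooled-estimate cluster assignment).
#' @export
icasso <- function(whitened, c, n_runs = 10, base_seed = 1, ...) {
  stopifnot(n_runs >= 2)
  runs <- lapply(seq_len(n_runs), function(r)
    infomax_ica(whitened, seed = base_seed + r - 1, ...))
  pooled_s <- do.call(rbind, lapply(runs, `[[`, "s"))    # (c*R) x V
  pooled_w <- do.call(rbind, lapply(runs, `[[`, "w"))    # (c*R) x c
  sim <- abs(stats::cor(t(pooled_s)))
  hc <- stats::hclust(stats::as.dist(1 - sim), method = "average")
  cl <- stats::cutree(hc, k = c)
  counts <- tabulate(cl, c)
  if (any(counts == 0)) {
    warning("empty ICASSO cluster; reducing order to ", sum(counts > 0))
    keep <- which(counts > 0)
    cl <- match(cl, keep)
    c <- length(keep)
  }
  centro <- integer(c); iq <- numeric(c)
  for (k in seq_len(c)) {
    members <- which(cl == k)
    within <- sim[members, members, drop = FALSE]
    centro[k] <- members[which.max(rowSums(within))]
    between <- sim[members, setdiff(seq_len(nrow(sim)), members), drop = FALSE]
    iq[k] <- mean(within) - if (ncol(between)) mean(between) else 0
  }
  ord <- order(iq, decreasing = TRUE)
  centro <- centro[ord]; iq <- iq[ord]
  list(s = pooled_s[centro, , drop = FALSE],
       w = pooled_w[centro, , drop = FALSE],
       iq = iq, cluster = cl, centrotypes = centro)
}

#' GICA3 back-reconstruction of subject maps and time courses
#'
#' Subject time courses come from the subject's partition of the group
#' projection composed with the subject-level de-whitening,
#' `R_i = F_i E_i Lambda^{1/2} W^{-1}`; subject maps use the GICA3
#' partitioned projection `S_i = N W Lambda^{-1/2} E_i' Y_i`, whose defining
#' property is that the mean over subjects of the subject maps equals the
#' aggregate map exactly.
#'
#' @param reduction an `ica_reduction` from [two_stage_pca].
#' @param w c x c unmixing matrix (from [infomax_ica] or [icasso]).
#' @return list with `subject_maps` (list of c x V), `subject_timecourses`
#'   (list of T x c), `aggregate_maps` (c x V = `w %*% z`).
#' @export
gica3_backreconstruct <- function(reduction, w) {
  stopifnot(inherits(reduction, "ica_reduction"))
  n <- reduction$n_subjects
  l1 <- reduction$l1
  c_dim <- reduction$c
  w_inv <- solve(w)
  lam_sqrt <- sqrt(reduction$lambda)
  v_dim <- ncol(reduction$z)
  maps <- tcs <- vector("list", n)
  for (i in seq_len(n)) {
    rows <- (i - 1) * l1 + seq_len(l1)
    e_i <- reduction$e[rows, , drop = FALSE]          # l1 x c
    maps[[i]] <- n * sqrt(v_dim) *
      (w %*% ((1 / lam_sqrt) * crossprod(e_i, reduction$y[[i]])))
    a_i <- e_i %*% ((lam_sqrt / sqrt(v_dim)) * w_inv) # l1 x c (de-whitening)
    tcs[[i]] <- reduction$f[[i]] %*% a_i              # T x c
  }
  list(subject_maps = maps, subject_timecourses = tcs,
       aggregate_maps = w %*% reduction$z)
}

#' Z-score spatial maps over a mask
#'
#' Per map: subtract the in-mask mean and divide by the in-mask SD; the sign
#' is fixed so the voxel of maximum absolute value is positive (deterministic
#' resolution of the ICA sign ambiguity).
#'
#' @param maps C x V matrix.
#' @param mask logical vector of length V (default: all voxels).
#' @return list with `maps` (z-scored C x V) and `signs` (the +-1 flips
#'   applied, to be propagated to time courses).
#' @export
zscore_maps <- function(maps, mask = NULL) {
  mask <- mask %||% rep(TRUE, ncol(maps))
  mask <- as.logical(mask)
  if (!any(mask)) stop("empty mask")
  out <- maps
  signs <- numeric(nrow(maps))
  for (k in seq_len(nrow(maps))) {
    v <- maps[k, mask]
    s <- stats::sd(v)
    if (s == 0) stop("zero-variance map ", k)
    z <- (maps[k, ] - mean(v)) / s
    signs[k] <- if (z[mask][which.max(abs(z[mask]))] < 0) -1 else 1
    out[k, ] <- signs[k] * z
  }
  list(maps = out, signs = signs)
}

#' Group spatial ICA of a multi-subject BOLD cohort
#'
#' End-to-end wrapper: stacks each subject's runs, estimates the order by MDL
#' (or uses a fixed order), reduces with two-stage PCA, runs ICASSO-stabilized
#' infomax, back-reconstructs subject maps/time courses with GICA3 and
#' z-scores the aggregate maps over the mask.
#'
#' @param bold_list list (subjects) of lists (runs) of [bold4d] objects.
#' @param order integer component count, or `"mdl"` (default) to estimate.
#' @param l1 subject-level PCA dimension (default `round(1.5 * order)`).
#' @param icasso_runs ICA repetitions for stability (default 10).
#' @param seed RNG seed.
#' @param mdl_n_effective effective sample size for MDL order estimation
#'   (default: the in-mask voxel count). Smoothed data have spatially
#'   correlated noise, which inflates MDL orders; passing a resel count
#'   (voxels / kernel volume in voxels) restores sensible estimates.
#' @param ... passed to [infomax_ica].
#' @return object of class `component_set`: `order`, `aggregate_maps`
#'   (C x V z-scored), `aggregate_maps_raw`, `subject_maps`,
#'   `subject_timecourses` (sign-aligned with the maps), `stability_iq`,
#'   `reduction`, `mask`, `grid`, `run_frames`.
#' @export
group_ica <- function(bold_list, order = "mdl", l1 = NULL, icasso_runs = 10,
                      seed = 1, mdl_n_effective = NULL, ...) {
  grid <- dim(bold_list[[1]][[1]]$data)[1:3]
  mask <- bold_list[[1]][[1]]$mask
  run_frames <- vapply(bold_list[[1]], function(b) dim(b$data)[4], 0L)
  mats <- lapply(bold_list, function(runs) {
    do.call(rbind, lapply(runs, function(b) {
      d <- dim(b$data)
      t(matrix(b$data, prod(d[1:3]), d[4])[as.vector(mask), , drop = FALSE])
    }))
  })
  if (identical(order, "mdl")) {
    # per-subject estimates aggregated by the median (frames <= voxels holds
    # per subject, unlike for the temporally stacked group matrix)
    order <- round(stats::median(vapply(mats, function(m)
      estimate_order_mdl(m, n_samples_effective = mdl_n_effective), 0L)))
  }
  order <- as.integer(order)
  l1 <- l1 %||% min(round(1.5 * order), min(vapply(mats, nrow, 0L)))
  red <- two_stage_pca(mats, l1 = l1, c = order)
  ic <- icasso(red$z, c = order, n_runs = icasso_runs, base_seed = seed, ...)
  back <- gica3_backreconstruct(red, ic$w)
  zs <- zscore_maps(back$aggregate_maps)
  subject_tcs <- lapply(back$subject_timecourses, function(tc)
    sweep(tc, 2, zs$signs, "*"))
  subject_maps <- lapply(back$subject_maps, function(m) zs$signs * m)
  structure(list(order = order, aggregate_maps = zs$maps,
                 aggregate_maps_raw = back$aggregate_maps,
                 subject_maps = subject_maps,
                 subject_maps_raw = back$subject_maps,
                 subject_timecourses = subject_tcs,
                 stability_iq = ic$iq, reduction = red, unmixing = ic$w,
                 signs = zs$signs, mask = mask, grid = grid,
                 run_frames = run_frames),
            class = "component_set")
}

#' @export
print.component_set <- function(x, ...) {
  cat(sprintf("<component_set> %d components, %d subjects, %d mask voxels\n",
              x$order, length(x$subject_maps), sum(x$mask)))
  cat("  stability Iq:", paste(sprintf("%.2f", x$stability_iq), collapse = " "),
      "\n")
  invisible(x)
}

#' Unflatten a component map row into a 3D volume on the mask grid
#' @param cs a `component_set`.
#' @param k component index.
#' @param aggregate use aggregate (TRUE) or a subject map via `subject`.
#' @param subject subject index when `aggregate = FALSE`.
#' @return 3D array with NA outside the mask.
#' @export
component_volume <- function(cs, k, aggregate = TRUE, subject = 1) {
  v <- array(NA_real_, cs$grid)
  row <- if (aggregate) cs$aggregate_maps[k, ] else cs$subject_maps[[subject]][k, ]
  v[cs$mask] <- row
  v
}
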