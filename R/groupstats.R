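# Group-level inference: one-sample t maps, moderated multiple regression
# with ApoE x identification x familiarity interactions, cluster-extent
# thresholding, marginal means.

#' Build the moderated group regression design
#'
#' Ten columns: intercept, ApoE e4 status (0/1), centered identification
#' score, centered familiarity, sex (0/1), centered age, and the interaction
#' terms ApoE x SDOIT, ApoE x familiarity, SDOIT x familiarity and
#' ApoE x SDOIT x familiarity. Continuous predictors are mean-centered
#' before products are formed; the binary ApoE and sex columns are not
#' centered.
#'
#' @param participants data.frame with `apoe4`, `sdoit`, `familiarity`,
#'   `age`, `sex` (see [load_participants]); rows with missing covariates are
#'   dropped with a message.
#' @param center center continuous predictors (default TRUE).
#' @return object of class `group_design`: `x` (n x 10 matrix), `kept`
#'   (row indices used), `means` (centering constants), `sds`.
#' @export
group_design <- function(participants, center = TRUE) {
  need <- c("apoe4", "sdoit", "familiarity", "age", "sex")
  stopifnot(all(need %in% names(participants)))
  keep <- stats::complete.cases(participants[, need])
  if (any(!keep))
    message(sum(!keep), " subject(s) removed due to missing covariates")
  p <- participants[keep, ]
  mu <- c(sdoit = mean(p$sdoit), familiarity = mean(p$familiarity),
          age = mean(p$age))
  sds <- c(sdoit = stats::sd(p$sdoit), familiarity = stats::sd(p$familiarity),
           age = stats::sd(p$age))
  ctr <- function(v, m) if (center) v - m else v
  sd_c <- ctr(p$sdoit, mu["sdoit"])
  fam_c <- ctr(p$familiarity, mu["familiarity"])
  age_c <- ctr(p$age, mu["age"])
  x <- cbind(intercept = 1, apoe = p$apoe4, sdoit = sd_c, fam = fam_c,
             sex = p$sex, age = age_c,
             apoe_x_sdoit = p$apoe4 * sd_c, apoe_x_fam = p$apoe4 * fam_c,
             sdoit_x_fam = sd_c * fam_c,
             apoe_x_sdoit_x_fam = p$apoe4 * sd_c * fam_c)
  if (qr(x)$rank < ncol(x)) {
    cc <- abs(suppressWarnings(stats::cor(x[, -1]))); diag(cc) <- 0
    cc[!is.finite(cc)] <- 1
    pair <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    stop("group design is rank deficient; aliased columns: ",
         colnames(x)[-1][pair[1]], " ~ ", colnames(x)[-1][pair[2]])
  }
  structure(list(x = x, kept = which(keep), means = mu, sds = sds,
                 center = center),
            class = "group_design")
}

#' Moderated multiple regression of an outcome on the group design
#'
#' OLS with two-tailed p-values from the t distribution with
#' `n - ncol(design)` degrees of freedom. The outcome may be a vector (one
#' value per subject, e.g. a condition beta) or a subjects x voxels matrix
#' (e.g. TMFC maps), in which case every voxel is fitted with one
#' pseudo-inverse. Subjects with missing outcome are dropped with a message.
#'
#' @param outcome numeric vector (n) or matrix (n x V).
#' @param design a `group_design`; its `kept` rows must align with `outcome`
#'   rows (outcome is subset by `design$kept` when longer).
#' @return object of class `group_fit`: `coef`, `se`, `t`, `p` (each
#'   coefficients x outcomes), `df`, `n`, `design`.
#' @export
fit_group_regression <- function(outcome, design) {
  stopifnot(inherits(design, "group_design"))
  y <- as.matrix(outcome)
  if (nrow(y) > nrow(design$x)) y <- y[design$kept, , drop = FALSE]
  if (nrow(y) != nrow(design$x))
    stop("outcome rows (", nrow(y), ") do not match design rows (",
         nrow(design$x), ")")
  ok <- apply(is.finite(y), 1, all)
  x <- design$x
  if (any(!ok)) {
    message(sum(!ok), " subject(s) removed due to missing outcome")
    y <- y[ok, , drop = FALSE]; x <- x[ok, , drop = FALSE]
  }
  n <- nrow(x); k <- ncol(x)
  if (n <= k) stop("need more subjects (", n, ") than design columns (", k, ")")
  xtx_inv <- solve(crossprod(x))
  beta <- xtx_inv %*% crossprod(x, y)
  resid <- y - x %*% beta
  df <- n - k
  sigma2 <- colSums(resid^2) / df
  se <- sqrt(outer(diag(xtx_inv), sigma2))
  tt <- beta / se
  tt[se == 0] <- 0
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  dimnames(beta) <- dimnames(se) <- dimnames(tt) <- dimnames(p) <-
    list(colnames(x), colnames(y))
  structure(list(coef = beta, se = se, t = tt, p = p, df = df, n = n,
                 design = design),
            class = "group_fit")
}

#' @export
print.group_fit <- function(x, ...) {
  cat(sprintf("<group_fit> n = %d, df = %d, %d outcome(s)\n",
              x$n, x$df, ncol(x$coef)))
  if (ncol(x$coef) == 1) {
    tab <- data.frame(coef = x$coef[, 1], se = x$se[, 1], t = x$t[, 1],
                      p = x$p[, 1])
    print(round(tab, 4))
  }
  invisible(x)
}

#' One-sample t map of subject spatial maps
#'
#' Per voxel `t = mean / (sd / sqrt(n))`, df = n - 1, two-tailed p; then
#' cluster-extent thresholded (defaults: voxel p < .0001, k >= 100).
#'
#' @param subject_maps n x V matrix of aligned subject maps.
#' @param grid 3-vector of volume dims; with `mask`, maps voxel columns into
#'   the volume.
#' @param mask logical vector of length `prod(grid)` (default all TRUE).
#' @param p_voxel voxel-level threshold (default 1e-4).
#' @param k_min cluster-extent threshold (default 100).
#' @param connectivity 6, 18 or 26 (default 26).
#' @return a `stat_map` (see [cluster_threshold]).
#' @export
one_sample_tmap <- function(subject_maps, grid, mask = NULL, p_voxel = 1e-4,
                            k_min = 100, connectivity = 26) {
  m <- as.matrix(subject_maps)
  n <- nrow(m)
  if (n < 3) stop("one-sample t map needs >= 3 subjects")
  mu <- colMeans(m)
  sdv <- apply(m, 2, stats::sd)
  tt <- rep(0, length(mu)); pv <- rep(1, length(mu))
  pos <- sdv > 0
  tt[pos] <- mu[pos] / (sdv[pos] / sqrt(n))
  pv[pos] <- 2 * stats::pt(abs(tt[pos]), n - 1, lower.tail = FALSE)
  # zero-variance, nonzero-mean voxels are degenerate: flag at the boundary
  degen <- !pos & mu != 0
  pv[degen] <- .Machine$double.xmin
  tt[degen] <- Inf * sign(mu[degen])
  cluster_threshold(stat = tt, p = pv, grid = grid, mask = mask,
                    p_voxel = p_voxel, k_min = k_min,
                    connectivity = connectivity, df = n - 1)
}

#' Cluster-extent thresholding of a statistic volume
#'
#' Binarizes `p < p_voxel` separately for positive- and negative-statistic
#' voxels, labels connected components at the requested connectivity
#' (6 faces / 18 faces+edges / 26 faces+edges+vertices), discards clusters
#' smaller than `k_min`, and emits a cluster table sorted by size.
#'
#' @param stat numeric statistic values over mask voxels.
#' @param p matching p-values.
#' @param grid 3-vector of volume dims.
#' @param mask logical vector of length `prod(grid)`; default all TRUE.
#' @param p_voxel voxel-level p threshold.
#' @param k_min minimum cluster extent in voxels.
#' @param connectivity 6, 18 or 26.
#' @param df degrees of freedom recorded in the metadata.
#' @return object of class `stat_map`: `stat`, `p` (volumes with NA outside
#'   mask), `labels` (integer cluster-label volume, 0 = background),
#'   `clusters` (data.frame: label, direction, size, peak indices, peak
#'   stat), `threshold` metadata list.
#' @export
cluster_threshold <- function(stat, p, grid, mask = NULL, p_voxel = 0.001,
                              k_min = 75, connectivity = 26, df = NA) {
  if (!connectivity %in% c(6, 18, 26))
    stop("connectivity must be 6, 18 or 26, got ", connectivity)
  V <- prod(grid)
  mask <- mask %||% rep(TRUE, V)
  mask <- as.logical(mask)
  stat_vol <- p_vol <- array(NA_real_, grid)
  stat_vol[mask] <- stat
  p_vol[mask] <- p
  labels <- array(0L, grid)
  clusters <- list()
  next_label <- 1L
  for (direction in c("positive", "negative")) {
    supra <- !is.na(p_vol) & p_vol < p_voxel &
      (if (direction == "positive") stat_vol > 0 else stat_vol < 0)
    comp <- label_components(supra, connectivity)
    for (lab in seq_len(comp$n)) {
      vox <- which(comp$labels == lab)
      if (length(vox) < k_min) next
      peak <- vox[which.max(abs(stat_vol[vox]))]
      pk <- arrayInd(peak, grid)
      labels[vox] <- next_label
      clusters[[next_label]] <- data.frame(
        label = next_label, direction = direction, size = length(vox),
        peak_x = pk[1], peak_y = pk[2], peak_z = pk[3],
        peak_stat = stat_vol[peak])
      next_label <- next_label + 1L
    }
  }
  tab <- if (length(clusters)) do.call(rbind, clusters)
         else data.frame(label = integer(0), direction = character(0),
                         size = integer(0), peak_x = integer(0),
                         peak_y = integer(0), peak_z = integer(0),
                         peak_stat = numeric(0))
  tab <- tab[order(-tab$size), ]
  rownames(tab) <- NULL
  structure(list(stat = stat_vol, p = p_vol, labels = labels, clusters = tab,
                 threshold = list(p_voxel = p_voxel, k_min = k_min,
                                  connectivity = connectivity, df = df)),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  th <- x$threshold
  cat(sprintf("<stat_map> voxel p < %g, k >= %d, connectivity %d: %d cluster(s)\n",
              th$p_voxel, th$k_min, th$connectivity, nrow(x$clusters)))
  if (nrow(x$clusters)) print(utils::head(x$clusters, 10))
  invisible(x)
}

# Connected-component labeling of a logical volume by breadth-first search.
label_components <- function(supra, connectivity) {
  grid <- dim(supra)
  offs <- connectivity_offsets(connectivity)
  labels <- array(0L, grid)
  n <- 0L
  idx_all <- which(supra)
  for (start in idx_all) {
    if (labels[start] != 0L) next
    n <- n + 1L
    queue <- start
    labels[start] <- n
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      co <- arrayInd(cur, grid)
      for (k in seq_len(nrow(offs))) {
        nb <- co + offs[k, ]
        if (any(nb < 1L) || any(nb > grid)) next
        lin <- nb[1] + (nb[2] - 1L) * grid[1] + (nb[3] - 1L) * grid[1] * grid[2]
        if (supra[lin] && labels[lin] == 0L) {
          labels[lin] <- n
          queue <- c(queue, lin)
        }
      }
    }
  }
  list(labels = labels, n = n)
}

connectivity_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  d <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = d == 1, "18" = d >= 1 & d <= 2, "26" = d >= 1)
  g[keep, , drop = FALSE]
}

#' Marginal means of the moderated regression
#'
#' Predicted outcomes over a grid of identification scores at familiarity one
#' SD below and above the mean, for carriers and non-carriers, with age at
#' its mean and sex weighted 0.5 — the standard simple-slopes display for a
#' three-way interaction.
#'
#' @param fit a `group_fit` with a single outcome.
#' @param sdoit_values identification scores to predict at (default 0..8).
#' @param familiarity_sd multiples of the familiarity SD (default `c(-1, 1)`).
#' @return data.frame: `sdoit`, `familiarity`, `familiarity_group`, `apoe`,
#'   `predicted`, `extrapolated` (outside the observed covariate ranges).
#' @export
marginal_means <- function(fit, sdoit_values = 0:8,
                           familiarity_sd = c(-1, 1)) {
  stopifnot(inherits(fit, "group_fit"), ncol(fit$coef) == 1)
  des <- fit$design
  mu <- des$means; sds <- des$sds
  fam_vals <- mu["familiarity"] + familiarity_sd * sds["familiarity"]
  gr <- expand.grid(sdoit = sdoit_values, familiarity = fam_vals,
                    apoe = c(0, 1))
  gr$familiarity_group <- ifelse(gr$familiarity < mu["familiarity"],
                                 "low", "high")
  sd_c <- gr$sdoit - if (des$center) mu["sdoit"] else 0
  fam_c <- gr$familiarity - if (des$center) mu["familiarity"] else 0
  x <- cbind(1, gr$apoe, sd_c, fam_c, 0.5, 0,
             gr$apoe * sd_c, gr$apoe * fam_c, sd_c * fam_c,
             gr$apoe * sd_c * fam_c)
  gr$predicted <- as.numeric(x %*% fit$coef[, 1])
  rng_s <- range(des$x[, "sdoit"]) + if (des$center) mu["sdoit"] else 0
  rng_f <- range(des$x[, "fam"]) + if (des$center) mu["familiarity"] else 0
  gr$extrapolated <- gr$sdoit < rng_s[1] | gr$sdoit > rng_s[2] |
    gr$familiarity < rng_f[1] | gr$familiarity > rng_f[2]
  gr[, c("sdoit", "familiarity", "familiarity_group", "apoe", "predicted",
         "extrapolated")]
}
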