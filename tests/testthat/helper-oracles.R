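# Independent oracles and small fixture builders used across the suite.

# Textbook normal-equations OLS, independent of the package's pinv path.
naive_ols <- function(x, y) solve(crossprod(x), crossprod(x, y))

# Connected-component labeling by iterative label propagation (minimum-label
# relaxation until fixpoint) -- an algorithm independent of the package's BFS.
flood_fill_oracle <- function(supra, connectivity) {
  grid <- dim(supra)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  d <- rowSums(abs(offs))
  offs <- offs[switch(as.character(connectivity),
                      "6" = d == 1, "18" = d >= 1 & d <= 2, "26" = d >= 1), ,
               drop = FALSE]
  lab <- array(0L, grid)
  lab[supra] <- seq_len(sum(supra))
  idx <- which(supra)
  co <- arrayInd(idx, grid)
  repeat {
    changed <- FALSE
    for (i in seq_along(idx)) {
      cur <- lab[idx[i]]
      for (k in seq_len(nrow(offs))) {
        nb <- co[i, ] + offs[k, ]
        if (any(nb < 1L) || any(nb > grid)) next
        lin <- nb[1] + (nb[2] - 1L) * grid[1] + (nb[3] - 1L) * grid[1] * grid[2]
        if (supra[lin] && lab[lin] < cur) { cur <- lab[lin]; changed <- TRUE }
      }
      lab[idx[i]] <- cur
    }
    if (!changed) break
  }
  lab
}

# Two labelings describe the same partition iff the label pairing is 1-1.
same_partition <- function(a, b) {
  ia <- a[a > 0 | b > 0]; ib <- b[a > 0 | b > 0]
  if (any((ia > 0) != (ib > 0))) return(FALSE)
  tab <- table(ia, ib)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

# Small fast cohort spec for unit tests (one run, 12^3 grid, 72 frames).
tiny_spec <- function(...) {
  args <- list(n_subjects = 2, grid = c(12, 12, 12), n_runs = 1,
               reps_per_run = 1)
  args[names(list(...))] <- list(...)
  do.call(cohort_spec, args)
}

# A minimal valid event table.
make_events <- function(onsets, durations = 16, outcomes = "hit",
                        trial_type = "stim") {
  data.frame(onset = onsets, duration = durations, trial_type = trial_type,
             odorant = seq_along(onsets), outcome = outcomes)
}
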