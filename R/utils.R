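# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Moore-Penrose pseudo-inverse via SVD
#' @param x numeric matrix.
#' @param tol singular values below `tol * max(d)` are treated as zero.
#' @return the pseudo-inverse of `x`.
#' @keywords internal
pinv <- function(x, tol = 1e-10) {
  s <- svd(x)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) return(matrix(0, ncol(x), nrow(x)))
  s$v[, keep, drop = FALSE] %*%
    ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}

# Derive a child RNG seed from a base seed; kept within 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483629)
}

#' Match estimated to reference components by absolute correlation
#'
#' Resolves the permutation ambiguity of ICA when comparing recovered spatial
#' maps to a reference set. For small numbers of components (<= 8) the exact
#' assignment maximizing the total absolute correlation is found by
#' enumerating permutations; beyond that a greedy assignment is used.
#'
#' @param est matrix, components in rows (C_est x V).
#' @param ref matrix, components in rows (C_ref x V); requires C_est >= C_ref.
#' @return data.frame with columns `ref`, `est`, `abs_r`.
#' @export
match_components <- function(est, ref) {
  ce <- nrow(est); cr <- nrow(ref)
  stopifnot(ce >= cr, ncol(est) == ncol(ref))
  r <- abs(stats::cor(t(ref), t(est)))  # cr x ce
  if (ce <= 8) {
    perms <- all_injections(cr, ce)
    scores <- vapply(perms, function(p) sum(r[cbind(seq_len(cr), p)]), 0)
    best <- perms[[which.max(scores)]]
  } else {
    best <- integer(cr); avail <- rep(TRUE, ce)
    ord <- order(apply(r, 1, max), decreasing = TRUE)
    for (i in ord) {
      j <- which.max(ifelse(avail, r[i, ], -Inf))
      best[i] <- j; avail[j] <- FALSE
    }
  }
  data.frame(ref = seq_len(cr), est = best, abs_r = r[cbind(seq_len(cr), best)])
}

# All injective maps 1..k -> 1..n (k <= n), as a list of integer vectors.
all_injections <- function(k, n) {
  if (k == 0) return(list(integer(0)))
  out <- list()
  rec <- function(prefix, avail) {
    if (length(prefix) == k) { out[[length(out) + 1L]] <<- prefix; return() }
    for (j in avail) rec(c(prefix, j), setdiff(avail, j))
  }
  rec(integer(0), seq_len(n))
  out
}

# Stop with a stage-tagged message; used by the pipeline orchestrator.
stage_stop <- function(stage, subject = NULL, msg) {
  ctx <- if (is.null(subject)) stage else sprintf("%s [subject %s]", stage, subject)
  stop(sprintf("[%s] %s", ctx, msg), call. = FALSE)
}
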