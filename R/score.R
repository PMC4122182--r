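# Sufficient statistics for decomposable Gaussian BIC scoring.
# On standardized data every local regression is intercept-free, so each
# dataset is summarized by its (uncentered) second-moment matrix
# S = X'X / n and its row count; the residual variance of node j on
# parent set P is S[j,j] - S[j,P] S[P,P]^{-1} S[P,j].
suffstats <- function(datasets) {
  if (!length(datasets)) stop("need at least one dataset")
  if (inherits(datasets, "condition_dataset")) datasets <- list(datasets)
  labels <- colnames(datasets[[1L]]$matrix)
  lapply(datasets, function(ds) {
    stopifnot(inherits(ds, "condition_dataset"))
    if (!ds$standardized)
      stop("datasets must be standardized (see standardize())")
    if (!identical(colnames(ds$matrix), labels))
      stop("datasets do not share the same ROI labels/order")
    X <- ds$matrix
    list(S = crossprod(X) / nrow(X), n = nrow(X), labels = labels)
  })
}

# score of one dataset: -n log sigma2_ML - c * k * log n, k = |P| + 1
local_score_one <- function(S, n, j, P, c) {
  if (length(P) >= n - 1L)
    stop("unidentifiable regression: |parents| >= n - 1")
  sigma2 <- if (!length(P)) {
    S[j, j]
  } else if (length(P) == 1L) {
    S[j, j] - S[j, P]^2 / S[P, P]
  } else {
    # solve() via Cholesky with a ridge fallback for (near-)collinear
    # parent sets, which a candidate move may transiently propose
    Spp <- S[P, P]
    beta <- tryCatch(solve(Spp, S[P, j]),
                     error = function(e)
                       solve(Spp + diag(1e-8, length(P)), S[P, j]))
    S[j, j] - drop(crossprod(S[P, j], beta))
  }
  sigma2 <- max(sigma2, 1e-12)
  -n * log(sigma2) - c * (length(P) + 1) * log(n)
}

local_score_avg <- function(stats, j, P, c) {
  tot <- 0
  for (st in stats) tot <- tot + local_score_one(st$S, st$n, j, P, c)
  tot / length(stats)
}

#' Local penalized-likelihood (BIC) score of a node given parents
#'
#' For each per-subject dataset, the node is regressed on its candidate
#' parents by intercept-free least squares (the data being standardized);
#' with maximum-likelihood residual variance `sigma2` (divisor n) the
#' dataset's contribution is `-n * log(sigma2) - c * k * log(n)` where
#' `k = |parents| + 1` and `c` is the penalty discount.  The returned
#' score is the arithmetic mean across datasets (all subjects weighted
#' equally), the quantity the multi-subject greedy search maximizes.
#' Constants common to all models are dropped.
#'
#' @param datasets list of standardized [condition_dataset()]s (one per
#'   subject) sharing ROI labels.
#' @param node ROI label of the child.
#' @param parents character vector of parent ROI labels (may be empty).
#' @param c penalty discount (>= 1 in normal use; larger is sparser).
#' @return averaged score (unitless; larger is better).
#' @export
local_bic <- function(datasets, node, parents = character(0), c = 1) {
  stats <- suffstats(datasets)
  labels <- stats[[1L]]$labels
  j <- match(node, labels)
  P <- match(parents, labels)
  if (is.na(j) || anyNA(P)) stop("unknown ROI label")
  if (j %in% P) stop("node must not be among its parents")
  local_score_avg(stats, j, P, c)
}
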