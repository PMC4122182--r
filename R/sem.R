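#' Fit SEM path coefficients for one subject
#'
#' For a directed acyclic graph with independent errors, the
#' maximum-likelihood SEM estimate factorizes into one ordinary
#' least-squares regression of each node on its parents (intercept-free on
#' standardized data), so coefficients are obtained in closed form rather
#' than by an iterative optimizer.  Per-node residual variances
#' (maximum-likelihood, divisor n) and the Gaussian log-likelihood are
#' retained as goodness-of-fit output.
#'
#' @param g a `dag`.
#' @param ds a standardized [condition_dataset()] whose ROI labels cover
#'   the DAG's nodes.
#' @return An object of class `sem_fit`: list with `coefficients`
#'   (data frame `source`, `target`, `estimate`), `residual_variances`
#'   (named, one per node), `loglik` and `subject_id`.
#' @export
fit_subject <- function(g, ds) {
  stopifnot(inherits(g, "dag"), inherits(ds, "condition_dataset"))
  if (!ds$standardized)
    stop("dataset must be standardized (see standardize())")
  X <- ds$matrix
  missing <- setdiff(g$nodes, colnames(X))
  if (length(missing))
    stop("DAG nodes missing from dataset: ", paste(missing, collapse = ", "))
  n <- nrow(X)
  coefs <- list()
  rv <- numeric(length(g$nodes))
  names(rv) <- g$nodes
  for (v in g$nodes) {
    pa <- g$edges[g$edges[, 2L] == v, 1L]
    if (length(pa) >= n)
      stop("node ", v, " has more parents (", length(pa),
           ") than data points (", n, ")")
    if (length(pa)) {
      fit <- stats::.lm.fit(X[, pa, drop = FALSE], X[, v])
      b <- fit$coefficients
      rv[v] <- mean(fit$residuals^2)
      coefs[[v]] <- data.frame(source = pa, target = v, estimate = b)
    } else {
      rv[v] <- mean(X[, v]^2)
    }
  }
  coefficients <- if (length(coefs)) do.call(rbind, coefs) else
    data.frame(source = character(0), target = character(0),
               estimate = numeric(0))
  rownames(coefficients) <- NULL
  loglik <- -n / 2 * sum(log(2 * pi * pmax(rv, 1e-300)) + 1)
  structure(list(coefficients = coefficients,
                 residual_variances = rv,
                 loglik = loglik,
                 subject_id = ds$subject_id),
            class = "sem_fit")
}

#' Aggregate per-subject SEM fits to mean (SD) edge estimates
#'
#' @param fits list of [fit_subject()] results sharing one edge set.
#' @return An object of class `edge_estimates`: data frame with `source`,
#'   `target`, `mean`, `sd` (sample SD, divisor n - 1), `n_subjects` and
#'   `degenerate` (`TRUE` when only one subject, in which case `sd` is
#'   reported as 0 rather than missing); attribute `per_subject` holds the
#'   full edge x subject coefficient matrix.
#' @export
aggregate_fits <- function(fits) {
  if (!length(fits)) stop("no fits to aggregate")
  frames <- lapply(fits, function(f) {
    if (inherits(f, "sem_fit")) f$coefficients else f
  })
  keys <- lapply(frames, function(f) sort(edge_key(f$source, f$target)))
  if (!all(vapply(keys[-1L], identical, logical(1), keys[[1L]])))
    stop("per-subject fits do not share the same edge set")
  ref <- frames[[1L]][order(frames[[1L]]$source, frames[[1L]]$target),
                      c("source", "target")]
  ref_keys <- edge_key(ref$source, ref$target)
  per_subject <- vapply(frames, function(f) {
    est <- f$estimate
    names(est) <- edge_key(f$source, f$target)
    est[ref_keys]
  }, numeric(nrow(ref)))
  per_subject <- matrix(per_subject, nrow = nrow(ref),
                        dimnames = list(ref_keys, NULL))
  n_sub <- length(fits)
  degenerate <- n_sub == 1L
  out <- data.frame(
    source = ref$source, target = ref$target,
    mean = if (nrow(ref)) rowMeans(per_subject) else numeric(0),
    sd = if (!nrow(ref)) numeric(0)
         else if (degenerate) 0
         else apply(per_subject, 1L, stats::sd),
    n_subjects = n_sub,
    degenerate = degenerate)
  rownames(out) <- NULL
  structure(out, per_subject = per_subject,
            class = c("edge_estimates", "data.frame"))
}

#' Estimate edge coefficients across subjects for a fixed DAG
#'
#' Convenience wrapper: [fit_subject()] per dataset then
#' [aggregate_fits()].
#'
#' @param g a `dag`.
#' @param datasets list of standardized [condition_dataset()]s.
#' @return an `edge_estimates` object.
#' @export
estimate_edges <- function(g, datasets) {
  aggregate_fits(lapply(datasets, function(ds) fit_subject(g, ds)))
}
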