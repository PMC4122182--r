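#' Adjacency recovery metrics against a truth graph
#'
#' @param found a `skeleton` or `dag` (projected).
#' @param truth the generating `dag`.
#' @return list with `recall` (fraction of true adjacencies recovered),
#'   `precision` (fraction of reported adjacencies that are true),
#'   `n_true`, `n_found`.
#' @export
adjacency_metrics <- function(found, truth) {
  if (inherits(found, "dag")) found <- skeleton_of(found)
  stopifnot(inherits(found, "skeleton"), inherits(truth, "dag"))
  tp <- pair_key(truth$edges[, 1L], truth$edges[, 2L])
  fp <- if (nrow(found$edges)) pair_key(found$edges[, 1L], found$edges[, 2L])
        else character(0)
  list(recall = if (length(tp)) mean(tp %in% fp) else NA_real_,
       precision = if (length(fp)) mean(fp %in% tp) else NA_real_,
       n_true = length(tp), n_found = length(fp))
}

#' Orientation agreement with a truth graph
#'
#' Among the oriented edges whose unordered pair is a true adjacency, the
#' fraction pointing in the generating direction.
#'
#' @param oriented a `dag` (typically from [orient_edges()]).
#' @param truth the generating `dag`.
#' @return list with `agreement` (`NA` if no true adjacency was found),
#'   `n_correct` and `n_considered`.
#' @export
orientation_agreement <- function(oriented, truth) {
  stopifnot(inherits(oriented, "dag"), inherits(truth, "dag"))
  true_keys <- edge_key(truth$edges[, 1L], truth$edges[, 2L])
  true_pairs <- pair_key(truth$edges[, 1L], truth$edges[, 2L])
  if (!nrow(oriented$edges))
    return(list(agreement = NA_real_, n_correct = 0L, n_considered = 0L))
  keys <- edge_key(oriented$edges[, 1L], oriented$edges[, 2L])
  pairs <- pair_key(oriented$edges[, 1L], oriented$edges[, 2L])
  considered <- pairs %in% true_pairs
  n_considered <- sum(considered)
  n_correct <- sum(keys[considered] %in% true_keys)
  list(agreement = if (n_considered) n_correct / n_considered else NA_real_,
       n_correct = n_correct, n_considered = n_considered)
}
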