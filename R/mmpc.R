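# MMPC (max-min parents-and-children) feature reduction and its iterated
# divide-and-conquer wrapper for very large feature sets.

# Association measure used throughout: 1 - p when the test rejects at
# `threshold`, 0 otherwise (independence found).
assoc_from_p <- function(p, threshold) ifelse(p <= threshold, 1 - p, 0)

# All subsets of `pool` (integer vector) with size between lo and hi,
# returned as a list of integer vectors.
subsets_upto <- function(pool, lo, hi) {
  out <- list()
  for (k in seq.int(lo, min(hi, length(pool)))) {
    if (k == 0L) { out <- c(out, list(integer(0))); next }
    cmb <- utils::combn(pool, k, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

#' MMPC selection of candidate parents/children of the phenotype
#'
#' Constraint-based selection of the features that cannot be rendered
#' conditionally independent of the phenotype by any conditioning subset of
#' the selected set of size at most `maxK`.
#'
#' Forward phase: repeatedly add the candidate maximising the minimum
#' association (`1 - p` if `p <= threshold`, else 0) over all conditioning
#' subsets of the current selected set up to size `maxK`; stop when the best
#' remaining candidate's min-association is 0. The minimum is maintained
#' incrementally: after each addition only the new subsets (those containing
#' the newest member) are tested. Backward phase: remove any selected
#' feature that some conditioning subset (size at most `maxK`) of the other
#' selected features renders independent of the phenotype
#' (`p > threshold`). Ties in the forward phase are broken by input feature
#' order.
#'
#' @param x A `binary_matrix` or plain 0/1 matrix with column names.
#' @param status Phenotype; taken from `x` when it is a `binary_matrix`.
#' @param candidates Optional character vector restricting the candidate
#'   features (default: all columns).
#' @param threshold Significance level of the independence tests
#'   (default 0.1, deliberately permissive so that useful attributes are not
#'   over-excluded).
#' @param maxK Maximum conditioning-set size (default 2).
#' @return Character vector of selected feature ids (in selection order).
#' @export
mmpc <- function(x, status = NULL, candidates = NULL,
                 threshold = 0.1, maxK = 2L) {
  if (inherits(x, "binary_matrix")) {
    V <- x$values
    if (is.null(status)) status <- x$status
  } else V <- as.matrix(x)
  stopifnot(threshold > 0, threshold < 1, maxK >= 0L)
  status <- as_status(status)
  t01 <- as.integer(status == "case")
  ids <- colnames(V)
  if (is.null(ids)) ids <- paste0("f", seq_len(ncol(V)))
  cand <- if (is.null(candidates)) seq_len(ncol(V)) else match(candidates, ids)
  if (anyNA(cand)) stop("unknown candidate feature ids", call. = FALSE)
  if (length(cand) == 0L) stop("candidates must be nonempty", call. = FALSE)

  Vc <- V[, cand, drop = FALSE]
  p0 <- ci_chi2_batch(Vc, t01)$p_value
  minassoc <- assoc_from_p(p0, threshold)
  selected <- integer(0)          # indices into cand
  remaining <- seq_along(cand)

  repeat {
    if (length(remaining) == 0L) break
    live <- remaining[minassoc[remaining] > 0]
    if (length(live) == 0L) break
    best <- live[[which.max(minassoc[live])]]
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
    live <- remaining[minassoc[remaining] > 0]
    if (length(live) == 0L || maxK == 0L) {
      if (maxK == 0L) next else break
    }
    # Update min-association with the subsets that contain the new member.
    older <- setdiff(selected, best)
    subs <- subsets_upto(older, 0L, maxK - 1L)
    for (s in subs) {
      Z <- Vc[, c(s, best), drop = FALSE]
      pv <- ci_chi2_batch(Vc[, live, drop = FALSE], t01, Z)$p_value
      minassoc[live] <- pmin(minassoc[live], assoc_from_p(pv, threshold))
      live <- live[minassoc[live] > 0]
      if (length(live) == 0L) break
    }
  }

  # Backward phase: drop any selected feature shown independent of the
  # phenotype by some subset of the other selected features.
  if (length(selected) > 1L && maxK >= 1L) {
    removed <- logical(length(selected))
    subs <- subsets_upto(seq_along(selected), 1L, maxK)
    for (s in subs) {
      targets <- which(!removed & !(seq_along(selected) %in% s))
      if (length(targets) == 0L) next
      Z <- Vc[, selected[s], drop = FALSE]
      pv <- ci_chi2_batch(Vc[, selected[targets], drop = FALSE], t01, Z)$p_value
      removed[targets[pv > threshold]] <- TRUE
    }
    selected <- selected[!removed]
  }
  ids[cand[selected]]
}

#' Deterministic random partition of a feature set
#'
#' Seeded shuffle followed by contiguous chunking: every feature lands in
#' exactly one group; the last group may be smaller.
#'
#' @param features Character vector of feature ids.
#' @param group_size Target group size (at least 2).
#' @param seed Integer seed; the same seed always yields the same partition.
#' @return List of character vectors.
#' @export
partition_features <- function(features, group_size, seed) {
  stopifnot(group_size >= 2L)
  n <- length(features)
  shuffled <- with_seed(seed, features[sample.int(n)])
  split(shuffled, ceiling(seq_len(n) / group_size))
}

#' Iterated MMPC reduction for large feature sets
#'
#' MMPC's cost is exponential in the size of its output, so it cannot be run
#' directly on very large feature sets. This wrapper partitions the
#' surviving features into groups (a fresh seeded shuffle each iteration),
#' runs [mmpc()] on each group independently, replaces the survivors by the
#' union of the groups' outputs, and iterates to a fixed point. The result
#' is a small candidate superset of the useful features. Once the survivors
#' fit in a single group, one final plain MMPC pass finishes the job.
#'
#' @inheritParams mmpc
#' @param group_size Features per group (default 1000).
#' @param seed Integer seed driving the per-iteration shuffles.
#' @param max_iterations Safety cap on iterations (default 50); reaching it
#'   raises a warning and returns the current survivor set.
#' @return An object of class `candidate_set`: `feature_ids` (character),
#'   `history` (survivor-set size after each iteration) and `params`.
#' @export
itermmpc <- function(x, status = NULL, threshold = 0.1, maxK = 2L,
                     group_size = 1000L, seed = 1L, max_iterations = 50L) {
  if (inherits(x, "binary_matrix")) {
    if (is.null(status)) status <- x$status
  }
  ids0 <- if (inherits(x, "binary_matrix")) colnames(x$values) else colnames(x)
  survivors <- ids0
  history <- integer(0)
  converged <- FALSE
  for (iter in seq_len(max_iterations)) {
    if (length(survivors) <= group_size) {
      survivors <- mmpc(x, status, candidates = survivors,
                        threshold = threshold, maxK = maxK)
      history <- c(history, length(survivors))
      converged <- TRUE
      break
    }
    groups <- partition_features(survivors, group_size,
                                 seed = derive_seed(seed, iter))
    kept <- lapply(groups, function(g)
      mmpc(x, status, candidates = g, threshold = threshold, maxK = maxK))
    new_survivors <- intersect(survivors, unique(unlist(kept, use.names = FALSE)))
    history <- c(history, length(new_survivors))
    if (setequal(new_survivors, survivors)) {
      survivors <- new_survivors
      converged <- TRUE
      break
    }
    survivors <- new_survivors
  }
  if (!converged)
    warning("itermmpc did not reach a fixed point within ", max_iterations,
            " iterations; returning the current survivor set", call. = FALSE)
  structure(list(feature_ids = survivors, history = history,
                 params = list(threshold = threshold, maxK = maxK,
                               group_size = group_size, seed = seed)),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("Candidate set:", length(x$feature_ids), "features",
      sprintf("(threshold %.3g, maxK %d, group_size %d)\n",
              x$params$threshold, x$params$maxK, x$params$group_size))
  cat("  survivor sizes by iteration:", paste(x$history, collapse = " -> "), "\n")
  invisible(x)
}
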