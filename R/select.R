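# Greedy forward/backward wrapper feature selection for the naive Bayes
# classifier: best-scorer (opt) and second-best-scorer (subopt) variants.

new_trace <- function(variant, folds, seed, alpha) {
  structure(list(variant = variant,
                 steps = data.frame(phase = character(0),
                                    feature_id = character(0),
                                    score_after = numeric(0)),
                 features = character(0), score = NA_real_,
                 folds = folds, seed = seed, alpha = alpha,
                 forward_done = FALSE),
            class = "selection_trace")
}

add_step <- function(trace, phase, feature_id, score) {
  trace$steps <- rbind(trace$steps,
                       data.frame(phase = phase, feature_id = feature_id,
                                  score_after = score))
  trace$score <- score
  trace
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("Selection trace (", x$variant, "): ", length(x$features),
      " feature(s), CV log-posterior score ", sprintf("%.4f", x$score),
      "\n", sep = "")
  fw <- sum(x$steps$phase == "forward")
  bw <- sum(x$steps$phase == "backward")
  cat("  ", fw, "forward addition(s),", bw, "backward deletion(s)\n")
  invisible(x)
}

#' Forward phase of the greedy naive Bayes wrapper selection
#'
#' Starting from the empty (prior-only) model, each step tentatively adds
#' every remaining candidate and computes the cross-validated log-posterior
#' score ([model_score()]; the fold split is frozen once per run). The
#' `"opt"` variant commits the highest scorer; the `"subopt"` variant
#' commits the second-highest scorer (falling back to the best when only one
#' candidate improves), which yields a deliberately different, comparably
#' good model -- a second expert. The phase stops as soon as no tentative
#' addition strictly increases the score, so the committed score sequence is
#' strictly increasing.
#'
#' Ties are broken by candidate input order; with a tied first/second score
#' the subopt variant takes the later-ordered of the tied pair.
#'
#' @param x A `binary_matrix` or plain 0/1 matrix.
#' @param status Phenotype; taken from `x` when it is a `binary_matrix`.
#' @param candidates Candidate feature ids (default: all columns).
#' @param variant `"opt"` or `"subopt"`.
#' @param folds,seed,alpha Passed to the frozen CV scorer.
#' @param max_features Optional cap on the selected-set size.
#' @return A `selection_trace` (partial; feed to [backward_phase()]).
#' @export
forward_phase <- function(x, status = NULL, candidates = NULL,
                          variant = c("opt", "subopt"), folds = 10L,
                          seed = 1L, alpha = 1, max_features = Inf) {
  variant <- match.arg(variant)
  d <- unwrap_binary(x, status)
  cand <- resolve_features(d$V, candidates)
  trace <- new_trace(variant, folds, seed, alpha)
  if (length(cand) == 0L) {
    warning("empty candidate set: returning the prior-only selection",
            call. = FALSE)
    trace$score <- model_score(d$V, d$status, character(0),
                               folds = folds, seed = seed, alpha = alpha)
    trace$forward_done <- TRUE
    return(trace)
  }
  sc <- make_cv_scorer(d$V, d$status, folds = folds, seed = seed, alpha = alpha)
  trace$folds <- sc$folds
  acase <- sc$a0case; actrl <- sc$a0ctrl
  score <- sc$score_from(acase, actrl)
  trace$score <- score
  remaining <- cand
  chosen <- integer(0)
  while (length(remaining) > 0L && length(chosen) < max_features) {
    scores <- sc$score_additions(acase, actrl, remaining)
    ord <- order(scores, decreasing = TRUE)   # stable: ties keep input order
    pick <- NA_integer_
    if (variant == "opt") {
      if (scores[ord[1L]] > score) pick <- ord[1L]
    } else {
      if (length(ord) >= 2L && scores[ord[2L]] > score) pick <- ord[2L]
      else if (scores[ord[1L]] > score) pick <- ord[1L]
    }
    if (is.na(pick)) break
    j <- remaining[pick]
    chosen <- c(chosen, j)
    score <- scores[pick]
    acase <- acase + sc$Lcase[, j]
    actrl <- actrl + sc$Lctrl[, j]
    trace <- add_step(trace, "forward", colnames(d$V)[j], score)
    remaining <- remaining[-pick]
  }
  trace$features <- colnames(d$V)[chosen]
  trace$forward_done <- TRUE
  trace
}

#' Backward phase of the greedy naive Bayes wrapper selection
#'
#' Each step tentatively deletes every currently selected feature and finds
#' the deletion yielding the highest resulting score (the feature
#' contributing least); the deletion is committed if the resulting score
#' does not decrease (ties favour the smaller model), and the phase stops as
#' soon as every deletion would lower the score. The model is never emptied
#' below one feature.
#'
#' @param trace A completed [forward_phase()] trace.
#' @param x,status The same data the forward phase used (the frozen fold
#'   split is reconstructed from the trace's seed).
#' @return The finalised `selection_trace`.
#' @export
backward_phase <- function(trace, x, status = NULL) {
  stopifnot(inherits(trace, "selection_trace"), isTRUE(trace$forward_done))
  if (length(trace$features) <= 1L) return(trace)
  d <- unwrap_binary(x, status)
  sc <- make_cv_scorer(d$V, d$status, folds = trace$folds, seed = trace$seed,
                       alpha = trace$alpha)
  current <- match(trace$features, colnames(d$V))
  acc <- sc$accumulate(current)
  acase <- acc$acase; actrl <- acc$actrl
  score <- sc$score_from(acase, actrl)
  while (length(current) > 1L) {
    del <- sc$score_deletions(acase, actrl, current)
    k <- which.max(del)
    if (del[k] < score) break
    j <- current[k]
    score <- del[k]
    acase <- acase - sc$Lcase[, j]
    actrl <- actrl - sc$Lctrl[, j]
    current <- current[-k]
    trace <- add_step(trace, "backward", colnames(d$V)[j], score)
  }
  trace$features <- colnames(d$V)[current]
  trace$score <- score
  trace
}

select_nbc <- function(x, status, candidates, variant, folds, seed, alpha,
                       max_features) {
  d <- unwrap_binary(x, status)
  trace <- forward_phase(d$V, d$status, candidates = candidates,
                         variant = variant, folds = folds, seed = seed,
                         alpha = alpha, max_features = max_features)
  trace <- backward_phase(trace, d$V, d$status)
  model <- nbc_fit(d$V, d$status, features = trace$features, alpha = alpha)
  if (inherits(x, "binary_matrix"))
    model$codings <- x$codings[trace$features]
  structure(list(model = model, trace = trace, variant = variant,
                 score = trace$score),
            class = "nbc_selection")
}

#' Select an optimal naive Bayes feature set (best-scorer variant)
#'
#' Composes [forward_phase()] (variant `"opt"`) and [backward_phase()],
#' then fits the final naive Bayes model on all data over the selected
#' features.
#'
#' @inheritParams forward_phase
#' @return An `nbc_selection`: `model` ([nbc_fit()] on the final features),
#'   `trace`, `variant`, `score`.
#' @export
optnbc <- function(x, status = NULL, candidates = NULL, folds = 10L,
                   seed = 1L, alpha = 1, max_features = Inf) {
  select_nbc(x, status, candidates, "opt", folds, seed, alpha, max_features)
}

#' Select an alternative naive Bayes feature set (second-best variant)
#'
#' Identical to [optnbc()] except that each forward step commits the
#' second-highest scorer, producing a deliberately different feature set of
#' comparable quality -- the "second expert" used by the remedying
#' procedures.
#'
#' @inheritParams forward_phase
#' @return An `nbc_selection`.
#' @export
suboptnbc <- function(x, status = NULL, candidates = NULL, folds = 10L,
                      seed = 1L, alpha = 1, max_features = Inf) {
  select_nbc(x, status, candidates, "subopt", folds, seed, alpha, max_features)
}

#' @export
print.nbc_selection <- function(x, ...) {
  cat("Selected NBC (", x$variant, " variant): ",
      length(x$model$feature_ids), " feature(s), CV score ",
      sprintf("%.4f", x$score), "\n", sep = "")
  invisible(x)
}
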