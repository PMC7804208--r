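# Evaluation: confusion metrics (accuracy, sensitivity, specificity, MCC),
# leave-one-out, and repeated stratified k-fold cross-validation.

#' Confusion-matrix metrics for binary diagnoses
#'
#' Accuracy `(TP + TN) / n`, sensitivity `TP / (TP + FN)`, specificity
#' `TN / (TN + FP)` and the Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))` (0 when any
#' factor of the denominator is 0). "Positive" is the case class.
#'
#' @param pred Predicted labels ("case"/"control") or posterior
#'   probabilities (thresholded at 0.5, ties predicting case).
#' @param labels True labels.
#' @return A list of class `eval_report` with the four metrics and the
#'   confusion counts `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_metrics <- function(pred, labels) {
  if (length(pred) == 0L) stop("empty input", call. = FALSE)
  if (is.numeric(pred)) pred <- ifelse(pred >= 0.5, "case", "control")
  stopifnot(length(pred) == length(labels))
  truth <- as_status(labels) == "case"
  phat <- as.character(pred) == "case"
  tp <- sum(phat & truth); fp <- sum(phat & !truth)
  tn <- sum(!phat & !truth); fn <- sum(!phat & truth)
  den <- prod(sqrt(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
  structure(list(accuracy = (tp + tn) / length(pred),
                 sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
                 mcc = mcc, tp = tp, fp = fp, tn = tn, fn = fn),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("accuracy %.2f%%  sensitivity %.2f%%  specificity %.2f%%  MCC %.4f\n",
              100 * x$accuracy, 100 * x$sensitivity, 100 * x$specificity,
              x$mcc))
  if (!is.null(x$repeats))
    cat(sprintf("  over %d repeats: accuracy %.2f%% +/- %.2f%%\n",
                x$repeats, 100 * x$accuracy, 100 * x$accuracy_sd))
  invisible(x)
}

# Leave-one-out posteriors for a fixed feature set: for each sample the
# model is refit on the remaining n-1 samples (counts minus the held-out
# sample's own contribution), fully vectorised.
loo_posteriors <- function(V, y, alpha = 1) {
  n <- nrow(V); p <- ncol(V)
  is_case <- y == "case"
  ncase <- sum(is_case); nctrl <- n - ncase
  if (p == 0L) {
    prior <- (ncase - is_case) / (n - 1)
    return(prior)
  }
  tot1c <- colSums(V[is_case, , drop = FALSE])
  tot10 <- colSums(V[!is_case, , drop = FALSE])
  # Training counts with sample i removed from its own class.
  sub_c <- matrix(tot1c, n, p, byrow = TRUE) - V * is_case
  sub_0 <- matrix(tot10, n, p, byrow = TRUE) - V * !is_case
  nc_i <- ncase - is_case
  n0_i <- nctrl - !is_case
  p1c <- (sub_c + alpha) / (nc_i + 2 * alpha)      # n x p
  p10 <- (sub_0 + alpha) / (n0_i + 2 * alpha)
  lcase <- rowSums(V * log(p1c) + (1 - V) * log(1 - p1c)) + log(nc_i / (n - 1))
  lctrl <- rowSums(V * log(p10) + (1 - V) * log(1 - p10)) + log(n0_i / (n - 1))
  1 / (1 + exp(lctrl - lcase))
}

#' Leave-one-out evaluation of a fixed feature set
#'
#' For each sample, the naive Bayes parameters are refit on the remaining
#' samples over the (fixed) selected features and the held-out sample is
#' diagnosed. Feature selection and binary codings are *not* re-derived per
#' fold: this is the optimistic protocol a sequential pipeline reports;
#' nested re-selection is available via [repeated_kfold()]'s
#' `refit_pipeline`.
#'
#' @param x `binary_matrix` or 0/1 matrix.
#' @param status Phenotype; taken from `x` when it is a `binary_matrix`.
#' @param features Feature ids/indices (fixed selected set).
#' @param alpha Laplace smoothing pseudo-count.
#' @return An `eval_report` with an extra element `posterior` (per-sample
#'   leave-one-out posterior of "case").
#' @export
loo_evaluate <- function(x, status = NULL, features = NULL, alpha = 1) {
  d <- unwrap_binary(x, status)
  if (nrow(d$V) < 2L) stop("leave-one-out needs at least 2 samples", call. = FALSE)
  idx <- resolve_features(d$V, features)
  post <- loo_posteriors(d$V[, idx, drop = FALSE], d$status, alpha = alpha)
  rep <- confusion_metrics(post, d$status)
  rep$posterior <- post
  rep
}

#' Nested (fully honest) cross-validated evaluation of the whole pipeline
#'
#' The default evaluation protocols ([loo_evaluate()], [repeated_kfold()])
#' keep the binary codings and the selected feature set fixed -- both were
#' derived on the full data, so their accuracy estimates are optimistically
#' biased. This protocol re-runs the *entire* pipeline inside every
#' training fold: binary codings are re-derived ([snp2bin()]), the
#' candidate superset is re-reduced ([itermmpc()]), features are
#' re-selected ([optnbc()] or [suboptnbc()]), and only then is the held-out
#' fold diagnosed (unseen genotype categories fall in a coding's "0" set).
#'
#' @param x A [genotype_matrix()].
#' @param k Folds (default 5; nested folds are expensive).
#' @param seed Integer seed for the fold split and the per-fold pipeline.
#' @param variant `"opt"` or `"subopt"` selection.
#' @param threshold,maxK,group_size,folds,alpha,max_features Pipeline
#'   parameters, as in [snpdx_fit()].
#' @return An `eval_report` with element `posterior` (held-out posteriors).
#' @export
nested_evaluate <- function(x, k = 5L, seed = 1L, variant = c("opt", "subopt"),
                            threshold = 0.1, maxK = 2L, group_size = 1000L,
                            folds = 10L, alpha = 1, max_features = Inf) {
  stopifnot(inherits(x, "genotype_matrix"))
  variant <- match.arg(variant)
  select_fun <- if (variant == "opt") optnbc else suboptnbc
  y <- x$status
  fold <- stratified_folds(y, k, derive_seed(seed, 7L))
  post <- numeric(length(y))
  for (f in seq_len(k)) {
    test <- fold == f
    train <- genotype_matrix(x$geno[!test, , drop = FALSE], y[!test])
    bm <- snp2bin(preprocess(train))
    cand <- itermmpc(bm, threshold = threshold, maxK = maxK,
                     group_size = group_size, seed = derive_seed(seed, f))
    sel <- select_fun(bm, candidates = cand$feature_ids, folds = folds,
                      seed = derive_seed(seed, 100L + f), alpha = alpha,
                      max_features = max_features)
    test_gm <- genotype_matrix(x$geno[test, , drop = FALSE], y[test])
    Vtest <- encode_with_codings(test_gm, bm$codings)
    post[test] <- posterior_positive(sel$model, Vtest)
  }
  rep <- confusion_metrics(post, y)
  rep$posterior <- post
  rep
}

#' Repeated stratified k-fold cross-validation of a fixed feature set
#'
#' Each repeat draws a fresh seeded stratified partition into `k` folds;
#' within a repeat every fold is held out in turn, the naive Bayes
#' parameters are refit on the remaining folds over the fixed features, and
#' the held-out samples are diagnosed. Metrics are reported per repeat and
#' as mean +/- sd across repeats. By default only the NBC parameters are
#' refit per fold (codings and feature selection stay fixed -- the
#' optimistic protocol); [nested_evaluate()] re-runs the whole pipeline per
#' fold instead.
#'
#' @param x `binary_matrix` or 0/1 matrix.
#' @param status Phenotype; taken from `x` when it is a `binary_matrix`.
#' @param features Fixed feature ids/indices (ignored when `refit_pipeline`
#'   is given).
#' @param k Folds per repeat (default 10; reduced with a warning when a
#'   class has fewer than `k` members).
#' @param repeats Number of repeats (default 100).
#' @param seed Integer seed; repeat `r` uses a seed derived from it.
#' @param alpha Laplace smoothing pseudo-count.
#' @param refit_pipeline Optional `function(train_x, train_status)`
#'   returning a character vector of selected feature ids, re-run inside
#'   every training fold (nested re-selection on pre-encoded features).
#' @return An `eval_report` (metrics averaged over repeats) with
#'   `accuracy_sd`, `sensitivity_sd`, `specificity_sd`, `mcc_sd`,
#'   `repeats`, and `per_repeat` (data.frame).
#' @export
repeated_kfold <- function(x, status = NULL, features = NULL, k = 10L,
                           repeats = 100L, seed = 1L, alpha = 1,
                           refit_pipeline = NULL) {
  d <- unwrap_binary(x, status)
  y <- d$status
  ncls <- min(table(y))
  if (ncls < k) {
    warning("reducing k from ", k, " to ", max(2L, ncls),
            " (smallest class has ", ncls, " samples)", call. = FALSE)
    k <- max(2L, ncls)
  }
  idx <- if (is.null(refit_pipeline)) resolve_features(d$V, features)
  per <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    fold <- stratified_folds(y, k, derive_seed(seed, r))
    post <- numeric(nrow(d$V))
    for (f in seq_len(k)) {
      test <- fold == f
      if (is.null(refit_pipeline)) {
        fit <- nbc_fit(d$V[!test, idx, drop = FALSE], y[!test], alpha = alpha)
        post[test] <- posterior_positive(fit, d$V[test, idx, drop = FALSE])
      } else {
        feats <- refit_pipeline(d$V[!test, , drop = FALSE], y[!test])
        fit <- nbc_fit(d$V[!test, feats, drop = FALSE], y[!test], alpha = alpha)
        post[test] <- posterior_positive(fit, d$V[test, feats, drop = FALSE])
      }
    }
    m <- confusion_metrics(post, y)
    per[[r]] <- data.frame(repeat_ = r, accuracy = m$accuracy,
                           sensitivity = m$sensitivity,
                           specificity = m$specificity, mcc = m$mcc)
  }
  per <- do.call(rbind, per)
  out <- structure(list(accuracy = mean(per$accuracy),
                        sensitivity = mean(per$sensitivity),
                        specificity = mean(per$specificity),
                        mcc = mean(per$mcc),
                        accuracy_sd = stats::sd(per$accuracy),
                        sensitivity_sd = stats::sd(per$sensitivity),
                        specificity_sd = stats::sd(per$specificity),
                        mcc_sd = stats::sd(per$mcc),
                        repeats = repeats, k = k, per_repeat = per),
                   class = "eval_report")
  out
}
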