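# Naive Bayes classifier over binary features, with posterior-probability
# outputs and the cross-validated log-posterior score driving the wrapper
# feature selection.

resolve_features <- function(V, features) {
  if (is.null(features)) return(seq_len(ncol(V)))
  if (is.character(features)) {
    idx <- match(features, colnames(V))
    if (anyNA(idx)) stop("unknown feature ids: ",
                         paste(features[is.na(idx)], collapse = ", "),
                         call. = FALSE)
    idx
  } else as.integer(features)
}

unwrap_binary <- function(x, status) {
  if (inherits(x, "binary_matrix")) {
    list(V = x$values, status = if (is.null(status)) x$status else as_status(status))
  } else {
    V <- as.matrix(x)
    if (!is_binary01(V)) stop("feature matrix must be 0/1", call. = FALSE)
    list(V = V, status = as_status(status))
  }
}

#' Fit a naive Bayes classifier on binary features
#'
#' Class priors are the observed class frequencies; each conditional
#' probability table entry is Laplace-smoothed,
#' `P(x = 1 | class) = (count + alpha) / (class size + 2 * alpha)`, which
#' keeps every entry strictly inside (0, 1) so that log-space posteriors are
#' always finite.
#'
#' @param x A `binary_matrix` or plain 0/1 matrix.
#' @param status Phenotype; taken from `x` when it is a `binary_matrix`.
#' @param features Feature ids (or indices) to use; default all columns. An
#'   empty selection yields a prior-only model.
#' @param alpha Smoothing pseudo-count, must be > 0 (default 1).
#' @return An object of class `nbc_model`: `feature_ids`,
#'   `prior_positive`, `cpt` (features x 2 matrix of `P(x = 1 | control)`
#'   and `P(x = 1 | case)`), `alpha`, `n_train`.
#' @export
nbc_fit <- function(x, status = NULL, features = NULL, alpha = 1) {
  if (alpha <= 0) stop("alpha must be > 0 (unsmoothed tables produce zero ",
                       "posteriors)", call. = FALSE)
  d <- unwrap_binary(x, status)
  idx <- resolve_features(d$V, features)
  if (anyDuplicated(idx)) stop("duplicate features", call. = FALSE)
  y <- d$status
  ncase <- sum(y == "case"); nctrl <- sum(y == "control")
  if (ncase == 0L || nctrl == 0L)
    stop("training data must contain both classes", call. = FALSE)
  V <- d$V[, idx, drop = FALSE]
  c1case <- colSums(V[y == "case", , drop = FALSE])
  c1ctrl <- colSums(V[y == "control", , drop = FALSE])
  cpt <- cbind(control = (c1ctrl + alpha) / (nctrl + 2 * alpha),
               case = (c1case + alpha) / (ncase + 2 * alpha))
  rownames(cpt) <- colnames(V)
  structure(list(feature_ids = colnames(V),
                 prior_positive = ncase / (ncase + nctrl),
                 cpt = cpt, alpha = alpha, n_train = ncase + nctrl),
            class = "nbc_model")
}

#' @export
print.nbc_model <- function(x, ...) {
  cat("Naive Bayes classifier:", length(x$feature_ids), "binary feature(s),",
      sprintf("prior P(case) = %.4f, alpha = %g\n", x$prior_positive, x$alpha))
  invisible(x)
}

# Per-instance class log-scores (unnormalised) for a 0/1 matrix.
nbc_logscores <- function(model, V) {
  if (length(model$feature_ids)) {
    miss <- setdiff(model$feature_ids, colnames(V))
    if (length(miss)) stop("instance is missing model features: ",
                           paste(utils::head(miss, 5L), collapse = ", "),
                           call. = FALSE)
    V <- V[, model$feature_ids, drop = FALSE]
    if (anyNA(V)) stop("missing feature value in instance", call. = FALSE)
    lcase <- V %*% log(model$cpt[, "case"]) +
      (1 - V) %*% log(1 - model$cpt[, "case"])
    lctrl <- V %*% log(model$cpt[, "control"]) +
      (1 - V) %*% log(1 - model$cpt[, "control"])
  } else {
    lcase <- lctrl <- matrix(0, nrow(V), 1L)
  }
  cbind(control = as.numeric(lctrl) + log(1 - model$prior_positive),
        case = as.numeric(lcase) + log(model$prior_positive))
}

#' Posterior probability of "positive" (case)
#'
#' Bayes rule under the class-conditional independence assumption, computed
#' in log space and normalised.
#'
#' @param model An [nbc_fit()] model.
#' @param newdata 0/1 matrix (or vector for a single instance) whose columns
#'   cover the model's features.
#' @return Numeric vector of posterior case probabilities in `[0, 1]`.
#' @export
posterior_positive <- function(model, newdata) {
  stopifnot(inherits(model, "nbc_model"))
  if (is.null(dim(newdata))) {
    newdata <- matrix(newdata, nrow = 1L,
                      dimnames = list(NULL, names(newdata)))
  }
  if (inherits(newdata, "binary_matrix")) newdata <- newdata$values
  ls <- nbc_logscores(model, as.matrix(newdata))
  as.numeric(1 / (1 + exp(ls[, "control"] - ls[, "case"])))
}

#' Predict method for naive Bayes diagnostic models
#'
#' @param object An `nbc_model`.
#' @param newdata 0/1 feature matrix or `binary_matrix`.
#' @param type `"posterior"` for P(case | features), `"class"` for the
#'   predicted label (case iff posterior >= `threshold`).
#' @param threshold Decision threshold; exactly-threshold posteriors predict
#'   "case".
#' @param ... Ignored.
#' @export
predict.nbc_model <- function(object, newdata, type = c("posterior", "class"),
                              threshold = 0.5, ...) {
  type <- match.arg(type)
  p <- posterior_positive(object, newdata)
  if (type == "posterior") return(p)
  factor(ifelse(p >= threshold, "case", "control"),
         levels = c("control", "case"))
}

# ---------------------------------------------------------------------------
# Cross-validated log-posterior scoring
# ---------------------------------------------------------------------------

# Precomputed scoring context shared by a whole selection run. The fold
# split is frozen once (stratified by class, fixed by `seed`) so that every
# greedy comparison uses the same resampling. For each instance i and
# feature j it precomputes the log-likelihood contribution of feature j to
# each class score when i's fold is held out, so scoring a feature set is a
# rowSums, and scoring "current set + each candidate" is one matrix sweep.
make_cv_scorer <- function(V, y, folds = 10L, seed = 1L, alpha = 1) {
  n <- nrow(V); p <- ncol(V)
  ncls <- table(y)
  if (min(ncls) < folds) {
    folds <- max(2L, min(ncls))
    warning("reducing folds to ", folds,
            " (smallest class has only ", min(ncls), " samples)",
            call. = FALSE)
  }
  fold <- stratified_folds(y, folds, seed)
  is_case <- y == "case"
  Lcase <- matrix(0, n, p); Lctrl <- matrix(0, n, p)
  a0case <- numeric(n); a0ctrl <- numeric(n)
  for (f in seq_len(folds)) {
    test <- fold == f
    trc <- is_case & !test; trn <- !is_case & !test
    nc <- sum(trc); n0 <- sum(trn)
    p1c <- (colSums(V[trc, , drop = FALSE]) + alpha) / (nc + 2 * alpha)
    p10 <- (colSums(V[trn, , drop = FALSE]) + alpha) / (n0 + 2 * alpha)
    Vb <- V[test, , drop = FALSE]
    nb <- nrow(Vb)
    Lcase[test, ] <- Vb * matrix(log(p1c), nb, p, byrow = TRUE) +
      (1 - Vb) * matrix(log(1 - p1c), nb, p, byrow = TRUE)
    Lctrl[test, ] <- Vb * matrix(log(p10), nb, p, byrow = TRUE) +
      (1 - Vb) * matrix(log(1 - p10), nb, p, byrow = TRUE)
    a0case[test] <- log(nc / (nc + n0))
    a0ctrl[test] <- log(n0 / (nc + n0))
  }
  env <- list(V = V, y = y, is_case = is_case, folds = folds, seed = seed,
              alpha = alpha, fold = fold, Lcase = Lcase, Lctrl = Lctrl,
              a0case = a0case, a0ctrl = a0ctrl)

  # Sum over held-out instances of the log posterior of the true class.
  env$score_from <- function(acase, actrl) {
    m <- pmax(acase, actrl)
    lse <- m + log(exp(acase - m) + exp(actrl - m))
    sum(ifelse(env$is_case, acase, actrl) - lse)
  }
  env$accumulate <- function(idx) {
    list(acase = env$a0case + rowSums(env$Lcase[, idx, drop = FALSE]),
         actrl = env$a0ctrl + rowSums(env$Lctrl[, idx, drop = FALSE]))
  }
  # Scores of (current set + j) for every candidate j, given the current
  # accumulated class scores.
  env$score_additions <- function(acase, actrl, cand) {
    Mc <- acase + env$Lcase[, cand, drop = FALSE]
    Mb <- actrl + env$Lctrl[, cand, drop = FALSE]
    Mx <- pmax(Mc, Mb)
    lse <- Mx + log1p(exp(pmin(Mc, Mb) - Mx))
    Tt <- Mc
    Tt[!env$is_case, ] <- Mb[!env$is_case, ]
    colSums(Tt - lse)
  }
  env$score_deletions <- function(acase, actrl, current) {
    Mc <- acase - env$Lcase[, current, drop = FALSE]
    Mb <- actrl - env$Lctrl[, current, drop = FALSE]
    Mx <- pmax(Mc, Mb)
    lse <- Mx + log1p(exp(pmin(Mc, Mb) - Mx))
    Tt <- Mc
    Tt[!env$is_case, ] <- Mb[!env$is_case, ]
    colSums(Tt - lse)
  }
  env
}

#' Cross-validated log-posterior score of a feature set
#'
#' The model score used by the greedy selectors: stratified k-fold
#' cross-validation with the fold split frozen by `seed`; for each held-out
#' instance the naive Bayes model is refit on the remaining folds and the
#' log posterior probability assigned to the instance's true class is
#' accumulated. Higher (closer to 0) is better; the empty feature set
#' scores the prior-only model.
#'
#' @param x A `binary_matrix` or plain 0/1 matrix.
#' @param status Phenotype; taken from `x` when it is a `binary_matrix`.
#' @param features Feature ids or indices (may be empty).
#' @param folds Number of folds (default 10).
#' @param seed Integer seed freezing the stratified fold split.
#' @param alpha Laplace smoothing pseudo-count.
#' @return The summed log posterior of the true classes (a scalar, <= 0).
#' @export
model_score <- function(x, status = NULL, features = character(0),
                        folds = 10L, seed = 1L, alpha = 1) {
  d <- unwrap_binary(x, status)
  idx <- resolve_features(d$V, features)
  sc <- make_cv_scorer(d$V, d$status, folds = folds, seed = seed, alpha = alpha)
  acc <- sc$accumulate(idx)
  sc$score_from(acc$acase, acc$actrl)
}
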