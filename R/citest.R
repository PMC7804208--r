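# (Conditional) independence testing between binary features and the
# case/control target, used by the MMPC reduction and the association scans.

# Vectorised engine: Pearson chi-square of every column of X against t,
# stratified by the joint states of the conditioning columns Z (0/1 matrix
# with 0..maxK columns). Returns statistic, df and p for each column.
#
# Within each stratum the 2x2 (x, t) table contributes its Pearson
# statistic and 1 df; a stratum where x or t is constant (a zero margin)
# contributes 0 to both. With no conditioning this reduces exactly to the
# marginal test.
ci_chi2_batch <- function(X, t01, Z = NULL) {
  n <- length(t01)
  if (is.null(dim(X))) X <- matrix(X, ncol = 1L)
  if (is.null(Z) || NCOL(Z) == 0L) {
    stratum <- rep(1L, n); ns <- 1L
  } else {
    Z <- as.matrix(Z)
    stratum <- as.integer(Z %*% 2L^(seq_len(ncol(Z)) - 1L)) + 1L
    ns <- 2L^ncol(Z)
  }
  # D: n x (ns*2) indicator of (stratum, t); crossprod gives per-feature
  # counts of x = 1 in every (stratum, class) cell.
  cell <- stratum + ns * t01            # 1..2*ns
  D <- matrix(0, n, 2L * ns)
  D[cbind(seq_len(n), cell)] <- 1
  ones <- crossprod(X, D)               # p x (2*ns), x=1 counts
  tot <- colSums(D)                     # cell totals
  stat <- numeric(ncol(X)); df <- integer(ncol(X))
  for (s in seq_len(ns)) {
    a <- ones[, s + ns]                 # x=1, case
    b <- ones[, s]                      # x=1, control
    c_ <- tot[s + ns] - a               # x=0, case
    d <- tot[s] - b
    nn <- a + b + c_ + d
    den <- (a + b) * (c_ + d) * (a + c_) * (b + d)
    ok <- den > 0
    stat[ok] <- stat[ok] + nn[ok] * (a[ok] * d[ok] - b[ok] * c_[ok])^2 / den[ok]
    df <- df + as.integer(ok)
  }
  p <- ifelse(df > 0, stats::pchisq(stat, df, lower.tail = FALSE), 1)
  list(statistic = stat, df = df, p_value = p)
}

#' Conditional independence test of a binary feature against the phenotype
#'
#' With an empty conditioning set this is the plain Pearson chi-square test
#' of the 2x2 feature-by-status table. With conditioning features, the data
#' are stratified by the joint states of the conditioners; each
#' non-degenerate stratum contributes its Pearson statistic and 1 degree of
#' freedom, degenerate strata (a zero margin) contribute nothing, and the
#' p-value comes from the chi-square upper tail on the summed df.
#'
#' A test is flagged unreliable when the sample size falls below 5 times
#' the nominal df of the stratified table (`5 * 2^|cond|`); unreliable tests
#' report `p_value = 1` and are treated as showing independence, so sparse
#' strata can only make the procedure more conservative.
#'
#' @param x Binary (0/1) feature vector.
#' @param status Phenotype (two states).
#' @param cond Optional 0/1 matrix (or vector) of conditioning features.
#' @return A list of class `ci_test`: `statistic`, `df`, `p_value`,
#'   `reliable`.
#' @export
independence_test <- function(x, status, cond = NULL) {
  if (length(x) == 0L) stop("empty data", call. = FALSE)
  status <- as_status(status)
  if (!is_binary01(x)) stop("x must be a 0/1 feature", call. = FALSE)
  if (!is.null(cond)) {
    cond <- as.matrix(cond)
    if (!is_binary01(cond)) stop("conditioning features must be 0/1", call. = FALSE)
  }
  t01 <- as.integer(status == "case")
  res <- ci_chi2_batch(matrix(as.numeric(x), ncol = 1L), t01, cond)
  k <- if (is.null(cond)) 0L else ncol(cond)
  reliable <- length(x) >= 5L * 2L^k
  out <- list(statistic = res$statistic[[1L]], df = res$df[[1L]],
              p_value = if (reliable) res$p_value[[1L]] else 1,
              reliable = reliable)
  class(out) <- "ci_test"
  out
}

#' @export
print.ci_test <- function(x, ...) {
  cat(sprintf("Chi-square CI test: statistic %.4f on %d df, p = %.4g%s\n",
              x$statistic, x$df, x$p_value,
              if (!x$reliable) " (unreliable; treated as independent)" else ""))
  invisible(x)
}

#' Genome-wide association scan (0-order or 1-order p-values)
#'
#' Order 0 reports, per feature, the marginal chi-square p-value against the
#' phenotype. Order 1 reports, per feature, the maximum p-value over tests
#' conditioned on each single member of `conditioning_pool` except the
#' feature itself: a feature whose marginal association evaporates under
#' some single conditioner (large max-p) carries a superficially, not truly,
#' high association.
#'
#' @param x A `binary_matrix` (from [snp2bin()]) or a plain 0/1 matrix.
#' @param status Phenotype; taken from `x` when it is a `binary_matrix`.
#' @param order 0 or 1.
#' @param conditioning_pool Character vector of feature ids used as single
#'   conditioners (required for `order = 1`).
#' @return A data.frame with `snp_id`, `chi2`, `df`, `p`, `log10p` (for
#'   order 1 these describe the maximum-p conditional test).
#' @export
association_scan <- function(x, status = NULL, order = 0,
                             conditioning_pool = NULL) {
  if (inherits(x, "binary_matrix")) {
    V <- x$values
    if (is.null(status)) status <- x$status
  } else V <- as.matrix(x)
  status <- as_status(status)
  t01 <- as.integer(status == "case")
  ids <- colnames(V)
  if (is.null(ids)) ids <- paste0("f", seq_len(ncol(V)))
  if (order == 0) {
    res <- ci_chi2_batch(V, t01)
  } else if (order == 1) {
    if (is.null(conditioning_pool) || length(conditioning_pool) == 0L)
      stop("order-1 scan needs a nonempty conditioning_pool", call. = FALSE)
    pool <- match(conditioning_pool, ids)
    if (anyNA(pool)) stop("conditioning_pool names features absent from x",
                          call. = FALSE)
    stat <- numeric(ncol(V)); df <- integer(ncol(V))
    p <- rep(-1, ncol(V))
    for (z in unique(pool)) {
      res_z <- ci_chi2_batch(V, t01, V[, z])
      res_z$p_value[z] <- -1     # never condition a feature on itself
      upd <- res_z$p_value > p
      p[upd] <- res_z$p_value[upd]
      stat[upd] <- res_z$statistic[upd]
      df[upd] <- res_z$df[upd]
    }
    # A pool member whose only conditioner would be itself keeps its
    # marginal test.
    solo <- which(p < 0)
    if (length(solo)) {
      res0 <- ci_chi2_batch(V[, solo, drop = FALSE], t01)
      p[solo] <- res0$p_value; stat[solo] <- res0$statistic; df[solo] <- res0$df
    }
    res <- list(statistic = stat, df = df, p_value = p)
  } else stop("order must be 0 or 1", call. = FALSE)
  data.frame(snp_id = ids, chi2 = res$statistic, df = res$df,
             p = res$p_value, log10p = log10(pmax(res$p_value, 1e-300)),
             row.names = NULL)
}
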