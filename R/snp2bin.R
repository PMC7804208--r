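# Optimal 2-value recoding of genotype categories, scored by the Pearson
# chi-square statistic of the induced 2x2 table against the phenotype.

#' Enumerate candidate binary codings of a category set
#'
#' A binary coding of a SNP assigns each genotype category to either the
#' "1" set or the "0" set (both nonempty). A coding and its complement-swap
#' induce the same 2x2 table up to row exchange and hence the same
#' chi-square score, so only one representative per complement pair is
#' emitted: `2^(m-1) - 1` codings for `m` categories, in a deterministic
#' canonical order (by size of the "1" set, then lexicographically within a
#' size, using the order of `categories`).
#'
#' @param categories Character vector of distinct genotype categories
#'   (length at least 2). The missing-genotype sentinel, if present, is an
#'   ordinary category and may land in either set.
#' @param snp_id Optional SNP identifier recorded on each coding.
#' @return A list of unscored codings; each element has `snp_id`,
#'   `one_set`, `zero_set` and `score = NA`.
#' @export
enumerate_codings <- function(categories, snp_id = NA_character_) {
  categories <- as.character(categories)
  m <- length(categories)
  if (anyDuplicated(categories)) stop("categories must be distinct", call. = FALSE)
  if (m < 2L)
    stop("cannot recode a single-category SNP (exclude constant columns first)",
         call. = FALSE)
  if (m > 16L)
    stop("refusing to enumerate bipartitions of ", m, " categories", call. = FALSE)
  masks <- seq_len(2L^m - 2L)               # nonempty proper subsets
  member <- vapply(seq_len(m), function(j) bitwAnd(masks, bitwShiftL(1L, j - 1L)) > 0L,
                   logical(length(masks)))
  if (is.null(dim(member))) member <- matrix(member, nrow = 1L)
  sizes <- rowSums(member)
  comp_mask <- (2L^m - 1L) - masks
  # Canonical representative of each complement pair: the smaller "1" set,
  # ties (equal sizes) resolved by the smaller bitmask.
  keep <- sizes < (m - sizes) | (sizes == m - sizes & masks < comp_mask)
  member <- member[keep, , drop = FALSE]
  sizes <- sizes[keep]
  lex <- apply(member, 1L, function(r) paste(sprintf("%02d", which(r)), collapse = ","))
  ord <- order(sizes, lex)
  member <- member[ord, , drop = FALSE]
  lapply(seq_len(nrow(member)), function(i) {
    one <- categories[member[i, ]]
    structure(list(snp_id = snp_id, one_set = one,
                   zero_set = setdiff(categories, one), score = NA_real_),
              class = "binary_coding")
  })
}

#' Pearson chi-square statistic of a contingency table
#'
#' Plain Pearson statistic `sum((O - E)^2 / E)` with no continuity
#' correction. A table with any zero row or column margin is defined to
#' score 0 (no evidence of association), not an error.
#'
#' @param counts Numeric matrix of non-negative counts.
#' @return The chi-square statistic (non-negative scalar).
#' @export
#' @examples
#' chi2_statistic(matrix(c(20, 0, 0, 20), 2))  # 40: perfect 2x2 association
chi2_statistic <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  rs <- rowSums(counts); cs <- colSums(counts)
  if (any(rs == 0) || any(cs == 0) || sum(counts) == 0) return(0)
  expected <- outer(rs, cs) / sum(counts)
  sum((counts - expected)^2 / expected)
}

# Fast closed form for a batch of 2x2 tables given as count vectors
# (a, b, c, d) = (x1&case, x1&ctrl, x0&case, x0&ctrl); zero margins -> 0.
chi2_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b; r0 <- c + d; c1 <- a + c; c0 <- b + d
  den <- r1 * r0 * c1 * c0
  out <- numeric(length(n))
  ok <- den > 0
  out[ok] <- n[ok] * (a[ok] * d[ok] - b[ok] * c[ok])^2 / den[ok]
  out
}

# Category-by-class count matrix for one genotype column.
category_counts <- function(code, m, is_case) {
  cnt <- tabulate(code + m * is_case, nbins = 2L * m)
  matrix(cnt, nrow = m, dimnames = list(NULL, c("control", "case")))
}

#' Optimal binary coding of one SNP against the phenotype
#'
#' Scores every candidate bipartition of the SNP's categories (see
#' [enumerate_codings()]) by the Pearson chi-square statistic of the induced
#' 2x2 table versus case/control status, and returns the coding with the
#' maximal score. Ties are broken by canonical enumeration order (first
#' wins), which makes the result deterministic.
#'
#' @param values Character vector of genotype categories, one per sample.
#' @param status Phenotype factor/vector (two states; see
#'   [genotype_matrix()]).
#' @param snp_id Optional identifier recorded on the coding.
#' @return A `binary_coding`: `one_set`, `zero_set` and the maximal
#'   chi-square `score`.
#' @export
optimal_coding <- function(values, status, snp_id = NA_character_) {
  status <- as_status(status)
  cats <- snp_categories(values)
  codings <- enumerate_codings(cats, snp_id = snp_id)
  code <- match(values, cats)
  cnt <- category_counts(code, length(cats), as.integer(status == "case"))
  one <- vapply(codings, function(cd) cats %in% cd$one_set,
                logical(length(cats)))
  one <- matrix(one, nrow = length(cats))
  a <- as.numeric(crossprod(one, cnt[, "case"]))
  b <- as.numeric(crossprod(one, cnt[, "control"]))
  scores <- chi2_2x2(a, b, sum(cnt[, "case"]) - a, sum(cnt[, "control"]) - b)
  best <- which.max(scores)
  cd <- codings[[best]]
  cd$score <- scores[[best]]
  cd
}

#' @export
print.binary_coding <- function(x, ...) {
  cat("Binary coding", if (!is.na(x$snp_id)) paste0("for ", x$snp_id) else "",
      "\n  1 <-", paste(x$one_set, collapse = ", "),
      "\n  0 <-", paste(x$zero_set, collapse = ", "),
      sprintf("\n  chi-square score: %.4f\n", x$score))
  invisible(x)
}

#' Recode every SNP of a study into its optimal binary variable
#'
#' Applies [optimal_coding()] column-by-column: each non-constant SNP
#' becomes one binary feature (1 if the genotype falls in the coding's "1"
#' set), with the coding kept as provenance. Constant SNPs (a single
#' observed category, for which no bipartition exists) are dropped. Sample
#' order is preserved. Codings are derived once, on the full dataset, before
#' any cross-validation (see the package vignette for the leakage
#' implications).
#'
#' @param x A [genotype_matrix()]; preprocessed automatically if needed.
#' @return An object of class `binary_matrix`: `values` (samples x features
#'   0/1 integer matrix), `feature_ids`, `codings` (named list of
#'   `binary_coding`), `status`, `sample_ids`.
#' @export
snp2bin <- function(x) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (!isTRUE(attr(x, "preprocessed"))) x <- preprocess(x)
  keep <- which(!attr(x, "constant"))
  n <- nrow(x$geno)
  is_case <- as.integer(x$status == "case")
  vals <- matrix(0L, n, length(keep),
                 dimnames = list(x$sample_ids, x$snp_ids[keep]))
  codings <- vector("list", length(keep))
  names(codings) <- x$snp_ids[keep]
  for (k in seq_along(keep)) {
    j <- keep[[k]]
    cd <- optimal_coding(x$geno[, j], x$status, snp_id = x$snp_ids[[j]])
    codings[[k]] <- cd
    vals[, k] <- as.integer(x$geno[, j] %in% cd$one_set)
  }
  structure(list(values = vals, feature_ids = x$snp_ids[keep],
                 codings = codings, status = x$status,
                 sample_ids = x$sample_ids),
            class = "binary_matrix")
}

#' @export
dim.binary_matrix <- function(x) dim(x$values)

#' @export
print.binary_matrix <- function(x, ...) {
  cat("Binary feature matrix:", nrow(x$values), "samples x",
      ncol(x$values), "features\n")
  sc <- vapply(x$codings, `[[`, 0, "score")
  cat(sprintf("  coding chi-square scores: median %.2f, max %.2f\n",
              stats::median(sc), max(sc)))
  invisible(x)
}

#' Write coding provenance as TSV
#'
#' One row per feature: `snp_id`, the categories coded 1 (comma-joined) and
#' the chi-square score of the coding.
#'
#' @param x A `binary_matrix` (or a list of `binary_coding`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_codings <- function(x, path) {
  codings <- if (inherits(x, "binary_matrix")) x$codings else x
  df <- data.frame(
    snp_id = vapply(codings, `[[`, "", "snp_id"),
    one_set = vapply(codings, function(cd) paste(cd$one_set, collapse = ","), ""),
    chi2 = vapply(codings, `[[`, 0, "score"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
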