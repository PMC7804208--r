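# End-to-end dual-expert diagnostic model: encode -> reduce -> select
# (best and second-best variants) -> remedy-capable model pair.

#' Fit a dual naive Bayes diagnostic model from genotypes
#'
#' Runs the full pipeline on a case/control genotype study:
#' \enumerate{
#'   \item [preprocess()] and [snp2bin()]: each SNP (missing calls included
#'     as an explicit category) becomes the binary variable whose category
#'     bipartition maximises the chi-square statistic against the phenotype;
#'   \item [itermmpc()]: iterated MMPC reduces the binary features to a
#'     small candidate superset;
#'   \item [optnbc()] and [suboptnbc()]: greedy wrapper selection fits two
#'     naive Bayes models -- the best-scorer "main" expert and the
#'     second-best-scorer "alternative" expert;
#' }
#' Diagnoses whose main posterior falls in the doubt band (0.45, 0.55) can
#' then be routed to the alternative expert ([predict.snpdx_model()],
#' [remedy_table()]).
#'
#' @param x A [genotype_matrix()] (or an already-encoded `binary_matrix`,
#'   skipping step 1).
#' @param threshold,maxK MMPC independence-test level and maximum
#'   conditioning-set size (defaults 0.1 and 2, deliberately permissive so
#'   useful attributes are not over-excluded).
#' @param group_size Features per IterMMPC group.
#' @param folds Cross-validation folds for the selection score.
#' @param seed Integer seed driving IterMMPC's shuffles and the frozen fold
#'   split.
#' @param alpha Laplace smoothing pseudo-count.
#' @param max_features Optional cap on each selected feature set.
#' @return An object of class `snpdx_model`: `binary` (the encoded
#'   features), `candidates` (the [itermmpc()] result), `main` and `alt`
#'   (`nbc_selection` objects), `call`.
#' @export
#' @examples
#' sim <- simulate_genotypes(simulation_spec(
#'   n_cases = 120, n_controls = 120, n_snps = 40,
#'   causal = causal_additive(1:3, beta = 1.2), seed = 7))
#' fit <- snpdx_fit(sim$genotypes, group_size = 40, seed = 7)
#' fit
snpdx_fit <- function(x, threshold = 0.1, maxK = 2L, group_size = 1000L,
                      folds = 10L, seed = 1L, alpha = 1,
                      max_features = Inf) {
  cl <- match.call()
  bm <- if (inherits(x, "binary_matrix")) x else snp2bin(preprocess(x))
  cand <- itermmpc(bm, threshold = threshold, maxK = maxK,
                   group_size = group_size, seed = seed)
  ids <- cand$feature_ids
  if (length(ids) == 0L) {
    warning("no feature survived the MMPC reduction; fitting prior-only ",
            "models", call. = FALSE)
  }
  main <- optnbc(bm, candidates = ids, folds = folds,
                 seed = derive_seed(seed, 101L), alpha = alpha,
                 max_features = max_features)
  alt <- suboptnbc(bm, candidates = ids, folds = folds,
                   seed = derive_seed(seed, 101L), alpha = alpha,
                   max_features = max_features)
  structure(list(binary = bm, candidates = cand, main = main, alt = alt,
                 call = cl),
            class = "snpdx_model")
}

#' @export
print.snpdx_model <- function(x, ...) {
  cat("Dual naive Bayes diagnostic model\n")
  cat("  binary features:", ncol(x$binary$values),
      "| candidate superset:", length(x$candidates$feature_ids), "\n")
  cat(sprintf("  main (opt):   %d features, CV score %.4f\n",
              length(x$main$model$feature_ids), x$main$score))
  cat(sprintf("  alt (subopt): %d features, CV score %.4f\n",
              length(x$alt$model$feature_ids), x$alt$score))
  invisible(x)
}

#' @export
summary.snpdx_model <- function(object, ...) {
  loo_main <- loo_evaluate(object$binary,
                           features = object$main$model$feature_ids)
  loo_alt <- loo_evaluate(object$binary,
                          features = object$alt$model$feature_ids)
  rt <- remedy_table(object$main$model, object$alt$model, object$binary,
                     mode = "band")
  out <- list(model = object, loo_main = loo_main, loo_alt = loo_alt,
              remedy = rt)
  class(out) <- "summary.snpdx_model"
  out
}

#' @export
print.summary.snpdx_model <- function(x, ...) {
  print(x$model)
  cat("leave-one-out, main: "); print(x$loo_main)
  cat("leave-one-out, alt:  "); print(x$loo_alt)
  overlap <- length(intersect(x$model$main$model$feature_ids,
                              x$model$alt$model$feature_ids))
  cat("  expert feature overlap:", overlap, "feature(s)\n")
  print(x$remedy)
  invisible(x)
}

#' Predict method for dual diagnostic models
#'
#' @param object An [snpdx_fit()] model.
#' @param newdata A `binary_matrix`, a 0/1 matrix over the encoded feature
#'   ids, or a [genotype_matrix()] (encoded with the model's stored
#'   codings).
#' @param type `"posterior"` (data.frame of main/alt/final posteriors),
#'   `"class"` (final predicted labels).
#' @param remedy If `TRUE` (default), in-band diagnoses take the
#'   alternative expert's posterior.
#' @param ... Ignored.
#' @export
predict.snpdx_model <- function(object, newdata = NULL,
                                type = c("posterior", "class"),
                                remedy = TRUE, ...) {
  type <- match.arg(type)
  V <- if (is.null(newdata)) object$binary$values
  else if (inherits(newdata, "binary_matrix")) newdata$values
  else if (inherits(newdata, "genotype_matrix"))
    encode_with_codings(newdata, object$binary$codings)
  else as.matrix(newdata)
  pm <- posterior_positive(object$main$model, V)
  pa <- posterior_positive(object$alt$model, V)
  final <- if (remedy) ifelse(in_doubt_band(pm), pa, pm) else pm
  if (type == "class")
    return(factor(ifelse(final >= 0.5, "case", "control"),
                  levels = c("control", "case")))
  data.frame(main = pm, alt = pa, final = final)
}

# Apply stored binary codings to new genotype data (unseen categories fall
# in the "0" set).
encode_with_codings <- function(gm, codings) {
  stopifnot(inherits(gm, "genotype_matrix"))
  ids <- names(codings)
  miss <- setdiff(ids, gm$snp_ids)
  if (length(miss)) stop("new data lacks SNPs: ",
                         paste(utils::head(miss, 5L), collapse = ", "),
                         call. = FALSE)
  V <- matrix(0L, nrow(gm$geno), length(ids),
              dimnames = list(gm$sample_ids, ids))
  for (k in seq_along(ids)) {
    V[, k] <- as.integer(gm$geno[, ids[[k]]] %in% codings[[k]]$one_set)
  }
  V
}

#' @export
coef.snpdx_model <- function(object, expert = c("main", "alt"), ...) {
  expert <- match.arg(expert)
  m <- object[[expert]]$model
  # Per-feature log-odds contribution of observing a 1 vs a 0.
  data.frame(feature_id = m$feature_ids,
             p1_case = m$cpt[, "case"],
             p1_control = m$cpt[, "control"],
             log_odds_1 = log(m$cpt[, "case"] / m$cpt[, "control"]),
             log_odds_0 = log((1 - m$cpt[, "case"]) / (1 - m$cpt[, "control"])),
             row.names = NULL)
}

#' Plot the selection trace of a fitted diagnostic model
#'
#' Cross-validated log-posterior score against the standardised forward
#' phase (0 = first addition, 1 = last) for both experts.
#'
#' @param x An `snpdx_model`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.snpdx_model <- function(x, ...) {
  tr_m <- x$main$trace$steps
  tr_a <- x$alt$trace$steps
  fw_m <- tr_m[tr_m$phase == "forward", ]
  fw_a <- tr_a[tr_a$phase == "forward", ]
  xs_m <- seq(0, 1, length.out = max(nrow(fw_m), 2L))[seq_len(nrow(fw_m))]
  xs_a <- seq(0, 1, length.out = max(nrow(fw_a), 2L))[seq_len(nrow(fw_a))]
  graphics::plot(xs_m, fw_m$score_after, type = "b", pch = 16,
                 xlab = "standardised forward phase",
                 ylab = "CV log-posterior score", ...)
  graphics::lines(xs_a, fw_a$score_after, type = "b", pch = 1, lty = 2)
  graphics::legend("bottomright", legend = c("main (opt)", "alt (subopt)"),
                   pch = c(16, 1), lty = c(1, 2), bty = "n")
  invisible(x)
}

#' Serialise a fitted naive Bayes model to JSON
#'
#' Writes feature ids, priors, conditional probability tables, the
#' smoothing pseudo-count and (when present) the binary-coding provenance.
#'
#' @param model An `nbc_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_nbc_json <- function(model, path) {
  stopifnot(inherits(model, "nbc_model"))
  obj <- list(feature_ids = model$feature_ids,
              prior_positive = model$prior_positive,
              cpt_case = unname(model$cpt[, "case"]),
              cpt_control = unname(model$cpt[, "control"]),
              alpha = model$alpha, n_train = model$n_train)
  if (!is.null(model$codings)) {
    obj$codings <- lapply(model$codings, function(cd)
      list(snp_id = cd$snp_id, one_set = cd$one_set, score = cd$score))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a serialised naive Bayes model
#'
#' @param path Path written by [write_nbc_json()].
#' @return An `nbc_model`.
#' @export
read_nbc_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cpt <- cbind(control = as.numeric(obj$cpt_control),
               case = as.numeric(obj$cpt_case))
  rownames(cpt) <- obj$feature_ids
  out <- structure(list(feature_ids = as.character(obj$feature_ids),
                        prior_positive = obj$prior_positive,
                        cpt = cpt, alpha = obj$alpha,
                        n_train = obj$n_train),
                   class = "nbc_model")
  out
}
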