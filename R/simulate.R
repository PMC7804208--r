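# Synthetic case/control genotype generator: Hardy-Weinberg genotypes,
# a logistic liability over planted causal SNPs, linkage proxies
# (noisy copies), and missing calls.

#' Specify a synthetic case/control genotype study
#'
#' Genotypes at each SNP are drawn under Hardy-Weinberg equilibrium at a
#' minor-allele frequency uniform in `maf_range`; disease status follows a
#' logistic liability summing per-genotype weights over the causal SNPs
#' (centred so the baseline prevalence is `plogis(intercept)`); proxy SNPs
#' are noisy copies of source SNPs (re-drawn from the source's marginal
#' with probability `flip_probability`); missing calls are masked at
#' `missing_rate` (missing completely at random by default).
#'
#' @param n_cases,n_controls Target class sizes.
#' @param n_snps Number of SNPs.
#' @param causal List of causal effects, each `list(index =, weights =)`
#'   with `weights` the per-genotype (AA/AB/BB) liability contributions;
#'   see [causal_additive()] for the common additive parameterisation.
#' @param maf_range Minor-allele-frequency interval within (0, 0.5].
#' @param ld_proxies List of `list(source =, copy =, flip_probability =)`
#'   entries; column `copy` becomes a noisy copy of column `source`.
#' @param missing_rate Probability a genotype call is masked, in `[0, 1)`.
#' @param missing_case_multiplier Optional multiplier on the missing rate
#'   for cases (informative missingness; default 1 = MCAR).
#' @param intercept Baseline log-odds of disease (default 0: prevalence
#'   one half, matching balanced case/control sampling).
#' @param seed Integer seed; everything is reproducible from it.
#' @return A validated list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_cases, n_controls, n_snps, causal = list(),
                            maf_range = c(0.05, 0.5), ld_proxies = list(),
                            missing_rate = 0.02, missing_case_multiplier = 1,
                            intercept = 0, seed = 1L) {
  stopifnot(n_cases >= 1L, n_controls >= 1L, n_snps >= 1L,
            length(maf_range) == 2L, maf_range[1L] > 0,
            maf_range[2L] <= 0.5, maf_range[1L] <= maf_range[2L],
            missing_rate >= 0, missing_rate < 1,
            missing_case_multiplier >= 0)
  for (cs in causal) {
    stopifnot(cs$index >= 1L, cs$index <= n_snps, length(cs$weights) == 3L)
  }
  for (pr in ld_proxies) {
    stopifnot(pr$source >= 1L, pr$source <= n_snps,
              pr$copy >= 1L, pr$copy <= n_snps, pr$source != pr$copy,
              pr$flip_probability >= 0, pr$flip_probability <= 1)
  }
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 n_snps = as.integer(n_snps), causal = causal,
                 maf_range = maf_range, ld_proxies = ld_proxies,
                 missing_rate = missing_rate,
                 missing_case_multiplier = missing_case_multiplier,
                 intercept = intercept, seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Additive causal effects
#'
#' Convenience constructor of per-genotype weights `(0, beta, 2 beta)` --
#' each copy of the minor allele adds `beta` to the disease log-odds.
#'
#' @param indices SNP indices.
#' @param beta Per-allele log-odds effect (recycled).
#' @return A list suitable for `simulation_spec(causal =)`.
#' @export
causal_additive <- function(indices, beta) {
  beta <- rep_len(beta, length(indices))
  Map(function(i, b) list(index = i, weights = c(0, b, 2 * b)),
      indices, beta)
}

.GENO_LABELS <- c("AA", "AB", "BB")

#' Simulate a case/control genotype study
#'
#' Draws genotypes and phenotypes per the spec (see [simulation_spec()]).
#' Case/control quotas are filled by rejection: batches of individuals are
#' generated and assigned a status from the liability model until both
#' quotas are met; an infeasible spec (a quota still unmet after a capped
#' number of batches) is an error.
#'
#' @param spec A [simulation_spec()].
#' @return A list with elements `genotypes` (a [genotype_matrix()]) and
#'   `truth` (class `simulation_truth`: `causal_ids`, `proxy_ids`,
#'   `weights`, `mafs`, `intercept`).
#' @export
simulate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  with_seed(spec$seed, {
    p <- spec$n_snps
    mafs <- stats::runif(p, spec$maf_range[1L], spec$maf_range[2L])
    hw <- rbind((1 - mafs)^2, 2 * mafs * (1 - mafs), mafs^2)  # 3 x p
    causal_idx <- vapply(spec$causal, `[[`, 0, "index")
    W <- vapply(spec$causal, function(cs) as.numeric(cs$weights),
                numeric(3L))
    # Centre the liability so `intercept` is the baseline log-odds.
    centre <- if (length(causal_idx))
      sum(colSums(matrix(W, nrow = 3L) * hw[, causal_idx, drop = FALSE]))
    else 0

    need_case <- spec$n_cases; need_ctrl <- spec$n_controls
    total <- need_case + need_ctrl
    kept_geno <- matrix(0L, 0L, p)
    kept_status <- character(0)
    draw_batch <- function(m) {
      u <- matrix(stats::runif(m * p), m, p)
      g <- matrix(0L, m, p)
      thr1 <- matrix(hw[1L, ], m, p, byrow = TRUE)
      thr2 <- thr1 + matrix(hw[2L, ], m, p, byrow = TRUE)
      g[u >= thr1] <- 1L
      g[u >= thr2] <- 2L
      g
    }
    for (attempt in seq_len(40L)) {
      if (need_case <= 0L && need_ctrl <= 0L) break
      m <- max(64L, ceiling(1.4 * (need_case + need_ctrl)))
      g <- draw_batch(m)
      eta <- rep(spec$intercept - centre, m)
      if (length(causal_idx)) {
        for (k in seq_along(causal_idx)) {
          eta <- eta + W[g[, causal_idx[k]] + 1L, k]
        }
      }
      is_case <- stats::runif(m) < stats::plogis(eta)
      take_case <- which(is_case)[seq_len(min(need_case, sum(is_case)))]
      take_ctrl <- which(!is_case)[seq_len(min(need_ctrl, sum(!is_case)))]
      take <- sort(c(take_case, take_ctrl))
      kept_geno <- rbind(kept_geno, g[take, , drop = FALSE])
      kept_status <- c(kept_status,
                       ifelse(is_case[take], "case", "control"))
      need_case <- spec$n_cases - sum(kept_status == "case")
      need_ctrl <- spec$n_controls - sum(kept_status == "control")
    }
    if (need_case > 0L || need_ctrl > 0L)
      stop("liability model cannot fill the case/control quotas ",
           "(prevalence too extreme for the requested sizes)", call. = FALSE)
    g <- kept_geno
    n <- nrow(g)

    proxy_idx <- integer(0)
    for (pr in spec$ld_proxies) {
      src <- pr$source; dst <- pr$copy
      flip <- stats::runif(n) < pr$flip_probability
      g[, dst] <- g[, src]
      if (any(flip)) {
        u <- stats::runif(sum(flip))
        redraw <- ifelse(u < hw[1L, src], 0L,
                         ifelse(u < hw[1L, src] + hw[2L, src], 1L, 2L))
        g[flip, dst] <- redraw
      }
      proxy_idx <- c(proxy_idx, dst)
    }

    geno <- matrix(.GENO_LABELS[g + 1L], n, p)
    if (spec$missing_rate > 0) {
      rate <- rep(spec$missing_rate, n)
      rate[kept_status == "case"] <-
        min(spec$missing_rate * spec$missing_case_multiplier, 0.95)
      mask <- matrix(stats::runif(n * p), n, p) < rate
      geno[mask] <- NA_character_
    }
    snp_ids <- sprintf("snp%04d", seq_len(p))
    gm <- genotype_matrix(geno, kept_status, snp_ids = snp_ids,
                          sample_ids = sprintf("S%05d", seq_len(n)))
    truth <- structure(
      list(causal_ids = snp_ids[causal_idx],
           proxy_ids = snp_ids[proxy_idx],
           weights = if (length(causal_idx))
             stats::setNames(asplit(matrix(W, nrow = 3L), 2L),
                             snp_ids[causal_idx]) else list(),
           mafs = mafs, intercept = spec$intercept),
      class = "simulation_truth")
    list(genotypes = gm, truth = truth)
  })
}

# Canonical named fixtures with frozen seeds, shared by the test-suite and
# the documentation. Sizes are chosen to exercise the regime each fixture
# stands for while staying desk-scale.
fixture_specs <- list(
  null = quote(simulation_spec(
    n_cases = 250, n_controls = 250, n_snps = 200,
    causal = list(), missing_rate = 0.02, seed = 481101L)),
  planted_small = quote(simulation_spec(
    n_cases = 1000, n_controls = 1000, n_snps = 100,
    causal = causal_additive(1:5, beta = 0.8),
    missing_rate = 0.02, seed = 481102L)),
  planted_polygenic = quote(simulation_spec(
    n_cases = 1000, n_controls = 1000, n_snps = 5000,
    causal = causal_additive(seq_len(50), beta = 0.45),
    ld_proxies = lapply(1:25, function(k)
      list(source = k, copy = 50L + k, flip_probability = 0.1)),
    missing_rate = 0.02, seed = 481103L)),
  duplicated_feature = quote(simulation_spec(
    n_cases = 300, n_controls = 300, n_snps = 30,
    causal = causal_additive(1:2, beta = 1.0),
    ld_proxies = list(list(source = 1L, copy = 3L, flip_probability = 0)),
    missing_rate = 0, seed = 481104L))
)

#' Materialise a canonical simulation fixture
#'
#' Four frozen-seed fixtures used across the test suite and documentation:
#' `null` (no causal SNPs; type-I-error suites), `planted_small` (5 strong
#' causal SNPs among 100), `planted_polygenic` (50 weak causal SNPs among
#' 5000, with 25 linkage proxies -- the many-small-effects regime of a
#' complex disease), and `duplicated_feature` (an exact-copy SNP pair for
#' redundancy-exclusion tests).
#'
#' @param name Fixture name.
#' @param dir Optional directory; when given, writes
#'   `<name>_genotypes.tsv` and `<name>_truth.json` there.
#' @return The `simulate_genotypes()` result, invisibly when `dir` is
#'   given; with `dir`, the element `paths` lists the files written.
#' @export
make_fixture <- function(name = c("null", "planted_small",
                                  "planted_polygenic", "duplicated_feature"),
                         dir = NULL) {
  name <- match.arg(name)
  sim <- simulate_genotypes(eval(fixture_specs[[name]]))
  if (is.null(dir)) return(sim)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gpath <- file.path(dir, paste0(name, "_genotypes.tsv"))
  tpath <- file.path(dir, paste0(name, "_truth.json"))
  write_genotypes(sim$genotypes, gpath)
  jsonlite::write_json(
    list(causal_ids = sim$truth$causal_ids,
         proxy_ids = sim$truth$proxy_ids,
         intercept = sim$truth$intercept),
    tpath, auto_unbox = FALSE, digits = NA)
  sim$paths <- c(genotypes = gpath, truth = tpath)
  invisible(sim)
}
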