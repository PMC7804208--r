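# Shared in-code fixtures for the test suite. Everything is generated
# programmatically under fixed seeds; nothing is read from disk except the
# bundled worked-examples table.

# Binary features generated from a naive-Bayes structure: the phenotype
# drives `n_causal` features at success probabilities p1 (case) vs 1 - p1,
# plus `n_noise` fair-coin features.
make_nb_data <- function(seed, n = 2000, n_causal = 5, n_noise = 50,
                         p1 = 0.7) {
  set.seed(seed)
  t01 <- rbinom(n, 1, 0.5)
  V <- cbind(
    sapply(seq_len(n_causal), function(j)
      rbinom(n, 1, ifelse(t01 == 1, p1, 1 - p1))),
    matrix(rbinom(n * n_noise, 1, 0.5), n, n_noise))
  colnames(V) <- c(sprintf("causal%02d", seq_len(n_causal)),
                   sprintf("noise%02d", seq_len(n_noise)))
  list(V = V, y = ifelse(t01 == 1, "case", "control"),
       causal = sprintf("causal%02d", seq_len(n_causal)))
}

# A small genotype matrix with known content, including missing calls.
make_tiny_gm <- function() {
  geno <- matrix(c("AA", "AG", "GG", "AA", NA,
                   "CC", "CC", "CT", "TT", "CT",
                   "AA", "AA", "AA", "AA", "AA"),
                 nrow = 5,
                 dimnames = list(paste0("S", 1:5), c("rs1", "rs2", "rs3")))
  genotype_matrix(geno, c("case", "case", "control", "control", "case"))
}

# Random multi-category genotype column with every category represented.
random_column <- function(n, m, labels = c("AA", "AB", "BB", missing_label())) {
  labels <- labels[seq_len(m)]
  repeat {
    pr <- rgamma(m, 2); pr <- pr / sum(pr)
    x <- sample(labels, n, replace = TRUE, prob = pr)
    if (length(unique(x)) == m) return(x)
  }
}

random_status <- function(n) sample(c("case", "control"), n, replace = TRUE)

snp_cats <- function(gm, id) unique(gm$geno[, id])

# Independent brute-force coding oracle: every bipartition in both
# orientations, scored with stats::chisq.test (no continuity correction).
oracle_best_coding_score <- function(values, status) {
  cats <- sort(unique(values))
  m <- length(cats)
  best <- -Inf
  for (mask in 1:(2^m - 2)) {
    one <- cats[bitwAnd(mask, bitwShiftL(1, seq_len(m) - 1)) > 0]
    xb <- factor(values %in% one, levels = c(FALSE, TRUE))
    tab <- table(xb, status)
    stat <- suppressWarnings(
      stats::chisq.test(tab, correct = FALSE)$statistic)
    if (is.finite(stat) && stat > best) best <- unname(stat)
  }
  best
}
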