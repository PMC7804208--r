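test_that("bipartition enumeration has 2^(m-1)-1 codings in a deterministic order", {
  expect_length(enumerate_codings(c("AA", "AB")), 1L)
  expect_length(enumerate_codings(c("AA", "AB", "BB")), 3L)
  expect_length(enumerate_codings(c("AA", "AB", "BB", missing_label())), 7L)
  # every coding is a proper bipartition; representatives are unique up to
  # complement-swap (checked against a plain subset enumeration)
  cats <- c("AA", "AB", "BB", missing_label())
  cods <- enumerate_codings(cats)
  keys <- vapply(cods, function(cd) {
    one <- paste(sort(cd$one_set), collapse = "|")
    zero <- paste(sort(cd$zero_set), collapse = "|")
    paste(sort(c(one, zero)), collapse = "//")
  }, "")
  expect_false(anyDuplicated(keys) > 0)
  for (cd in cods) {
    expect_true(length(cd$one_set) >= 1 && length(cd$zero_set) >= 1)
    expect_setequal(c(cd$one_set, cd$zero_set), cats)
  }
  expect_identical(enumerate_codings(cats), enumerate_codings(cats))
  expect_error(enumerate_codings("AA"), "single-category")
})

test_that("chi-square statistic matches hand values and handles degenerate margins", {
  expect_equal(chi2_statistic(matrix(c(10, 10, 10, 10), 2)), 0)
  expect_equal(chi2_statistic(matrix(c(20, 0, 0, 20), 2)), 40)
  expect_equal(chi2_statistic(matrix(c(12, 6, 8, 14), 2)), 3.64,
               tolerance = 0.01 / 3.64)
  # zero margin is defined as no association, not an error
  expect_equal(chi2_statistic(matrix(c(5, 0, 7, 0), 2)), 0)
  expect_error(chi2_statistic(matrix(c(-1, 2, 3, 4), 2)), "negative")
})

test_that("chi-square statistic agrees with stats::chisq.test on random tables", {
  set.seed(11)
  for (i in 1:20) {
    tab <- matrix(rpois(6, 20) + 1, 2, 3)
    expect_equal(chi2_statistic(tab),
                 unname(suppressWarnings(
                   chisq.test(tab, correct = FALSE)$statistic)),
                 tolerance = 1e-12)
  }
})

test_that("optimal coding equals the brute-force argmax over all bipartitions", {
  set.seed(21)
  for (i in 1:30) {
    m <- sample(2:4, 1)
    x <- random_column(200, m)
    y <- random_status(200)
    cd <- optimal_coding(x, y)
    expect_equal(cd$score, oracle_best_coding_score(x, y), tolerance = 1e-12)
  }
})

test_that("complement-swapped codings score identically", {
  set.seed(22)
  x <- random_column(300, 4)
  y <- random_status(300)
  cd <- optimal_coding(x, y)
  tab1 <- table(x %in% cd$one_set, y)
  tab2 <- table(x %in% cd$zero_set, y)
  expect_equal(chi2_statistic(tab1), chi2_statistic(tab2), tolerance = 1e-12)
})

test_that("a genotype seen only in cases is isolated in the one set", {
  x <- c(rep("AA", 30), rep("AB", 30), rep("BB", 20))
  y <- c(rep("case", 20), rep("control", 10), rep("case", 15),
         rep("control", 15), rep("case", 20))  # BB occurs in cases only
  cd <- optimal_coding(x, y)
  expect_true("BB" %in% cd$one_set || "BB" %in% cd$zero_set)
  solo <- if (length(cd$one_set) == 1) cd$one_set else cd$zero_set
  expect_identical(solo, "BB")
})

test_that("a two-category column scores exactly its raw 2x2 table", {
  set.seed(23)
  x <- sample(c("AA", "AB"), 200, replace = TRUE)
  y <- random_status(200)
  cd <- optimal_coding(x, y)
  expect_equal(cd$score, chi2_statistic(table(x, y)), tolerance = 1e-12)
})

test_that("snp2bin drops constant SNPs, preserves order and records provenance", {
  gm <- make_tiny_gm()   # rs3 constant
  bm <- snp2bin(preprocess(gm))
  expect_identical(bm$feature_ids, c("rs1", "rs2"))
  expect_identical(rownames(bm$values), gm$sample_ids)
  expect_true(all(bm$values %in% 0:1))
  # definitional: each entry is one-set membership of the source genotype
  for (id in bm$feature_ids) {
    expect_identical(bm$values[, id],
                     setNames(as.integer(gm$geno[, id] %in%
                                           bm$codings[[id]]$one_set),
                              gm$sample_ids))
  }
  # optimality: each score is at least the score of the fixed
  # first-category-vs-rest coding
  for (id in bm$feature_ids) {
    cats <- sort(unique(gm$geno[, id]))
    fixed <- chi2_statistic(table(gm$geno[, id] == cats[1], gm$status))
    expect_gte(bm$codings[[id]]$score, fixed - 1e-12)
  }
})

test_that("binary recoding does not lose power against a planted effect", {
  # median over replicates: p-value of the optimal 2x2 coding is no larger
  # than the multi-category table's p-value
  set.seed(31)
  p2 <- pm <- numeric(40)
  for (i in 1:40) {
    n <- 400
    t01 <- rbinom(n, 1, 0.5)
    x <- ifelse(runif(n) < 0.25 + 0.12 * t01, "BB",
                ifelse(runif(n) < 0.5, "AB", "AA"))
    y <- ifelse(t01 == 1, "case", "control")
    cd <- optimal_coding(x, y)
    p2[i] <- pchisq(cd$score, 1, lower.tail = FALSE)
    tab <- table(x, y)
    pm[i] <- suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
  }
  expect_lte(median(p2), median(pm))
})

test_that("codings derived under the null stay null on an independent replicate", {
  # independence preservation: replicate p-values are uniform
  set.seed(32)
  pvals <- replicate(200, {
    n <- 200
    pr <- rgamma(3, 2); pr <- pr / sum(pr)
    x1 <- sample(c("AA", "AB", "BB"), n, TRUE, pr)
    y1 <- random_status(n)
    cd <- optimal_coding(x1, y1)
    x2 <- sample(c("AA", "AB", "BB"), n, TRUE, pr)
    y2 <- random_status(n)
    independence_test(as.integer(x2 %in% cd$one_set), y2)$p_value
  })
  expect_gt(suppressWarnings(ks.test(pvals, "punif")$p.value), 0.01)
})
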