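test_that("stratified statistic with empty conditioning equals the marginal test", {
  set.seed(41)
  x <- rbinom(500, 1, 0.4)
  y <- random_status(500)
  t0 <- independence_test(x, y)
  tab <- table(factor(x, 0:1), y)
  expect_equal(t0$statistic, chi2_statistic(tab), tolerance = 1e-12)
  expect_identical(t0$df, 1L)
})

test_that("perfect dependence and within-stratum constancy behave as limits", {
  y <- rep(c("case", "control"), each = 50)
  x <- as.integer(y == "case")
  expect_lt(independence_test(x, y)$p_value, 1e-20)
  # x a deterministic copy of the conditioning variable: no within-stratum
  # variation, statistic 0, p 1
  set.seed(42)
  z <- rbinom(200, 1, 0.5)
  res <- independence_test(z, random_status(200), cond = z)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_error(independence_test(integer(0), character(0)), "empty")
})

test_that("conditioning on the mediator of a chain removes the association", {
  set.seed(44)
  n <- 2000
  x <- rbinom(n, 1, 0.5)
  z <- rbinom(n, 1, ifelse(x == 1, 0.8, 0.2))
  y <- ifelse(rbinom(n, 1, ifelse(z == 1, 0.8, 0.2)) == 1, "case", "control")
  expect_lt(independence_test(x, y)$p_value, 1e-10)
  expect_gt(independence_test(x, y, cond = z)$p_value, 0.05)
})

test_that("unreliable tests (too few samples for the strata) report independence", {
  res <- independence_test(c(0, 1, 0, 1, 1, 0), rep(c("case", "control"), 3),
                           cond = cbind(c(0, 1, 0, 1, 0, 1),
                                        c(1, 1, 0, 0, 1, 0)))
  expect_false(res$reliable)
  expect_equal(res$p_value, 1)
})

test_that("Pearson statistic tracks a hand-rolled G2 on well-populated tables", {
  g2_stat <- function(x, y) {
    tab <- table(x, y)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    2 * sum(ifelse(tab > 0, tab * log(tab / e), 0))
  }
  set.seed(45)
  for (i in 1:20) {
    x <- rbinom(600, 1, runif(1, 0.3, 0.7))
    y <- ifelse(rbinom(600, 1, ifelse(x == 1, 0.55, 0.45)) == 1,
                "case", "control")
    pe <- independence_test(x, y)$statistic
    g2 <- g2_stat(x, y)
    # asymptotically equivalent statistics: cross-check, not equality
    expect_lt(abs(pe - g2), 0.15 * max(pe, g2) + 0.5)
  }
})

test_that("conditional type-I error stays near the nominal level", {
  set.seed(46)
  rej <- 0
  for (i in 1:300) {
    z <- rbinom(400, 1, 0.5)
    x <- rbinom(400, 1, ifelse(z == 1, 0.7, 0.3))
    y <- ifelse(rbinom(400, 1, ifelse(z == 1, 0.7, 0.3)) == 1,
                "case", "control")
    if (independence_test(x, y, cond = z)$p_value < 0.05) rej <- rej + 1
  }
  expect_gt(rej / 300, 0.02)
  expect_lt(rej / 300, 0.09)
})

test_that("order-0 scan is uniform under the null and flags a planted signal", {
  set.seed(47)
  V <- matrix(rbinom(400 * 60, 1, 0.5), 400, 60)
  colnames(V) <- paste0("f", 1:60)
  y <- random_status(400)
  sc <- association_scan(V, y, order = 0)
  expect_gt(suppressWarnings(ks.test(sc$p, "punif")$p.value), 0.01)
  # plant one causal feature: its p-value drops below the Bonferroni line
  t01 <- rbinom(2000, 1, 0.5)
  V2 <- cbind(causal = rbinom(2000, 1, ifelse(t01 == 1, 0.7, 0.3)),
              matrix(rbinom(2000 * 59, 1, 0.5), 2000, 59))
  colnames(V2) <- c("causal", paste0("f", 1:59))
  sc2 <- association_scan(V2, ifelse(t01 == 1, "case", "control"), order = 0)
  expect_lt(sc2$p[sc2$snp_id == "causal"], 0.05 / ncol(V2))
})

test_that("order-1 scan exposes superficially high associations of redundant SNPs", {
  set.seed(48)
  n <- 2000
  t01 <- rbinom(n, 1, 0.5)
  causal <- rbinom(n, 1, ifelse(t01 == 1, 0.75, 0.25))
  proxy <- causal
  fl <- rbinom(n, 1, 0.05) == 1
  proxy[fl] <- 1L - proxy[fl]
  V <- cbind(causal = causal, proxy = proxy,
             noise = rbinom(n, 1, 0.5))
  y <- ifelse(t01 == 1, "case", "control")
  sc0 <- association_scan(V, y, order = 0)
  sc1 <- association_scan(V, y, order = 1, conditioning_pool = "causal")
  expect_lt(sc0$p[sc0$snp_id == "proxy"], 1e-10)       # marginally strong
  expect_gt(sc1$p[sc1$snp_id == "proxy"], 0.05)        # vanishes conditioned
  expect_error(association_scan(V, y, order = 1), "conditioning_pool")
})
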