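test_that("smoothed CPT estimation follows the counting formula", {
  V <- cbind(f = c(rep(1, 8), rep(0, 2), rep(1, 2), rep(0, 8)))
  y <- rep(c("case", "control"), each = 10)
  m <- nbc_fit(V, y, alpha = 1)
  expect_equal(unname(m$cpt["f", "case"]), 9 / 12)
  expect_equal(unname(m$cpt["f", "control"]), 3 / 12)
  expect_equal(m$prior_positive, 0.5)
  expect_error(nbc_fit(V, y, alpha = 0), "alpha")
  expect_error(nbc_fit(V, rep("case", 10)), "binary|both classes")
})

test_that("posterior follows Bayes rule on hand-computable cases", {
  m <- structure(list(feature_ids = "f", prior_positive = 0.5,
                      cpt = matrix(c(0.25, 0.75), 1,
                                   dimnames = list("f", c("control", "case"))),
                      alpha = 1, n_train = 20),
                 class = "nbc_model")
  expect_equal(posterior_positive(m, c(f = 1)), 0.75, tolerance = 1e-12)
  expect_equal(posterior_positive(m, c(f = 0)), 0.25, tolerance = 1e-12)
  # uninformative evidence: posterior equals the prior
  m$cpt[] <- 0.4
  expect_equal(posterior_positive(m, c(f = 1)), 0.5, tolerance = 1e-12)
  # prior-only model
  V <- cbind(f = rep(0:1, 10))
  y <- rep(c("case", "control"), 10)
  m0 <- nbc_fit(V, y, features = character(0))
  expect_equal(posterior_positive(m0, V), rep(0.5, 20), tolerance = 1e-12)
  # instances must cover the model's features
  m1 <- nbc_fit(V, y)
  expect_error(posterior_positive(m1, matrix(1, 1, 1,
                                             dimnames = list(NULL, "g"))),
               "missing")
})

test_that("posterior equals the brute-force joint-table computation", {
  # independent oracle: enumerate the full joint distribution over all
  # feature configurations and condition on it
  set.seed(61)
  p <- 10
  V <- matrix(rbinom(60 * p, 1, 0.5), 60, p,
              dimnames = list(NULL, paste0("f", 1:p)))
  y <- random_status(60)
  m <- nbc_fit(V, y, alpha = 1)
  grid <- as.matrix(expand.grid(rep(list(0:1), p)))
  colnames(grid) <- paste0("f", 1:p)
  got <- posterior_positive(m, grid)
  joint <- function(cls) {
    pr <- if (cls == "case") m$prior_positive else 1 - m$prior_positive
    lik <- rep(pr, nrow(grid))
    for (j in seq_len(p)) {
      pj <- m$cpt[j, cls]
      lik <- lik * ifelse(grid[, j] == 1, pj, 1 - pj)
    }
    lik
  }
  jc <- joint("case"); j0 <- joint("control")
  expect_equal(got, jc / (jc + j0), tolerance = 1e-12)
})

test_that("decision threshold predicts case on exact ties", {
  V <- cbind(f = rep(0:1, 10))
  y <- rep(c("case", "control"), 10)
  m0 <- nbc_fit(V, y, features = character(0))  # posterior exactly 0.5
  expect_true(all(predict(m0, V, type = "class") == "case"))
})

test_that("CV score is reproducible, order-invariant and sensibly bounded", {
  d <- make_nb_data(62, n = 200, n_causal = 3, n_noise = 5)
  s1 <- model_score(d$V, d$y, features = c("causal01", "causal02"),
                    folds = 10, seed = 3)
  s2 <- model_score(d$V, d$y, features = c("causal02", "causal01"),
                    folds = 10, seed = 3)
  expect_identical(s1, s2)           # bit-reproducible and order-invariant
  # empty set on balanced classes: about n * log(0.5)
  s0 <- model_score(d$V, d$y, features = character(0), folds = 10, seed = 3)
  expect_equal(s0, 200 * log(0.5), tolerance = 0.01)
  # a perfectly predictive feature scores near 0
  y <- rep(c("case", "control"), each = 100)
  V <- cbind(perfect = as.integer(y == "case"))
  expect_gt(model_score(V, y, features = "perfect", folds = 10, seed = 3),
            -0.05 * 200)
})

test_that("an independent noise feature does not raise the expected score", {
  set.seed(63)
  diffs <- replicate(30, {
    V <- cbind(noise = rbinom(300, 1, 0.5))
    y <- random_status(300)
    model_score(V, y, features = "noise", folds = 10, seed = 5) -
      model_score(V, y, features = character(0), folds = 10, seed = 5)
  })
  expect_lt(mean(diffs), 0)
})
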