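test_that("confusion metrics match hand computations", {
  pred <- c(rep("case", 9), "control", rep("control", 8), "case", "case")
  labs <- c(rep("case", 10), rep("control", 10))
  m <- confusion_metrics(pred, labs)
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$accuracy, 0.85)
  expect_identical(c(m$tp, m$fn, m$tn, m$fp), c(9L, 1L, 8L, 2L))
  # all correct
  all_ok <- confusion_metrics(labs, labs)
  expect_equal(all_ok$accuracy, 1)
  expect_equal(all_ok$mcc, 1)
  # degenerate denominator defined as 0
  expect_equal(confusion_metrics(rep("case", 5), rep("case", 5))$mcc, 0)
  expect_error(confusion_metrics(character(0), character(0)), "empty")
})

test_that("MCC equals the Pearson correlation of prediction/label vectors", {
  set.seed(91)
  for (i in 1:30) {
    n <- sample(20:200, 1)
    pred <- rbinom(n, 1, runif(1, 0.2, 0.8))
    labs <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(pred)) < 2 || length(unique(labs)) < 2) next
    m <- confusion_metrics(ifelse(pred == 1, "case", "control"),
                           ifelse(labs == 1, "case", "control"))
    expect_equal(m$mcc, cor(pred, labs), tolerance = 1e-12)
  }
})

test_that("random predictions on balanced labels give MCC near zero", {
  set.seed(92)
  m <- confusion_metrics(ifelse(rbinom(4000, 1, 0.5) == 1, "case", "control"),
                         rep(c("case", "control"), 2000))
  expect_lt(abs(m$mcc), 0.06)
})

test_that("leave-one-out behaves at the separable, null and degenerate limits", {
  # perfectly separable
  y <- rep(c("case", "control"), each = 30)
  V <- cbind(f = as.integer(y == "case"))
  expect_equal(loo_evaluate(V, y, features = "f")$accuracy, 1)
  # single uninformative feature: near chance
  set.seed(93)
  V2 <- cbind(f = rbinom(1000, 1, 0.5))
  y2 <- rep(c("case", "control"), 500)
  acc <- loo_evaluate(V2, y2, features = "f")$accuracy
  expect_gt(acc, 0.4); expect_lt(acc, 0.6)
  # n = 2, one per class: defined, both folds evaluated
  r <- loo_evaluate(cbind(f = c(0, 1)), c("case", "control"), features = "f")
  expect_length(r$posterior, 2)
  expect_error(loo_evaluate(cbind(f = 1), "case", features = "f"), "2 samples")
})

test_that("leave-one-out of a prior-only model predicts the training majority", {
  # balanced data: removing a sample makes its own class the minority, so
  # every held-out sample is predicted as the other class (accuracy 0)
  y <- rep(c("case", "control"), each = 10)
  V <- matrix(integer(0), 20, 0)
  r <- loo_evaluate(V, y, features = integer(0))
  expect_equal(r$accuracy, 0)
  # unbalanced data: the global majority wins every fold
  y2 <- c(rep("case", 15), rep("control", 5))
  r2 <- loo_evaluate(matrix(integer(0), 20, 0), y2, features = integer(0))
  expect_equal(r2$accuracy, 0.75)
})

test_that("repeated k-fold is reproducible and reports spread", {
  d <- make_nb_data(94, n = 150, n_causal = 2, n_noise = 4, p1 = 0.6)
  r1 <- repeated_kfold(d$V, d$y, features = d$causal[1:2], repeats = 2,
                       seed = 7)
  r2 <- repeated_kfold(d$V, d$y, features = d$causal[1:2], repeats = 2,
                       seed = 7)
  expect_identical(r1$per_repeat, r2$per_repeat)
  # with weak features the fold split genuinely moves the estimate
  r3 <- repeated_kfold(d$V, d$y, features = colnames(d$V), repeats = 20,
                       seed = 8)
  expect_gt(r3$accuracy_sd, 0)
  # k larger than the smallest class is reduced with a warning
  yk <- c(rep("case", 4), rep("control", 40))
  Vk <- cbind(f = rbinom(44, 1, 0.5))
  expect_warning(repeated_kfold(Vk, yk, features = "f", k = 10, repeats = 1,
                                seed = 1),
                 "reducing k")
})

test_that("k-fold and leave-one-out agree on planted-signal data", {
  d <- make_nb_data(95, n = 400, n_causal = 3, n_noise = 3, p1 = 0.65)
  loo <- loo_evaluate(d$V, d$y, features = d$causal)
  kf <- repeated_kfold(d$V, d$y, features = d$causal, repeats = 20, seed = 9)
  expect_lt(abs(kf$accuracy - loo$accuracy), 2 * max(kf$accuracy_sd, 0.01))
})
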