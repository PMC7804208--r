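test_that("opt adds the best candidate first, subopt the second best", {
  set.seed(71)
  n <- 600
  t01 <- rbinom(n, 1, 0.5)
  V <- cbind(strong = rbinom(n, 1, ifelse(t01 == 1, 0.85, 0.15)),
             weak = rbinom(n, 1, ifelse(t01 == 1, 0.65, 0.35)))
  y <- ifelse(t01 == 1, "case", "control")
  tr_opt <- forward_phase(V, y, variant = "opt", seed = 2)
  tr_sub <- forward_phase(V, y, variant = "subopt", seed = 2)
  expect_identical(tr_opt$steps$feature_id[1], "strong")
  expect_identical(tr_sub$steps$feature_id[1], "weak")
})

test_that("a single informative candidate is selected and the phase stops", {
  y <- rep(c("case", "control"), each = 60)
  V <- cbind(hit = as.integer(y == "case"))
  tr <- forward_phase(V, y, variant = "opt", seed = 1)
  expect_identical(tr$features, "hit")
  expect_identical(nrow(tr$steps), 1L)
  # subopt falls back to the best when only one candidate improves
  tr2 <- forward_phase(cbind(V, dead = rep(0:1, 60)), y,
                       variant = "subopt", seed = 1)
  expect_identical(tr2$steps$feature_id[1], "hit")
})

test_that("forward-phase committed scores are strictly increasing", {
  for (s in c(72, 73)) {
    d <- make_nb_data(s, n = 500, n_causal = 4, n_noise = 10)
    for (variant in c("opt", "subopt")) {
      tr <- forward_phase(d$V, d$y, variant = variant, seed = 3)
      fw <- tr$steps$score_after[tr$steps$phase == "forward"]
      expect_true(all(diff(fw) > 0))
    }
  }
})

test_that("backward phase drops a redundant feature without lowering the score", {
  # constructed fixture: a noisy majority-summary of three sources is
  # redundant once all three sources are in the model
  set.seed(1)
  n <- 600
  t01 <- rbinom(n, 1, 0.5)
  a <- rbinom(n, 1, ifelse(t01 == 1, 0.70, 0.30))
  b <- rbinom(n, 1, ifelse(t01 == 1, 0.70, 0.30))
  d <- rbinom(n, 1, ifelse(t01 == 1, 0.70, 0.30))
  summ <- as.integer(a + b + d >= 2)
  fl <- rbinom(n, 1, 0.15) == 1
  summ[fl] <- 1L - summ[fl]
  V <- cbind(summary_f = summ, a = a, b = b, d = d)
  y <- ifelse(t01 == 1, "case", "control")
  full <- model_score(V, y, features = colnames(V), folds = 10, seed = 2)
  tr <- structure(list(variant = "opt",
                       steps = data.frame(phase = character(0),
                                          feature_id = character(0),
                                          score_after = numeric(0)),
                       features = colnames(V), score = full, folds = 10,
                       seed = 2, alpha = 1, forward_done = TRUE),
                  class = "selection_trace")
  out <- backward_phase(tr, V, y)
  expect_false("summary_f" %in% out$features)
  expect_gte(out$score, full)
  bw <- out$steps$score_after[out$steps$phase == "backward"]
  expect_true(all(diff(c(full, bw)) >= 0))
  # the model is never emptied below one feature
  V1 <- V[, "a", drop = FALSE]
  tr1 <- forward_phase(V1, y, seed = 2)
  out1 <- backward_phase(tr1, V1, y)
  expect_gte(length(out1$features), 1L)
})

test_that("selection is deterministic given data and seed", {
  d <- make_nb_data(74, n = 400, n_causal = 3, n_noise = 8)
  s1 <- optnbc(d$V, d$y, folds = 10, seed = 6)
  s2 <- optnbc(d$V, d$y, folds = 10, seed = 6)
  expect_identical(s1$trace$steps, s2$trace$steps)
  expect_identical(s1$model$feature_ids, s2$model$feature_ids)
})

test_that("greedy selection is near the exhaustive-subset optimum", {
  set.seed(75)
  for (prob in 1:3) {
    n <- 200
    t01 <- rbinom(n, 1, 0.5)
    p_eff <- runif(6, 0.5, 0.75)
    V <- sapply(1:6, function(j)
      rbinom(n, 1, ifelse(t01 == 1, p_eff[j], 1 - p_eff[j])))
    colnames(V) <- paste0("f", 1:6)
    y <- ifelse(t01 == 1, "case", "control")
    sel <- optnbc(V, y, folds = 10, seed = 5)
    best <- -Inf
    for (mask in 0:63) {
      feats <- which(bitwAnd(mask, bitwShiftL(1, 0:5)) > 0)
      best <- max(best, model_score(V, y, features = feats,
                                    folds = 10, seed = 5))
    }
    expect_gte(sel$score, best / 0.95)  # scores are negative
  }
})

test_that("opt and subopt diverge on the duplicated-feature fixture", {
  sim <- make_fixture("duplicated_feature")
  bm <- snp2bin(preprocess(sim$genotypes))
  m1 <- optnbc(bm, folds = 10, seed = 8, max_features = 10)
  m2 <- suboptnbc(bm, folds = 10, seed = 8, max_features = 10)
  expect_false(identical(m1$model$feature_ids, m2$model$feature_ids))
  # comparable scores: two experts of similar quality
  expect_lt(abs(m1$score - m2$score), 0.2 * abs(m1$score))
})

test_that("null data yields models far smaller than the candidate pool", {
  # The frozen fold split means the max over many noisy CV deltas is
  # positive with non-trivial probability, so a handful of null features
  # slip in; the guard is that the greedy search stops well before
  # swallowing the pool (see the vignette's overfitting discussion).
  set.seed(76)
  sizes <- replicate(10, {
    V <- matrix(rbinom(1000 * 50, 1, 0.5), 1000, 50)
    colnames(V) <- paste0("f", 1:50)
    y <- random_status(1000)
    sel <- optnbc(V, y, folds = 10, seed = 4)
    length(sel$model$feature_ids)
  })
  expect_true(all(sizes <= 16))
  expect_lt(mean(sizes), 12)
})

test_that("an empty candidate set returns a prior-only model with a warning", {
  d <- make_nb_data(77, n = 100, n_causal = 1, n_noise = 2)
  expect_warning(sel <- optnbc(d$V, d$y, candidates = character(0), seed = 1),
                 "empty")
  expect_length(sel$model$feature_ids, 0)
})
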