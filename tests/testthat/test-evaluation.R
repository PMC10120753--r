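test_that("metrics hit their textbook values", {
  perfect <- rbind(c(0.9, 0.1), c(0.1, 0.9), c(0.8, 0.2), c(0.2, 0.8))
  rep_b <- compute_metrics(perfect, c(0, 1, 0, 1))
  expect_equal(rep_b$acc, 1)
  expect_equal(rep_b$f1, 1)
  expect_equal(rep_b$auc, 1)

  # argmax accuracy with one false positive
  probs <- cbind(1 - c(0.9, 0.8, 0.6, 0.1), c(0.9, 0.8, 0.6, 0.1))
  labels <- c(1, 1, 0, 0)
  rep1 <- compute_metrics(probs, labels)
  expect_equal(rep1$acc, 0.75)
  expect_equal(rep1$auc, auc_oracle(probs[, 2], labels))

  # a tied positive-negative pair contributes one half: 3.5 of 4 pairs
  p_tie <- c(0.9, 0.6, 0.6, 0.1)
  rep2 <- compute_metrics(cbind(1 - p_tie, p_tie), labels)
  expect_equal(rep2$auc, 0.875)
  expect_equal(rep2$auc, auc_oracle(p_tie, labels))
})

test_that("rank-statistic AUC equals brute-force enumeration", {
  set.seed(5)
  for (rep_i in 1:30) {
    n <- sample(4:50, 1)
    labels <- rbinom(n, 1, 0.5)
    p1 <- round(runif(n), 2)  # rounding forces occasional ties
    ours <- compute_metrics(cbind(1 - p1, p1), labels)$auc
    expect_equal(ours, auc_oracle(p1, labels), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(6)
  labels <- rbinom(40, 1, 0.5)
  p1 <- runif(40)
  ours <- compute_metrics(cbind(1 - p1, p1), labels)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, p1, quiet = TRUE,
                                        levels = c(0, 1), direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("degenerate single-class labels give NA AUC, not zero", {
  p1 <- c(0.2, 0.8, 0.5)
  rep_d <- compute_metrics(cbind(1 - p1, p1), c(1, 1, 1))
  expect_true(is.na(rep_d$auc))
  expect_false(identical(rep_d$auc, 0))
})

test_that("weighted and macro F1 coincide under equal support", {
  set.seed(7)
  labels <- rep(0:2, each = 10)
  probs <- matrix(runif(90), 30, 3)
  probs <- probs / rowSums(probs)
  rep_m <- compute_metrics(probs, labels, task = "multiclass")
  expect_equal(rep_m$weighted_f1, rep_m$macro_f1)
  expect_true(all(c(rep_m$acc, rep_m$weighted_f1, rep_m$macro_f1) >= 0))
  expect_true(all(c(rep_m$acc, rep_m$weighted_f1, rep_m$macro_f1) <= 1))
})

test_that("accuracy and F1 are invariant to argmax-preserving rescaling", {
  set.seed(8)
  probs <- matrix(runif(20), 10, 2)
  probs <- probs / rowSums(probs)
  labels <- rbinom(10, 1, 0.5)
  a <- compute_metrics(probs, labels)
  squashed <- probs^3 / rowSums(probs^3)  # monotone, argmax-preserving
  b <- compute_metrics(squashed, labels)
  expect_equal(a$acc, b$acc)
  expect_equal(a$f1, b$f1)
})

test_that("a single-point sweep reduces to complete-data evaluation", {
  ds <- tiny_dataset(n = 40, v = c(8, 7, 6))
  ctl <- fast_control(epochs = 10)
  sw <- missing_rate_sweep(ds, etas = 0, seeds = 1, control = ctl)
  expect_equal(nrow(sw), 1L)
  expect_equal(sw$eta, 0)
  # at eta = 0 there is no mask randomness: a second run is identical
  sw2 <- missing_rate_sweep(ds, etas = 0, seeds = 1, control = ctl)
  expect_identical(sw, sw2)
})

test_that("sweep tables are reproducible and carry summaries", {
  ds <- tiny_dataset(n = 40, v = c(8, 7, 6))
  ctl <- fast_control(epochs = 8)
  sw <- missing_rate_sweep(ds, etas = c(0.2, 0.4), seeds = c(1, 2),
                           control = ctl)
  expect_equal(nrow(sw), 4L)
  expect_identical(sw, missing_rate_sweep(ds, etas = c(0.2, 0.4),
                                          seeds = c(1, 2), control = ctl))
  s <- attr(sw, "summary")
  expect_equal(nrow(s), 2L)
  expect_true(all(c("mean", "se") %in% names(s)))
})

test_that("layer combinations default to all-layers plus pairs", {
  ds <- tiny_dataset(n = 40, v = c(8, 7, 6))
  ctl <- fast_control(epochs = 8)
  lc <- layer_combination_study(ds, eta = 0, seeds = 1, control = ctl)
  expect_equal(nrow(lc), 4L)  # all three + the three pairs
  expect_setequal(lc$combo,
                  c("omics1+omics2+omics3", "omics1+omics2",
                    "omics1+omics3", "omics2+omics3"))
  expect_error(layer_combination_study(ds, combos = list(character(0)),
                                       control = ctl), "domain error")
})

test_that("a signal-free layer hurts at high missing rates", {
  # two informative layers plus one pure-noise layer
  ds <- tiny_dataset(n = 90, v = c(20, 20, 20), sep = 4, seed = 3)
  set.seed(31)
  ds$layers[[3]][] <- rnorm(length(ds$layers[[3]]))
  ctl <- fast_control(epochs = 60, latent_dim = 8)
  lc <- layer_combination_study(
    ds, combos = list(c(1, 2), c(1, 3), c(2, 3)), eta = 0.6,
    seeds = 1:3, control = ctl)
  s <- attr(lc, "summary")
  acc_clean <- s$mean[s$key == "omics1+omics2"]
  acc_noisy <- s$mean[s$key %in% c("omics1+omics3", "omics2+omics3")]
  expect_gt(acc_clean, max(acc_noisy))
})

test_that("the ablation table has the four variants with reduced objectives", {
  ds <- tiny_dataset(n = 40, v = c(8, 7, 6))
  ab <- ablation_study(ds, eta = 0.3, seeds = 1,
                       control = fast_control(epochs = 6))
  expect_setequal(ab$variant, c("plain", "ctst", "aux", "ctst+aux"))
  expect_equal(nrow(ab), 4L)
})
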