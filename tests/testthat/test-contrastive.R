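test_that("latents map to row-stochastic distributions", {
  expect_equal(latents_to_distributions(c(0, 0)), matrix(0.5, 1, 2),
               ignore_attr = TRUE)
  expect_equal(as.numeric(latents_to_distributions(c(log(3), 0))),
               c(0.75, 0.25))
  z <- matrix(rnorm(12), 3, 4)
  s <- latents_to_distributions(z)
  expect_equal(rowSums(s), rep(1, 3))
  expect_true(all(s > 0 & s < 1))
  # shift invariance per row
  expect_equal(latents_to_distributions(z + 5), s)
})

test_that("the joint distribution is a normalized average outer product", {
  jd <- joint_distribution(matrix(c(1, 0), 1), matrix(c(1, 0), 1))
  expect_equal(jd$P, matrix(c(1, 0, 0, 0), 2, 2))
  expect_equal(jd$row_marginals, c(1, 0))

  s <- matrix(1 / 3, 4, 3)
  jd_u <- joint_distribution(s, s)
  expect_equal(jd_u$P, matrix(1 / 9, 3, 3))

  set.seed(1)
  for (rep_i in 1:10) {
    a <- latents_to_distributions(matrix(rnorm(15), 3, 5))
    b <- latents_to_distributions(matrix(rnorm(15), 3, 5))
    expect_equal(sum(joint_distribution(a, b)$P), 1)
  }
  expect_error(joint_distribution(matrix(1, 2, 2), matrix(1, 3, 2)),
               "dimension error")
})

test_that("contrastive loss matches the double-loop oracle", {
  set.seed(2)
  for (rep_i in 1:100) {
    di <- sample(2:5, 1); dk <- sample(2:5, 1)
    n <- sample(2:6, 1)
    a <- latents_to_distributions(matrix(rnorm(n * di), n, di))
    b <- latents_to_distributions(matrix(rnorm(n * dk), n, dk))
    alpha <- sample(c(0, 1, 9), 1)
    jd <- joint_distribution(a, b, alpha)
    expect_equal(pair_contrastive_loss(jd),
                 contrastive_oracle(jd$P, alpha), tolerance = 1e-10)
  }
})

test_that("closed-form limits hold", {
  # degenerate single dimension
  expect_equal(pair_contrastive_loss(matrix(1, 1, 1), alpha = 5), 0)
  # uniform P over D x D gives -2 alpha log D
  for (D in c(2, 4, 8)) {
    for (alpha in c(0, 1, 9)) {
      P <- matrix(1 / D^2, D, D)
      expect_equal(pair_contrastive_loss(P, alpha = alpha),
                   -2 * alpha * log(D), tolerance = 1e-12)
    }
  }
  # independence with alpha = 0 vanishes
  p <- c(0.2, 0.3, 0.5); q <- c(0.6, 0.4)
  expect_equal(pair_contrastive_loss(outer(p, q), alpha = 0), 0,
               tolerance = 1e-12)
  # zero entries contribute zero (0 log 0 convention), loss stays finite
  P <- matrix(c(0.5, 0, 0, 0.5), 2, 2)
  expect_true(is.finite(pair_contrastive_loss(P, alpha = 1)))
  expect_error(pair_contrastive_loss(matrix(c(-0.1, 1.1, 0, 0), 2, 2),
                                     alpha = 0), "validity error")
})

test_that("multi-omics loss sums ordered pairs and respects symmetry", {
  set.seed(3)
  z <- matrix(rnorm(20), 4, 5)
  # identical views: twice the single-pair loss
  s <- latents_to_distributions(z)
  single <- pair_contrastive_loss(joint_distribution(s, s, 9))
  expect_equal(multi_omics_contrastive_loss(list(z, z)), 2 * single)
  expect_equal(multi_omics_contrastive_loss(list(z, z), pairs = "unordered"),
               single)

  # M = 3: six ordered pair terms, invariant to relabeling
  zs <- lapply(1:3, function(i) matrix(rnorm(20), 4, 5))
  total <- multi_omics_contrastive_loss(zs)
  manual <- 0
  for (i in 1:3) for (k in 1:3) {
    if (i != k) {
      manual <- manual + pair_contrastive_loss(joint_distribution(
        latents_to_distributions(zs[[i]]),
        latents_to_distributions(zs[[k]]), 9))
    }
  }
  expect_equal(total, manual)
  expect_equal(multi_omics_contrastive_loss(zs[c(2, 3, 1)]), total)

  # pair loss is symmetric after symmetrization
  a <- latents_to_distributions(matrix(rnorm(20), 4, 5))
  b <- latents_to_distributions(matrix(rnorm(20), 4, 5))
  expect_equal(pair_contrastive_loss(joint_distribution(a, b, 3)),
               pair_contrastive_loss(joint_distribution(b, a, 3)),
               tolerance = 1e-10)
})

test_that("mutual information grows as paired views get cleaner", {
  # sign test over 20 replicates: MI (negative of the alpha = 0 loss) at low
  # noise should be at least the MI at high noise
  wins <- 0L
  for (rep_i in 1:20) {
    set.seed(rep_i + 50)
    z <- matrix(rnorm(40 * 4, sd = 2), 40, 4)
    mi_at <- function(noise) {
      a <- z + matrix(rnorm(length(z), sd = noise), nrow(z))
      b <- z + matrix(rnorm(length(z), sd = noise), nrow(z))
      -pair_contrastive_loss(joint_distribution(
        latents_to_distributions(a), latents_to_distributions(b), 0))
    }
    if (mi_at(0.2) >= mi_at(2)) wins <- wins + 1L
  }
  # one-sided binomial bound: 15+/20 successes rejects p = 1/2 at 0.05
  expect_gte(wins, 15L)
})
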