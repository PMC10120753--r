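test_that("feature attention is the sigmoid of the attention net", {
  f0 <- const_stack("3-3")
  expect_equal(feature_attention(c(1, -5, 100), f0),
               matrix(0.5, 1, 3), ignore_attr = TRUE)

  f1 <- identity_stack(1)
  expect_equal(as.numeric(feature_attention(0, f1)), 0.5)
  expect_gt(as.numeric(feature_attention(30, f1)), 1 - 1e-10)

  f2 <- linear_stack(matrix(c(1, 0, 0, -1), 2, 2))
  expect_equal(as.numeric(feature_attention(c(log(3), log(3)), f2)),
               c(0.75, 0.25))

  expect_error(feature_attention(c(1, 2), f0), "dimension error")
})

test_that("feature-attended embedding honours both gating conventions", {
  emb <- identity_stack(2)   # no bias, so emb(0) = 0 under either gate
  x <- c(2, 4)
  expect_equal(embed_with_feature_attention(x, c(1, 1), emb),
               matrix(x, 1), ignore_attr = TRUE)
  expect_equal(embed_with_feature_attention(x, c(0, 0), emb),
               matrix(0, 1, 2), ignore_attr = TRUE)
  expect_equal(embed_with_feature_attention(x, c(0, 0), emb,
                                            convention = "output"),
               matrix(0, 1, 2), ignore_attr = TRUE)
  expect_equal(embed_with_feature_attention(x, c(0.5, 0.25), emb),
               matrix(c(1, 1), 1), ignore_attr = TRUE)
  # non-square embedding only types under input gating
  emb2 <- linear_stack(matrix(1, 3, 2))
  expect_silent(embed_with_feature_attention(c(1, 1, 1), c(1, 1, 1), emb2))
  expect_error(embed_with_feature_attention(c(1, 1, 1), c(1, 1, 1), emb2,
                                            convention = "output"),
               "dimension error")
})

test_that("omics attention is a sigmoid scalar per subject", {
  g0 <- const_stack("2-1")
  expect_equal(as.numeric(omics_attention(c(4, -4), g0)), 0.5)
  g1 <- linear_stack(matrix(c(1, 1), 2, 1))
  expect_equal(as.numeric(omics_attention(c(0, 0), g1)), 0.5)
  g2 <- linear_stack(matrix(c(1, 0), 2, 1))
  expect_equal(as.numeric(omics_attention(c(log(3), 7), g2)), 0.75)
  expect_error(omics_attention(c(1, 2, 3), g0), "dimension error")
})

test_that("omics-level scaling is scalar multiplication", {
  expect_equal(scale_by_omics_attention(c(2, -4), 0.5),
               matrix(c(1, -2), 1), ignore_attr = TRUE)
  x <- matrix(rnorm(6), 2, 3)
  matt <- c(0.3, 0.9)
  z <- scale_by_omics_attention(x, matt)
  expect_equal(sqrt(rowSums(z^2)), matt * sqrt(rowSums(x^2)))
})

test_that("fusion concatenates blocks in layer order", {
  z1 <- matrix(c(1, 2), 1)
  z2 <- matrix(3, 1)
  expect_equal(fuse_latents(list(z1, z2)), matrix(c(1, 2, 3), 1),
               ignore_attr = TRUE)
  # permuting the layers permutes the blocks
  expect_equal(fuse_latents(list(z2, z1)), matrix(c(3, 1, 2), 1),
               ignore_attr = TRUE)
  # fused width is the sum of latent dims (the 3 x 300 -> 900 pattern)
  zs <- lapply(1:3, function(i) matrix(rnorm(300), 1))
  expect_equal(ncol(fuse_latents(zs)), 900)
  # blocks are recoverable by slicing
  fused <- fuse_latents(list(z1, z2))
  expect_equal(fused[, 1:2, drop = FALSE], z1, ignore_attr = TRUE)
  expect_error(fuse_latents(list(z1, matrix(NA_real_, 1, 1))),
               "completion required")
})

test_that("attention scores stay inside (0,1) for finite inputs", {
  set.seed(7)
  for (rep_i in 1:20) {
    v <- sample(2:6, 1)
    f <- build_stack(sprintf("%d-%d", v, v))
    g <- build_stack(sprintf("%d-1", v))
    x <- matrix(rnorm(5 * v, sd = 10), 5, v)
    fatt <- feature_attention(x, f)
    matt <- omics_attention(x, g)
    expect_true(all(fatt > 0 & fatt < 1))
    expect_true(all(matt > 0 & matt < 1))
  }
})

test_that("zeroed attention nets reduce the pipeline to 0.25 x embedding", {
  set.seed(8)
  v <- 4
  x <- matrix(rnorm(3 * v), 3, v)
  f0 <- const_stack(sprintf("%d-%d", v, v))
  g0 <- const_stack(sprintf("%d-1", v))
  emb <- linear_stack(matrix(rnorm(v * v), v, v))  # linear, no bias
  fatt <- feature_attention(x, f0)
  xhat <- embed_with_feature_attention(x, fatt, emb)
  matt <- omics_attention(xhat, g0)
  zhat <- scale_by_omics_attention(xhat, matt)
  expect_equal(zhat, 0.25 * clclsa:::stack_apply(emb, x), tolerance = 1e-12)
})
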