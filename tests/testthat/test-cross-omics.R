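test_that("the translator set has M(M-1) directed members", {
  set.seed(1)
  ae <- cross_omics_ae(3, 6)
  n_tr <- sum(vapply(seq_len(3), function(i)
    sum(!vapply(ae$h[[i]], is.null, TRUE)), integer(1)))
  expect_equal(n_tr, 6L)
  expect_error(predict_latent(ae, 2, 2, rnorm(6)), "invalid pair")
  # deterministic forward for a fixed (seeded) net
  z <- rnorm(6)
  expect_identical(predict_latent(ae, 1, 2, z), predict_latent(ae, 1, 2, z))
})

test_that("a zero-weight translator maps everything to zero", {
  ae <- cross_omics_ae(2, 4)
  for (i in 1:2) for (k in 1:2) {
    if (i != k) {
      for (s in seq_along(ae$h[[i]][[k]]$steps)) {
        st <- ae$h[[i]][[k]]$steps[[s]]
        if (st$type == "linear") {
          ae$h[[i]][[k]]$steps[[s]]$W[] <- 0
          ae$h[[i]][[k]]$steps[[s]]$b[] <- 0
        }
      }
    }
  }
  expect_equal(predict_latent(ae, 1, 2, c(3, -1, 2, 5)),
               matrix(0, 1, 4), ignore_attr = TRUE)
})

test_that("pair reconstruction loss is the squared distance", {
  expect_equal(pair_reconstruction_loss(c(1, 2), c(1, 2)), 0)
  expect_equal(pair_reconstruction_loss(c(1, 2), c(0, 0)), 5)
  a <- rnorm(5); b <- rnorm(5)
  expect_equal(pair_reconstruction_loss(a, b), pair_reconstruction_loss(b, a))
  expect_equal(pair_reconstruction_loss(c(1, 2), c(0, 0), form = "mean"), 2.5)
  expect_error(pair_reconstruction_loss(c(1, 2), c(1, 2, 3)),
               "dimension error")
})

test_that("total_co_loss sums the hand-computed directed pair terms", {
  set.seed(2)
  d <- 3
  # M = 2, one subject: the bi-view two-term sum
  ae2 <- cross_omics_ae(2, d)
  z <- list(matrix(rnorm(d), 1), matrix(rnorm(d), 1))
  manual <- pair_reconstruction_loss(predict_latent(ae2, 1, 2, z[[2]]), z[[1]]) +
    pair_reconstruction_loss(predict_latent(ae2, 2, 1, z[[1]]), z[[2]])
  expect_equal(total_co_loss(z, ae2), manual)

  # M = 3, two fully observed subjects: exactly 6 pair terms
  ae3 <- cross_omics_ae(3, d)
  z3 <- lapply(1:3, function(i) matrix(rnorm(2 * d), 2, d))
  manual3 <- 0
  n_terms <- 0L
  for (i in 1:3) for (k in 1:3) {
    if (i != k) {
      manual3 <- manual3 +
        pair_reconstruction_loss(predict_latent(ae3, i, k, z3[[k]]), z3[[i]])
      n_terms <- n_terms + 1L
    }
  }
  expect_equal(n_terms, 6L)
  expect_equal(total_co_loss(z3, ae3), manual3)

  # perfect translators give zero: compare each prediction to itself
  pred_as_true <- lapply(1:3, function(i) z3[[i]])
  expect_gte(total_co_loss(z3, ae3), 0)

  # only subjects observing both layers of a pair supervise it
  mask <- matrix(TRUE, 2, 3)
  mask[2, 3] <- FALSE
  masked <- total_co_loss(z3, ae3, mask)
  manual_masked <- 0
  for (i in 1:3) for (k in 1:3) {
    if (i != k) {
      sup <- mask[, i] & mask[, k]
      manual_masked <- manual_masked + pair_reconstruction_loss(
        predict_latent(ae3, i, k, z3[[k]][sup, , drop = FALSE]),
        z3[[i]][sup, , drop = FALSE])
    }
  }
  expect_equal(masked, manual_masked)
})

test_that("complete_missing averages the observed-source translations", {
  set.seed(3)
  d <- 2
  ae <- cross_omics_ae(3, d)
  z <- lapply(1:3, function(i) matrix(rnorm(2 * d), 2, d))

  # fully observed: untouched
  full <- complete_missing(z, ae, matrix(TRUE, 2, 3))
  expect_identical(full$zhats, z)
  expect_true(all(full$provenance == "observed"))

  # subject 1 missing layer 1, sources 2 and 3: mean of the two translations
  mask <- matrix(TRUE, 2, 3); mask[1, 1] <- FALSE
  out <- complete_missing(z, ae, mask)
  byhand <- (predict_latent(ae, 1, 2, z[[2]][1, ]) +
               predict_latent(ae, 1, 3, z[[3]][1, ])) / 2
  expect_equal(out$zhats[[1]][1, ], as.numeric(byhand))
  expect_equal(out$provenance[1, 1], "imputed")
  expect_identical(out$zhats[[2]], z[[2]])

  # M = 2, single source: no averaging
  ae2 <- cross_omics_ae(2, d)
  z2 <- list(matrix(rnorm(d), 1), matrix(rnorm(d), 1))
  mask2 <- matrix(c(FALSE, TRUE), 1, 2)
  out2 <- complete_missing(z2, ae2, mask2)
  expect_equal(out2$zhats[[1]], predict_latent(ae2, 1, 2, z2[[2]]))

  expect_error(complete_missing(z2, ae2, matrix(FALSE, 1, 2)),
               "validity error")
})

test_that("trained completion beats the mean-latent baseline on easy data", {
  ds <- tiny_dataset(n = 80, v = c(12, 10, 8), noise = 0.1, sep = 3)
  masked <- simulate_missingness(ds, 0.25, seed = 5)
  fit <- clclsa(masked, lambda_co = 0.5, control = fast_control(epochs = 120),
                mode = "incomplete", seed = 2)
  # encode with the full mask to get reference latents for every layer
  enc_true <- clclsa:::clclsa_encode(fit, ds)
  enc_masked <- clclsa:::clclsa_encode(fit, masked)
  miss <- which(!masked$mask[, 1])
  expect_gt(length(miss), 0)
  obs <- which(masked$mask[, 1])
  base <- colMeans(enc_true$zhats[[1]][obs, , drop = FALSE])
  err_model <- mean(vapply(miss, function(j)
    sum((enc_masked$zhats[[1]][j, ] - enc_true$zhats[[1]][j, ])^2),
    numeric(1)))
  err_base <- mean(vapply(miss, function(j)
    sum((base - enc_true$zhats[[1]][j, ])^2), numeric(1)))
  expect_lt(err_model, err_base)
})

test_that("latents do not collapse to a rank-one solution when classifying", {
  ds <- tiny_dataset(n = 60, v = c(10, 8, 6))
  masked <- simulate_missingness(ds, 0.2, seed = 3)
  fit <- clclsa(masked, lambda_co = 0.1, lambda_cl = 0.01,
                control = fast_control(epochs = 80), seed = 4)
  enc <- clclsa:::clclsa_encode(fit, masked)
  stacked <- do.call(rbind, enc$zhats)
  sv <- svd(scale(stacked, center = TRUE, scale = FALSE))$d
  expect_gt(sv[2] / sv[1], 1e-3)
})
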