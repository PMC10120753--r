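test_that("load_dataset reads delimited layers and defaults the mask", {
  dir <- withr::local_tempdir()
  x <- matrix(c(0.5, 1.25, -2, 3, 4.5, 0, 7, 8), 4, 2)
  write.csv(x, file.path(dir, "layerA.csv"), row.names = FALSE)
  writeLines(c("0", "1", "0", "1"), file.path(dir, "labels.csv"))
  ds <- load_dataset(c(layerA = file.path(dir, "layerA.csv")),
                     file.path(dir, "labels.csv"))
  expect_equal(ds$n, 4L)
  expect_equal(ds$m, 1L)
  expect_identical(dim(ds$mask), c(4L, 1L))
  expect_true(all(ds$mask))
  expect_equal(unname(ds$layers$layerA), x, ignore_attr = TRUE)
  expect_equal(ds$labels, c(0L, 1L, 0L, 1L))
})

test_that("load_dataset validates row counts and numeric cells", {
  dir <- withr::local_tempdir()
  write.csv(matrix(rnorm(10), 5, 2), file.path(dir, "a.csv"),
            row.names = FALSE)
  write.csv(matrix(rnorm(12), 6, 2), file.path(dir, "b.csv"),
            row.names = FALSE)
  writeLines(as.character(rep(0:1, length.out = 5)),
             file.path(dir, "labels.csv"))
  expect_error(
    load_dataset(c(file.path(dir, "a.csv"), file.path(dir, "b.csv")),
                 file.path(dir, "labels.csv")),
    "dimension error")
  writeLines(c("V1,V2", "1,2", "3,oops"), file.path(dir, "bad.csv"))
  expect_error(load_dataset(file.path(dir, "bad.csv"),
                            file.path(dir, "labels.csv")),
               "parse error.*row 2, column 2")
})

test_that("a mask row with no observed layer is rejected", {
  layers <- list(a = matrix(1, 3, 2), b = matrix(2, 3, 2))
  mask <- matrix(c(1, 1, 0, 1, 1, 0), 3, 2)
  expect_error(multi_omics_dataset(layers, c(0, 1, 0), mask),
               "validity error")
})

test_that("save/load round-trips matrices bit-identically", {
  ds <- tiny_dataset(n = 12, v = c(5, 4, 3))
  ds <- simulate_missingness(ds, 0.25, seed = 9)
  dir <- withr::local_tempdir()
  save_dataset(ds, dir, meta = list(eta = 0.25, seed = 9))
  back <- clclsa:::load_dataset_dir(dir)
  for (i in 1:3) {
    expect_identical(unname(back$layers[[i]]), unname(ds$layers[[i]]))
  }
  expect_identical(back$labels, ds$labels)
  expect_identical(unname(back$mask), unname(ds$mask))
})

test_that("simulate_missingness hits the exact incomplete count", {
  ds <- tiny_dataset(n = 10, v = c(4, 4, 4))
  out <- simulate_missingness(ds, 0.2, seed = 1)
  incomplete <- rowSums(out$mask) < out$m
  expect_equal(sum(incomplete), 2L)
  expect_equal(sum(!incomplete), 8L)
  expect_equal(missing_rate(out), 0.2)

  # eta = 0 is a no-op
  out0 <- simulate_missingness(ds, 0, seed = 1)
  expect_true(all(out0$mask))

  expect_error(simulate_missingness(ds, 1.2, seed = 1), "domain error")
})

test_that("with two layers every incomplete subject keeps exactly one", {
  ds <- tiny_dataset(n = 50, m = 2, v = c(6, 5))
  m1 <- simulate_missingness(ds, 0.5, seed = 1)$mask
  m2 <- simulate_missingness(ds, 0.5, seed = 2)$mask
  for (mk in list(m1, m2)) {
    inc <- rowSums(mk) < 2
    expect_equal(sum(inc), 25L)
    expect_true(all(rowSums(mk[inc, , drop = FALSE]) == 1L))
  }
  expect_false(identical(m1, m2))
  # determinism given the seed
  expect_identical(m1, simulate_missingness(ds, 0.5, seed = 1)$mask)
})

test_that("random missingness never strands a subject with zero layers", {
  rng_cases <- 200L
  set.seed(4)
  for (case in seq_len(rng_cases)) {
    n <- sample(5:40, 1)
    m <- sample(2:5, 1)
    eta <- runif(1)
    ds <- multi_omics_dataset(
      lapply(seq_len(m), function(i) matrix(rnorm(n * 3), n, 3)),
      rep(0:1, length.out = n))
    mk <- simulate_missingness(ds, eta, seed = case)$mask
    expect_true(all(rowSums(mk) >= 1L))
    inc <- rowSums(mk) < m
    expect_equal(sum(inc), round(eta * n))
    if (any(inc)) {
      expect_true(all(rowSums(mk[inc, , drop = FALSE]) <= m - 1L))
    }
  }
})

test_that("stratified splits are disjoint and cover all classes", {
  labels <- rep(0:2, times = c(20, 15, 9))
  sp <- train_test_split(labels, 0.7, seed = 3)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), seq_along(labels))
  expect_setequal(unique(labels[sp$train]), 0:2)
  expect_setequal(unique(labels[sp$test]), 0:2)
})
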