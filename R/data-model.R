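#' Construct a multi-omics dataset
#'
#' Bundles M per-omics feature matrices (subjects in rows, positionally
#' aligned across layers), an integer class-label vector with values in
#' \code{0..C-1}, and an N x M logical presence mask whose entry (j, i) says
#' whether omics layer i was observed for subject j. Every subject must carry
#' at least one observed layer.
#'
#' @param layers named list of numeric matrices, all with the same number of
#'   rows.
#' @param labels integer vector of class labels in \code{0..C-1}.
#' @param mask optional N x M logical/0-1 matrix; defaults to all-observed.
#' @return an object of class \code{"multi_omics_dataset"} with elements
#'   \code{layers}, \code{labels}, \code{mask}, \code{n}, \code{m},
#'   \code{n_class}.
#' @export
multi_omics_dataset <- function(layers, labels, mask = NULL) {
  stopifnot(is.list(layers), length(layers) >= 1L)
  layers <- lapply(layers, function(x) {
    x <- as.matrix(x)
    storage.mode(x) <- "double"
    x
  })
  if (is.null(names(layers)) || any(!nzchar(names(layers)))) {
    names(layers) <- paste0("omics", seq_along(layers))
  }
  n <- nrow(layers[[1L]])
  for (i in seq_along(layers)) {
    if (nrow(layers[[i]]) != n) {
      stop("dimension error: layer '", names(layers)[i], "' has ",
           nrow(layers[[i]]), " rows but layer '", names(layers)[1L],
           "' has ", n)
    }
    if (ncol(layers[[i]]) < 1L) {
      stop("layer '", names(layers)[i], "' has no features")
    }
  }
  labels <- as.integer(labels)
  if (length(labels) != n) {
    stop("labels length ", length(labels), " does not match ", n, " subjects")
  }
  if (any(is.na(labels)) || any(labels < 0L)) {
    stop("labels must be non-negative integers")
  }
  m <- length(layers)
  if (is.null(mask)) {
    mask <- matrix(TRUE, n, m)
  } else {
    mask <- as.matrix(mask)
    if (!identical(dim(mask), c(n, m))) {
      stop("mask must be ", n, " x ", m, ", got ",
           nrow(mask), " x ", ncol(mask))
    }
    mask <- mask != 0
  }
  colnames(mask) <- names(layers)
  if (any(rowSums(mask) == 0L)) {
    stop("validity error: subject(s) ",
         paste(which(rowSums(mask) == 0L), collapse = ", "),
         " have no observed omics layer")
  }
  for (i in seq_len(m)) {
    vals <- layers[[i]][mask[, i], , drop = FALSE]
    if (length(vals) && any(!is.finite(vals))) {
      stop("layer '", names(layers)[i],
           "' contains non-finite values for observed subjects")
    }
  }
  structure(list(layers = layers, labels = labels, mask = mask,
                 n = n, m = m, n_class = max(labels) + 1L),
            class = "multi_omics_dataset")
}

#' @export
print.multi_omics_dataset <- function(x, ...) {
  dims <- vapply(x$layers, ncol, integer(1))
  n_ic <- sum(rowSums(x$mask) < x$m)
  cat("Multi-omics dataset: ", x$n, " subjects, ", x$m, " layers, ",
      x$n_class, " classes\n", sep = "")
  cat("  layers: ",
      paste(sprintf("%s (V=%d)", names(x$layers), dims), collapse = ", "),
      "\n", sep = "")
  cat(sprintf("  incomplete subjects: %d (missing rate %.3f)\n",
              n_ic, n_ic / x$n))
  invisible(x)
}

read_delim_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  toks <- strsplit(first, sep, fixed = TRUE)[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(toks))))
  df <- utils::read.table(path, header = has_header, sep = sep,
                          colClasses = "character", check.names = FALSE)
  x <- suppressWarnings(matrix(as.numeric(as.matrix(df)),
                               nrow(df), ncol(df)))
  if (anyNA(x)) {
    bad <- which(is.na(x), arr.ind = TRUE)[1L, ]
    stop("parse error in '", path, "': non-numeric cell at row ", bad[1L],
         ", column ", bad[2L])
  }
  colnames(x) <- if (has_header) trimws(toks) else NULL
  x
}

#' Load a multi-omics dataset from delimited text files
#'
#' Each omics layer is one delimited matrix file (comma or tab, auto-detected;
#' optional feature-name header row), subjects in rows, positionally aligned
#' across files. Labels are a single column of non-negative integers; the
#' optional mask file is an N x M 0/1 matrix.
#'
#' @param layer_paths character vector of matrix file paths; names become
#'   layer names (basenames otherwise).
#' @param label_path path to the label file.
#' @param mask_path optional path to the presence-mask file.
#' @return a [multi_omics_dataset()].
#' @export
load_dataset <- function(layer_paths, label_path, mask_path = NULL) {
  nms <- names(layer_paths)
  if (is.null(nms)) {
    nms <- sub("\\.[^.]*$", "", basename(layer_paths))
  }
  layers <- lapply(layer_paths, read_delim_matrix)
  names(layers) <- nms
  rows <- vapply(layers, nrow, integer(1))
  if (length(unique(rows)) > 1L) {
    bad <- which(rows != rows[1L])[1L]
    stop("dimension error: '", layer_paths[bad], "' has ", rows[bad],
         " rows, expected ", rows[1L])
  }
  labels <- read_delim_matrix(label_path)
  labels <- as.integer(round(labels[, 1L]))
  mask <- if (!is.null(mask_path)) read_delim_matrix(mask_path) else NULL
  multi_omics_dataset(layers, labels, mask)
}

#' Save a multi-omics dataset as a directory of delimited files
#'
#' Writes one CSV per layer (\code{<name>.csv}), \code{labels.csv},
#' \code{mask.csv} and a small \code{meta.json} (layer names and dimensions,
#' plus any extra metadata fields supplied).
#'
#' @param dataset a [multi_omics_dataset()].
#' @param dir output directory (created if needed).
#' @param meta named list of extra metadata stored in \code{meta.json}.
#' @return the directory path, invisibly.
#' @export
save_dataset <- function(dataset, dir, meta = list()) {
  stopifnot(inherits(dataset, "multi_omics_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(dataset$layers)) {
    x <- dataset$layers[[nm]]
    # %.17g preserves doubles exactly across the text round trip
    fm <- matrix(sprintf("%.17g", x), nrow(x), ncol(x))
    colnames(fm) <- colnames(x)
    utils::write.table(fm, file.path(dir, paste0(nm, ".csv")),
                       sep = ",", row.names = FALSE, quote = FALSE,
                       col.names = !is.null(colnames(x)))
  }
  utils::write.table(matrix(dataset$labels, ncol = 1L),
                     file.path(dir, "labels.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(1L * dataset$mask, file.path(dir, "mask.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  info <- c(list(layers = names(dataset$layers),
                 dims = vapply(dataset$layers, ncol, integer(1)),
                 n = dataset$n, m = dataset$m, n_class = dataset$n_class),
            meta)
  jsonlite::write_json(info, file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Load a dataset directory written by [save_dataset()]
#' @param dir dataset directory.
#' @return a [multi_omics_dataset()].
#' @export
load_dataset_dir <- function(dir) {
  info <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  paths <- file.path(dir, paste0(info$layers, ".csv"))
  names(paths) <- info$layers
  load_dataset(paths, file.path(dir, "labels.csv"),
               mask_path = file.path(dir, "mask.csv"))
}

#' Simulate missing omics layers at a target missing rate
#'
#' The missing rate eta is the fraction of subjects observing at most M-1
#' layers (eta = N_ic / N). Exactly \code{round(eta * N)} subjects, chosen
#' uniformly at random, are made incomplete; each keeps a number of observed
#' layers drawn uniformly from \code{1..M-1}, with the surviving layer
#' identities drawn uniformly. Feature values are retained in storage; only
#' the presence mask changes. Deterministic given \code{seed}.
#'
#' @param dataset a fully observed [multi_omics_dataset()].
#' @param eta target missing rate in \[0, 1\].
#' @param seed integer seed.
#' @return the dataset with an updated mask.
#' @export
simulate_missingness <- function(dataset, eta, seed = 1L) {
  stopifnot(inherits(dataset, "multi_omics_dataset"))
  if (!is.numeric(eta) || length(eta) != 1L || is.na(eta) ||
      eta < 0 || eta > 1) {
    stop("domain error: eta must be a number in [0, 1]")
  }
  if (!all(dataset$mask)) {
    stop("simulate_missingness expects a fully observed dataset")
  }
  n <- dataset$n
  m <- dataset$m
  n_ic <- round(eta * n)
  if (n_ic > 0L && m < 2L) {
    stop("cannot make subjects incomplete with a single omics layer")
  }
  mask <- matrix(TRUE, n, m)
  if (n_ic > 0L) {
    rng <- local_rng(seed)
    incomplete <- rng_sample(rng, n, n_ic)
    for (j in incomplete) {
      keep_count <- rng_sample(rng, m - 1L, 1L)
      keep <- rng_sample(rng, m, keep_count)
      row <- rep(FALSE, m)
      row[keep] <- TRUE
      mask[j, ] <- row
    }
  }
  colnames(mask) <- names(dataset$layers)
  dataset$mask <- mask
  dataset
}

#' Missing rate of a dataset
#'
#' Fraction of subjects with at least one unobserved omics layer.
#' @param dataset a [multi_omics_dataset()].
#' @return a number in \[0, 1\].
#' @export
missing_rate <- function(dataset) {
  sum(rowSums(dataset$mask) < dataset$m) / dataset$n
}

#' Restrict a dataset to a subset of layers and/or subjects
#' @param dataset a [multi_omics_dataset()].
#' @param layers layer names or indices to keep (default all).
#' @param subjects subject indices to keep (default all).
#' @return a [multi_omics_dataset()].
#' @export
subset_dataset <- function(dataset, layers = NULL, subjects = NULL) {
  if (is.null(layers)) layers <- seq_len(dataset$m)
  if (is.character(layers)) layers <- match(layers, names(dataset$layers))
  if (anyNA(layers)) stop("unknown layer name(s)")
  if (is.null(subjects)) subjects <- seq_len(dataset$n)
  lay <- lapply(dataset$layers[layers],
                function(x) x[subjects, , drop = FALSE])
  multi_omics_dataset(lay, dataset$labels[subjects],
                      dataset$mask[subjects, layers, drop = FALSE])
}

#' Stratified train/test split
#'
#' Draws a seeded random split with class proportions preserved per stratum.
#'
#' @param labels integer class labels.
#' @param train_frac fraction of subjects assigned to training.
#' @param seed integer seed.
#' @return list with integer vectors \code{train} and \code{test}.
#' @export
train_test_split <- function(labels, train_frac = 0.7, seed = 1L) {
  stopifnot(train_frac > 0, train_frac < 1)
  rng <- local_rng(seed)
  train <- integer(0)
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    k <- max(1L, round(train_frac * length(idx)))
    k <- min(k, length(idx) - 1L)  # keep every class represented in test
    if (k < 1L) k <- 1L
    take <- rng_sample(rng, length(idx), k)
    train <- c(train, idx[take])
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}
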