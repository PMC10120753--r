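# Directed cross-omics autoencoders h_ik = dec_i(enc_k(.)): one bottleneck
# network per ordered pair (i, k), translating omics-k latents into omics-i
# latent space. Trained on subjects observing both layers; at completion time
# a missing latent is the mean of the translations from all observed layers.

default_ae_arch <- function(d) {
  b1 <- max(8L, min(64L, as.integer(ceiling(d / 2))))
  b2 <- max(4L, as.integer(ceiling(b1 / 2)))
  sprintf("%d-%d-BN-ReLU-%d-ReLU-%d-BN-ReLU-%d", d, b1, b2, b1, d)
}

#' Build the set of directed cross-omics autoencoders
#'
#' Creates the M(M-1) translators \code{h[[i]][[k]]} for all ordered pairs
#' with i != k, each an independent bottleneck network (default architecture
#' \code{"D-b-BN-ReLU-b/2-ReLU-b-BN-ReLU-D"}, mirroring the
#' 300-64-BN-ReLU-32-ReLU-64-BN-ReLU-300 pattern used at full scale).
#'
#' @param m number of omics layers.
#' @param d shared latent dimension D.
#' @param arch optional architecture string overriding the default.
#' @return an object of class \code{"cross_omics_ae"}.
#' @export
cross_omics_ae <- function(m, d, arch = NULL) {
  stopifnot(m >= 2L, d >= 1L)
  if (is.null(arch)) arch <- default_ae_arch(d)
  parsed <- parse_architecture(arch)
  if (parsed$dim_in != d || parsed$dim_out != d) {
    stop("autoencoder architecture must map D=", d, " to D=", d)
  }
  h <- vector("list", m)
  for (i in seq_len(m)) {
    h[[i]] <- vector("list", m)
    for (k in seq_len(m)) {
      if (i != k) h[[i]][[k]] <- build_stack(parsed)
    }
  }
  structure(list(m = m, d = d, arch = arch, h = h),
            class = "cross_omics_ae")
}

#' @export
print.cross_omics_ae <- function(x, ...) {
  cat("<cross_omics_ae> ", x$m * (x$m - 1L), " directed translators, ",
      x$arch, "\n", sep = "")
  invisible(x)
}

#' Predict one omics latent from another
#'
#' Runs the directed translator \code{h_ik}: omics-k latents in, predicted
#' omics-i latents out. Batch-normalization layers use their running
#' statistics (evaluation mode).
#'
#' @param ae a [cross_omics_ae()].
#' @param i target omics index. @param k source omics index (i != k).
#' @param z_k matrix (subjects x D) or vector of source latents.
#' @return matrix of predicted omics-i latents.
#' @export
predict_latent <- function(ae, i, k, z_k) {
  stopifnot(inherits(ae, "cross_omics_ae"))
  if (i == k) stop("invalid pair: i and k must differ")
  stack_apply(ae$h[[i]][[k]], as_mat(z_k))
}

#' Reconstruction loss for one directed pair
#'
#' Squared Euclidean distance between the predicted and the observed latent
#' (\code{form = "sum"}, the classical convention); \code{form = "mean"}
#' averages over latent dimensions instead, the scale-stable form used
#' internally during training.
#'
#' @param predicted,true equal-length vectors or equal-shape matrices (a
#'   matrix is treated as one batch: losses are summed over subjects).
#' @param form \code{"sum"} or \code{"mean"} over latent dimensions.
#' @return non-negative scalar.
#' @export
pair_reconstruction_loss <- function(predicted, true, form = c("sum", "mean")) {
  form <- match.arg(form)
  predicted <- as_mat(predicted)
  true <- as_mat(true)
  if (!identical(dim(predicted), dim(true))) {
    stop("dimension error: predicted and true latents differ in shape")
  }
  d2 <- (predicted - true)^2
  if (form == "sum") sum(d2) else mean(d2)
}

#' Total cross-omics reconstruction loss
#'
#' Sums the pair losses over all ordered pairs (i, k), i != k, over the
#' subjects for which both layers are observed (\code{supervision =
#' "pairwise"}) or only over fully complete subjects
#' (\code{"complete-only"}). With M = 2 this reduces to the two-term bi-view
#' sum.
#'
#' @param zhats list of M latent matrices (subjects x D), rows aligned.
#' @param ae a [cross_omics_ae()].
#' @param mask N x M logical presence matrix (default: all observed).
#' @param form passed to [pair_reconstruction_loss()]; \code{"mean"}
#'   additionally averages over contributing subjects.
#' @param supervision which subjects supervise each pair.
#' @return non-negative scalar.
#' @export
total_co_loss <- function(zhats, ae, mask = NULL,
                          form = c("sum", "mean"),
                          supervision = c("pairwise", "complete-only")) {
  form <- match.arg(form)
  supervision <- match.arg(supervision)
  m <- length(zhats)
  n <- nrow(as_mat(zhats[[1L]]))
  if (is.null(mask)) mask <- matrix(TRUE, n, m)
  complete <- rowSums(mask) == m
  total <- 0
  n_terms <- 0L
  for (i in seq_len(m)) {
    for (k in seq_len(m)) {
      if (i == k) next
      sup <- if (supervision == "pairwise") mask[, i] & mask[, k] else complete
      if (!any(sup)) next
      pred <- predict_latent(ae, i, k, as_mat(zhats[[k]])[sup, , drop = FALSE])
      true <- as_mat(zhats[[i]])[sup, , drop = FALSE]
      if (form == "sum") {
        total <- total + sum((pred - true)^2)
      } else {
        total <- total + mean((pred - true)^2)
        n_terms <- n_terms + 1L
      }
    }
  }
  if (form == "mean" && n_terms > 0L) total <- total / n_terms
  total
}

#' Complete missing omics latents
#'
#' For every missing (subject, layer) entry, predicts the latent from each of
#' the subject's observed layers through the corresponding translator and
#' averages the predictions (a singleton mean when only one source exists).
#' Observed entries are untouched.
#'
#' @param zhats list of M latent matrices; rows for unobserved subjects may
#'   hold arbitrary values (they are replaced).
#' @param ae a [cross_omics_ae()].
#' @param mask N x M logical presence matrix.
#' @return list with \code{zhats} (completed matrices) and \code{provenance}
#'   (N x M character matrix, \code{"observed"} / \code{"imputed"}).
#' @export
complete_missing <- function(zhats, ae, mask) {
  m <- length(zhats)
  zhats <- lapply(zhats, as_mat)
  n <- nrow(zhats[[1L]])
  stopifnot(identical(dim(mask), c(n, m)))
  if (any(rowSums(mask) == 0L)) {
    stop("validity error: subject with zero observed layers")
  }
  prov <- matrix("observed", n, m)
  for (i in seq_len(m)) {
    miss <- which(!mask[, i])
    if (!length(miss)) next
    acc <- matrix(0, length(miss), ncol(zhats[[i]]))
    cnt <- numeric(length(miss))
    for (k in seq_len(m)) {
      if (k == i) next
      src <- mask[miss, k]
      if (!any(src)) next
      pred <- predict_latent(ae, i, k,
                             zhats[[k]][miss[src], , drop = FALSE])
      acc[src, ] <- acc[src, , drop = FALSE] + pred
      cnt[src] <- cnt[src] + 1
    }
    zhats[[i]][miss, ] <- acc / cnt
    prov[miss, i] <- "imputed"
  }
  list(zhats = zhats, provenance = prov)
}
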