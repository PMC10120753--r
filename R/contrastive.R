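# Cross-view contrastive alignment. Latent vectors are mapped to per-subject
# probability distributions over latent dimensions (row softmax); averaging
# the outer products of paired distributions gives a joint distribution
# matrix P over the latent dimensions of two omics. The loss rewards mutual
# information between the two views and, through the exponent alpha, high
# marginal entropy of each view.

#' Map latents to per-subject distributions over latent dimensions
#'
#' Row-wise softmax: each subject's latent vector becomes a probability
#' distribution over the D latent dimensions, making the joint-distribution
#' construction well defined.
#'
#' @param z matrix (subjects x D).
#' @return row-stochastic matrix of the same shape.
#' @export
latents_to_distributions <- function(z) {
  row_softmax(z)
}

#' Joint distribution over latent dimensions of two omics
#'
#' \eqn{P = (1/N) \sum_j s_i^{(j)} (s_k^{(j)})^T} for row-stochastic inputs,
#' then (when square) symmetrized as \eqn{(P + P^T)/2} and renormalized to sum
#' to one. Row and column marginals are attached.
#'
#' @param s_i,s_k row-stochastic matrices (subjects x D_i, subjects x D_k)
#'   with equal subject counts.
#' @param alpha entropy-regularization exponent carried into the loss.
#' @param symmetrize symmetrize when D_i = D_k (default TRUE).
#' @return object of class \code{"joint_distribution"} with \code{P},
#'   \code{row_marginals}, \code{col_marginals}, \code{alpha}.
#' @export
joint_distribution <- function(s_i, s_k, alpha = 9, symmetrize = TRUE) {
  s_i <- as_mat(s_i); s_k <- as_mat(s_k)
  if (nrow(s_i) != nrow(s_k)) {
    stop("dimension error: subject counts differ (", nrow(s_i), " vs ",
         nrow(s_k), ")")
  }
  p <- crossprod(s_i, s_k) / nrow(s_i)
  if (symmetrize && ncol(s_i) == ncol(s_k)) p <- (p + t(p)) / 2
  p <- p / sum(p)
  structure(list(P = p, row_marginals = rowSums(p),
                 col_marginals = colSums(p), alpha = alpha),
            class = "joint_distribution")
}

#' @export
print.joint_distribution <- function(x, ...) {
  cat("<joint_distribution> ", nrow(x$P), " x ", ncol(x$P),
      ", alpha = ", x$alpha, ", sum = ", format(sum(x$P)), "\n", sep = "")
  invisible(x)
}

#' Entropy-regularized contrastive loss of a joint distribution
#'
#' \deqn{L = -\sum_{d,d'} P_{dd'} \ln\frac{P_{dd'}}{P_d^{\alpha+1} P_{d'}^{\alpha+1}}}
#' which decomposes as minus the mutual information between the two views'
#' latent dimensions plus \eqn{\alpha} times the sum of the two marginal
#' entropies (up to sign). Entries with \eqn{P_{dd'} = 0} contribute zero.
#'
#' @param jd a [joint_distribution()], or a plain non-negative matrix summing
#'   to one (then \code{alpha} must be given).
#' @param alpha overrides the alpha stored in \code{jd}.
#' @param floor numerical floor inside logarithms.
#' @return scalar loss (can be negative: entropy terms enter with a bonus).
#' @export
pair_contrastive_loss <- function(jd, alpha = NULL, floor = 1e-12) {
  if (inherits(jd, "joint_distribution")) {
    p <- jd$P
    pd <- jd$row_marginals
    pdp <- jd$col_marginals
    if (is.null(alpha)) alpha <- jd$alpha
  } else {
    p <- as_mat(jd)
    if (is.null(alpha)) stop("alpha must be supplied for a raw matrix")
    pd <- rowSums(p)
    pdp <- colSums(p)
  }
  if (any(p < 0)) stop("validity error: negative joint-distribution entries")
  lp <- log(pmax(p, floor))
  lmarg <- outer(log(pmax(pd, floor)), log(pmax(pdp, floor)), "+")
  -sum(p * (lp - (alpha + 1) * lmarg))
}

#' Multi-omics contrastive loss
#'
#' Sums the pairwise contrastive loss over all ordered pairs of omics layers
#' (i != k); \code{pairs = "unordered"} keeps each unordered pair once.
#'
#' @param zhats list of M latent matrices (subjects x D), rows aligned
#'   (completed latents included).
#' @param alpha entropy-regularization exponent.
#' @param pairs \code{"ordered"} (the full double sum) or
#'   \code{"unordered"}.
#' @param symmetrize passed to [joint_distribution()].
#' @return scalar loss.
#' @export
multi_omics_contrastive_loss <- function(zhats, alpha = 9,
                                         pairs = c("ordered", "unordered"),
                                         symmetrize = TRUE) {
  pairs <- match.arg(pairs)
  m <- length(zhats)
  stopifnot(m >= 2L)
  s <- lapply(zhats, latents_to_distributions)
  total <- 0
  for (i in seq_len(m)) {
    for (k in seq_len(m)) {
      if (i == k) next
      if (pairs == "unordered" && k < i) next
      total <- total +
        pair_contrastive_loss(joint_distribution(s[[i]], s[[k]], alpha,
                                                 symmetrize = symmetrize))
    }
  }
  total
}
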