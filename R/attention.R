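# Sigmoid self-attention gating: feature-level gates (one per input feature)
# and an omics-level scalar gate, applied around the omics-specific embedding.

#' Feature-level self-attention scores
#'
#' Applies the per-omics attention network and a sigmoid, giving a gate in
#' (0, 1) for every input feature: \eqn{fatt = \sigma(f_i(x))}.
#'
#' @param x numeric vector (length V) or matrix (subjects x V).
#' @param f attention network: a \code{clclsa_stack} with matching input and
#'   output dimension V.
#' @return matrix of attention scores in (0, 1), same shape as \code{x}.
#' @export
feature_attention <- function(x, f) {
  x <- as_mat(x)
  if (ncol(x) != f$arch$dim_in) {
    stop("dimension error: x has ", ncol(x), " features, attention net expects ",
         f$arch$dim_in)
  }
  sigmoid(stack_apply(f, x))
}

#' Embed an omics profile under feature-level attention
#'
#' Default convention gates the input features before the embedding network:
#' \eqn{\hat{x} = emb_i(x \odot fatt)}. The alternative \code{"output"}
#' convention computes \eqn{emb_i(x) \odot fatt} and requires the embedding
#' output dimension to equal V.
#'
#' @param x vector/matrix of omics features.
#' @param fatt attention scores from [feature_attention()].
#' @param emb embedding network (\code{clclsa_stack}).
#' @param convention \code{"input"} (default) or \code{"output"} gating.
#' @return embedded matrix (subjects x D).
#' @export
embed_with_feature_attention <- function(x, fatt, emb,
                                         convention = c("input", "output")) {
  convention <- match.arg(convention)
  x <- as_mat(x)
  fatt <- as_mat(fatt)
  if (convention == "input") {
    if (!identical(dim(x), dim(fatt))) {
      stop("dimension error: fatt must match x under input gating")
    }
    stack_apply(emb, x * fatt)
  } else {
    out <- stack_apply(emb, x)
    if (!identical(dim(out), dim(fatt))) {
      stop("dimension error: fatt must match the embedding output under ",
           "output gating (V must equal D)")
    }
    out * fatt
  }
}

#' Omics-level self-attention score
#'
#' A single sigmoid gate per subject and omics, interpreted as modality
#' importance: \eqn{matt = \sigma(g_i(\hat{x}))}.
#'
#' @param xhat embedded matrix (subjects x D) or vector.
#' @param g omics-attention network (\code{clclsa_stack}, D to 1).
#' @return column matrix of scores in (0, 1).
#' @export
omics_attention <- function(xhat, g) {
  xhat <- as_mat(xhat)
  if (ncol(xhat) != g$arch$dim_in) {
    stop("dimension error: xhat has ", ncol(xhat),
         " columns, omics attention net expects ", g$arch$dim_in)
  }
  sigmoid(stack_apply(g, xhat))
}

#' Scale a latent embedding by its omics-level attention
#'
#' \eqn{\hat{z} = matt \cdot \hat{x}} (scalar broadcast per subject).
#'
#' @param xhat embedded matrix (subjects x D).
#' @param matt per-subject scalar gates (length-n vector or n x 1 matrix).
#' @return matrix of the same shape as \code{xhat}.
#' @export
scale_by_omics_attention <- function(xhat, matt) {
  xhat <- as_mat(xhat)
  xhat * as.numeric(matt)
}

#' Fuse per-omics latents by concatenation
#'
#' Concatenates the attended latents in fixed layer order; the fused width is
#' the sum of the per-layer latent dimensions.
#'
#' @param zhats list of M matrices (subjects x D_i), every entry defined
#'   (observed or completed).
#' @return matrix subjects x sum(D_i).
#' @export
fuse_latents <- function(zhats) {
  stopifnot(is.list(zhats), length(zhats) >= 1L)
  for (i in seq_along(zhats)) {
    if (is.null(zhats[[i]]) || anyNA(zhats[[i]])) {
      stop("completion required: latent for layer ", i, " is undefined")
    }
  }
  do.call(cbind, lapply(zhats, as_mat))
}
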