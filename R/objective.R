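# The composite training objective: cross-entropy classification on the
# fused representation, a per-omics auxiliary loss tying the omics attention
# score to the auxiliary classifier's confidence, the cross-omics
# reconstruction loss and the contrastive loss, combined as
# L = L_clf + lambda_al * L_al + lambda_co * L_co + lambda_cl * L_cl.

#' Cross-entropy classification loss
#'
#' Mean negative log-probability of the true class over the batch;
#' probabilities are floored at \code{1e-12}.
#'
#' @param probs matrix (subjects x C) of class probabilities (rows on the
#'   simplex).
#' @param labels integer labels in \code{0..C-1}.
#' @return non-negative scalar.
#' @export
classification_loss <- function(probs, labels) {
  probs <- as_mat(probs)
  labels <- as.integer(labels)
  stopifnot(length(labels) == nrow(probs),
            all(labels >= 0L), all(labels < ncol(probs)))
  p_true <- probs[cbind(seq_len(nrow(probs)), labels + 1L)]
  mean(-log(pmax(p_true, 1e-12)))
}

#' Auxiliary confidence-regularization loss
#'
#' For each omics layer: the squared difference between the omics attention
#' score and the auxiliary classifier's confidence (its maximal softmax
#' output), plus the cross-entropy of the auxiliary prediction — both
#' averaged over the batch and summed over layers. The confidence term is
#' computed for observed entries only (attention scores exist only where the
#' layer was measured); the cross-entropy term covers imputed entries as well
#' unless \code{include_imputed = FALSE}.
#'
#' @param aux_probs list of M matrices (subjects x C) of auxiliary-classifier
#'   probabilities on the (completed) latents.
#' @param matts N x M matrix of omics attention scores (NA where missing).
#' @param labels integer labels in \code{0..C-1}.
#' @param mask N x M logical presence matrix (default all observed).
#' @param include_imputed include unobserved entries in the cross-entropy
#'   term.
#' @return non-negative scalar.
#' @export
auxiliary_loss <- function(aux_probs, matts, labels, mask = NULL,
                           include_imputed = TRUE) {
  m <- length(aux_probs)
  n <- nrow(as_mat(aux_probs[[1L]]))
  matts <- as_mat(matts)
  if (is.null(mask)) mask <- matrix(TRUE, n, m)
  total <- 0
  for (i in seq_len(m)) {
    probs <- as_mat(aux_probs[[i]])
    conf <- apply(probs, 1L, max)
    obs <- mask[, i]
    if (any(obs)) {
      total <- total + mean((matts[obs, i] - conf[obs])^2)
    }
    ce_rows <- if (include_imputed) rep(TRUE, n) else obs
    if (any(ce_rows)) {
      total <- total + classification_loss(probs[ce_rows, , drop = FALSE],
                                           labels[ce_rows])
    }
  }
  total
}

#' Loss weights
#'
#' Non-negative balancing weights for the auxiliary, cross-omics and
#' contrastive terms. In complete-data mode the cross-omics autoencoders are
#' inactive and \code{lambda_co} is forced to zero.
#'
#' @param lambda_al,lambda_co,lambda_cl non-negative reals.
#' @param mode \code{"incomplete"} or \code{"complete"}.
#' @return object of class \code{"loss_weights"}.
#' @export
loss_weights <- function(lambda_al = 0.1, lambda_co = 0.1, lambda_cl = 0.01,
                         mode = c("incomplete", "complete")) {
  mode <- match.arg(mode)
  stopifnot(lambda_al >= 0, lambda_co >= 0, lambda_cl >= 0)
  if (mode == "complete") lambda_co <- 0
  structure(list(lambda_al = lambda_al, lambda_co = lambda_co,
                 lambda_cl = lambda_cl, mode = mode),
            class = "loss_weights")
}

#' Combine loss components into the training objective
#'
#' @param l_clf,l_al,l_co,l_cl the four component losses.
#' @param weights a [loss_weights()].
#' @return object of class \code{"loss_breakdown"}: the four components,
#'   their weights and \code{total}.
#' @export
total_loss <- function(l_clf, l_al, l_co, l_cl, weights) {
  comps <- c(l_clf = l_clf, l_al = l_al, l_co = l_co, l_cl = l_cl)
  bad <- names(comps)[!is.finite(comps)]
  if (length(bad)) {
    stop("training divergence: non-finite loss component(s): ",
         paste(bad, collapse = ", "))
  }
  total <- l_clf + weights$lambda_al * l_al + weights$lambda_co * l_co +
    weights$lambda_cl * l_cl
  structure(list(l_clf = l_clf, l_al = l_al, l_co = l_co, l_cl = l_cl,
                 weights = weights, total = total),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf(
    "Loss: total %.6g = clf %.6g + %.3g*al %.6g + %.3g*co %.6g + %.3g*cl %.6g\n",
    x$total, x$l_clf, x$weights$lambda_al, x$l_al,
    x$weights$lambda_co, x$l_co, x$weights$lambda_cl, x$l_cl))
  invisible(x)
}

#' Hyperparameter grid over the loss weights
#'
#' The full grid sets each weight to one of
#' \code{{0, 0.01, 0.02, 0.05, 0.1, 1}}. In incomplete mode
#' \code{lambda_co} must be positive (the autoencoders are required), giving
#' 6 x 5 x 6 = 180 cells; in complete mode \code{lambda_co} is fixed at 0,
#' giving 36.
#'
#' @param mode \code{"incomplete"} or \code{"complete"}.
#' @param values candidate values for each weight.
#' @return data.frame with columns \code{lambda_al}, \code{lambda_co},
#'   \code{lambda_cl}.
#' @export
lambda_grid <- function(mode = c("incomplete", "complete"),
                        values = c(0, 0.01, 0.02, 0.05, 0.1, 1.0)) {
  mode <- match.arg(mode)
  co_vals <- if (mode == "incomplete") values[values > 0] else 0
  g <- expand.grid(lambda_al = values, lambda_co = co_vals,
                   lambda_cl = values, KEEP.OUT.ATTRS = FALSE)
  g[order(g$lambda_al, g$lambda_co, g$lambda_cl), , drop = FALSE]
}
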