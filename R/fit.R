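# Model fitting: builds the attention/embedding networks, the directed
# cross-omics autoencoders, the classifier heads, and trains them jointly by
# full-batch Adam on the composite objective. Subjects with complete data
# supervise the autoencoders; incomplete subjects are completed in latent
# space with the current translators (held constant for that step's
# classification gradient by default) and contribute to the classification,
# auxiliary and contrastive terms.

#' Training control parameters
#'
#' @param epochs maximum full-batch epochs.
#' @param lr initial Adam learning rate.
#' @param lr_decay_factor,lr_decay_every multiplicative learning-rate decay
#'   applied every \code{lr_decay_every} epochs.
#' @param dropout dropout probability in the embedding networks (training
#'   only).
#' @param latent_dim shared latent dimension D for every omics layer.
#' @param gate_convention \code{"input"}: embed the attention-gated features
#'   \code{emb(x * fatt)}; \code{"output"}: gate the embedding output
#'   (requires V = D).
#' @param co_form \code{"mean"} (per-dimension mean squared error, stable
#'   across latent widths) or \code{"sum"} (summed squared error).
#' @param co_supervision \code{"pairwise"} (any subject observing both layers
#'   of a pair supervises it) or \code{"complete-only"}.
#' @param pairs ordered or unordered pair convention in the contrastive sum.
#' @param include_imputed_aux include imputed entries in the auxiliary
#'   cross-entropy term.
#' @param detach_imputed treat imputed latents as constants for the
#'   classification path within each step.
#' @param attention use the sigmoid attention gates; \code{FALSE} bypasses
#'   both gates as identity (the "plain" ablation variant).
#' @param arch optional named list of architecture-string overrides with any
#'   of the elements \code{f}, \code{emb}, \code{g}, \code{h}, \code{c_aux},
#'   \code{c} (each a single template or one string per layer, using the
#'   dash grammar of [parse_architecture()]).
#' @param verbose print a progress line every 50 epochs.
#' @return a list of class \code{"clclsa_control"}.
#' @export
clclsa_control <- function(epochs = 2500L, lr = 1e-4,
                           lr_decay_factor = 0.2, lr_decay_every = 500L,
                           dropout = 0.5, latent_dim = 32L,
                           gate_convention = c("input", "output"),
                           co_form = c("mean", "sum"),
                           co_supervision = c("pairwise", "complete-only"),
                           pairs = c("ordered", "unordered"),
                           include_imputed_aux = TRUE,
                           detach_imputed = TRUE,
                           attention = TRUE,
                           arch = NULL,
                           verbose = FALSE) {
  structure(list(
    epochs = as.integer(epochs), lr = lr,
    lr_decay_factor = lr_decay_factor,
    lr_decay_every = as.integer(lr_decay_every),
    dropout = dropout, latent_dim = as.integer(latent_dim),
    gate_convention = match.arg(gate_convention),
    co_form = match.arg(co_form),
    co_supervision = match.arg(co_supervision),
    pairs = match.arg(pairs),
    include_imputed_aux = isTRUE(include_imputed_aux),
    detach_imputed = isTRUE(detach_imputed),
    attention = isTRUE(attention),
    arch = arch, verbose = isTRUE(verbose)), class = "clclsa_control")
}

arch_override <- function(arch, key, i, default) {
  if (is.null(arch) || is.null(arch[[key]])) return(default)
  v <- arch[[key]]
  if (length(v) == 1L) v else v[[i]]
}

# Build all networks for a dataset's dimensions under a seeded RNG stream.
clclsa_build_net <- function(v, n_class, control, rng) {
  m <- length(v)
  d <- control$latent_dim
  a <- control$arch
  stacks <- list()
  with_rng(rng, {
    for (i in seq_len(m)) {
      stacks[[paste0("f", i)]] <- build_stack(
        arch_override(a, "f", i, sprintf("%d-%d", v[i], v[i])))
      stacks[[paste0("emb", i)]] <- build_stack(
        arch_override(a, "emb", i, sprintf("%d-%d-ReLU-DP", v[i], d)))
      stacks[[paste0("g", i)]] <- build_stack(
        arch_override(a, "g", i, sprintf("%d-1", d)))
      stacks[[paste0("caux", i)]] <- build_stack(
        arch_override(a, "c_aux", i, sprintf("%d-%d-Softmax", d, n_class)))
    }
    stacks[["c"]] <- build_stack(
      arch_override(a, "c", 1L, sprintf("%d-%d-Softmax", m * d, n_class)))
    for (i in seq_len(m)) {
      for (k in seq_len(m)) {
        if (i != k) {
          stacks[[paste0("h", i, "_", k)]] <- build_stack(
            arch_override(a, "h", 1L, default_ae_arch(d)))
        }
      }
    }
  })
  net <- new.env(parent = emptyenv())
  net$stacks <- stacks
  net$m <- m
  net$d <- d
  net$n_class <- n_class
  net
}

# Stable enumeration of every trainable parameter slot.
net_param_index <- function(net) {
  out <- list()
  for (nm in names(net$stacks)) {
    for (slot in stack_param_slots(net$stacks[[nm]])) {
      out[[length(out) + 1L]] <- list(stack = nm, step = slot$step,
                                      field = slot$field)
    }
  }
  out
}

net_get_params <- function(net, index) {
  lapply(index, function(s) net$stacks[[s$stack]]$steps[[s$step]][[s$field]])
}

net_set_params <- function(net, index, values) {
  for (j in seq_along(index)) {
    s <- index[[j]]
    net$stacks[[s$stack]]$steps[[s$step]][[s$field]] <- values[[j]]
  }
  invisible(NULL)
}

make_pnodes <- function(tape, net, index) {
  nodes <- vector("list", length(index))
  by_stack <- list()
  for (j in seq_along(index)) {
    s <- index[[j]]
    nd <- ad_leaf(tape, net$stacks[[s$stack]]$steps[[s$step]][[s$field]])
    nodes[[j]] <- nd
    key <- paste0(s$step, ".", s$field)
    if (is.null(by_stack[[s$stack]])) by_stack[[s$stack]] <- list()
    by_stack[[s$stack]][[key]] <- nd
  }
  list(nodes = nodes, by_stack = by_stack)
}

# Wrap zero-filled rows around a node covering a subset of rows.
merge_rows <- function(tape, n, idx, node, fill_idx = NULL, fill_node = NULL) {
  pieces <- list(list(idx = idx, node = node))
  if (length(fill_idx)) {
    pieces[[2L]] <- list(idx = fill_idx, node = fill_node)
  }
  ad_row_merge(tape, n, pieces)
}

# Full forward pass building all loss components on a tape.
# Returns nodes for each component plus diagnostics values.
clclsa_forward <- function(tape, net, control, weights, alpha,
                           X, mask, labels, training, pn) {
  m <- net$m
  n <- nrow(mask)
  d <- net$d
  zhat_obs <- vector("list", m)   # nodes over observed rows
  matt_obs <- vector("list", m)
  obs_idx <- vector("list", m)
  for (i in seq_len(m)) {
    obs <- which(mask[, i])
    obs_idx[[i]] <- obs
    x <- ad_leaf(tape, X[[i]][obs, , drop = FALSE])
    gated <- x
    if (control$attention) {
      fatt <- ad_sigmoid(tape, stack_forward(
        tape, net$stacks[[paste0("f", i)]], x, training = training,
        pnodes = pn$by_stack[[paste0("f", i)]], dropout_p = control$dropout))
      if (control$gate_convention == "input") gated <- ad_emul(tape, x, fatt)
    }
    xhat <- stack_forward(tape, net$stacks[[paste0("emb", i)]], gated,
                          training = training,
                          pnodes = pn$by_stack[[paste0("emb", i)]],
                          dropout_p = control$dropout)
    if (control$attention && control$gate_convention == "output") {
      xhat <- ad_emul(tape, xhat, fatt)
    }
    if (control$attention) {
      matt <- ad_sigmoid(tape, stack_forward(
        tape, net$stacks[[paste0("g", i)]], xhat, training = training,
        pnodes = pn$by_stack[[paste0("g", i)]], dropout_p = control$dropout))
      zhat_obs[[i]] <- ad_emul(tape, xhat, matt)
    } else {
      matt <- ad_leaf(tape, matrix(1, length(obs), 1L))
      zhat_obs[[i]] <- xhat
    }
    matt_obs[[i]] <- matt
  }

  # Cross-omics reconstruction over supervising subjects.
  l_co <- NULL
  complete <- rowSums(mask) == m
  if (weights$lambda_co > 0 && m >= 2L) {
    terms <- 0L
    for (i in seq_len(m)) {
      for (k in seq_len(m)) {
        if (i == k) next
        sup <- if (control$co_supervision == "pairwise") {
          which(mask[, i] & mask[, k])
        } else which(complete)
        if (!length(sup)) next
        src <- ad_row_subset(tape, zhat_obs[[k]],
                             match(sup, obs_idx[[k]]))
        pred <- stack_forward(tape, net$stacks[[paste0("h", i, "_", k)]],
                              src, training = training,
                              pnodes = pn$by_stack[[paste0("h", i, "_", k)]],
                              dropout_p = control$dropout)
        true <- ad_row_subset(tape, zhat_obs[[i]],
                              match(sup, obs_idx[[i]]))
        sq <- ad_square(tape, ad_sub(tape, pred, true))
        term <- if (control$co_form == "sum") ad_sum(tape, sq)
                else ad_mean(tape, sq)
        terms <- terms + 1L
        l_co <- if (is.null(l_co)) term else ad_add(tape, l_co, term)
      }
    }
    if (is.null(l_co)) {
      stop("unsupervisable cross-omics autoencoders: no subject observes ",
           "both layers of any pair while lambda_co > 0")
    }
    if (control$co_form == "mean" && terms > 0L) {
      l_co <- ad_scale(tape, l_co, 1 / terms)
    }
  }
  if (is.null(l_co)) l_co <- ad_leaf(tape, matrix(0, 1L, 1L))

  # Latent completion for missing entries.
  zhat_full <- vector("list", m)
  for (i in seq_len(m)) {
    miss <- which(!mask[, i])
    if (!length(miss)) {
      zhat_full[[i]] <- if (length(obs_idx[[i]]) == n && all(obs_idx[[i]] == seq_len(n)))
        zhat_obs[[i]] else merge_rows(tape, n, obs_idx[[i]], zhat_obs[[i]])
      next
    }
    if (control$detach_imputed) {
      # numeric completion in evaluation mode, constant for this step
      zvals <- lapply(seq_len(m), function(k) {
        full <- matrix(0, n, d)
        full[obs_idx[[k]], ] <- zhat_obs[[k]]$value
        full
      })
      ae <- as_cross_omics_ae(net)
      comp <- complete_missing(zvals, ae, mask)
      imput <- ad_leaf(tape, comp$zhats[[i]][miss, , drop = FALSE])
    } else {
      acc <- NULL
      cnt <- numeric(length(miss))
      for (k in seq_len(m)) {
        if (k == i) next
        src_rows <- which(mask[miss, k])
        if (!length(src_rows)) next
        subj <- miss[src_rows]
        src <- ad_row_subset(tape, zhat_obs[[k]],
                             match(subj, obs_idx[[k]]))
        pred <- stack_forward(tape, net$stacks[[paste0("h", i, "_", k)]],
                              src, training = FALSE,
                              pnodes = pn$by_stack[[paste0("h", i, "_", k)]])
        rest <- setdiff(seq_along(miss), src_rows)
        spread <- if (length(rest)) {
          merge_rows(tape, length(miss), src_rows, pred, rest,
                     ad_leaf(tape, matrix(0, length(rest), d)))
        } else merge_rows(tape, length(miss), src_rows, pred)
        acc <- if (is.null(acc)) spread else ad_add(tape, acc, spread)
        cnt[src_rows] <- cnt[src_rows] + 1
      }
      imput <- ad_emul(tape, acc, ad_leaf(tape, matrix(1 / cnt, ncol = 1L)))
    }
    zhat_full[[i]] <- merge_rows(tape, n, obs_idx[[i]], zhat_obs[[i]],
                                 miss, imput)
  }

  # Contrastive alignment over completed latents.
  l_cl <- NULL
  if (weights$lambda_cl > 0 && m >= 2L) {
    smx <- lapply(zhat_full, function(z) ad_row_softmax(tape, z))
    for (i in seq_len(m)) {
      for (k in seq_len(m)) {
        if (i == k) next
        if (control$pairs == "unordered" && k < i) next
        p <- ad_scale(tape, ad_mm(tape, ad_transpose(tape, smx[[i]]),
                                  smx[[k]]), 1 / n)
        p <- ad_scale(tape, ad_add(tape, p, ad_transpose(tape, p)), 0.5)
        p <- ad_div_scalar(tape, p, ad_sum(tape, p))
        lp <- ad_log(tape, p)
        lmarg <- ad_add_outer(tape, ad_log(tape, ad_row_sums(tape, p)),
                              ad_log(tape, ad_transpose(tape,
                                                        ad_col_sums(tape, p))))
        inner <- ad_sub(tape, lp, ad_scale(tape, lmarg, alpha + 1))
        term <- ad_scale(tape, ad_sum(tape, ad_emul(tape, p, inner)), -1)
        l_cl <- if (is.null(l_cl)) term else ad_add(tape, l_cl, term)
      }
    }
  }
  if (is.null(l_cl)) l_cl <- ad_leaf(tape, matrix(0, 1L, 1L))

  # Classification on the fused representation.
  fused <- ad_concat_cols(tape, zhat_full)
  probs <- stack_forward(tape, net$stacks[["c"]], fused, training = training,
                         pnodes = pn$by_stack[["c"]],
                         dropout_p = control$dropout)
  onehot <- matrix(0, n, net$n_class)
  onehot[cbind(seq_len(n), labels + 1L)] <- 1
  l_clf <- ad_scale(tape, ad_sum(tape, ad_emul(tape, ad_log(tape, probs),
                                               ad_leaf(tape, onehot))),
                    -1 / n)

  # Auxiliary confidence loss.
  l_al <- NULL
  if (weights$lambda_al > 0) {
    for (i in seq_len(m)) {
      probs_i <- stack_forward(tape, net$stacks[[paste0("caux", i)]],
                               zhat_full[[i]], training = training,
                               pnodes = pn$by_stack[[paste0("caux", i)]],
                               dropout_p = control$dropout)
      conf <- ad_row_max(tape, probs_i)
      conf_obs <- ad_row_subset(tape, conf, obs_idx[[i]])
      sq <- ad_mean(tape, ad_square(tape, ad_sub(tape, matt_obs[[i]],
                                                 conf_obs)))
      rows <- if (control$include_imputed_aux) seq_len(n) else obs_idx[[i]]
      oh <- matrix(0, length(rows), net$n_class)
      oh[cbind(seq_along(rows), labels[rows] + 1L)] <- 1
      probs_rows <- if (length(rows) == n) probs_i
                    else ad_row_subset(tape, probs_i, rows)
      ce <- ad_scale(tape, ad_sum(tape, ad_emul(tape,
                                                ad_log(tape, probs_rows),
                                                ad_leaf(tape, oh))),
                     -1 / length(rows))
      term <- ad_add(tape, sq, ce)
      l_al <- if (is.null(l_al)) term else ad_add(tape, l_al, term)
    }
  }
  if (is.null(l_al)) l_al <- ad_leaf(tape, matrix(0, 1L, 1L))

  total <- ad_add(tape, l_clf,
                  ad_add(tape, ad_scale(tape, l_al, weights$lambda_al),
                         ad_add(tape, ad_scale(tape, l_co, weights$lambda_co),
                                ad_scale(tape, l_cl, weights$lambda_cl))))
  list(total = total, l_clf = l_clf, l_al = l_al, l_co = l_co, l_cl = l_cl,
       probs = probs)
}

# View the translator stacks of a net as a cross_omics_ae object.
as_cross_omics_ae <- function(net) {
  h <- vector("list", net$m)
  for (i in seq_len(net$m)) {
    h[[i]] <- vector("list", net$m)
    for (k in seq_len(net$m)) {
      if (i != k) h[[i]][[k]] <- net$stacks[[paste0("h", i, "_", k)]]
    }
  }
  structure(list(m = net$m, d = net$d, arch = "net", h = h),
            class = "cross_omics_ae")
}

adam_new <- function(index) {
  st <- new.env(parent = emptyenv())
  st$m <- lapply(index, function(s) NULL)
  st$v <- lapply(index, function(s) NULL)
  st$t <- 0L
  st
}

adam_step <- function(st, values, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (j in seq_along(values)) {
    g <- grads[[j]]
    if (is.null(g)) next
    if (is.null(st$m[[j]])) {
      st$m[[j]] <- g * 0
      st$v[[j]] <- g * 0
    }
    st$m[[j]] <- beta1 * st$m[[j]] + (1 - beta1) * g
    st$v[[j]] <- beta2 * st$v[[j]] + (1 - beta2) * g * g
    values[[j]] <- values[[j]] -
      lr * (st$m[[j]] / bc1) / (sqrt(st$v[[j]] / bc2) + eps)
  }
  values
}

#' Fit a CLCLSA multi-omics classifier
#'
#' Trains the full model — per-omics feature- and omics-level attention gates,
#' omics-specific embeddings, directed cross-omics autoencoders for latent
#' completion, a contrastive alignment term, per-omics auxiliary classifiers
#' and a fused softmax classifier — by full-batch Adam on
#' \code{L = L_clf + lambda_al L_al + lambda_co L_co + lambda_cl L_cl}.
#'
#' @param data a [multi_omics_dataset()] (the training cohort; incomplete
#'   subjects are used for the classification, auxiliary and contrastive
#'   terms after latent completion).
#' @param lambda_al,lambda_co,lambda_cl loss weights; see [loss_weights()].
#' @param alpha entropy-regularization exponent of the contrastive loss.
#' @param mode \code{"auto"} picks \code{"incomplete"} when any subject has a
#'   missing layer; \code{"complete"} forces \code{lambda_co = 0}.
#' @param control a [clclsa_control()].
#' @param seed integer seed governing weight initialization and dropout.
#' @param epochs,lr optional convenience overrides of the control values.
#' @return an object of class \code{"clclsa"} with elements \code{net},
#'   \code{weights}, \code{alpha}, \code{control}, \code{history} (per-epoch
#'   loss breakdown), \code{final} (last [total_loss()] breakdown),
#'   \code{layer_names}, \code{dims}, \code{n_class}, \code{seed}.
#' @examples
#' ds <- synth_multiomics(synthetic_spec(n = 60, v = c(12, 10, 8)))
#' fit <- clclsa(ds, control = clclsa_control(epochs = 30, latent_dim = 8,
#'                                            lr = 1e-3))
#' fit
#' head(predict(fit, ds, type = "class"))
#' @export
clclsa <- function(data, lambda_al = 0.1, lambda_co = 0.1, lambda_cl = 0.01,
                   alpha = 9, mode = c("auto", "incomplete", "complete"),
                   control = clclsa_control(), seed = 1L,
                   epochs = NULL, lr = NULL) {
  stopifnot(inherits(data, "multi_omics_dataset"))
  mode <- match.arg(mode)
  if (mode == "auto") {
    mode <- if (missing_rate(data) > 0) "incomplete" else "complete"
  }
  if (!is.null(epochs)) control$epochs <- as.integer(epochs)
  if (!is.null(lr)) control$lr <- lr
  weights <- loss_weights(lambda_al, lambda_co, lambda_cl, mode = mode)
  if (mode == "incomplete" && weights$lambda_co == 0 && missing_rate(data) > 0) {
    warning("lambda_co = 0 with missing data: the completion autoencoders ",
            "receive no training signal")
  }
  classes <- sort(unique(data$labels))
  if (!identical(classes, seq(0L, data$n_class - 1L))) {
    stop("every class in 0..C-1 must appear in the training data")
  }
  v <- vapply(data$layers, ncol, integer(1))
  net <- clclsa_build_net(v, data$n_class, control,
                          local_rng(derive_seed(seed, "init")))
  index <- net_param_index(net)
  adam <- adam_new(index)
  rng_train <- local_rng(derive_seed(seed, "train"))
  X <- data$layers
  mask <- data$mask
  labels <- data$labels
  hist <- matrix(NA_real_, control$epochs, 6L)
  colnames(hist) <- c("epoch", "l_clf", "l_al", "l_co", "l_cl", "total")
  for (ep in seq_len(control$epochs)) {
    tape <- tape_new()
    pn <- make_pnodes(tape, net, index)
    out <- with_rng(rng_train,
      clclsa_forward(tape, net, control, weights, alpha, X, mask, labels,
                     training = TRUE, pn = pn))
    tape_backward(tape, out$total)
    grads <- lapply(pn$nodes, function(nd) nd$grad)
    lr_now <- control$lr *
      control$lr_decay_factor^((ep - 1L) %/% control$lr_decay_every)
    values <- net_get_params(net, index)
    values <- adam_step(adam, values, grads, lr_now)
    net_set_params(net, index, values)
    hist[ep, ] <- c(ep, out$l_clf$value, out$l_al$value, out$l_co$value,
                    out$l_cl$value, out$total$value)
    if (control$verbose && (ep %% 50L == 0L || ep == 1L)) {
      message(sprintf("epoch %4d  total %.5f  clf %.5f  co %.5f  cl %.5f",
                      ep, out$total$value, out$l_clf$value, out$l_co$value,
                      out$l_cl$value))
    }
  }
  final <- total_loss(hist[control$epochs, "l_clf"],
                      hist[control$epochs, "l_al"],
                      hist[control$epochs, "l_co"],
                      hist[control$epochs, "l_cl"], weights)
  structure(list(net = net, weights = weights, alpha = alpha,
                 control = control, history = as.data.frame(hist),
                 final = final, layer_names = names(data$layers),
                 dims = v, n_class = data$n_class, n_train = data$n,
                 mode = mode, seed = as.integer(seed)),
            class = "clclsa")
}

# Evaluation-mode encoding of a dataset: per-layer completed latents,
# attention scores and provenance.
clclsa_encode <- function(object, data) {
  net <- object$net
  control <- object$control
  m <- net$m
  stopifnot(data$m == m)
  n <- data$n
  zhats <- vector("list", m)
  matts <- matrix(NA_real_, n, m)
  for (i in seq_len(m)) {
    obs <- which(data$mask[, i])
    x <- data$layers[[i]][obs, , drop = FALSE]
    if (control$attention) {
      fatt <- sigmoid(stack_apply(net$stacks[[paste0("f", i)]], x))
      gated <- if (control$gate_convention == "input") x * fatt else x
      xhat <- stack_apply(net$stacks[[paste0("emb", i)]], gated)
      if (control$gate_convention == "output") xhat <- xhat * fatt
      matt <- sigmoid(stack_apply(net$stacks[[paste0("g", i)]], xhat))
      z <- xhat * as.numeric(matt)
    } else {
      xhat <- stack_apply(net$stacks[[paste0("emb", i)]], x)
      matt <- matrix(1, length(obs), 1L)
      z <- xhat
    }
    full <- matrix(0, n, net$d)
    full[obs, ] <- z
    zhats[[i]] <- full
    matts[obs, i] <- matt
  }
  comp <- complete_missing(zhats, as_cross_omics_ae(net), data$mask)
  list(zhats = comp$zhats, provenance = comp$provenance, matts = matts)
}

#' Predict from a fitted CLCLSA model
#'
#' Runs the evaluation-mode forward pass (dropout off, batch normalization on
#' running statistics), completing any missing layers through the trained
#' cross-omics translators before fusion.
#'
#' @param object a fitted [clclsa()] model.
#' @param newdata a [multi_omics_dataset()] with the same layers.
#' @param type \code{"prob"} (class-probability matrix), \code{"class"}
#'   (integer labels), \code{"latent"} (list of completed per-omics latents)
#'   or \code{"fused"} (concatenated representation).
#' @param ... unused.
#' @return see \code{type}.
#' @export
predict.clclsa <- function(object, newdata,
                           type = c("prob", "class", "latent", "fused"),
                           ...) {
  type <- match.arg(type)
  enc <- clclsa_encode(object, newdata)
  if (type == "latent") return(enc$zhats)
  fused <- fuse_latents(enc$zhats)
  if (type == "fused") return(fused)
  probs <- stack_apply(object$net$stacks[["c"]], fused)
  colnames(probs) <- paste0("class", seq_len(object$n_class) - 1L)
  if (type == "prob") probs else max.col(probs, ties.method = "first") - 1L
}

#' @export
print.clclsa <- function(x, ...) {
  cat("CLCLSA multi-omics classifier\n")
  cat("  layers: ",
      paste(sprintf("%s (V=%d)", x$layer_names, x$dims), collapse = ", "),
      "\n", sep = "")
  cat(sprintf("  latent dim %d, %d classes, mode %s\n",
              x$net$d, x$n_class, x$mode))
  cat(sprintf("  weights: lambda_al %.3g, lambda_co %.3g, lambda_cl %.3g, alpha %.3g\n",
              x$weights$lambda_al, x$weights$lambda_co, x$weights$lambda_cl,
              x$alpha))
  cat(sprintf("  trained %d epochs on %d subjects; final ",
              nrow(x$history), x$n_train))
  print(x$final)
  invisible(x)
}

#' @export
summary.clclsa <- function(object, ...) {
  h <- object$history
  out <- list(model = object, final = object$final,
              loss_path = h[c(1L, nrow(h)), ],
              n_params = sum(vapply(
                net_get_params(object$net, net_param_index(object$net)),
                length, numeric(1))))
  class(out) <- "summary.clclsa"
  out
}

#' @export
print.summary.clclsa <- function(x, ...) {
  print(x$model)
  cat(sprintf("  trainable parameters: %d\n", x$n_params))
  cat("  loss at first/last epoch:\n")
  print(x$loss_path, row.names = FALSE)
  invisible(x)
}

#' @export
coef.clclsa <- function(object, ...) {
  idx <- net_param_index(object$net)
  vals <- net_get_params(object$net, idx)
  names(vals) <- vapply(idx, function(s)
    paste0(s$stack, ".", s$step, ".", s$field), character(1))
  vals
}

#' @export
plot.clclsa <- function(x, which = c("total", "l_clf", "l_co", "l_cl"), ...) {
  h <- x$history
  which <- intersect(which, colnames(h))
  matplot(h$epoch, h[, which, drop = FALSE], type = "l", lty = 1,
          xlab = "epoch", ylab = "loss", ...)
  legend("topright", legend = which, col = seq_along(which), lty = 1,
         bty = "n")
  invisible(x)
}

# Loss components and flat gradients at the current parameters (no update).
# Used for gradient verification; `training` keeps batch-norm in batch mode
# so the forward is a deterministic function of the parameters when dropout
# is zero.
clclsa_loss_grads <- function(object, data, component = "total",
                              training = TRUE) {
  net <- object$net
  index <- net_param_index(net)
  tape <- tape_new()
  pn <- make_pnodes(tape, net, index)
  ctl <- object$control
  ctl$dropout <- 0
  out <- clclsa_forward(tape, net, ctl, object$weights, object$alpha,
                        data$layers, data$mask, data$labels,
                        training = training, pn = pn)
  root <- out[[component]]
  tape_backward(tape, root)
  list(value = root$value[1L],
       components = vapply(c("total", "l_clf", "l_al", "l_co", "l_cl"),
                           function(nm) out[[nm]]$value[1L], numeric(1)),
       grads = lapply(pn$nodes, function(nd) {
         if (is.null(nd$grad)) nd$value * 0 else nd$grad
       }),
       index = index)
}
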