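#' Parse a network architecture string
#'
#' Architectures are written as dash-separated tokens: integers give layer
#' widths (each consecutive pair of integers is a fully connected map) and the
#' tokens \code{ReLU}, \code{BN}, \code{DP} and \code{Softmax} insert a
#' rectifier, batch normalization, dropout, or a softmax head after the most
#' recent linear layer. Examples: \code{"200-300-ReLU-DP"} (one linear map
#' 200 to 300 followed by ReLU and dropout),
#' \code{"300-64-BN-ReLU-32-ReLU-64-BN-ReLU-300"} (a bottleneck autoencoder),
#' \code{"900-2-Softmax"} (a linear softmax classifier).
#'
#' @param text architecture string.
#' @return an object of class \code{"clclsa_arch"}: a list with \code{steps}
#'   (ordered list of step descriptors), \code{dim_in} and \code{dim_out}.
#' @examples
#' parse_architecture("300-2-Softmax")
#' parse_architecture("200-64-BN-ReLU-32-ReLU-64-BN-ReLU-200")
#' @export
parse_architecture <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  toks <- strsplit(trimws(text), "-", fixed = TRUE)[[1]]
  if (length(toks) < 2L) {
    stop("architecture '", text, "' needs at least two tokens")
  }
  is_int <- grepl("^[0-9]+$", toks)
  if (!is_int[1L]) {
    stop("architecture parse error at token 1 ('", toks[1L],
         "'): expected an integer input dimension")
  }
  steps <- list()
  prev_dim <- as.integer(toks[1L])
  dim_in <- prev_dim
  for (pos in seq_along(toks)[-1L]) {
    tok <- toks[pos]
    if (is_int[pos]) {
      d <- as.integer(tok)
      if (d <= 0L) stop("architecture parse error at token ", pos,
                        ": dimension must be positive")
      steps[[length(steps) + 1L]] <- list(type = "linear",
                                          d_in = prev_dim, d_out = d)
      prev_dim <- d
    } else if (tok == "ReLU") {
      steps[[length(steps) + 1L]] <- list(type = "relu")
    } else if (tok == "BN") {
      steps[[length(steps) + 1L]] <- list(type = "bn", d = prev_dim)
    } else if (tok == "DP") {
      steps[[length(steps) + 1L]] <- list(type = "dropout")
    } else if (tok == "Softmax") {
      steps[[length(steps) + 1L]] <- list(type = "softmax")
    } else {
      stop("architecture parse error at token ", pos, " ('", tok,
           "'): expected an integer or one of ReLU, BN, DP, Softmax")
    }
  }
  structure(list(text = text, steps = steps,
                 dim_in = dim_in, dim_out = prev_dim),
            class = "clclsa_arch")
}

#' @export
print.clclsa_arch <- function(x, ...) {
  cat("<clclsa_arch> ", x$text, "  (", x$dim_in, " -> ", x$dim_out, ")\n",
      sep = "")
  invisible(x)
}

#' Build a layer stack from an architecture
#'
#' Instantiates the weights of an architecture parsed by
#' [parse_architecture()]. Linear weights use fan-in-scaled uniform
#' initialization \code{U(-1/sqrt(d_in), 1/sqrt(d_in))}; batch-normalization
#' scale/shift start at 1/0 with zeroed running statistics. Weights are drawn
#' from R's current RNG stream, so wrap in [set.seed()] (or let
#' [clclsa()] do it) for reproducibility.
#'
#' @param arch a \code{clclsa_arch} or an architecture string.
#' @return a \code{"clclsa_stack"}: list of steps carrying their parameters.
#' @export
build_stack <- function(arch) {
  if (is.character(arch)) arch <- parse_architecture(arch)
  stopifnot(inherits(arch, "clclsa_arch"))
  steps <- lapply(arch$steps, function(st) {
    if (st$type == "linear") {
      bound <- 1 / sqrt(st$d_in)
      st$W <- matrix(stats::runif(st$d_in * st$d_out, -bound, bound),
                     st$d_in, st$d_out)
      st$b <- matrix(stats::runif(st$d_out, -bound, bound), 1L, st$d_out)
    } else if (st$type == "bn") {
      st$gamma <- matrix(1, 1L, st$d)
      st$beta <- matrix(0, 1L, st$d)
      st$state <- new.env(parent = emptyenv())
      st$state$running_mean <- rep(0, st$d)
      st$state$running_var <- rep(1, st$d)
    }
    st
  })
  structure(list(arch = arch, steps = steps), class = "clclsa_stack")
}

# Collect references to the numeric parameter slots of a stack, as a list of
# list(stack_name, step index, field). Used to enumerate all trainable
# parameters of a model in a stable order.
stack_param_slots <- function(stack) {
  out <- list()
  for (i in seq_along(stack$steps)) {
    st <- stack$steps[[i]]
    if (st$type == "linear") {
      out[[length(out) + 1L]] <- list(step = i, field = "W")
      out[[length(out) + 1L]] <- list(step = i, field = "b")
    } else if (st$type == "bn") {
      out[[length(out) + 1L]] <- list(step = i, field = "gamma")
      out[[length(out) + 1L]] <- list(step = i, field = "beta")
    }
  }
  out
}

# Forward pass of a stack over the tape. `x` is a node (n x d_in). Parameter
# nodes are taken from `pnodes` when given (training: nodes shared across the
# whole step so gradients accumulate); otherwise fresh leaves are created.
# Dropout draws masks from the current RNG stream when training.
stack_forward <- function(tape, stack, x, training = FALSE,
                          pnodes = NULL, dropout_p = 0.5) {
  h <- x
  for (i in seq_along(stack$steps)) {
    st <- stack$steps[[i]]
    if (st$type == "linear") {
      W <- if (is.null(pnodes)) ad_leaf(tape, st$W) else pnodes[[paste0(i, ".W")]]
      b <- if (is.null(pnodes)) ad_leaf(tape, st$b) else pnodes[[paste0(i, ".b")]]
      h <- ad_add(tape, ad_mm(tape, h, W), b)
    } else if (st$type == "relu") {
      h <- ad_relu(tape, h)
    } else if (st$type == "bn") {
      gamma <- if (is.null(pnodes)) ad_leaf(tape, st$gamma) else pnodes[[paste0(i, ".gamma")]]
      beta <- if (is.null(pnodes)) ad_leaf(tape, st$beta) else pnodes[[paste0(i, ".beta")]]
      h <- ad_batchnorm(tape, h, gamma, beta, st$state, training)
    } else if (st$type == "dropout") {
      if (training && dropout_p > 0) {
        mask <- matrix(stats::rbinom(length(h$value), 1L, 1 - dropout_p),
                       nrow(h$value), ncol(h$value))
        h <- ad_dropout(tape, h, mask, 1 - dropout_p)
      }
    } else if (st$type == "softmax") {
      h <- ad_row_softmax(tape, h)
    }
  }
  h
}

# Plain numeric forward (no tape, evaluation mode).
stack_apply <- function(stack, x) {
  tp <- tape_new()
  stack_forward(tp, stack, ad_leaf(tp, x), training = FALSE)$value
}

# Overwrite the weights of the first linear layer (test/configuration helper).
stack_set_linear <- function(stack, index, W, b) {
  lin <- which(vapply(stack$steps, function(s) s$type == "linear", TRUE))
  i <- lin[index]
  stopifnot(identical(dim(stack$steps[[i]]$W), dim(as_mat(W)) ) ||
              length(W) == length(stack$steps[[i]]$W))
  stack$steps[[i]]$W <- matrix(W, nrow(stack$steps[[i]]$W),
                               ncol(stack$steps[[i]]$W))
  stack$steps[[i]]$b <- matrix(b, 1L, ncol(stack$steps[[i]]$b))
  stack
}
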