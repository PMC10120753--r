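# Minimal reverse-mode automatic differentiation on dense matrices.
#
# A tape records nodes in execution order; each node is an environment holding
# its value, an accumulated gradient, and a backward closure that pushes the
# node's gradient into its parents. Backpropagation walks the tape in reverse.
# All values are numeric matrices (scalars are 1x1) so every op has a single
# shape discipline.

tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

ad_node <- function(tape, value, backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$backward <- backward
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  nd$id <- tape$n
  tape$nodes[[tape$n]] <- nd
  nd
}

ad_accum <- function(nd, g) {
  if (is.null(nd$grad)) nd$grad <- g else nd$grad <- nd$grad + g
  invisible(NULL)
}

as_mat <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}

# Leaf holding data; gradients are accumulated but typically only read for
# parameters.
ad_leaf <- function(tape, value) ad_node(tape, as_mat(value))

ad_const <- ad_leaf

# Walk the tape backwards from a scalar root.
tape_backward <- function(tape, root) {
  stopifnot(length(root$value) == 1L)
  root$grad <- matrix(1, 1L, 1L)
  for (i in seq(root$id, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd$grad)
  }
  invisible(NULL)
}

ad_mm <- function(tape, a, b) {
  av <- a$value; bv <- b$value
  ad_node(tape, av %*% bv, backward = function(g) {
    ad_accum(a, g %*% t(bv))
    ad_accum(b, t(av) %*% g)
  })
}

ad_transpose <- function(tape, a) {
  ad_node(tape, t(a$value), backward = function(g) ad_accum(a, t(g)))
}

# a + b; b may match a, be a 1 x ncol(a) row (bias broadcast over rows),
# or be 1 x 1.
ad_add <- function(tape, a, b) {
  av <- a$value; bv <- b$value
  if (identical(dim(av), dim(bv))) {
    val <- av + bv
    bk <- function(g) { ad_accum(a, g); ad_accum(b, g) }
  } else if (nrow(bv) == 1L && ncol(bv) == ncol(av)) {
    val <- sweep(av, 2L, as.numeric(bv), "+")
    bk <- function(g) {
      ad_accum(a, g)
      ad_accum(b, matrix(colSums(g), 1L))
    }
  } else if (length(bv) == 1L) {
    val <- av + bv[1L]
    bk <- function(g) { ad_accum(a, g); ad_accum(b, matrix(sum(g), 1L, 1L)) }
  } else stop("ad_add: incompatible shapes")
  ad_node(tape, val, backward = bk)
}

ad_sub <- function(tape, a, b) ad_add(tape, a, ad_scale(tape, b, -1))

# Elementwise product; shapes may match, or b may be an nrow(a) x 1 column
# (broadcast across columns) or 1 x 1 scalar.
ad_emul <- function(tape, a, b) {
  av <- a$value; bv <- b$value
  if (identical(dim(av), dim(bv))) {
    val <- av * bv
    bk <- function(g) { ad_accum(a, g * bv); ad_accum(b, g * av) }
  } else if (ncol(bv) == 1L && nrow(bv) == nrow(av)) {
    val <- av * as.numeric(bv)
    bk <- function(g) {
      ad_accum(a, g * as.numeric(bv))
      ad_accum(b, matrix(rowSums(g * av), ncol = 1L))
    }
  } else if (length(bv) == 1L) {
    val <- av * bv[1L]
    bk <- function(g) {
      ad_accum(a, g * bv[1L])
      ad_accum(b, matrix(sum(g * av), 1L, 1L))
    }
  } else stop("ad_emul: incompatible shapes")
  ad_node(tape, val, backward = bk)
}

ad_scale <- function(tape, a, k) {
  ad_node(tape, a$value * k, backward = function(g) ad_accum(a, g * k))
}

ad_square <- function(tape, a) {
  av <- a$value
  ad_node(tape, av * av, backward = function(g) ad_accum(a, 2 * av * g))
}

ad_relu <- function(tape, a) {
  av <- a$value
  keep <- av > 0
  ad_node(tape, av * keep, backward = function(g) ad_accum(a, g * keep))
}

ad_sigmoid <- function(tape, a) {
  s <- 1 / (1 + exp(-a$value))
  ad_node(tape, s, backward = function(g) ad_accum(a, g * s * (1 - s)))
}

ad_row_softmax <- function(tape, a) {
  av <- a$value
  mx <- apply(av, 1L, max)
  e <- exp(av - mx)
  p <- e / rowSums(e)
  ad_node(tape, p, backward = function(g) {
    dot <- rowSums(g * p)
    ad_accum(a, p * (g - dot))
  })
}

ad_sum <- function(tape, a) {
  av <- a$value
  ad_node(tape, matrix(sum(av), 1L, 1L), backward = function(g) {
    ad_accum(a, matrix(g[1L], nrow(av), ncol(av)))
  })
}

ad_mean <- function(tape, a) {
  av <- a$value
  n <- length(av)
  ad_node(tape, matrix(mean(av), 1L, 1L), backward = function(g) {
    ad_accum(a, matrix(g[1L] / n, nrow(av), ncol(av)))
  })
}

ad_row_sums <- function(tape, a) {
  av <- a$value
  ad_node(tape, matrix(rowSums(av), ncol = 1L), backward = function(g) {
    ad_accum(a, matrix(as.numeric(g), nrow(av), ncol(av)))
  })
}

ad_col_sums <- function(tape, a) {
  av <- a$value
  ad_node(tape, matrix(colSums(av), nrow = 1L), backward = function(g) {
    ad_accum(a, matrix(as.numeric(g), nrow(av), ncol(av), byrow = TRUE))
  })
}

# log(max(a, floor)); gradient is zero below the floor.
ad_log <- function(tape, a, floor = 1e-12) {
  av <- pmax(a$value, floor)
  live <- a$value >= floor
  ad_node(tape, log(av), backward = function(g) ad_accum(a, g * live / av))
}

# Outer sum u %o% 1 + 1 %o% v for column vectors u (n x 1) and v (m x 1).
ad_add_outer <- function(tape, u, v) {
  uv <- as.numeric(u$value); vv <- as.numeric(v$value)
  val <- outer(uv, vv, "+")
  ad_node(tape, val, backward = function(g) {
    ad_accum(u, matrix(rowSums(g), ncol = 1L))
    ad_accum(v, matrix(colSums(g), ncol = 1L))
  })
}

# a / s for a scalar (1x1) node s.
ad_div_scalar <- function(tape, a, s) {
  av <- a$value; sv <- s$value[1L]
  ad_node(tape, av / sv, backward = function(g) {
    ad_accum(a, g / sv)
    ad_accum(s, matrix(-sum(g * av) / sv^2, 1L, 1L))
  })
}

ad_concat_cols <- function(tape, parts) {
  vals <- lapply(parts, function(p) p$value)
  widths <- vapply(vals, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ad_node(tape, do.call(cbind, vals), backward = function(g) {
    for (i in seq_along(parts)) {
      ad_accum(parts[[i]], g[, starts[i]:ends[i], drop = FALSE])
    }
  })
}

ad_row_subset <- function(tape, a, idx) {
  av <- a$value
  ad_node(tape, av[idx, , drop = FALSE], backward = function(g) {
    full <- matrix(0, nrow(av), ncol(av))
    full[idx, ] <- full[idx, , drop = FALSE] + g
    ad_accum(a, full)
  })
}

# Assemble an n x d matrix from row blocks; pieces is a list of
# list(idx = <row indices>, node = <length(idx) x d node>). Indices must
# jointly cover 1..n without overlap.
ad_row_merge <- function(tape, n, pieces) {
  d <- ncol(pieces[[1L]]$node$value)
  val <- matrix(0, n, d)
  for (p in pieces) val[p$idx, ] <- p$node$value
  ad_node(tape, val, backward = function(g) {
    for (p in pieces) ad_accum(p$node, g[p$idx, , drop = FALSE])
  })
}

# Row-wise maximum with subgradient routed to the (first) argmax entry.
ad_row_max <- function(tape, a) {
  av <- a$value
  which_mx <- max.col(av, ties.method = "first")
  mx <- av[cbind(seq_len(nrow(av)), which_mx)]
  ad_node(tape, matrix(mx, ncol = 1L), backward = function(g) {
    full <- matrix(0, nrow(av), ncol(av))
    full[cbind(seq_len(nrow(av)), which_mx)] <- as.numeric(g)
    ad_accum(a, full)
  })
}

# Inverted dropout with a pre-drawn 0/1 mask and keep probability.
ad_dropout <- function(tape, a, mask, keep) {
  av <- a$value
  ad_node(tape, av * mask / keep, backward = function(g) {
    ad_accum(a, g * mask / keep)
  })
}

# Batch normalization over columns. gamma/beta are 1 x d parameter nodes.
# `state` is an environment with running_mean / running_var, updated in
# training mode with the given momentum; eval mode normalizes by the running
# statistics (constant w.r.t. the batch).
ad_batchnorm <- function(tape, a, gamma, beta, state, training,
                         momentum = 0.1, eps = 1e-5) {
  av <- a$value
  gv <- as.numeric(gamma$value)
  bv <- as.numeric(beta$value)
  m <- nrow(av)
  if (training) {
    mu <- colMeans(av)
    xc <- sweep(av, 2L, mu, "-")
    var_b <- colMeans(xc * xc)
    ivar <- 1 / sqrt(var_b + eps)
    xhat <- sweep(xc, 2L, ivar, "*")
    var_u <- if (m > 1L) var_b * m / (m - 1L) else var_b
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    state$running_var <- (1 - momentum) * state$running_var + momentum * var_u
    out <- sweep(sweep(xhat, 2L, gv, "*"), 2L, bv, "+")
    ad_node(tape, out, backward = function(g) {
      ad_accum(gamma, matrix(colSums(g * xhat), 1L))
      ad_accum(beta, matrix(colSums(g), 1L))
      dxhat <- sweep(g, 2L, gv, "*")
      s1 <- colSums(dxhat)
      s2 <- colSums(dxhat * xhat)
      dx <- sweep(
        dxhat - matrix(s1 / m, m, length(s1), byrow = TRUE) -
          xhat * matrix(s2 / m, m, length(s2), byrow = TRUE),
        2L, ivar, "*")
      ad_accum(a, dx)
    })
  } else {
    ivar <- 1 / sqrt(state$running_var + eps)
    xhat <- sweep(sweep(av, 2L, state$running_mean, "-"), 2L, ivar, "*")
    out <- sweep(sweep(xhat, 2L, gv, "*"), 2L, bv, "+")
    ad_node(tape, out, backward = function(g) {
      ad_accum(gamma, matrix(colSums(g * xhat), 1L))
      ad_accum(beta, matrix(colSums(g), 1L))
      ad_accum(a, sweep(sweep(g, 2L, gv, "*"), 2L, ivar, "*"))
    })
  }
}

# Forward value passes through; gradient is blocked.
ad_detach <- function(tape, a) ad_node(tape, a$value)
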