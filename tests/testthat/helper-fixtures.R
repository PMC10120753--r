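# Shared fixtures and independent oracles, built in code at test time.

# A stack whose parameters are all set to given constants (default zero).
const_stack <- function(arch, weight = 0, bias = 0) {
  st <- build_stack(arch)
  for (i in seq_along(st$steps)) {
    if (st$steps[[i]]$type == "linear") {
      st$steps[[i]]$W[] <- weight
      st$steps[[i]]$b[] <- bias
    }
  }
  st
}

# A single-linear-layer stack with explicit weights (d_in x d_out) and bias.
linear_stack <- function(W, b = 0) {
  W <- as.matrix(W)
  st <- build_stack(sprintf("%d-%d", nrow(W), ncol(W)))
  st$steps[[1]]$W <- W
  st$steps[[1]]$b <- matrix(b, 1, ncol(W))
  st
}

# Identity embedding stack (square, no bias, no nonlinearity).
identity_stack <- function(d) linear_stack(diag(d), 0)

tiny_dataset <- function(n = 40, m = 3, n_class = 2, v = c(8, 7, 6),
                         d_shared = 3, sep = 4, noise = 1, seed = 1) {
  synth_multiomics(synthetic_spec(
    n = n, m = m, n_class = n_class, v = v, d_shared = d_shared,
    class_separation = sep, noise_sd = noise,
    loading_seed = seed + 100, sample_seed = seed + 200))
}

fast_control <- function(epochs = 40, latent_dim = 8, lr = 1e-3, ...) {
  clclsa_control(epochs = epochs, latent_dim = latent_dim, lr = lr, ...)
}

# Brute-force double-loop oracle for the contrastive loss of a joint
# distribution matrix (independent of the vectorized implementation).
contrastive_oracle <- function(P, alpha) {
  pd <- rowSums(P)
  pdp <- colSums(P)
  total <- 0
  for (d in seq_len(nrow(P))) {
    for (dp in seq_len(ncol(P))) {
      if (P[d, dp] > 0) {
        total <- total - P[d, dp] *
          log(P[d, dp] / (pd[d]^(alpha + 1) * pdp[dp]^(alpha + 1)))
      }
    }
  }
  total
}

# Brute-force AUC: enumerate all positive-negative pairs, ties count 1/2.
auc_oracle <- function(p1, labels) {
  pos <- p1[labels == 1]
  neg <- p1[labels == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

cosine <- function(a, b) sum(a * b) / sqrt(sum(a * a) * sum(b * b))
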