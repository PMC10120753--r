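#' Specification for a synthetic multi-omics dataset
#'
#' The generator draws, for every subject, a shared latent state
#' \eqn{s^{(j)} \sim N(\mu_{y^{(j)}}, I)} in \code{d_shared} dimensions, with
#' one mean per class placed at the vertices of a scaled simplex so that all
#' pairwise class-mean distances equal \code{class_separation}. Each omics
#' layer i is then a linear readout \eqn{X_i[j,] = s^{(j)} W_i + \epsilon},
#' \eqn{\epsilon \sim N(0, noise\_sd^2 I)}, with a fixed random loading matrix
#' \eqn{W_i} (\code{d_shared} x \code{V[i]}). All layers are thus noisy views
#' of one underlying biological state, the structure the model assumes.
#'
#' @param n subjects. @param m number of omics layers.
#' @param n_class number of classes (labels balanced up to remainder).
#' @param v integer vector of per-layer feature dimensions (recycled to m).
#' @param d_shared shared latent dimension.
#' @param class_separation pairwise distance between class means in latent
#'   space, in units of the latent noise standard deviation (which is 1).
#' @param noise_sd observation noise standard deviation per feature.
#' @param loading_seed,sample_seed seeds for the fixed loadings and for the
#'   per-subject draws.
#' @return an object of class \code{"synthetic_spec"}.
#' @export
synthetic_spec <- function(n = 200L, m = 3L, n_class = 2L,
                           v = c(50L, 50L, 30L), d_shared = 5L,
                           class_separation = 4, noise_sd = 1,
                           loading_seed = 11L, sample_seed = 7L) {
  v <- rep_len(as.integer(v), m)
  stopifnot(n >= n_class, d_shared >= 1L, all(v > 0L), m >= 1L,
            class_separation >= 0, noise_sd > 0)
  structure(list(n = as.integer(n), m = as.integer(m),
                 n_class = as.integer(n_class), v = v,
                 d_shared = as.integer(d_shared),
                 class_separation = class_separation, noise_sd = noise_sd,
                 loading_seed = as.integer(loading_seed),
                 sample_seed = as.integer(sample_seed)),
            class = "synthetic_spec")
}

# Class means at the vertices of a regular simplex with side `sep`,
# embedded in d dimensions. Exact when d >= C-1; otherwise the centered
# vertices are projected onto the leading d coordinates (distances then only
# approximate, flagged by a warning).
simplex_means <- function(n_class, d, sep) {
  if (n_class == 1L) return(matrix(0, 1L, d))
  verts <- diag(n_class)
  verts <- sweep(verts, 2L, colMeans(verts), "-")
  # pairwise vertex distance of the centered identity corners is sqrt(2)
  verts <- verts * (sep / sqrt(2))
  basis <- svd(t(verts))$u  # n_class x (n_class-1) column space
  coords <- verts %*% basis
  k <- ncol(coords)
  if (d >= k) {
    cbind(coords, matrix(0, n_class, d - k))
  } else {
    warning("d_shared < n_class - 1: class-mean distances are approximate")
    coords[, seq_len(d), drop = FALSE]
  }
}

#' Generate a synthetic multi-omics dataset
#'
#' @param spec a [synthetic_spec()].
#' @param eta optional missing rate; when positive, [simulate_missingness()]
#'   is applied with \code{mask_seed}.
#' @param mask_seed seed for the missingness mask.
#' @return a [multi_omics_dataset()] with attribute \code{"ground_truth"}: a
#'   list with the shared latents \code{s} (n x d_shared), \code{class_means}
#'   and per-layer \code{loadings}.
#' @examples
#' d <- synth_multiomics(synthetic_spec(n = 40, v = c(10, 8, 6)))
#' d
#' @export
synth_multiomics <- function(spec, eta = 0, mask_seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  rng_w <- local_rng(spec$loading_seed)
  loadings <- lapply(spec$v, function(vi) {
    matrix(rng_rnorm(rng_w, spec$d_shared * vi, sd = 1 / sqrt(spec$d_shared)),
           spec$d_shared, vi)
  })
  mu <- simplex_means(spec$n_class, spec$d_shared, spec$class_separation)
  labels <- rep_len(seq_len(spec$n_class) - 1L, spec$n)
  rng_s <- local_rng(spec$sample_seed)
  s <- matrix(rng_rnorm(rng_s, spec$n * spec$d_shared), spec$n, spec$d_shared)
  s <- s + mu[labels + 1L, , drop = FALSE]
  layers <- vector("list", spec$m)
  for (i in seq_len(spec$m)) {
    noise <- matrix(rng_rnorm(rng_s, spec$n * spec$v[i], sd = spec$noise_sd),
                    spec$n, spec$v[i])
    layers[[i]] <- s %*% loadings[[i]] + noise
  }
  names(layers) <- paste0("omics", seq_len(spec$m))
  ds <- multi_omics_dataset(layers, labels)
  if (eta > 0) ds <- simulate_missingness(ds, eta, seed = mask_seed)
  attr(ds, "ground_truth") <- list(s = s, class_means = mu,
                                   loadings = loadings)
  ds
}
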