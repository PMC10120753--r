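# Reference experiments at package scale: fixed synthetic study conditions
# exercising the full method end to end. The same definitions back the test
# suite and the reproduction script, so the reported numbers always come from
# the code paths users run.

study_control <- function(epochs, latent_dim = 16L, lr = 1e-3) {
  clclsa_control(epochs = epochs, latent_dim = latent_dim, lr = lr)
}

#' Reference experiment: latent completion vs a mean-latent baseline
#'
#' Generates low-noise three-layer data (300 subjects, shared latent
#' dimension 5, observation noise 0.2), trains the full model on a fully
#' observed 80\% subset, then hides the first omics layer for the held-out
#' subjects and completes it from the remaining layers. For every held-out
#' subject the cosine similarity between the imputed latent and the latent
#' the encoder would have produced from the unmasked input is compared
#' against the similarity achieved by predicting the mean training latent.
#'
#' @param seed integer seed for all randomness.
#' @return list with \code{win_rate} (fraction of held-out subjects where the
#'   model beats the baseline), \code{mean_cosine_model},
#'   \code{mean_cosine_baseline} and \code{n} (held-out subjects).
#' @export
study_imputation_recovery <- function(seed = 1L) {
  spec <- synthetic_spec(n = 300, m = 3, n_class = 2, v = c(50, 50, 30),
                         d_shared = 5, class_separation = 4, noise_sd = 0.2,
                         loading_seed = derive_seed(seed, "imp-load"),
                         sample_seed = derive_seed(seed, "imp-samp"))
  ds <- synth_multiomics(spec)
  split <- train_test_split(ds$labels, 0.8, seed = derive_seed(seed, "imp-split"))
  train_ds <- subset_dataset(ds, subjects = split$train)
  held <- subset_dataset(ds, subjects = split$test)
  fit <- clclsa(train_ds, lambda_al = 0.1, lambda_co = 0.1,
                lambda_cl = 0.01, mode = "incomplete",
                control = study_control(200), seed = derive_seed(seed, "imp-fit"))
  enc_true <- clclsa_encode(fit, held)
  masked <- held
  masked$mask[, 1] <- FALSE
  enc_masked <- clclsa_encode(fit, masked)
  enc_train <- clclsa_encode(fit, train_ds)
  base <- colMeans(enc_train$zhats[[1]])
  cos_model <- vapply(seq_len(held$n), function(j)
    cosine_sim(enc_masked$zhats[[1]][j, ], enc_true$zhats[[1]][j, ]),
    numeric(1))
  cos_base <- vapply(seq_len(held$n), function(j)
    cosine_sim(base, enc_true$zhats[[1]][j, ]), numeric(1))
  list(win_rate = mean(cos_model > cos_base),
       mean_cosine_model = mean(cos_model),
       mean_cosine_baseline = mean(cos_base),
       n = held$n)
}

#' Reference experiment: end-to-end classification with missing layers
#'
#' Two well-separated classes (class-mean distance 4 latent standard
#' deviations), 200 subjects over three omics layers, missing rate 0.2
#' applied to the whole cohort; 300 full-batch training epochs on a 70\%
#' stratified split.
#'
#' @param seed integer seed.
#' @return list with \code{acc}, \code{f1}, \code{auc}, \code{n_test}.
#' @export
study_end_to_end <- function(seed = 1L) {
  spec <- synthetic_spec(n = 200, m = 3, n_class = 2, v = c(50, 50, 30),
                         d_shared = 5, class_separation = 4, noise_sd = 1,
                         loading_seed = derive_seed(seed, "e2e-load"),
                         sample_seed = derive_seed(seed, "e2e-samp"))
  ds <- synth_multiomics(spec)
  res <- run_case(ds, eta = 0.2, seed = derive_seed(seed, "e2e"),
                  lambda_al = 0.1, lambda_co = 0.1, lambda_cl = 0.01,
                  alpha = 9, control = study_control(300))
  list(acc = res$report$acc, f1 = res$report$f1, auc = res$report$auc,
       n_test = res$report$n_test)
}

#' Reference experiment: component ablation at missing rate 0.3
#'
#' Moderately separated classes (distance 2.5) over three layers of 120
#' subjects keep the task off the accuracy ceiling; the \code{plain} variant
#' (no attention, no auxiliary or contrastive loss) and the full
#' \code{ctst+aux} variant are each trained over ten seeds.
#'
#' @param seed integer seed.
#' @return list with \code{acc_plain}, \code{acc_full}, \code{gap},
#'   \code{gap_se} (pooled standard error of the gap) and the per-run
#'   \code{table}.
#' @export
study_ablation <- function(seed = 1L) {
  spec <- synthetic_spec(n = 120, m = 3, n_class = 2, v = c(30, 30, 20),
                         d_shared = 5, class_separation = 2.5, noise_sd = 1,
                         loading_seed = derive_seed(seed, "abl-load"),
                         sample_seed = derive_seed(seed, "abl-samp"))
  ds <- synth_multiomics(spec)
  seeds <- derive_seed(seed, "abl") + seq_len(10L)
  tab <- ablation_study(ds, eta = 0.3, seeds = seeds, lambda_co = 0.1,
                        lambda_al = 0.1, lambda_cl = 0.1,
                        control = study_control(200))
  s <- attr(tab, "summary")
  mplain <- s$mean[s$key == "plain"]
  mfull <- s$mean[s$key == "ctst+aux"]
  se_pool <- sqrt(s$se[s$key == "plain"]^2 + s$se[s$key == "ctst+aux"]^2)
  list(acc_plain = mplain, acc_full = mfull, gap = mfull - mplain,
       gap_se = se_pool, table = tab)
}

#' Reference experiment: accuracy as a function of the missing rate
#'
#' Sweeps missing rates 0, 0.2, 0.4, 0.6, 0.8 with three seeds per point on
#' a 160-subject three-layer cohort (class separation 3); each point retrains
#' from scratch.
#'
#' @param seed integer seed.
#' @return list with \code{etas}, \code{mean_acc}, \code{se} and the raw
#'   sweep \code{table}.
#' @export
study_missing_rate <- function(seed = 1L) {
  spec <- synthetic_spec(n = 160, m = 3, n_class = 2, v = c(30, 30, 20),
                         d_shared = 5, class_separation = 3, noise_sd = 1,
                         loading_seed = derive_seed(seed, "mono-load"),
                         sample_seed = derive_seed(seed, "mono-samp"))
  ds <- synth_multiomics(spec)
  etas <- c(0, 0.2, 0.4, 0.6, 0.8)
  seeds <- derive_seed(seed, "mono") + seq_len(3L)
  tab <- missing_rate_sweep(ds, etas = etas, seeds = seeds,
                            lambda_al = 0.1, lambda_co = 0.1,
                            lambda_cl = 0.01,
                            control = study_control(150, latent_dim = 12L))
  s <- attr(tab, "summary")
  ord <- order(as.numeric(s$key))
  list(etas = as.numeric(s$key)[ord], mean_acc = s$mean[ord],
       se = s$se[ord], table = tab)
}

cosine_sim <- function(a, b) sum(a * b) / sqrt(sum(a * a) * sum(b * b))
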