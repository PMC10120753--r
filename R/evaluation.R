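# Classification metrics and experiment harnesses: missing-rate sweeps,
# layer-combination studies, loss-weight grid search and ablations. Every
# harness case retrains from scratch on a seeded stratified split.

per_class_f1 <- function(pred, labels, classes) {
  vapply(classes, function(cl) {
    tp <- sum(pred == cl & labels == cl)
    fp <- sum(pred == cl & labels != cl)
    fn <- sum(pred != cl & labels == cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
}

#' Classification metrics
#'
#' Accuracy under argmax; for binary tasks additionally the F1 score of the
#' positive class (class 1) and the rank-statistic AUC of the class-1
#' probabilities (ties count one half); for multiclass tasks the
#' support-weighted and macro-averaged means of the per-class F1 scores.
#'
#' @param probs matrix (subjects x C) of class probabilities.
#' @param labels integer labels in \code{0..C-1}.
#' @param task \code{"auto"} (binary iff C = 2), \code{"binary"} or
#'   \code{"multiclass"}.
#' @return an object of class \code{"eval_report"}; for binary tasks with a
#'   single observed class the AUC is \code{NA} (undefined, not zero).
#' @export
compute_metrics <- function(probs, labels,
                            task = c("auto", "binary", "multiclass")) {
  task <- match.arg(task)
  probs <- as_mat(probs)
  labels <- as.integer(labels)
  stopifnot(nrow(probs) == length(labels))
  if (task == "auto") task <- if (ncol(probs) == 2L) "binary" else "multiclass"
  pred <- max.col(probs, ties.method = "first") - 1L
  acc <- mean(pred == labels)
  classes <- seq_len(ncol(probs)) - 1L
  if (task == "binary") {
    f1 <- per_class_f1(pred, labels, 1L)
    n1 <- sum(labels == 1L)
    n0 <- sum(labels == 0L)
    auc <- if (n1 == 0L || n0 == 0L) NA_real_ else {
      r <- rank(probs[, 2L])
      (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    }
    out <- list(task = task, acc = acc, f1 = f1, auc = auc,
                n_test = length(labels))
  } else {
    f1s <- per_class_f1(pred, labels, classes)
    support <- vapply(classes, function(cl) sum(labels == cl), numeric(1))
    weighted <- if (sum(support) > 0) sum(f1s * support) / sum(support) else 0
    out <- list(task = task, acc = acc, weighted_f1 = weighted,
                macro_f1 = mean(f1s), n_test = length(labels))
  }
  structure(out, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  if (x$task == "binary") {
    cat(sprintf("binary: ACC %.3f  F1 %.3f  AUC %s  (n=%d)\n", x$acc, x$f1,
                ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc)), x$n_test))
  } else {
    cat(sprintf("multiclass: ACC %.3f  WeightedF1 %.3f  MacroF1 %.3f  (n=%d)\n",
                x$acc, x$weighted_f1, x$macro_f1, x$n_test))
  }
  invisible(x)
}

report_row <- function(rep) {
  if (rep$task == "binary") {
    data.frame(acc = rep$acc, f1 = rep$f1, auc = rep$auc,
               n_test = rep$n_test)
  } else {
    data.frame(acc = rep$acc, weighted_f1 = rep$weighted_f1,
               macro_f1 = rep$macro_f1, n_test = rep$n_test)
  }
}

# Train on a seeded stratified split of `dataset` (masked at rate eta) and
# evaluate on the held-out part. Returns the metric row plus the fitted
# model.
run_case <- function(dataset, eta, seed, lambda_al, lambda_co, lambda_cl,
                     alpha, control, train_frac = 0.7,
                     apply_missing_to = c("both", "train", "test"),
                     layers = NULL, return_fit = FALSE) {
  apply_missing_to <- match.arg(apply_missing_to)
  if (!is.null(layers)) dataset <- subset_dataset(dataset, layers = layers)
  split <- train_test_split(dataset$labels, train_frac,
                            seed = derive_seed(seed, "split"))
  if (eta > 0) {
    masked <- simulate_missingness(dataset, eta,
                                   seed = derive_seed(seed, "mask"))
    mask <- masked$mask
    if (apply_missing_to == "train") mask[split$test, ] <- TRUE
    if (apply_missing_to == "test") mask[split$train, ] <- TRUE
    dataset$mask <- mask
  }
  mode <- if (eta > 0) "incomplete" else "complete"
  train_ds <- subset_dataset(dataset, subjects = split$train)
  test_ds <- subset_dataset(dataset, subjects = split$test)
  fit <- clclsa(train_ds, lambda_al = lambda_al, lambda_co = lambda_co,
                lambda_cl = lambda_cl, alpha = alpha, mode = mode,
                control = control, seed = derive_seed(seed, "fit"))
  probs <- predict(fit, test_ds, type = "prob")
  rep <- compute_metrics(probs, test_ds$labels)
  row <- cbind(data.frame(eta = eta, seed = seed), report_row(rep))
  if (return_fit) list(row = row, fit = fit, report = rep, split = split)
  else list(row = row, report = rep)
}

agg_summary <- function(df, by, metric = "acc") {
  sp <- split(df[[metric]], df[[by]])
  data.frame(key = names(sp),
             mean = vapply(sp, mean, numeric(1)),
             se = vapply(sp, function(x)
               if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0,
               numeric(1)),
             n = vapply(sp, length, numeric(1)),
             row.names = NULL)
}

#' Missing-rate sweep
#'
#' For every combination of missing rate and seed: simulate a presence mask,
#' split, train from scratch, and evaluate on the held-out subjects. A
#' mean +/- standard-error aggregation per missing rate is attached as
#' attribute \code{"summary"}.
#'
#' @param dataset a fully observed [multi_omics_dataset()].
#' @param etas missing rates to sweep (the full-scale protocol is 0.1 to 0.8
#'   in steps of 0.1).
#' @param seeds integer seeds, one training per (eta, seed).
#' @param lambda_al,lambda_co,lambda_cl,alpha loss configuration.
#' @param control a [clclsa_control()].
#' @param train_frac training fraction of the stratified split.
#' @param apply_missing_to mask the train partition, the test partition, or
#'   both (default).
#' @return data.frame with one row per (eta, seed).
#' @export
missing_rate_sweep <- function(dataset, etas = seq(0.1, 0.8, by = 0.1),
                               seeds = 1L, lambda_al = 0.1, lambda_co = 0.1,
                               lambda_cl = 0.01, alpha = 9,
                               control = clclsa_control(),
                               train_frac = 0.7,
                               apply_missing_to = "both") {
  stopifnot(all(etas >= 0 & etas <= 1))
  rows <- list()
  for (eta in etas) {
    for (sd_ in seeds) {
      rows[[length(rows) + 1L]] <-
        run_case(dataset, eta, sd_, lambda_al, lambda_co, lambda_cl, alpha,
                 control, train_frac, apply_missing_to)$row
    }
  }
  df <- do.call(rbind, rows)
  attr(df, "summary") <- agg_summary(df, "eta")
  df
}

#' Layer-combination study
#'
#' Trains and evaluates the model restricted to subsets of the omics layers
#' (default: all layers plus every pair, the four combinations at M = 3).
#' Two-layer combinations exercise the bi-view special case of the
#' cross-omics loss.
#'
#' @param dataset a fully observed [multi_omics_dataset()].
#' @param combos list of layer-name (or index) vectors; \code{NULL} for the
#'   default all + pairs.
#' @param eta missing rate applied per case.
#' @param seeds integer seeds.
#' @inheritParams missing_rate_sweep
#' @return data.frame with one row per (combo, seed).
#' @export
layer_combination_study <- function(dataset, combos = NULL, eta = 0,
                                    seeds = 1L, lambda_al = 0.1,
                                    lambda_co = 0.1, lambda_cl = 0.01,
                                    alpha = 9, control = clclsa_control(),
                                    train_frac = 0.7) {
  nms <- names(dataset$layers)
  if (is.null(combos)) {
    combos <- c(list(nms),
                utils::combn(nms, 2L, simplify = FALSE))
  }
  if (any(vapply(combos, length, integer(1)) == 0L)) {
    stop("domain error: empty layer combination")
  }
  rows <- list()
  for (ci in seq_along(combos)) {
    combo <- combos[[ci]]
    lab <- paste(if (is.character(combo)) combo else nms[combo],
                 collapse = "+")
    for (sd_ in seeds) {
      r <- run_case(dataset, eta, sd_, lambda_al, lambda_co, lambda_cl,
                    alpha, control, train_frac, layers = combo)$row
      rows[[length(rows) + 1L]] <- cbind(data.frame(combo = lab), r)
    }
  }
  df <- do.call(rbind, rows)
  attr(df, "summary") <- agg_summary(df, "combo")
  df
}

#' Ablation study
#'
#' Trains four variants with identical seeds at a fixed missing rate:
#' \code{plain} (no attention gates, no auxiliary or contrastive loss),
#' \code{ctst} (contrastive loss only), \code{aux} (attention gates +
#' auxiliary loss only) and \code{ctst+aux} (both). The cross-omics
#' reconstruction weight stays fixed and positive throughout (the completion
#' autoencoders are required with incomplete data).
#'
#' @param dataset a fully observed [multi_omics_dataset()].
#' @param eta missing rate (default 0.3).
#' @param seeds integer seeds; each variant is trained once per seed.
#' @param lambda_co fixed cross-omics weight (default 0.1).
#' @param lambda_al,lambda_cl weights used when the corresponding component
#'   is active.
#' @inheritParams missing_rate_sweep
#' @return data.frame with one row per (variant, seed); per-variant
#'   mean +/- s.e. in attribute \code{"summary"}.
#' @export
ablation_study <- function(dataset, eta = 0.3, seeds = 1:10,
                           lambda_co = 0.1, lambda_al = 0.1,
                           lambda_cl = 0.1, alpha = 9,
                           control = clclsa_control(), train_frac = 0.7) {
  stopifnot(lambda_co > 0)
  variants <- list(
    plain      = list(al = 0, cl = 0, attention = FALSE),
    ctst       = list(al = 0, cl = lambda_cl, attention = FALSE),
    aux        = list(al = lambda_al, cl = 0, attention = TRUE),
    `ctst+aux` = list(al = lambda_al, cl = lambda_cl, attention = TRUE))
  rows <- list()
  for (vn in names(variants)) {
    vv <- variants[[vn]]
    ctl <- control
    ctl$attention <- vv$attention
    for (sd_ in seeds) {
      r <- run_case(dataset, eta, sd_, vv$al, lambda_co, vv$cl, alpha,
                    ctl, train_frac)$row
      rows[[length(rows) + 1L]] <- cbind(data.frame(variant = vn), r)
    }
  }
  df <- do.call(rbind, rows)
  attr(df, "summary") <- agg_summary(df, "variant")
  df
}

#' Grid search over the loss weights
#'
#' Trains every row of the weight grid on a stratified training split and
#' selects the configuration with the highest validation accuracy; ties are
#' broken by lower final training loss, then lexicographically by
#' \code{(lambda_al, lambda_co, lambda_cl)}.
#'
#' @param dataset a [multi_omics_dataset()] (may already carry missingness).
#' @param grid data.frame with columns \code{lambda_al}, \code{lambda_co},
#'   \code{lambda_cl}; default [lambda_grid()] for the dataset's mode.
#' @param alpha contrastive exponent.
#' @param control a [clclsa_control()].
#' @param seed split/fit seed (shared across cells).
#' @param train_frac training fraction.
#' @return list with \code{best} (one-row data.frame) and \code{table} (all
#'   runs).
#' @export
grid_search <- function(dataset, grid = NULL, alpha = 9,
                        control = clclsa_control(), seed = 1L,
                        train_frac = 0.7) {
  mode <- if (missing_rate(dataset) > 0) "incomplete" else "complete"
  if (is.null(grid)) grid <- lambda_grid(mode)
  stopifnot(nrow(grid) >= 1L)
  split <- train_test_split(dataset$labels, train_frac,
                            seed = derive_seed(seed, "split"))
  train_ds <- subset_dataset(dataset, subjects = split$train)
  val_ds <- subset_dataset(dataset, subjects = split$test)
  rows <- list()
  for (r in seq_len(nrow(grid))) {
    fit <- clclsa(train_ds, lambda_al = grid$lambda_al[r],
                  lambda_co = grid$lambda_co[r],
                  lambda_cl = grid$lambda_cl[r], alpha = alpha, mode = mode,
                  control = control, seed = derive_seed(seed, "fit"))
    rep <- compute_metrics(predict(fit, val_ds, type = "prob"),
                           val_ds$labels)
    rows[[r]] <- cbind(grid[r, , drop = FALSE],
                       data.frame(val_acc = rep$acc,
                                  final_loss = fit$final$total))
  }
  tab <- do.call(rbind, rows)
  ord <- order(-tab$val_acc, tab$final_loss, tab$lambda_al, tab$lambda_co,
               tab$lambda_cl)
  list(best = tab[ord[1L], , drop = FALSE], table = tab[ord, , drop = FALSE])
}
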