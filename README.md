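# clclsa

Supervised multi-omics integration and classification when some subjects are
missing whole omics layers.

Multi-omics cohorts (e.g., mRNA expression + DNA methylation + miRNA
expression per subject) are rarely complete: cost and instrument sensitivity
leave many subjects with only a subset of layers. Dropping incomplete
subjects shrinks the cohort; imputing raw features is hard in thousands of
dimensions. `clclsa` instead completes missing layers **in latent space** and
trains the classifier on the full cohort. It is aimed at anyone building
subtype or case/control classifiers from partially overlapping omics
matrices.

## The model

For subject *j* and omics layer *i* with features
*x*<sub>*i*</sub><sup>(*j*)</sup> ∈ ℝ<sup>*V*<sub>*i*</sub></sup>:

- **Attention-gated embedding.** A feature-level sigmoid gate
  *fatt*<sub>*i*</sub> = σ(*f*<sub>*i*</sub>(*x*)) selects informative input
  features; the gated input is embedded,
  *x̂*<sub>*i*</sub> = emb<sub>*i*</sub>(*x* ⊙ *fatt*<sub>*i*</sub>), and an
  omics-level scalar gate *matt*<sub>*i*</sub> = σ(*g*<sub>*i*</sub>(*x̂*))
  weights the whole layer: *ẑ*<sub>*i*</sub> = *matt*<sub>*i*</sub> ·
  *x̂*<sub>*i*</sub>. All layers share one latent dimension *D*.
- **Cross-omics completion.** For every ordered pair (*i*, *k*) a directed
  bottleneck autoencoder *h*<sub>*ik*</sub> = dec<sub>*i*</sub> ∘
  enc<sub>*k*</sub> translates omics-*k* latents into omics-*i* latent space,
  trained with the reconstruction loss
  *L*<sub>co</sub> = Σ<sub>*j*</sub> Σ<sub>*i*≠*k*</sub>
  ‖*h*<sub>*ik*</sub>(*ẑ*<sub>*k*</sub>) − *ẑ*<sub>*i*</sub>‖² on subjects
  observing both layers. A missing *ẑ*<sub>*i*</sub> is the mean of the
  translations from the subject's observed layers.
- **Contrastive alignment.** Each latent vector is mapped to a distribution
  over its *D* dimensions (row softmax); averaging outer products of paired
  per-subject distributions gives a joint matrix *P* over latent dimensions
  of two layers, and the loss
  −Σ<sub>*d*,*d*′</sub> *P*<sub>*dd*′</sub> ln ( *P*<sub>*dd*′</sub> /
  (*P*<sub>*d*</sub><sup>α+1</sup> *P*<sub>*d*′</sub><sup>α+1</sup>) )
  rewards mutual information between layers plus (through α) marginal
  entropy, summed over ordered layer pairs.
- **Objective.** The completed latents are concatenated into
  *z* = [*ẑ*<sub>1</sub>, …, *ẑ*<sub>*M*</sub>] for a softmax classifier;
  per-omics auxiliary classifiers tie their confidence (maximal softmax
  output) to the omics attention score. Training minimizes
  *L* = *L*<sub>clf</sub> + λ<sub>al</sub>*L*<sub>al</sub> +
  λ<sub>co</sub>*L*<sub>co</sub> + λ<sub>cl</sub>*L*<sub>cl</sub>
  by full-batch Adam on the package's own reverse-mode autodiff engine.

## Worked example

```r
library(clclsa)

spec <- synthetic_spec(n = 150, m = 3, n_class = 2, v = c(40, 40, 25),
                       d_shared = 5, class_separation = 3, noise_sd = 1)
ds <- synth_multiomics(spec)
ds <- simulate_missingness(ds, eta = 0.3, seed = 1)
ds
#> Multi-omics dataset: 150 subjects, 3 layers, 2 classes
#>   layers: omics1 (V=40), omics2 (V=40), omics3 (V=25)
#>   incomplete subjects: 45 (missing rate 0.300)

split <- train_test_split(ds$labels, 0.7, seed = 1)
fit <- clclsa(subset_dataset(ds, subjects = split$train),
              lambda_al = 0.1, lambda_co = 0.1, lambda_cl = 0.01,
              control = clclsa_control(epochs = 200, lr = 1e-3, latent_dim = 16),
              seed = 1)
fit
#> CLCLSA multi-omics classifier
#>   layers: omics1 (V=40), omics2 (V=40), omics3 (V=25)
#>   latent dim 16, 2 classes, mode incomplete
#>   weights: lambda_al 0.1, lambda_co 0.1, lambda_cl 0.01, alpha 9
#>   trained 200 epochs on 104 subjects; final Loss: total -2.85789 = clf 0.0204854 + 0.1*al 0.703546 + 0.1*co 0.425252 + 0.01*cl -299.125

test <- subset_dataset(ds, subjects = split$test)
compute_metrics(predict(fit, test), test$labels)
#> binary: ACC 0.935  F1 0.936  AUC 0.974  (n=46)
```

A third of the cohort is missing at least one layer, yet the model classifies
the held-out subjects at 93% accuracy: the completion autoencoders supply the
latents the fused classifier needs. The negative contrastive component is
expected — its entropy bonus enters with a negative sign; what matters is the
near-zero classification loss.

Experiment harnesses mirror the standard study designs:
`missing_rate_sweep()` (accuracy vs missing rate), `layer_combination_study()`
(which layer subsets carry the signal), `ablation_study()`
(plain / ctst / aux / ctst+aux variants) and `grid_search()` over the
λ grid {0, 0.01, 0.02, 0.05, 0.1, 1}. The `exec/clclsa` script exposes
`synth`, `train`, `evaluate`, `sweep`, `ablate` and `grid` subcommands on the
same functions.

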