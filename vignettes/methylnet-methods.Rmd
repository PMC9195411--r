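---
title: "Methods: hybrid VAE/classifier analysis of methylation profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid VAE/classifier analysis of methylation profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylnet)
```

## The problem

DNA methylation at CpG islands is remodelled early in carcinogenesis and
differs strongly between tumour types, which makes array methylation
profiles (Illumina 450K-style beta values, the fraction of methylated
signal per probe, in $[0,1]$) a practical substrate for pan-cancer
diagnosis: given a profile, decide whether it is cancerous and, if so,
which of 33 tissue-of-origin classes it belongs to, with a 34th class
(`NORM`) for non-cancerous tissue of any type. methylnet implements this
workflow end to end: feature construction from the raw probe matrix, a
hybrid variational-autoencoder (VAE) / classifier network, evaluation, and
latent-space analysis, plus a synthetic-data generator so the entire
pipeline can be exercised and tested without access to controlled
consortium data.

## Feature construction

The preprocessor follows the CpG-density clustering recipe used by
methylation deconvolution tools:

1. **Island filter** — probes not assigned to a CpG island are dropped
   (`filter_island_probes()`). Island membership is taken as given in the
   manifest; no annotation release is assumed.
2. **Probe chaining** — per chromosome, island probes sorted by position
   are chained by single linkage: a new cluster starts whenever the gap to
   the previous probe exceeds `max_gap = 100` bp (`cluster_probes()`). The
   boundary case of a gap of exactly 100 bp joins, reading "within 100 bp"
   inclusively. Single linkage (rather than a max-span reading) is chosen
   because chained concatenation is what the reference preprocessing
   performs; the resulting partition is exactly the transitive closure of
   the pairwise "within 100 bp" relation, which is how the test suite
   verifies it against a brute-force $O(n^2)$ oracle.
3. **Size filter** — clusters of 3 probes or fewer are eliminated
   (`filter_clusters()`, `min_probes = 4`). Sizes are counted in probes:
   the manifest carries no per-probe CpG-site counts, so probes are the
   only available unit.
4. **Averaging** — each cluster feature is the arithmetic mean of its
   member probes' non-missing betas for that sample (`average_beta()`);
   a cell is missing only when every member is missing.
5. **Per-sample normalisation** — values are clipped to $[0,1]$ and any
   remaining missing entries are imputed with the sample's own mean over
   its non-missing entries (`normalize_sample()`).

Step 5 is deliberately minimal. Beta values are already fractions, so
normalisation beyond clipping would be speculative; more importantly,
every choice here is *per sample*: no step uses a statistic computed
across samples. This gives the leakage guarantee that the package tests as
an invariant — a sample's feature vector is identical whether it is
preprocessed alone or together with any other set of samples — so no
information can flow from test or validation samples into training
features. All-missing samples are rejected as uninformative rather than
silently imputed.

On the real 450K manifest this recipe yields on the order of 24,565
cluster features; the exact count depends on the manifest and island
annotation release, so it is treated as cohort-specific rather than a
contract.

## The network and its loss

The model couples an unsupervised generative path with a supervised
classifier through a shared Gaussian latent layer:

* **Encoder** — input ($p$ features) $\to$ dense relu layer (width 1000 at
  full scale) $\to$ two activation-free projection heads giving
  $\mu \in \mathbb{R}^k$ and $\log\sigma^2 \in \mathbb{R}^k$ of a diagonal
  Gaussian posterior ($k = 100$ at full scale).
* **Latent layer** — during training, $z = \mu + \sigma \odot \varepsilon$
  with $\varepsilon \sim \mathcal{N}(0, I)$ (the reparameterisation
  trick); at inference $z = \mu$, giving deterministic predictions.
* **Decoder** — $z \to$ dense relu layer $\to$ sigmoid output of width
  $p$, so reconstructions live in $(0,1)$ like beta values.
* **Classifier** — $z \to$ dense relu layer (width 100) $\to$ softmax over
  the 34 classes.

The per-sample objective is

$$\mathcal{L} = w_\text{vae}\,\big(\mathrm{CE}(x, \hat x) + \beta\,
\mathrm{KL}(q(z \mid x)\,\|\,\mathcal{N}(0, I))\big) +
w_\text{clf}\,\mathrm{CE}(y, \hat y),$$

with $w_\text{vae} = 0.01$, $w_\text{clf} = 1$ and $\beta = 1$ by default
($\beta > 1$ would give a disentangled VAE; it is exposed but untuned).
The reconstruction term against real-valued inputs in $[0,1]$ is
element-wise binary cross-entropy summed over features — the standard
idiom for sigmoid-output VAEs; a per-vector softmax reading would
contradict the sigmoid output layer. A config switch
(`recon_reduction = "mean"`) averages over features instead, which
rescales the effective VAE weight by $1/p$; sum is the default. The KL
term has the closed form
$\sum_i \tfrac12(\mu_i^2 + e^{\ell_i} - 1 - \ell_i)$ with
$\ell_i = \log\sigma_i^2$. Reconstructions are clamped away from
$\{0, 1\}$ by $10^{-7}$ inside the logs. The batch loss is the mean of
per-sample losses, which keeps the learning rate meaningful across batch
sizes.

Forward and backward passes are written directly as dense matrix algebra
in R (BLAS-backed); the analytic gradients are verified against central
finite differences to a relative error below $10^{-4}$ on a toy network as
part of the test suite. Weights are initialised with a fan-based uniform
(Glorot) scheme under the configuration seed; biases start at zero.

## Training protocol

Samples are split 80/10/10 into train/validation/test (`make_split()`).
The split is stratified by class by default because several real cancer
classes have under 100 samples and an unstratified 10% slice could miss
them entirely; a pure-random mode is available. Metastatic and recurrent
samples are excluded from splitting (`filter_eligible()`) — they are
evaluation-only material. Training sets are then deduplicated at the
patient level (`deduplicate_patients()`): when a patient contributes more
than one training sample (e.g. tumour/normal matched pairs), one is kept
at random and each removed sample is replaced, when possible, by an
unused sample of the same class whose patient is not already represented;
otherwise the slot stays unfilled.

Optimisation is Adam at learning rate 0.001 with minibatches of 128.
After each epoch, plain multiclass accuracy is computed on the validation
split; training stops once validation accuracy has failed to improve for
`patience_epochs = 50` consecutive epochs (ties broken by the earliest
epoch), and the returned parameters are those of the best validation
epoch. With patience 0 the loop stops at the first non-improving epoch. A
hard cap of 2000 epochs guards runs that never trigger the patience rule
(e.g. signal-free data where validation accuracy fluctuates around
chance). The entire run — initialisation, shuffling, latent draws — is a
deterministic function of the data and the configuration seed, and the
logged history decomposes exactly as
$w_\text{vae}(\text{recon} + \beta\,\text{KL}) + w_\text{clf}\,\text{CE}$
every epoch.

## Evaluation

`classification_report()` produces the confusion matrix over the fixed
34-label order, per-class precision/recall/F1, and two aggregates: the
**weighted F-measure** (support-weighted mean of per-class F1, the metric
of record under heavy class imbalance) and the **macro F-measure** (plain
mean). Zero-denominator classes score 0 and are flagged, matching the
zero-division convention of the common Python metric library so numbers
are comparable across implementations. `misclassification_profile()`
ranks where a class's errors go, normalised by support; the rates sum to
$1 - \text{recall}$.

## Latent-space analysis

`embed_samples()` returns the posterior means $\mu(x)$ — the
deterministic latent representation. Two tools consume it:

* `project_2d()` reduces to two dimensions for plots, by PCA
  (deterministic) or a seeded exact t-SNE (perplexity 30 by default,
  reduced automatically for small inputs; dense $O(n^2)$ implementation,
  adequate for test-set-sized embeddings). Projections are for
  visualisation only.
* `svm_separability()` measures whether a binary label occupies
  non-overlapping regions of the **full** latent space: mean stratified
  10-fold cross-validation accuracy of a linear-kernel SVM (cost 1,
  seeded folds). Separability is never computed on the 2-D projection,
  because apparent overlap in two dimensions says nothing about overlap
  in the full space.

## The synthetic-data generator

`generate_cohort()` emulates the statistical structure the method
assumes, at desk scale. The default corpus — used unchanged by the
package's integration tests — is 8 classes (7 cancer codes + NORM) of 100
samples each over 400 CpG islands:

* **Manifest geometry.** Within-island probe gaps are drawn from 20–80 bp
  (at most 100, so each island chains into exactly one cluster);
  between-island gaps are 10 kb (so islands never merge); islands carry
  4–8 probes (so none is removed by the size filter). A configurable 20%
  of additional non-island probes exercises the island filter. The
  expected cluster decomposition is therefore known by construction and
  the preprocessor is required to recover it exactly.
* **Class signatures.** Each class owns a disjoint signature set covering
  10% of islands (disjoint by default; a random-overlap mode exists).
  Signature-island probes draw from a hypermethylated Beta(8, 2) mode
  (mean 0.8), all others from a hypomethylated Beta(1.5, 8.5) mode (mean
  0.15), echoing the bimodality of real beta values while leaving
  overlapping within-class dispersion. Setting `signature_fraction = 0`
  removes all signal, making the classes exchangeable — the negative
  control under which held-out accuracy must fall to chance.
* **Patients and variants.** 10% of each class's samples share a patient
  with an earlier sample (matched pairs, exercising deduplication).
  `generate_variants()` derives metastasis-like copies (same signature,
  extra Gaussian dispersion of sd 0.05, flagged `metastatic`) and
  age-drift copies (NORM betas shifted down by 0.05 and clipped at 0,
  labels unchanged), emulating global age-related hypomethylation as a
  robustness probe.

What the generator does **not** emulate: array chemistry and detection
noise, batch effects, chromosomal structure, per-patient correlation
beyond shared class signatures, and the hierarchical relatedness of real
tissue lineages (a tissue-family grouping is available but off by
default). Passing tests on this corpus therefore demonstrates that the
implementation is correct and that the architecture can learn
signature-structured signal at realistic magnitudes — not that it attains
any particular accuracy on real cohorts.

## Numerical and design choices

* Internal genomic coordinates are 0-based; 1-based CSV manifest
  positions and 0-based BED-like starts are converted on read, nowhere
  else.
* Missing-value tokens accepted on input: `NA`, `NaN`, empty string,
  case-insensitive.
* Checkpoints are RDS archives (schema-versioned list of config +
  parameter arrays); round-trips are bit-exact.
* The desk-scale model used in integration tests is hidden width 64,
  latent 16, classifier hidden 16 — wide enough to solve the 8-class
  corpus in seconds on one CPU while exercising every code path at the
  reference optimiser settings (Adam 0.001, patience 50, weights 0.01/1,
  $\beta = 1$).
* Known limitations: training is single-threaded dense algebra — adequate
  up to a few thousand features and samples, not tuned for the full 450K
  problem size, where a BLAS with multithreading or a GPU framework would
  be the practical choice; t-SNE is exact (no Barnes–Hut approximation)
  and so quadratic in sample count; the early-stopping rule with
  patience 0 stops one epoch after the best rather than zero (a stop
  cannot be decided before observing a non-improving epoch).

## A worked run

```{r example, eval = FALSE}
spec <- synthetic_spec(seed = 1)
cohort <- generate_cohort(spec)
fb <- build_features(cohort$manifest, cohort$beta)
meta <- filter_eligible(cohort$metadata)
split <- deduplicate_patients(make_split(meta, seed = 1), meta, seed = 1)

cfg <- model_config(n_features = ncol(fb$features), hidden_size = 64,
                    latent_size = 16, n_classes = 8,
                    classifier_hidden = 16, seed = 1)
lab <- function(ids) meta$class_label[match(ids, meta$sample_id)]
fit <- train_model(cfg, fb$features[split$train_ids, ], lab(split$train_ids),
                   fb$features[split$val_ids, ], lab(split$val_ids),
                   class_levels = sort(unique(meta$class_label)))

pred <- predict(fit$state, fb$features[split$test_ids, ],
                labels = fit$class_levels)
classification_report(lab(split$test_ids), pred$class, fit$class_levels)
```

The same computation, together with the preprocessing oracle, gradient
check, separability and drift analyses, is what `scripts/acceptance.R`
reruns from scratch.
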