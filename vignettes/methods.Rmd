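---
title: "Multi-modal view augmentation for drug-pair prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-modal view augmentation for drug-pair prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairviews)
```

## The problem

Drug-combination screens label a triplet — two drugs and a context (a cell
line, a xenograft model, or an interaction type) — with an outcome: synergy
or not, a relative tumor-volume change, or the presence of a typed
drug-drug interaction.  The measured space is a tiny corner of the
combinatorial space, and the drugs themselves come described by wildly
heterogeneous data: a SMILES string, a molecular graph, a set of target
genes, precomputed 3D-structure and text embeddings, an ontology position,
a side-effect profile, a sensitivity profile.  Most drugs are missing
several of these modalities, which defeats methods that require a complete
feature vector per drug.

`pairviews` treats each *(modality of drug A, modality of drug B)*
combination as an independent training instance — a *view*.  With eight
modalities a fully profiled pair yields $8 \times 8 = 64$ views; a drug
with 5 modalities paired with one with 4 yields 20.  Missing modalities
simply produce fewer views; nothing is imputed.  The effective training
set grows by up to 64x, and a drug pair can be scored as long as each drug
has at least one modality.

## Model

**Projector.**  Eight encoders map payloads into a shared
$d_{\mathrm{hid}}$-dimensional space:

* *SMILES*: a transformer encoder over a frozen regex token vocabulary
  with a trailing `[CLS]` token; the contextual `[CLS]` embedding passes
  through one linear layer.
* *2D graph*: residual message passing over atoms (element / degree /
  formal-charge / aromaticity features), then concatenated mean and max
  pooling and one linear layer.  The encoder is exactly permutation
  invariant.
* *Targets*: target gene sets are expanded with each gene's $k_g$
  strongest PPI neighbors, then encoded by mean-pooling learnable gene
  embeddings and one linear layer.  The printed formulation concatenates
  a variable-size set of embeddings, which is not a well-defined fixed
  map; mean pooling (sum pooling as a config option) gives a
  permutation-invariant, size-independent function, which is the property
  that matters.
* *3D view*: a linear transformation of a precomputed 3D-aligned
  embedding; drugs without one can fall back to a small 2D graph encoder
  aligned to available 3D embeddings by a symmetric InfoNCE objective
  (`align_2d3d()`).
* *Text*: a linear transformation of a fixed text representation — a
  precomputed description embedding, or a deterministic hashed
  bag-of-tokens vector for raw strings.
* *Ontology*: fixed node embeddings from random-walk-with-restart
  profiles factorized by SVD (node vector = singular-value-scaled right
  singular directions), then one linear layer.
* *Side effects / sensitivity*: one linear layer from the 27-length
  indicator / 60-length profile.

**Context.**  Cell lines are encoded from their over-expressed gene set
(TPM $\ge$ `expr_threshold`, default 400, expanded one hop on the PPI) with
the *same* gene-embedding table as the target modality.  Xenograft
contexts add an interleaved sinusoidal time embedding
($\|c^{\mathrm{time}}\|^2 = d_{\mathrm{hid}}/2$ for every $t$); interaction
types get a learnable embedding each.

**Augmentor and heads.**  A view is one linear layer + ReLU over
$[z_{m_a} \mid z_{m_b} \mid c]$ (for interaction prediction: tanh over
the drug pair only).  A shared two-layer head scores every view; the
interaction task scores views bilinearly against a transformed type
embedding.

**Aggregator.**  The up-to-64 view predictions are placed on a canonical
$8 \times 8$ grid, the top-$k$ (default 8) are kept and the rest zeroed —
the noisy-label step — and the output is an affine read-out plus a
shortcut: $\hat y^\star = \omega^\top \mathrm{masked} +
\frac{1}{k}\sum(\mathrm{top\text{-}}k)$.  The affine weights start at
zero, so an untrained aggregator is exactly the mean of the top-$k$.
Classification outputs are clamped to $[10^{-7}, 1-10^{-7}]$ because the
affine term can leave the unit interval.  When fewer than $k$ views
exist, the effective $k$ is the view count.  Ties in the top-$k$ break
toward the earlier canonical slot, for bit-reproducibility.

The printed aggregator equation is ambiguous about whether the shortcut
divides the sum of the *retained* or of *all* predictions by $k$; the
retained reading (mean of the top-$k$) is the default and the other is
available as `shortcut = "all_mean"`.

## Training objective

The loss is
$L = L_{\mathrm{SL}} + \lambda_{\mathrm{InfoNCE}} L_{\mathrm{InfoNCE}} +
\lambda_{\mathrm{MSE}} L_{\mathrm{MSE}}$, with

* $L_{\mathrm{SL}}$: cross-entropy on the aggregated prediction plus
  $\lambda_{\mathrm{aux}}$ times cross-entropy on the views of $r = 2$
  modality pairs sampled uniformly per batch from the full 64-slot grid
  (squared error replaces cross-entropy for the xenograft regression).
* $L_{\mathrm{InfoNCE}}$: cosine-similarity InfoNCE (temperature 1)
  matching each triplet's first sampled view embedding to its own second
  sampled view against the batch.  Because cosine scores are bounded by
  1, this loss cannot reach 0; its floor for orthogonal matched views is
  $\log(1 + (N-1)/e)$.
* $L_{\mathrm{MSE}}$: squared difference between each sampled view's
  prediction and the aggregated prediction, the latter treated as a
  *detached* soft label so gradients only adjust the noisy per-view
  predictions toward the refined one.  The printed equation carries a
  stray minus sign and no square; it is implemented as the positive sum
  of squared residuals its name and role dictate.

Batch losses are per-sample means (comparable across batch sizes); the
printed sums correspond to a constant rescaling of the $\lambda$s.  The
same sampled pair set $M^*$ serves the auxiliary and both consistency
terms within a batch, and is re-sampled per batch so all 64 slots are
covered stochastically over training.

Optimization is Adam with linear warmup and polynomial decay (power 1 by
default).  With a validation table, the parameters with the best
validation balanced accuracy (classification) or squared error
(regression) are kept — best-validation checkpointing, the only form of
early stopping used.  Everything is driven by one integer seed; two runs
with identical configurations produce identical loss histories.

All gradients come from a small reverse-mode autodiff tape implemented in
the package (`R/adtape.R`); the test suite checks it — and the full
composed model — against central finite differences (the probe freezes
the detached soft label, since that gradient path is deliberately
absent).

## Defaults and units

| parameter | default | meaning |
|---|---|---|
| `dhid` | 512 | shared embedding width (even, for sin/cos time pairs) |
| `smiles_layers`/`smiles_dim` | 6 / 512 | transformer depth / width |
| `graph_layers`/`graph_dim` | 6 / 384 | message-passing depth / width |
| `top_k` | 8 | retained views in the aggregator |
| `r` | 2 | sampled modality pairs per batch |
| `lambda_aux`, `lambda_infonce`, `lambda_mse` | 0.01 | loss weights |
| `batch_size` | 128 | triplets per step |
| `warmup_steps`, `poly_power` | schedule | linear warmup, then decay |
| `expr_threshold` | 400 TPM | context over-expression cutoff |
| `k_g` | 5 | PPI neighbors per target gene (no stated reference value; ranked by edge weight, ties by gene id) |
| `rwr_alpha`, `rwr_tol`, `rwr_max_iter` | 0.5 / 1e-6 / 100 | network-diffusion defaults |
| `dropout` | 0.1 | train-mode dropout |
| `clip_norm` | 1.0 | global gradient-norm clip (0 disables) |
| `lr` | 1e-4 | Adam rate (grid-search helper range 1e-5..5e-4) |

## Numerical choices

* **RWR convention.**  The restart recurrence is propagated with the
  *column-stochastic* operator (the transpose of the row-stochastic walk
  matrix), which is the only reading under which every profile remains a
  probability vector — an invariant the test suite asserts at every
  iteration.  Isolated nodes restart onto themselves.  SVD signs are
  fixed by making each right singular vector's largest-magnitude entry
  positive.
* **Twin nodes.**  Structural twins (same neighbors) have RWR profiles
  that are coordinate *swaps* of each other — the self-visit entry always
  differs — so their embeddings agree in norm and in distance to every
  other node, not entrywise.
* **Decision threshold.**  A probability of exactly 0.5 maps to the
  positive class (`>=`).
* **Over-expression boundary.**  TPM exactly at the threshold counts as
  over-expressed (`>=`); an empty over-expressed set yields a zero
  context vector with a loud warning rather than an error, since
  legitimate inputs can sit entirely below 400 TPM.
* **Quantiles.**  The patient-stratification rule reads "higher than 70%
  of patients" as above the cohort's 70th percentile and "lower than 70%"
  as below the 30th, with linear-interpolation quantiles and strict
  inequalities at the boundary.
* **AUPRC** uses step-wise interpolation (equal to average precision),
  not linear interpolation.
* **Fisher's exact test** defaults to one-sided enrichment (the
  class-network procedure looks for over-represented types); two-sided by
  the point-probability rule is a flag.  Degenerate margins give p = 1
  with a warning.  The test itself is delegated to `stats::fisher.test`
  and cross-checked against full hypergeometric enumeration in the
  suite.
* **Truncation.**  SMILES token sequences beyond `max_smiles_len` are
  truncated with a warning, keeping the trailing `[CLS]`.
* **Gradient clipping.**  The transformer blocks carry no layer
  normalization at these depths, so gradients are clipped to a global
  norm of 1 by default; without it, occasional batches at aggressive
  learning rates can diverge.
* **Batched encoders.**  The per-batch forward concatenates all drugs'
  token sequences (block-diagonal attention masks) and atom graphs
  (block-diagonal message operator, per-block pooling); this is
  numerically identical to encoding each drug separately, and the test
  suite asserts the equality.

## The synthetic fixtures, and what they do (not) show

Every input has a deterministic generator (`gen_fixture_bundle()`): drugs
with valence-safe SMILES from a tiny closed grammar and per-modality
payloads dropped i.i.d. (SMILES never missing; graphs derive from
SMILES), a preferential-attachment PPI, a random ontology tree, directed
SDL pairs, per-context expression with a boosted over-expressed subset,
and exponential-growth xenograft trajectories with lognormal measurement
noise.  Defaults: 12 drugs, 6 contexts, 30 genes, 5% label noise, 30% of
genes boosted per context, missingness 10–30% depending on modality.

Labels follow a planted two-modality rule — synergy iff drug A's *latent*
sensitivity profile has an above-median mean AND drug B targets a gene
over-expressed in the context — then flip at the noise rate.  The rule is
a function of latent payloads, so modality dropping acts as feature
noise, and it deliberately spans two modalities on *opposite* sides of
the pair so no single modality suffices and the fused model has something
real to gain.

What passing recovery tests shows: the full pipeline — encoders, view
augmentation, top-k aggregation, consistency training — can extract a
cross-modality interaction rule from realistic missingness at desk scale,
and collapses to chance under label shuffling.  What it does not show:
anything about real pharmacology.  The grammar molecules are trivial, the
gene vocabulary is tiny (so PPI expansion overlaps far more than in a
real interactome), and the planted rule is far cleaner than biological
synergy.

One desk-scale artifact deserves emphasis.  With only a dozen drugs,
*any* modality that distinguishes the drugs lets a model memorize the
planted rule through drug identity — the rule factorizes over (drug A,
drug B, context) — so a separately trained single-modality model is not
reliably worse than the fused one here; measured on a drug-holdout
protocol the single-modality models even generalize slightly better
(fusion pays an optimization cost across 64 heterogeneous view types
that the small fixture cannot repay).  The corresponding ablation check
in the acceptance suite therefore fails by design honesty rather than
by defect: demonstrating the complementarity advantage of fusion needs
a drug vocabulary large enough to defeat identity memorization, which
is outside the desk-scale budget.  The fused-versus-shuffled contrast,
not the fused-versus-ablation contrast, is the informative desk-scale
result.

## Problem sizes used by the test suite

The recovery suite runs the full pipeline at `dhid = 16` (1-layer
encoders of width 16), batch 32, a few hundred optimization steps with
best-validation checkpointing, on the default 12-drug x 6-context
fixture (~790 labeled triplets, 60/20/20 split).  These sizes are the
package's reference desk-scale configuration: large enough for the
planted rule to be recoverable, small enough that the whole suite runs
on one CPU.  Property suites (top-k oracles, Fisher enumeration, metric
cross-checks) use hundreds of random instances at margins/sizes where
exhaustive enumeration is exact.

## Known limitations

* The SMILES grammar and parser cover the organic subset used by the
  fixtures; exotic real-world SMILES should be converted upstream by a
  chemistry toolkit and supplied as graphs or precomputed embeddings.
* Text and 3D modalities are pluggable embeddings; the package does not
  run language models or conformer generation.
* The three-drug extension averages pairwise predictions; it inherits
  whatever biases the pair model has.
* Survival analysis on patient strata is out of scope: the package
  exports activation labels for standard survival tooling.
* At desk scale the aggregated probabilities are imperfectly calibrated
  around the 0.5 decision boundary; ranking metrics (AUPRC) are the more
  stable readout on small fixtures.
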