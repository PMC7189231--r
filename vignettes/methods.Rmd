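---
title: "Modelling coded EHR histories with a bidirectional attention encoder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling coded EHR histories with a bidirectional attention encoder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The modelling problem

A primary-care record is a sequence of visits; each visit contributes a
*set* of diagnosis codes at a known patient age. Given the history up to
some visit, we want calibrated probabilities for which of the `G` diseases
in the vocabulary will appear next — in the next visit (task T1) or within
the next 6 or 12 months (T2, T3). Two features distinguish this from
ordinary sequence modelling: codes within a visit are unordered, and the
clinically meaningful clock is patient age, not sequence position.

`ehrformer` models this with a bidirectional self-attention encoder over a
tokenized history

```
CLS  d11 d12 ... SEP  d21 ... SEP  ...  PAD ...
```

where every token's input embedding is the **sum of four channels**:

* **disease** — a learned embedding of the code (or `CLS`/`SEP`/`MASK`);
* **age** — a learned embedding of the patient's completed years of age at
  the visit (one id per year, 0–110, plus a catch-all);
* **segment** — a learned two-row embedding alternating A/B between
  consecutive visits, marking visit boundaries;
* **position** — a *fixed* sinusoidal table indexed by the visit ordinal.

All tokens of a visit (codes and the trailing `SEP`) share the same age,
segment and position id, and `CLS` takes the first visit's age with
segment 0 and position 0. Because the only thing distinguishing two codes
of one visit is the disease channel itself, the encoder output is exactly
permutation-equivariant within a visit — the intra-visit order-invariance
the architecture is designed for, and a property the test suite checks both
at initialization and after training.

The position table is deliberately not trainable: with highly skewed
history-length distributions a learned positional embedding receives very
uneven updates, so a pre-determined encoding is used instead. Entry
$(p, 2i)$ is $\sin(p/10000^{2i/H})$ and $(p, 2i+1)$ the matching cosine.

## Pretraining: masked diagnosis modelling

Pretraining corrupts disease tokens independently: a token is kept with
probability 0.865, replaced by `MASK` with 0.12, and replaced by a
uniformly drawn disease code with 0.015 (the random redraw may repeat the
original). Only corrupted positions carry labels and loss — the flat
86.5/12/1.5 split already sums to one, so there is no separate
"selected-but-kept, still predicted" category. The loss is mean softmax
cross-entropy over the vocabulary at labelled positions.

The pretraining metric is a precision score at threshold 0.5: each
vocabulary entry's score passes through an elementwise sigmoid; entries
above 0.5 are predicted positives, a true positive is a predicted positive
equal to the label, and precision is computed per patient over all its
labelled positions, then averaged over patients (patients with no
predicted positives are skipped; with no labelled positions at all the
metric is undefined and returned as `NA`). The exact functional form of
this score is a declared convention of this package: per-class sigmoid is
the only reading under which a fixed 0.5 threshold is meaningful, and
per-patient averaging follows the evaluation style used everywhere else.

## Fine-tuning and evaluation

For supervised prediction, the encoder output is pooled into one patient
vector, passed through a dense + tanh layer and a single feed-forward
classifier with per-disease sigmoids. Two pooling modes are provided:
CLS (first-token) pooling, the convention of the BERT lineage, and mean
pooling over the real tokens' hidden states — the default. The choice is
empirical: at desk scale (hidden size 32, a few thousand optimizer
steps) the patient-specific part of the CLS state is a small perturbation
on a shared residual direction, and fine-tuning reliably stalls in the
constant-prevalence solution, while mean pooling exposes patient
information at full scale from the first step; at the original
hundreds-of-dimensions, hundreds-of-thousands-of-steps scale CLS pooling
is known to work, so `pooling = "cls"` remains available. Training
minimizes mean per-disease binary cross-entropy against the multi-hot
label; encoder weights carry over from pretraining and the head is
freshly initialized.

Task examples are built one per patient. For T1 a split index `j` is drawn
uniformly with `3 < j < n_p`; visits `1..j` are the input and the distinct
codes of visit `j+1` the label. For T2/T3 a patient is eligible only when
observation continues at least the horizon past visit 4; `j` is drawn
uniformly over `3 < j <= n*` where `n*` is the last index still followed by
a full horizon (we read the upper bound as inclusive of `n*`), and the
label collects codes of visits in `(age_j, age_j + horizon]` months.
Examples whose label would be empty are excluded. Visit timing is carried
as integer months of age; the age *embedding* uses completed years. Months
are the coarsest unit at which a 6-month window is non-degenerate, and the
year-level embedding keeps the age vocabulary small.

Evaluation computes the average precision score (APS) and AUROC per
patient against that patient's multi-hot label, then averages across
patients. AUROC uses the rank form with 0.5 credit per tied pair; patients
whose AUROC is undefined (no negative class) are excluded and counted
rather than imputed. The disease-wise view computes the same metrics per
disease column across patients, restricted to diseases with label
prevalence of at least 1% of the evaluated examples — the floor is applied
to the evaluation example set, the most direct reading of "prevalence in
the data at hand". First-incidence evaluation restricts each label to codes
absent from the input history and drops patients with nothing left.

## The synthetic cohort

Real primary-care corpora are access-restricted, so the package ships a
seeded generator whose defaults define the study conditions used
throughout the tests: 2,000 patients, 60 codes in 6 groups of 10, visits
uniform 5–12 per patient (everyone passes the ≥5-visit inclusion filter by
construction), 1–4 distinct codes per visit, start age N(45, 15²) years,
positive inter-visit gaps N(6, 4²) months rounded and clamped to ≥1, and
18 months of follow-up past the last visit.

Structure is planted so that every downstream claim is testable:

* **groups** — each visit has a latent active group evolving as a
  first-order Markov chain (self-transition 0.7); codes are drawn with
  weight 12 for the active group versus 1 elsewhere. Sequential group
  persistence is what gives masked-token prediction and next-visit
  prediction their signal.
* **age structure** — when the chain re-draws, group weights follow a
  Gaussian kernel (bandwidth 15 years) around group-specific preferred
  ages spread over 25–85, so the age channel carries predictive
  information.
* **latent attribute** — a binary gender-analog per patient; 20% of codes
  are exclusive to one level and are never emitted for the other. This is
  what the attribute-consistency audit measures: a model that infers the
  attribute from history should assign lower probability to disallowed
  codes without ever being told the attribute.

What the generator does *not* emulate: real nosology and code frequencies
(prevalences here are roughly balanced), calendar-time effects,
mortality/censoring, inter-patient correlation, or measurement noise in
coding. Passing tests therefore demonstrate that the implementation
recovers planted structure of these kinds at desk scale — not that the
model reaches any particular accuracy on clinical data.

## Numerical and training choices

The network is plain dense linear algebra (the training loop, attention,
layer normalization and AdamW are implemented in vectorized R; analytic
gradients are verified against central finite differences at tolerance
1e-4 in the test suite). Choices a maintainer should know:

* GELU in the tanh approximation; layer-norm epsilon 1e-12; residual
  connections around both sub-layers; attention scores scaled by
  `1/sqrt(d_head)`; padded keys masked with a −1e30 additive mask, so
  attention rows over real tokens sum to one exactly.
* Initialization is Glorot-scaled: dense weights N(0, 2/(fan_in +
  fan_out)), embedding tables N(0, 1/hidden); biases and layer-norm
  offsets at identity. A fixed small standard deviation (the BERT-lineage
  0.02, tuned for hidden sizes in the hundreds) starves a hidden-32 model:
  sub-layer outputs and the classifier head are then so small relative to
  the unit-scale residual stream and positional encodings that desk-scale
  training never escapes the constant-prediction solution. Dimension-aware
  scaling removes that pathology without touching the architecture.
* AdamW (β₁ 0.9, β₂ 0.999, ε 1e-8) with decoupled weight decay 0.01 on
  matrix-shaped parameters only, linear warmup over the first 10% of steps
  then linear decay to zero.
* Dropout (default 0.1) on the summed embedding and each sub-layer output
  during training only; the desk-scale experiments in the tests disable it
  where exact invariances are asserted.
* Default desk-scale architecture: 2 layers, 2 heads, hidden 32,
  intermediate 64, `max_len` 256 tokens (truncation drops whole oldest
  visits, never splitting a visit — recent history is the
  prediction-relevant context; the source architecture's 6/12/288/512
  configuration is available via `ehrt_config()` but not exercised by the
  tests).
* Training defaults used by the test-suite experiments: batch size 32,
  peak learning rate 2e-3 for pretraining (50 epochs) and 5e-3 for
  fine-tuning (40 epochs), chosen by a coarse sweep of ordinary training
  configurations on a held-out synthetic corpus — no Bayesian
  hyperparameter optimizer is included. The fine-tuning length matters qualitatively, not just
  quantitatively: the first epochs fit the per-disease bias (prevalence)
  solution, and escaping it toward history-dependent predictions takes a
  further one-to-two thousand optimizer steps at this scale; schedules cut
  short at 15-20 epochs regularly end inside the plateau. For the same
  reason the benefit of starting from a pretrained checkpoint is invisible
  in the first few epochs (both initializations sit on the plateau) and is
  assessed at the end of the schedule.
* The masking-distribution and corruption checks aggregate several
  independent corruption rounds of the default corpus so that at least
  10⁵ eligible disease tokens enter the binomial test; corruption is
  resampled every epoch during training anyway.

Ablation arms (`ablation_suite()`) train every channel subset from the
same random initialization with identical data and seeds, rather than
pretraining each arm separately: at desk scale this isolates the
contribution of the input channels from pretraining variance, and a
deactivated channel is *exactly* absent (its lookup contributes zero), so
arm invariance to that channel's ids is a structural guarantee, not an
approximation.

## Interpretability surfaces

`attention_map()` exports the chosen layer's attention (last by default,
where the most task-specific associations live), averaged over heads —
the mean of row-stochastic matrices is row-stochastic, so rows remain
normalized. The map is read as non-directional association strength; raw
row-stochastic values are stored without further intensity normalization.
`nearest_diseases()` ranks codes by cosine similarity of their learned
embeddings (ties broken by vocabulary order), and
`embedding_group_separation()` summarizes recovery of the planted groups
as mean within-group minus between-group cosine. Two-dimensional
projections (t-SNE and friends) are deliberately out of scope: embeddings
are exported as TSV for any external projector.

## Known limitations

* Desk-scale only: the full-size architecture trains in principle but the
  pure-R training loop is not engineered for millions of patients.
* The MLM precision score is a declared convention (see above); absolute
  values are not comparable across implementations that read the metric
  differently.
* The generator's balanced prevalences make the 1% disease-wise floor
  nearly vacuous on default settings; it matters for skewed corpora.
* Softmax-trained MLM logits are shift-invariant, so the sigmoid-at-0.5
  precision depends on the centring induced by weight decay; it is a
  useful relative signal, not an absolute calibration statement.
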