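---
title: "Class-contrastive explanations: models, procedure and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Class-contrastive explanations: models, procedure and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(classcontrast)
```

This vignette is the package's account of its methods: the data model, the
predictive models and their losses, the class-contrastive procedure, the
case-ablation procedure, what the synthetic simulator does and does not
emulate, and the numerical and design choices that were genuinely open.

## Data model

A cohort is a tibble with a `patient_id`, one 0/1 column per binary
clinical feature (diagnosis categories, medication categories, social and
personal risk factors), at most one continuous age column, and a binary
outcome: death at any point during the observation window, not within a
fixed horizon. A `feature_schema()` carries each column's role and a
display label used in narratives and plots.

Three loading rules are deliberate:

* **Age is min-max scaled to [0, 1].** "Feature scaling" admits several
  readings; min-max is the simplest, and a bounded input is required by the
  autoencoder's reconstruction losses. The scaler is fitted on the training
  data only — fitting on the full cohort before splitting would leak the
  test ages' range — and held-out ages outside the training bounds are
  clipped to [0, 1].
* **Binary features are stored as single 0/1 columns**, not as two one-hot
  indicator columns. For every downstream computation (logistic terms,
  reconstruction, perturbation) the two encodings are equivalent, and the
  single column halves the dimensionality; genuine multi-level categoricals
  go through `one_hot_encode()` and get one column per level.
* **Missing values are rejected, never imputed.** An imputed value would
  silently change what a contrast over that patient means.

## Predictive models

All models implement one contract — `fit` on a training cohort,
`predict_probability()` into [0, 1] — so the explanation machinery never
needs to know which model it is interrogating.

**Logistic regression.** `fit_logistic()` with `lambda = 0` is the
unpenalised maximum-likelihood fit via `stats::glm`, reported as an odds
table: per-term log-odds coefficient, odds ratio $e^{\hat\beta}$, Wald 95%
interval $e^{\hat\beta \pm 1.96\,\mathrm{se}}$ and p-value. Interaction
terms are product columns of named binary features. Separation or
non-convergence is recorded on the model object *and* re-raised as a
warning — a silently saturated fit would corrupt every downstream contrast.
With `lambda > 0` the model is the L1 (lasso) logistic fit via glmnet,
minimising the penalised negative log-likelihood
$-\sum_i \log P(y_i \mid x_i, \theta) + \lambda \lVert\theta\rVert_1$.
Features are already on comparable scales (0/1 indicators and age in
[0, 1]), so glmnet's internal standardisation is disabled.

**Penalty selection.** `select_lambda()` scores a grid by mean 10-fold
cross-validated negative log-likelihood and returns the minimiser, breaking
ties toward the larger penalty (prefer the simpler model when the data
cannot distinguish). The default grid is logarithmic, $10^{-4}$ to $10$,
7 points — wide enough to show both under- and over-regularisation on
cohorts of a few thousand patients. In the repeated-split evaluation the
penalty is chosen by cross-validation on the *validation* quarter and the
final model refitted on the training half, with metrics on the untouched
test quarter; selecting on folds of the training half is a defensible
alternative, but the three-way split makes the roles explicit and was the
protocol adopted here.

**Autoencoder + random forest.** The machine-learning model compresses the
feature vector through a single hidden layer of $v = 10$ ReLU neurons
($f(x) = \max(0, x)$) and reconstructs the $m$ inputs through a sigmoid
output layer; the hidden representation then feeds a random forest
classifier, and prediction is the forest's class-1 probability on encoded
rows. Defaults: Xavier (Glorot uniform) initialisation, full-batch
Adadelta ($\rho = 0.95$, $\varepsilon = 10^{-6}$), 1000 training epochs,
hidden width strictly below the input width. Two reconstruction losses are
available:

* `loss = "kl"` (default): a Kullback–Leibler divergence
  $\sum_k u'_k \log(u'_k / v'_k)$ between the per-row-normalised input
  $u'$ and the similarly normalised sigmoid reconstruction $v'$, with an
  $\epsilon = 10^{-7}$ floor inside the normalisations and logarithms. KL
  is defined between distributions, so row-normalisation is the natural
  way to apply it to a 0/1 feature vector; the floor keeps all-zero rows
  and saturated sigmoids finite.
* `loss = "cross_entropy"`: element-wise Bernoulli cross-entropy
  $-\sum_k [u_k \log v_k + (1 - u_k) \log(1 - v_k)]$, treating each
  feature as an independent Bernoulli.

Either loss may carry an L1 penalty $\lambda(\lVert W_1\rVert_1 +
\lVert W_2\rVert_1)$ on the weight matrices (biases unpenalised). The
backward pass is exact (the test suite checks every gradient block against
central finite differences at $10^{-5}$ tolerance), training aborts loudly
on a non-finite loss, and the per-epoch penalised loss trace is retained on
the fitted object. The forest uses library-conventional defaults — 500
trees, $\lfloor\sqrt{q}\rfloor$ candidate features per split — under a
seed distinct from the encoder's.

**Baselines.** A random forest on the raw features; PCA fitted on the
training data only, keeping the foremost 10 components, feeding either a
forest or a logistic model; and the L1 logistic model above.

**Evaluation.** `evaluate_auc()` repeats: fresh 50–25–25 split, fit (with
any penalty chosen on the validation part), AUC on the test part. The
summary interval is the 2.5/97.5 percentile of the repeat AUCs —
distribution-free and matching the repeated-split protocol; a normal
approximation over 10 repeats would be harder to defend. A repeat whose
test part has a single outcome class is re-drawn under a new derived seed
and counted in the report.

## The class-contrastive procedure

For a feature set $S$ of size 1–3 and each held-out patient,
`contrast_set()` copies the row, forces every feature in $S$ to 1, asks the
model for a death probability, forces them all to 0, asks again, and
reports the difference. One semantics covers all orders because both arms
overwrite $S$ completely: the patient's own values of those features never
enter, and everything else — age included — is identical in both arms, so
age's contribution cancels from the *difference* while remaining in each
absolute prediction. Continuous features cannot be contrasted (there is no
canonical "on" value); requesting age is an error.

`contrast_matrix()` enumerates all $\binom{k}{\text{order}}$ combinations
(or a requested subset) in lexicographic order and attaches to each column
the support of its all-ones pattern in the training and test cohorts. The
combinatorial growth at order 3 is handled by the subset parameter and a
hard cap (default 5000 columns) that errors rather than truncating: a
silently truncated heatmap would misrepresent the combination space.

Heatmaps cluster rows (patients) and columns (combinations) with Euclidean
distance and complete linkage on the raw $\Delta p$ values — no
pre-scaling, since all cells are already probability changes on one scale.
Row clustering is what groups patients with similar explanation profiles;
column clustering is also on by default (combinations with similar effect
patterns end up adjacent), and both are toggleable. The diverging colour
scale is symmetric about zero with limits $\pm\max|\Delta p|$, so colour
sign is always faithful. Forest plots draw each term's odds ratio with its
95% interval on a log axis, filled markers for $p < 0.05$, a reference
line at 1, and non-finite bounds (separation) drawn without whiskers plus
a logged message.

## Case ablation

`ablate_and_refit()` implements the data-centric explanation: find every
case matching a feature pattern *and* an outcome value, remove them, refit,
and report paired odds tables with per-term deltas and sign changes. The
refit defaults to unpenalised logistic regression — the only model kind
with exact per-term inference — though any builder can be substituted. The
input cohort is never mutated: the procedure's whole point is comparing two
fits over one data lineage. Removal operates on the cohort handed in,
before any re-splitting; to ablate only a training split, pass that split.

`ablation_demo_cohort()` packages the canonical scenario: a base cohort
where `prior_suicide_attempt` truly increases death odds (log-odds +1.0)
and never co-occurs with `SGA`, plus 539 appended alive patients carrying
both. On the combined 1706, the fitted coefficient of the risk factor is
negative — the co-occurrence excess teaches the model that the feature is
protective — and ablating the matched stratum (exactly 539 rows, leaving
1167) restores the positive sign. The appended stratum is exact rows, not
reweighted probabilities, precisely so that these counts are exact.

## Narratives and the zero-support caveat

Narrative direction ("higher"/"lower probability of death") follows the
sign of $\Delta p$, not the absolute predicted risk: the statement
describes the contrastive change, and absolute-risk phrasing would require
a calibration the method does not provide. The similar-patient count
matches the all-ones pattern in the reference cohort regardless of outcome,
excludes the index patient, and appends the outcome breakdown ("of whom
$d$ have died") — whether "similar patients" should condition on outcome is
ambiguous, so both numbers are reported. Changes below a reporting
threshold (default $|\Delta p| < 0.05$) are not narrated unless forced; a
forced zero change gets neutral wording with no direction claim. Ties in
`top_narratives()` break lexicographically by (patient id, column label),
making rendered output byte-identical across runs.

A combination whose all-ones pattern occurs in **no training and no test
patient** is flagged, and its narrative carries an explicit caveat that the
model may have picked up a spurious pattern. This is a headline output of
the method, not a diagnostic: the most striking contrastive stories are
often exactly the unsupported ones.

## The synthetic simulator

`simulate_cohort()` draws independent Bernoulli features, uniform ages
(entering the outcome model scaled), and a logistic outcome
$y \sim \mathrm{Bernoulli}(\sigma(\beta_0 + \beta^\top x +
\beta_{\text{age}} a + \sum_j \gamma_j \prod_{f \in I_j} x_f))$. Planted
strata are appended as exact rows; zero-support patterns are enforced by
redrawing violating rows, with a bounded number of passes and an error when
a pattern is (near-)unavoidable or forced by a planted stratum. A manifest
echoes the configuration and the realized prevalences, outcome rate and
per-pattern support counts, so recovery tests have ground truth.

The default configuration emulates the shape of a secondary-care severe
mental illness cohort: 1706 patients; 24 binary bio-social features named
after medication categories (SGA, FGA, antidepressants, diuretics, ...),
co-morbidities (diabetes, cardiovascular and respiratory disease, dementia,
delirium, ...) and social/personal factors (self-harm, prior suicide
attempt, lack of family support, ...); prevalences spread over 0.02–0.5 so
that rare combinations and near-empty cells occur; age 18–95 with a
positive effect on death. Real prevalences and effect sizes for such
cohorts are not public, so these values are illustrative and fixed once.

What the simulator does **not** emulate: correlated feature co-occurrence
(features are independent unless planted), ICD-coding artefacts and
under-coding, time-to-event structure and censoring, and measurement error
in NLP-derived medication flags. Tests passing on these cohorts therefore
demonstrate that the machinery is correct and that the procedures recover
planted structure — not that any particular clinical association is real.

## Reproducibility and numerical choices

* One master seed per run; each stage (simulate, split, model, forest,
  ...) draws from a named derived stream (`derive_seed()`), so changing
  one stage's randomness never shifts another's. Repeating a run with the
  same configuration reproduces contrast matrices and narrative text
  byte-for-byte (svg figures are content-identical; the svg device
  numbers its internal element ids globally, so byte equality is only
  guaranteed for the tabular and JSON artifacts).
* Cohort CSVs write the scaled age with `%.17g` and are re-read with the
  exact base-R parser, making load → write → load a true fixed point.
* Autoencoder: $\epsilon = 10^{-7}$ inside logs and normalisations;
  Adadelta $\rho = 0.95$, $\varepsilon = 10^{-6}$; Glorot uniform limits
  $\pm\sqrt{6/(\text{fan}_{in} + \text{fan}_{out})}$.
* Degenerate inputs fail loudly: constant age vectors, non-0/1 codes,
  duplicate ids, single-class outcomes after ablation, hidden layers as
  wide as the input, non-finite training loss.

The test suite runs the multi-seed checks at reduced but stated sizes,
chosen as the smallest cohorts at which the effects are comfortably
resolvable: coverage and interaction checks on 20 cohorts of 4000,
ablation sign-flips on 20 cohorts of 1706, autoencoder separability on 10
cohorts of 2000 with training shortened to 200 epochs (the loss curve is
flat well before that on 11-feature inputs), and the end-to-end
determinism check on cohorts of 900.

## Known limitations

Contrasts are associations of the *fitted model*, not causal effects of
treatment or diagnosis; narratives are hypothesis generators, not decision
support. Forcing a feature combination the model never saw realised
produces exactly the spurious stories the zero-support flag exists to
catch, but low-support (nonzero) combinations remain quietly unreliable —
the support counts attached to every column are the reader's guide. No
multiplicity correction is applied across the thousands of implicit
comparisons a full order-3 matrix performs. And the odds tables accompany
only logistic refits; for forest-based models the contrast matrix itself
is the only explanation surface.
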