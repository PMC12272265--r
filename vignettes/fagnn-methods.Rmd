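---
title: "Quadrant-attention brain-age modeling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quadrant-attention brain-age modeling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Brain age is the age implied by a subject's brain data; the *brain age
delta* (predicted minus chronological age, in days) is a compact marker of
accelerated or delayed aging.  This package estimates brain age in aging
mouse cohorts from three data streams per animal: a structural connectome
(an $n \times n$ matrix of streamline-count-derived connection weights
between brain regions, left-hemisphere regions listed first), a small
vector of risk-factor traits (sex, diet, APOE genotype, NOS2 variant), and
a Morris Water Maze behavior matrix (trials $\times$ metrics).  The model
is a fused network: a quadrant attention module (QAM) scores every
region-pair connection, a graph convolutional network (GNN) with top-K
pooling processes the score-weighted connectome, 1D and 2D CNNs embed
traits and behavior, and a small MLP regresses the concatenated embeddings
onto age with a mean-squared-error loss.

## Normalization

Everything entering the network lies in $[0, 1]$:

* **Connectomes** are dense-rank normalized: equal weights share a rank,
  the minimum maps to rank 0, and ranks are divided by the maximum rank.
  Absent connections (weight 0) therefore score 0, and the transform is
  invariant to any strictly monotone rescaling of the raw weights.
* **Traits**: binary traits map to $\{0, 1\}$; APOE alleles 2/3/4 map to
  $\{0, 0.5, 1\}$.
* **Behavior**: time-based metrics are divided by the 60 s trial cap;
  other metrics by their cohort-wide column maxima (cohort-wide, so
  subjects remain comparable).

The regression *target* (age in days) is standardized inside
`train_model()` and de-standardized at prediction time; the scalers travel
with the model.  Adam steps move parameters by at most the learning rate
per step, so a raw target on the scale of hundreds of days is unreachable
within 100 epochs at the protocol's learning rates; standardizing the
target is the conventional remedy and keeps all reported errors in days.

## The quadrant attention module

The connectome is split at the hemisphere boundary into four blocks
$X_{LL}, X_{LR}, X_{RL}, X_{RR}$ (each $(n/2) \times (n/2)$).  Each block
is scored by its own multihead scaled dot-product attention,

$$\mathrm{head}_j = \mathrm{softmax}\!\left(\frac{(XW^Q_j)(XW^K_j)^\top}{\sqrt{d_k}}\right) XW^V_j,
\qquad \mathrm{MHA}(X) = \mathrm{Concat}(\mathrm{head}_1,\dots,\mathrm{head}_h)\,W^O,$$

and the four score blocks reassemble into the $n \times n$ edge-score
matrix $S$ that multiplies the connectome elementwise before graph
convolution.  Defaults: $h = 4$ heads, $d_k = (n/2)/h$, independent
weights per quadrant (a sharing flag exists for ablations), no
nonlinearity on $S$ (the score equations contain none); a
`clamp_scores` option restricts $S$ to $[0,\infty)$ for interpretability
runs.  Weights initialize from a seeded uniform scaled by
$1/\sqrt{\text{fan-in}}$.

## Subnetworks and fusion

The graph update is
$$H^{(l+1)} = \mathrm{ReLU}\!\left[\left(I + H^{(l)} \odot S\,\delta_{l=1} + H^{(l)}\delta_{l>1}\right) D^{(l)} W^{(l)}\right],$$
with $H^{(0)} = X$ (node features are connectome rows).  $D^{(l)}$ is the
diagonal degree matrix of the current (score-weighted) adjacency, degrees
being row sums with isolated nodes assigned degree 1.  The update rule
multiplies by $D$ as printed, which amplifies well-connected (hub)
regions; a `degree_mode = "inverse"` option provides the GCN-style
$1/\text{degree}$ normalization instead.  Each of the two graph layers is
followed by top-K pooling (ratio 0.5) that keeps the highest-strength
nodes (row-mean scores, ties to the lowest index) and induces the
subgraph on the kept nodes.

**Readout.** The final pooled feature matrix is row-flattened into the
fusion vector.  A global-mean readout was tried first and discarded: on
simulated cohorts a linear probe of the mean readout explained $R^2
\approx 0.03$ of age against $R^2 \approx 0.40$ for the flattened matrix,
and the connectome-only ablation could not learn at all through the mean
(it collapsed to predicting the cohort mean age).  Averaging over kept
nodes destroys exactly the cell-level variation the attention gate is
supposed to exploit.

The trait vector passes through two 1D convolution layers (kernel 2;
8 then 16 channels), behavior through two 3$\times$3 2D convolution
layers (8 then 16 channels), each followed by global average pooling and
a linear map to a 32-wide embedding.  The fusion MLP is
concat $\to$ 64 $\to$ 16 $\to$ 1 with ReLU between layers.  Ablations:
`comp1` = GNN only with $S \equiv 1$; `comp2` = QAM+GNN; `comp3` adds
behavior; `comp4` adds traits; `full` = everything.

## Training protocol

Adam with per-subnetwork learning rates 0.001 (QAM), 0.001 (GNN), 0.002
(1D CNN), 0.002 (2D CNN), 0.003 (fusion block), 100 epochs.  The default
batch size is 8.  Full-batch training was tried first and discarded: at
these learning rates 100 full-batch steps leave the network badly
underfit (the connectome-only ablation stays at its initial loss), and
the reported wall-clock time per epoch is only consistent with
per-minibatch optimizer steps.  Gradients are exact — including through
the degree matrix — and are verified against central finite differences
in the test suite; the only non-differentiable points are the ReLU kinks,
the top-K selection, and the isolated-node clamp, where the standard
one-sided/zero conventions apply.

Evaluation uses repeated fivefold cross-validation: every subject is
predicted exactly once per run by the model that never trained on it;
MAE/RMSE are pooled per run and summarized with Student $t$ 95% intervals
across runs; each run draws a fresh seeded fold split.  The
group-transfer protocol trains on a reference (control) group and tests
on a risk group; $\Delta\mathrm{MAE}$ is the mean transfer MAE minus the
mean within-reference fivefold MAE.

## The synthetic world

`simulate_cohort()` emulates the structure of the reference mouse cohort:

* **N = 170** with a bimodal age distribution: 66 younger (12–15 months;
  truncated normal, mean 405 d, SD 20 d) and 104 old (15–20 months; mean
  525 d, SD 35 d), with the 15-month cutoff at 450 days (30-day months).
* **Trait margins per age cluster** follow the reference cohort (APOE
  58/56/56; 82 M / 88 F; 95 mNos2 / 75 hNOS2; 113 control / 57 high-fat
  diet).  The young-cluster mNos2 count is 28, the value consistent with
  the 95/75 NOS2 totals.
* **Effective brain age** (the latent that drives all signals) is
  chronological age plus additive trait effects — diet +40 d and hNOS2
  +40 d in the old cluster only, sex +30 d in the young cluster only,
  APOE 0 d — plus N(0, 15 d) subject noise.  The stratum-specific pattern
  gives the delta-group analyses a known directional answer.  Effect sizes of 30–40 days were chosen once as
  moderate relative to a ~45-day MAE scale; the APOE effect defaults to
  zero (APOE delta contrasts are not expected to separate).
* **Connectomes** are drawn per subject (symmetric Gamma(2, 0.2)
  weights), with one "cingulum-like" hub per hemisphere whose rows and
  columns are tripled, and `planted_edges` (default 8, mirrored across
  hemispheres) attached to the hubs whose weights decay linearly with
  effective brain age (fractional loss 0.6 across the age span) before
  N(0, 2) noise.  Per-subject draws — rather than noise around a shared
  template — give between-subject variability comparable to real
  streamline counts; a shared-template variant produced rank-normalized
  matrices so similar across animals that no network could learn from
  them.
* **Behavior** metrics are saturating monotone functions of effective
  brain age (latency-style metrics rise toward the 60 s cap) with a
  trial-level learning trend and N(0, 0.05) noise.

What a green test on this world establishes: the pipeline can extract a
planted, trait-modulated aging signal from the three data streams jointly
and reproduce the expected directional findings (full model beats the
connectome-only ablation; old-stratum diet/NOS2 delta contrasts dominate
young-stratum ones).  What it does not establish: recovery of the
reference numeric MAE/RMSE (those depend on the real 170-animal dataset),
or realism of the connectome topology beyond hub structure.

## Edge-score identifiability: a known limitation

The recovery experiment plants hub-attached, age-decaying edges and asks
whether they surface in the top decile of the cohort-mean edge-score
matrix.  In this implementation they reliably do not, and the analysis is
worth recording.  The planted cells are trivially identifiable from the
input (ranking cells by $|\mathrm{cor}(X_{ij}, \text{age})|$ recovers all
of them), and the trained model clearly uses them (the connectome-only
ablation reaches $r \approx 0.7{-}0.8$ on cohorts whose only age signal
is the planted decay).  But the score matrix $S = \mathrm{Concat}(\cdot)W^O$
assigns column $j$ a meaning only through the learned output projection
$W^O$: nothing ties output column $j$ to region $j$ except the gradient
pressure that flows through the elementwise product $X \odot S$.
Empirically that pressure is too weak at this scale: between-column
variance of the mean score matrix is dominated by initialization, and
neither clamping, minibatch size, exact degree gradients, cross-model
(fold) averaging, within-column standardization, nor the raw attention
weights raise top-decile recall much above chance.  The corresponding
acceptance criterion is deliberately left failing rather than redefining
the score matrix away from its defining equations; users who need edge
attribution should treat `top_edges()` output as hub/column-level rather
than cell-level evidence: top-connection sets in this kind of analysis
are best read as hub-convergent summaries.

## Tract statistics

The along-tract battery compares metric samples (FA, RTOP, RTAP, RTPP)
between groups with a tie-corrected Kruskal–Wallis omnibus test, Dunn's
rank-based pairwise $z$ tests, and Holm step-down adjustment of the
pairwise p-values (within tract by default; a joint option exists).
These are implemented from the rank formulas and unit-tested against
independent oracles (`stats::kruskal.test`, `stats::p.adjust`, and the
two-group closed form).  Linear mixed models for tract analysis are out
of scope.  Significance flags are reported at both 0.05 and the 0.01
convention used in along-tract figures.

## Numerical choices and degenerate inputs

* Softmax rows are computed with max-subtraction for stability.
* All-equal connectomes rank-normalize to all zeros (the maximum rank is
  zero); all-zero behavior columns are left untouched.
* Zero-variance targets set the standardization scale to 1.
* Top-K ties break toward the lowest node index; `ceiling` guarantees a
  non-empty selection.
* Zero-degree (isolated) nodes receive degree 1, so no division by zero
  occurs in either degree mode.
* Pearson $r$ is flagged undefined for zero-variance inputs rather than
  propagating `NA` silently.
* Per-run and per-fold seeds derive from the master seed through a
  fixed-integer recurrence kept below $2^{31}$.

## Known limitations

* Cell-level edge attribution is unidentified (see above).
* The criterion-8 delta contrasts are weakly powered by design: the full
  model receives the traits as inputs and can partially cancel the
  planted trait effects when predicting chronological age, shrinking the
  deltas; directionality (old-stratum contrasts dominating) is the tested
  property.
* The simulator's connectome is homogeneous apart from hubs and planted
  edges; community structure, distance dependence, and hemispheric
  asymmetries of real connectomes are not modeled.
* Training is CPU-bound C++ with exact gradients; there is no GPU path.
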