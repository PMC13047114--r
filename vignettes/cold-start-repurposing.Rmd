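---
title: "Relation-aware attention, disease-level meta-learning, and the cold-start protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relation-aware attention, disease-level meta-learning, and the cold-start protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetgnn)
```

## The problem

Predicting which existing drugs might treat a disease is naturally a link
prediction problem on a heterogeneous knowledge graph: drugs, genes,
diseases and pathways connected by typed relations such as
`drug_targets_gene`, `gene_associates_disease` or `gene_involved_in_pathway`.
The clinically interesting regime is the *cold start*: a disease with no
known treatment at all, so that nothing about its therapeutic edges can be
memorised and every prediction must come from its molecular neighbourhood —
its associated genes, their interactions, and the pathways they touch.

`hetgnn` implements an encoder-plus-meta-learning pipeline for this setting,
a strict disjoint-disease evaluation protocol, a disease-conditioned
variational autoencoder that proposes candidate drug pairs, and an
attention-weighted multi-omics fusion classifier with integrated-gradient
biomarker ranking. A seeded synthetic-graph generator with a planted,
exactly recomputable mechanism makes every stage testable offline.

## The encoder

Raw node features are heterogeneous — binary substructure fingerprints for
drugs, dense embeddings for genes, membership encodings for pathways — and
are first imputed (mask-based, feature-wise mean fallbacks), z-scored per
node type (continuous types only; binary types keep their bit semantics,
population 1/N standard deviation, constant columns map to 0), and projected
into a shared latent space by learnable type-specific affine maps
$h_i = W_t x_i + b_t$ with $d = 256$ by default.

Message passing is relation-aware. For relation $r$ and attention head $k$,
the weight that node $i$ gives neighbour $j \in N_i^r$ is

$$\alpha_{ij}^{r,k} = \mathrm{softmax}_j\,
  \mathrm{LeakyReLU}\!\left(a_{r,k}^\top
  \left[W_{r,k} h_i \,\|\, W_{r,k} h_j\right]\right),$$

with negative slope 0.2. Per-relation messages
$h_i^r = \big\Vert_k \sum_j \alpha_{ij}^{r,k} W_{r,k} h_j$ concatenate the
heads in hidden layers and average them in the final layer (keeping the
output width equal to the hidden dimension). A second attention stage fuses
across the relations actually present at the node,

$$\beta_r = \mathrm{softmax}_r\, (q^\top h_i^r), \qquad
  h_i' = \sum_r \beta_r\, h_i^r,$$

so different edge semantics are never mixed into one message stream and the
model learns which relation types matter. Three such layers are stacked with
ELU between layers and dropout 0.3 after each layer during training. A node
with no neighbour under any relation falls back to a learned
self-projection, which keeps every softmax well defined. Edges are stored as
directed triples; bidirectional flow comes from explicit inverse relations
with the reserved `_inv` suffix.

A pair $(d, s)$ is scored by the dot-product predictor
$y' = \sigma(h_d^\top h_s)$ and trained with binary cross-entropy against
known associations and sampled negatives (1:1 during training, re-sampled
every epoch; probabilities clipped at $10^{-7}$ so the loss is finite).

## Disease-as-task meta-learning

Every training disease defines a task: its 2-hop neighbourhood subgraph plus
the candidate drug pool with its 1-hop neighbourhood, and a support/query
split of its known positives (support capped at
$\min(5, \lfloor n_{\text{pos}}/2\rfloor)$, at least one pair on each side).
Crucially, the task disease's *own* therapeutic edges are hidden inside its
subgraph — the pairs being scored must not be readable as edges, exactly as
they will not be for a genuinely new disease. First-order model-agnostic
meta-learning then runs one inner gradient step per task at learning rate
0.01, evaluates the query loss at the adapted parameters, and applies the
summed query gradients (adaptation Jacobian dropped) with Adam at learning
rate 0.001. Diseases with fewer than two positives cannot form a task and
are skipped with an explicit signal. A meta-batch holds 4 tasks; one epoch
makes three shuffled passes over the training diseases.

## The cold-start protocol

Diseases with at least one known treatment are split 70/15/15 into
train/validation/test by seeded shuffling with largest-remainder rounding,
so the three sets are disjoint and exhaustive. Every `treats` edge of a
validation or test disease is removed from the training graph; a hard
assertion verifies both facts before any metric is reported, and its failure
is an error, never a warning. Training runs up to 100 epochs with negatives
re-sampled each epoch; validation ROC-AUC is recorded every epoch, the
checkpoint with the highest validation ROC-AUC is restored, and test metrics
(AUPRC, ROC-AUC, mean cross-entropy, confusion counts at threshold 0.5) are
computed exactly once from that checkpoint. Because convergence typically
occurs well before the epoch budget, training also stops once 15 epochs pass
without a new validation best, but never before epoch 25; the checkpoint
rule is unaffected. Evaluation ranks the full drug pool per held-out disease
by default; a 5:1 sampled-negative mode is available behind a flag, and the
report records which mode was used. A random-edge-split control
(`run_random_split_protocol`, 80/20 over therapeutic edges with every
disease still visible in training) quantifies how much harder true cold
start is; because that control has no validation diseases, its checkpoint is
selected on the meta-training loss and the held-out edges are touched once.

ROC-AUC is computed as the tie-aware rank statistic (the probability that a
positive outscores a negative), which equals the trapezoidal curve area.
AUPRC is step-wise average precision, $\sum_k (R_k - R_{k-1}) P_k$ with tied
scores grouped; the transposed orientation that is sometimes printed for
this quantity does not define a valid precision–recall area, so the standard
form is implemented. The omics classification loss likewise uses the
standard (positive) binary cross-entropy.

## The drug-pair generator

A conditional variational autoencoder operates on encoder embeddings. The
pair representation entering the encoder is order-invariant by construction
— $[h_{d_1}\!+\!h_{d_2} \,\|\, |h_{d_1}\!-\!h_{d_2}| \,\|\, h_s]$ — so
swapping the drugs changes nothing, bit for bit. Two 128-unit ReLU layers
feed linear heads for the mean and log-variance of a 64-dimensional latent
Gaussian; the reparameterised sample $z = \mu + \sigma \odot \varepsilon$
and the disease embedding drive a mirrored decoder with two output heads,
one per drug. Training minimises reconstruction error (mean squared error on
the pair embeddings) plus the closed-form KL divergence from the standard
normal, weight 1. Synergy of a decoded pair is
$\sigma(h_{d_1}'^\top h_{d_2}')$, read as the inner product since
juxtaposition of two vectors is otherwise undefined. Generated embeddings
are mapped to the library by cosine nearest neighbour; self-pairs and
duplicate unordered pairs are dropped (keeping the highest-scoring
instance), and pairs are returned in descending synergy order. This module
is hypothesis-generating: its training pairs are drugs sharing at least one
target, conditioned on a disease associated with a shared gene, and nothing
here is benchmarked against experimental synergy measurements.

## Multi-omics fusion and biomarker ranking

Each omics modality runs through its own two-layer encoder (ReLU, then a
linear layer of width 64); per sample, modality weights are
$\mathrm{softmax}_m\!\left(u^\top \tanh(W h^m)\right)$ with attention width
32, and a linear-sigmoid classifier on the fused representation is trained
with cross-entropy. Feature importances are integrated gradients of the
predicted probability along the straight path from the per-feature mean
baseline, midpoint rule with 50 steps, averaged in absolute value over
samples and normalised to sum 1 (descending order, lexicographic
tie-break). The completeness identity — attributions summing to
$f(x) - f(\text{baseline})$ — is verified in the test suite at 200 steps.

## What the synthetic generator emulates

The generator stands in for a curated multi-database build at roughly 1/50
scale: 50 drugs, 200 genes, 10 diseases, 20 pathways by default. Drug target
sets and disease gene sets are drawn by preferential attachment over a
shared gene popularity, which produces heavy-tailed gene degrees and makes
hub genes a common cause of drug-disease overlap. A `treats` edge is planted
exactly when a drug's targets and a disease's genes share at least 2
members, after which each label independently flips with probability 0.005.
That flip rate is calibrated to the *positive class*: with ~35-45 true
associations among 500 pairs, 0.005 corresponds to spurious indications
amounting to roughly 5% of the positives — about the contamination a curated
indications table carries — while leaving the ranking ceiling of the true
mechanism near 1. The resulting indications-per-drug distribution has mode 1
with a rapidly decaying tail, mirroring the strong left skew of real
indication counts, and positive pairs share systematically more genes than
sampled negatives.

Feature matrices mirror the real initialisations in miniature: 1024-bit
drug fingerprints whose bit banks are unions over per-gene 8-bit codes (so
chemistry proxies mechanism), 128-dimensional gene embeddings smoothed over
the gene-gene network (adjacent genes more similar than random pairs),
disease vectors equal to the mean of their genes' embeddings plus noise, and
binary pathway membership encodings. Five percent of gene feature entries
are masked to exercise imputation; fingerprints, being deterministic
functions of structure, are never masked or re-scaled.

The generator deliberately omits realistic chemistry (no SMILES), ontology
structure, batch effects and longitudinal measurements. Tests that pass on
it therefore demonstrate that the implementation recovers a known relational
mechanism under controlled noise — not that the method attains any
particular accuracy on real curated databases.

## Numerical and engineering choices

Gradients come from a small reverse-mode differentiation engine written for
this package: tape nodes hold forward values and backward closures, and the
per-relation attention pipeline (projection, per-edge logits, LeakyReLU,
segment softmax, weighted aggregation) is fused into a single compiled
kernel for speed. Every operation, and the full three-layer encoder loss,
is pinned against central finite differences at tolerance 1e-7 in the test
suite, and the whole layer is additionally checked against an independent
dense re-implementation written from the definitions. All randomness flows
from explicit seeds through stage-tagged derived streams, so a single seed
determines every artifact of a run; checkpoints embed a format-version tag
and the relation vocabulary and round-trip bit-exactly.

Problem sizes used by the protocol-level tests and the acceptance script are
the package's desk-scale setting: hidden dimension 32 with 4 heads and 3
layers on the default 280-node graph (the 256-dimensional default is kept
for the encoder itself), 20 seeds for the recovery and adaptation
experiments, 6 protocol seeds plus 3 control seeds in the acceptance script.

## Known limitations

Two limitations are worth stating plainly, because both are visible in the
package's own experiments. First, at 10 diseases the validation and test
sets of the disjoint split each contain one or two diseases, so both
checkpoint selection and the test metric itself are dominated by
per-disease idiosyncrasy: across seeds we observe validation traces that
are uninformative or even anti-correlated with test performance, and
per-seed test ROC-AUC spreads from about 0.1 (a test disease whose only
positive is a label flip, which a mechanism-based model correctly ranks
last) to 0.96, around a median near 0.77. For the same reason a single
inner adaptation step — one support gradient computed from two to six
pairs — reduces the disjoint query loss on only about two-thirds to
four-fifths of tasks, depending on the seed set. Both are properties of
few-shot statistics at very small disease counts, not of the encoder; the
original protocol assumes an order of magnitude more diseases. Second, the dot-product score of summed gene
embeddings has an intrinsic ceiling: counting set overlap through inner
products requires near-orthogonal per-gene codes, and 200 genes cannot be
orthogonalised inside 128-dimensional input features, so even the ideal
linear readout of the planted mechanism ranks imperfectly. The
architecture also follows the stated design exactly — no residual
connections, no layer normalisation — which makes very deep stacks
impractical but keeps the implementation faithful.
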