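# hetgnn

Relation-aware heterogeneous graph attention networks with disease-level
meta-learning, for computational drug repurposing and biomarker discovery.

Biomedical knowledge naturally forms a heterogeneous graph — drugs, genes,
diseases and pathways joined by typed relations such as `drug_targets_gene`,
`gene_associates_disease` or `gene_involved_in_pathway` — and predicting
which drugs might treat a disease is link prediction on that graph. The hard
and clinically relevant case is the *cold start*: a disease with no known
treatment, where nothing therapeutic can be memorised and every prediction
must come from the disease's molecular neighbourhood. `hetgnn` is aimed at
researchers who want to study this setting end to end with a fully seeded,
self-contained pipeline: a typed knowledge-graph data model, a relation-aware
attention encoder, first-order meta-learning over disease-centred tasks, a
strict disjoint-disease evaluation protocol, a disease-conditioned
variational autoencoder proposing candidate drug pairs, and an
attention-weighted multi-omics fusion classifier with integrated-gradient
biomarker ranking.

## The model

Raw node features (binary fingerprints for drugs, dense embeddings for
genes, membership encodings for pathways) are imputed, z-scored per type and
projected into a shared space, $h_i = W_t x_i + b_t$. Message passing is
per-relation multi-head attention:

$$\alpha_{ij}^{r,k} = \mathrm{softmax}_{j \in N_i^r}\,
  \mathrm{LeakyReLU}\!\left(a_{r,k}^\top [W_{r,k} h_i \,\|\, W_{r,k} h_j]\right),
  \qquad
  h_i^r = \Big\Vert_{k=1}^{K} \sum_{j} \alpha_{ij}^{r,k} W_{r,k} h_j ,$$

followed by a second attention stage that fuses across the relations present
at each node, $\beta_r = \mathrm{softmax}_r(q^\top h_i^r)$,
$h_i' = \sum_r \beta_r h_i^r$. Three such layers (4 heads, dropout 0.3)
produce embeddings scored by a dot-product predictor
$y'_{d,s} = \sigma(h_d^\top h_s)$ under binary cross-entropy. Training is
first-order model-agnostic meta-learning with one disease per task: one
inner gradient step (learning rate 0.01) on the task's support pairs, Adam
outer updates (learning rate 0.001) on the summed query losses. Evaluation
follows a disjoint-disease protocol: diseases split 70/15/15, every
therapeutic edge of a held-out disease removed from training, validation
ROC-AUC recorded each epoch, test metrics computed once from the
best-validation checkpoint. Gradients come from a small built-in
reverse-mode engine with the attention pipeline as a compiled kernel; a
seeded synthetic-graph generator with a planted shared-gene mechanism makes
everything testable offline.

## A worked example

```r
library(hetgnn)

cfg <- synthetic_config(seed = 7)     # 50 drugs, 200 genes, 10 diseases
kg  <- generate_kg(cfg)
kg$graph
#> <hetero_graph> 280 nodes (disease: 10, drug: 50, gene: 200, pathway: 20),
#>                988 edges, 6 relation types

features <- generate_node_features(kg$graph, cfg)
report <- run_cold_start_protocol(
  kg$graph, features,
  model_config = list(d_hidden = 32, n_heads = 4, n_layers = 3),
  seed = 7)
report
#> <eval_report> 6/1/1 train/val/test diseases | best epoch 22 (val ROC-AUC 0.7708)
#>   test: ROC-AUC 0.9592 | AUPRC 0.3333 | loss 0.2379 | mode full
```

The report says: of the diseases with at least one known treatment, six were
used for meta-training, one for validation-based checkpoint selection and
one held out entirely; the checkpoint from epoch 22 scored ROC-AUC 0.9592
when ranking all 50 drugs against the unseen test disease. Ranking that
disease's candidates with the trained encoder places its single true
treatment third of fifty:

```r
rank_candidates("disease_07", drugs, embeddings)   # see vignette for setup
#>    drug_id rank     score
#> 1 drug_028    1 0.9258578
#> 2 drug_036    2 0.7149149
#> 3 drug_050    3 0.6865058   <- the planted true treatment
```

A command-line wrapper over the same functions lives at
`inst/cli/hetgnn.R` (`generate`, `train`, `evaluate`, `predict`, `synergy`,
`omics`).

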