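# ddiextract

Sentence-level drug–drug interaction (DDI) extraction that fuses what a
sentence *says* about two drugs with what a biomedical knowledge graph
*knows* about them.

## The problem

Pharmacovigilance corpora such as DDIExtraction 2013 (SemEval-2013 Task 9)
annotate sentences with drug mentions and label each drug pair with one of
five classes — `Mechanism`, `Effect`, `Advise`, `Int`, or `Negative`.
Text-only classifiers struggle when the sentence is ambiguous but the
biology is not: two drugs that share a metabolizing enzyme, a pathway, or a
contraindication in a knowledge graph carry signal no sentence window
contains. `ddiextract` implements a classifier for this task whose input is
both channels:

* **Text channel.** The anonymized candidate sentence (target mentions
  replaced by `DRUG1`/`DRUG2`) is word-piece tokenized and embedded by a
  pluggable contextual encoder `e^w` (a small trainable self-attention
  encoder ships for desk-scale work; a pretrained biomedical transformer
  plugs into the same contract), concatenated with learned drug-relative
  position embeddings `e^p_i = [table1(i − pos_1); table2(i − pos_2)]`.
* **Graph channel.** For the pair (u, v) with identifiers in a typed
  knowledge graph, the *k*-hop **enclosing subgraph** is the graph induced
  on `N_k(u) ∩ N_k(v) ∪ {u, v}`. Each member node i is labeled with its
  double-radius one-hots `p_i = [onehot(d(i,u)); onehot(d(i,v))]` appended
  to its embedding. An attention-gated relational message-passing network
  then computes, per edge,
  `α_ij = tanh((h_j W_J)·(h_i W_I + r_ij)ᵀ / d_0)` and prunes edges with
  `α ≤ ζ`; messages are relation-transformed with basis-decomposed weights
  `W_r = Σ_b a_rb V_b`, FiLM-gated by the target node
  (`γ_v ⊙ (h_u W_r) + β_v`), and aggregated as
  `h_v' = ReLU(W_self h_v + Σ τ_uv (…))`. Layer-aggregated endpoint states
  and mean readouts form the pair representation
  `h^dp = ⊕_t [h_u^(t); h_v^(t); mean_i(W_sub h_i^(t))]`.
* **Fusion.** Three heads combine `e^w`, `e^p`, `h^dp` into a fixed-size
  vector `H` (default: method 2 — concatenate per token, windowed
  convolution with GELU, max-pool over positions, append `h^dp`). A linear
  layer and softmax give class probabilities, trained with a **multi-class
  focal loss** `−α_y (1 − p_t)^γ log p_t` (γ = 2) with count-derived class
  weights.

Evaluation reports per-class and micro/macro precision–recall–F1 (macro F1
as the harmonic mean of macro P and macro R), plus one-vs-rest AUC and
AUPR, excluding the `Negative` class from the averaging scope by default
(the DDIExtraction convention).

Because the full benchmark requires licensed database downloads and a
pretrained transformer, the package also ships a **synthetic world
generator**: a typed drug/protein/pathway/disease graph with label-specific
planted motifs and a template corpus whose label signal can be placed in
the text, in the graph, or both — so every stage, and the subgraph-ablation
logic, is testable end to end offline.

## Worked example

```r
library(ddiextract)

# a synthetic world: 300 drug pairs, label signal in text AND graph
scfg   <- synth_config(n_instances = 300, placement = "both", noise = 0, seed = 42)
world  <- generate_synthetic_kg(scfg)
corpus <- generate_synthetic_corpus(scfg, world, dir = "demo")

# the standard preprocessing chain: parse XML -> candidate pairs ->
# negative filtering -> DrugBank-identifier mapping
candidates <- parse_semeval(corpus$xml_path) |>
  generate_candidates() |>
  filter_negatives() |>
  map_to_drugbank(corpus$mapping_path)
dplyr::count(candidates, label)
#>   label         n
#> 1 Advise       39
#> 2 Effect       50
#> 3 Int          43
#> 4 Mechanism    45
#> 5 Negative     64

cfg <- ddi_config(max_length = 40, d_p = 6, d_w = 32, graph_dim = 16,
                  hop = 2, layers = 2, hidden_dim = 16, num_bases = 4,
                  channels = 24, lr = 5e-3, batch_size = 32, epochs = 6,
                  seed = 1)
fit <- ddi_train(candidates, world$kg, cfg, verbose = TRUE)
#> epoch 1: loss 0.1690, micro-F1 0.705
#> epoch 2: loss 0.0514, micro-F1 1.000
#> ...
glance(fit)
#>   epochs final_loss train_micro_f1 train_macro_f1 n_params
#> 1      6   0.000144              1              1    23963

report <- evaluate_run(fit, candidates)
report
#> <ddi_eval> scope: positives_only
#>   micro P/R/F1: 1.0000 / 1.0000 / 1.0000
#>   macro P/R/F1: 1.0000 / 1.0000 / 1.0000
tidy(report)      # per-class precision/recall/F1/AUC/AUPR
autoplot(report)  # confusion-matrix heatmap
```

With the signal placed in both channels and zero noise the generated task
is separable, so the trained model recovers every label on the training
set — the property the end-to-end tests pin down. The micro F1 here pools
TP/FP/FN over the four positive classes; `Negative` rows count only
through the errors they absorb.

The subgraph ablation flips `use_subgraph` in `ddi_config()`: on
`graph_only` data (templates shuffled across labels) the subgraph-aware
model recovers the labels while the text-only variant cannot beat the
majority class; on `text_only` data the two variants tie.

A thin command-line front end wrapping the same functions is installed at
`inst/cli/ddiextract` (subcommands `synth`, `preprocess`, `train`,
`evaluate`, `predict`).

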