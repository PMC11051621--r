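---
title: "Knowledge-subgraph-enhanced DDI classification: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-subgraph-enhanced DDI classification: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddiextract)
```

## The task and the model

`ddiextract` classifies candidate drug pairs in biomedical sentences into
five interaction classes (`Negative`, `Mechanism`, `Effect`, `Advise`,
`Int` — this order is fixed everywhere in the package). A candidate
instance is one unordered pair of gold drug mentions in one sentence, with
the two target mentions anonymized to `DRUG1`/`DRUG2` and all other drug
mentions left verbatim; a sentence with $n$ mentions yields
$\binom{n}{2}$ candidates.

The classifier fuses two information channels.

**Text.** The anonymized sentence is segmented by greedy longest-match
word-piece tokenization (the drug placeholders are atomic tokens) and
embedded by a contextual encoder into $e^w \in \mathbb{R}^{n \times d_w}$.
Each token also receives drug-relative position embeddings
$e^p_i = [\mathrm{T}_1(i - \mathrm{pos}_1); \mathrm{T}_2(i -
\mathrm{pos}_2)]$, where the offsets are signed distances in token units
to the nearest token of each drug span (0 inside the span), clamped to
$\pm$ the maximum length. The encoder is pluggable: the shipped trainable
encoder is a one-layer self-attention + feed-forward block with learned
token and token-position embeddings ($d_w = 32$), small enough to train at
desk scale yet context-sensitive; a frozen pretrained biomedical
transformer ($d_w = 768$) satisfies the same contract through
`encoder_adapter()` and is deliberately not exercised by the test suite.

**Graph.** Drug mentions are mapped to knowledge-graph identifiers
(DrugBank-style); pairs with an unmapped drug are excluded. For a pair
$(u, v)$ the $k$-hop *enclosing subgraph* is the subgraph induced on
$\left(N_k(u) \cap N_k(v)\right) \cup \{u, v\}$, distances taken on the
undirected view of the typed graph. Every member carries a double-radius
label — the concatenated one-hots of its distances to $u$ and to $v$,
clamped to $[0, k]$ — appended to its learned embedding (xavier-uniform,
gain 2, fixed seed). The message-passing network computes, once from
layer-0 states, a per-edge signal strength

$$\alpha_{ij} = \tanh\!\big( (h^{(0)}_j W_J)\,(h^{(0)}_i W_I + r_{ij})^\top / d_0 \big),$$

prunes edges with $\alpha \le \zeta$ (the pruned weight is
$\tau = \alpha$ for survivors, 0 otherwise), and then runs $T$ layers of
relation-aware propagation: relation weights are basis combinations
$W_r = \sum_b a_{rb} V_b$, messages are FiLM-gated by an affine map of the
*target* node ($\gamma_v \odot (h_u W_r) + \beta_v$, gates per layer), and
updates are $h_v' = \mathrm{ReLU}(h_v W_{self} + \sum_u \tau_{uv}(\cdot))$.
The pair representation concatenates, over layers $t = 0..T$, the two
endpoint states and the readout $\mathrm{mean}_i(h^{(t)}_i W_{sub})$.

**Fusion and prediction.** Fusion method 2 (the default) concatenates
$[e^w, e^p]$ per token, applies a windowed convolution (window 5, zero
padding so every position yields an output) with GELU, max-pools over
positions, and appends $h^{dp}$. Method 1 first runs $e^w$ through a
BiLSTM; method 3 instead broadcasts $h^{dp}$ and the two drug positions'
embeddings to every token and takes the pooled vector itself. A linear
layer plus softmax yields probabilities, trained with the multi-class
focal loss $-\alpha_y (1 - p_t)^\gamma \log p_t$, $\gamma = 2$, averaged
over the batch.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `max_length` | 390 tokens | sequences truncated from the end farther from both drugs |
| `d_p` | 10 | width of each position-embedding channel (a row of $e^p$ is $2 d_p$) |
| `hop` (k) | 3 | subgraph radius; label width is $2(k+1)$ |
| `graph_dim` | 75 | node-embedding width; layer-0 state width is $75 + 2(k+1)$ |
| `layers` (T) | 3 | propagation depth |
| `num_bases` (B) | 4 | basis matrices shared across (doubled) relations |
| `zeta` | 0.0 | attention pruning threshold; $-1$ disables pruning |
| `window` | 5 | convolution window (odd) |
| `dropout` | 0.1 | applied to the fused vector during training only |
| `lr`, `batch_size`, `epochs` | 5e-5, 32, 5 | adaptive-moment optimizer, decoupled weight decay 0.01 |
| `gamma` | 2 | focal-loss focusing strength |

The defaults are the reference experimental setting for the full-scale
task (pretrained encoder, large knowledge graph). The package's synthetic
experiments use a deliberately smaller instantiation — `graph_dim` 16,
`hidden_dim` 16, `layers` 2, `hop` 2, `d_w` 32, `d_p` 6, `channels` 24,
`max_length` 40, `lr` 5e-3 — sized so a training run on a few hundred
instances converges in seconds on one CPU. The higher learning rate is a
consequence of training all weights from random initialization rather than
fine-tuning a pretrained encoder; 5e-5 is a fine-tuning rate.

## Design decisions in ambiguous territory

Several aspects of this architecture admit more than one reading; the
package fixes them as follows and exposes switches where both readings are
defensible.

* **Attention is layer-independent.** $\alpha$ is computed once from
  layer-0 states and reused by every layer (the gating pair
  $(\gamma, \beta)$ *is* per layer). Recomputing $\alpha$ per layer is the
  main alternative; the layer-0 form makes pruning a single, stable
  decision per edge.
* **The attention divisor is $d_0$, not $\sqrt{d_0}$.** The scaled
  dot-product convention would use $\sqrt{d_0}$;
  `attention_scale = "sqrt_dim"` selects it.
* **$\zeta$ defaults to 0**, pruning the tanh-negative half of edges. No
  reference value exists; 0 is the natural sign boundary of the score.
* **Edge direction.** Stored edges are traversed in both directions: each
  relation gets a generated inverse (doubling the relation vocabulary),
  standard relational-GCN practice, and consistent with the undirected
  neighborhood definition.
* **Endpoints are always retained.** The strict intersection rule would
  drop $u$ or $v$ whenever $d(u, v) > k$ on one side, but the pair
  representation needs both endpoint states; unreachable distances clamp
  into bucket $k$ so labels stay fixed-length.
* **Focal-loss form.** The default is the standard true-class form
  $-\alpha_y(1-p_t)^\gamma \log p_t$. A variant that multiplies by
  $\sum_i \alpha_i / m$ instead of $\alpha_y$ is available as
  `focal_form = "printed_sum"`; when the weights sum to 1 it is a constant
  rescaling.
* **Class-weight direction.** `class_weights()` defaults to weights
  *proportional* to class counts ($\alpha_i = \mathrm{Count}_i / \sum
  \mathrm{Count}$), which up-weights the majority class; since that works
  against imbalance correction, the conventional inverse-frequency
  weighting ships as `weighting = "inverse"`. Neither is endorsed; the
  default is the faithful reading.
* **Averaging scope.** Micro/macro P/R/F1 exclude `Negative` by default
  (`classes = "positives_only"`, the DDIExtraction benchmark convention);
  `classes = "all"` pools every class, in which case micro precision
  equals micro recall. Macro F1 is the harmonic mean of macro precision
  and macro recall — *not* the mean of per-class F1; a regression test
  pins this down on an asymmetric confusion where the two differ.
* **Method 3 duplication.** The per-token text/graph concatenation
  includes the pair representation twice as printed in its defining
  equation; `dedup_hdp = TRUE` drops the duplicate.
* **Negative filtering rules.** The three screening rules (same
  name/abbreviation; coordinate list; parenthesized or "such as" special
  case) are cited in the literature without pseudocode. The
  operationalizations here are heuristics — normalized-name equality plus
  an initials test; a separator-only gap test after blanking other drug
  mentions; a parenthetical/apposition pattern — each individually
  toggleable. Only `Negative`-labeled candidates are ever removed: the
  mapping-based exclusion, which applies to every instance, accounts for
  positive-count shrinkage.
* **Optimizer.** Adaptive-moment estimation with *decoupled* weight decay
  (0.01), excluding biases and embedding tables from decay.
* **Cross-validation unit.** `cv_folds()` splits by document, the most
  conservative unit when the split unit is unspecified.

One documented invariant proved unattainable as stated: making the
method-1 BiLSTM an exact identity map by hand-set weights is impossible
with saturating gates ($h = o \odot \tanh(c)$ cannot equal $x$ exactly),
so method-1/method-2 equivalence is not tested through an identity LSTM;
method 1 is tested directly against its own contract instead.

## Numerical choices

All neural components run on a small tape-based reverse-mode automatic
differentiation engine over dense matrices written for this package;
gradient correctness is pinned by central finite-difference checks
(tolerance 1e-4 relative, at $\varepsilon = 10^{-5}$). Softmax is
stabilized by max subtraction; $p_t = 0$ is clamped to $10^{-12}$ with a
warning; GELU uses the exact error-function form $x\,\Phi(x)$; max-pooling
breaks ties by first index; member ordering inside a subgraph is sorted by
(dist to $u$, dist to $v$, identifier) so tensors are reproducible, and the
readout is permutation-invariant regardless. All randomness —
initialization, batch shuffling, dropout masks, the synthetic world —
derives from explicit integer seeds, giving bit-identical metrics across
reruns on one CPU.

## What the synthetic world emulates — and what it does not

The generator stands in for a licensed-resource stack: a typed
drug/protein/pathway/disease graph and an annotated corpus. Study
conditions are fixed at: 40 drugs, 25 proteins, 15 pathways, 12 diseases;
class mix `Negative` 0.4 and 0.15 for each positive class; one label per
pair, distinct pairs across instances; 120 background edges
(label-uninformative relations `targets`, `participates_in`,
`associated_with`, covering every drug); and one 2-hop motif per positive
label — both drugs linked to a shared neighbor through a label-specific
relation (`shares_metabolizing_enzyme` → protein, `perturbs_pathway` →
pathway, `contraindicated_in` → disease, `interacts_with_target` →
protein). Motifs are 2-hop so any subgraph with $k \ge 1$ contains them;
the synthetic experiments use $k = 2$. Sentences instantiate label-specific
trigger templates with pronounceable generated drug names (fixed-length,
collision-free, so the same-name filter rule never fires by accident).

`placement` controls where the label signal lives: `both` (text and graph
agree), `text_only` (motif labels drawn independently of gold), and
`graph_only` (templates drawn independently of gold). At `noise = 0` and
`placement = "both"` the task is separable by construction — a
Bayes-optimal classifier reaches 100% — which is what makes the end-to-end
recovery test meaningful: the trained model reaching ≥95% train micro-F1
within 30 epochs demonstrates that every stage (parsing, candidate
generation, mapping, subgraph extraction, propagation, fusion,
optimization) transmits the signal. The ablation tests use the asymmetric
placements: on `graph_only` data the subgraph-aware model beats the
subgraph-ablated one by a wide macro-F1 margin; on `text_only` data the
two tie.

What passing these tests does **not** show: anything about real biomedical
language (no lexical variety, negation, coordination depth, or discourse
structure), about graphs with realistic degree distributions or noisy
relations, or about generalization — the recovery test is measured on the
training instances by design, as a capacity-and-plumbing check. Benchmark
performance on the real corpus requires the pretrained encoder and a real
knowledge graph, both out of scope here.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run, per invocation: 200 random
graphs (≤ 60 nodes) against a brute-force BFS oracle; 10 random subgraph
instances for the pruning/attention identities; 100 random 50-instance
prediction sets against an independent metrics oracle; one 500-instance
separable training run (twice, for bit-reproducibility) and four
300-instance ablation runs, each within a 30-epoch budget that halts once
train micro-F1 saturates. These sizes are the package's desk-scale
protocol; they complete in a few minutes on one CPU.

## Known limitations

* The enclosing subgraph is recomputed per distinct pair and cached
  in-memory per run; no on-disk cache is shipped.
* Mini-batching is per-instance (gradient accumulation), not padded tensor
  batching; throughput is adequate at desk scale only.
* The negative-filtering heuristics are intentionally conservative
  operationalizations; on real corpora their precision/recall trade-off
  should be audited per collection.
* AUC/AUPR for a class absent from the gold labels is undefined and
  excluded from macro averages (with a warning path for P/R, which are set
  to 0 for classes absent from both gold and predictions).
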