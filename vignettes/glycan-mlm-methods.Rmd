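---
title: "Masked-language modeling on glycan token graphs: models and methods"
author: "glycanMLM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Masked-language modeling on glycan token graphs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Public glycan repositories hold hundreds of thousands of carbohydrate
structures written in IUPAC-condensed notation, but a large share of the
entries are incomplete: linkage positions written as `a2-3/6`, residues or
anomeric configurations replaced by `?`. glycanMLM models fully-defined
glycans as rooted labeled trees — monosaccharides as nodes, glycosidic bonds
as edges, the reducing end as root — and pretrains a pure-transformer encoder
with a masked-language-modeling (MLM) objective over both node and edge
tokens. The pretrained model yields (i) ranked candidate completions for
masked residues and linkages, scored by hit@K, and (ii) a whole-glycan
embedding (the final state of a prepended `[Graph]` token) usable as a
feature vector for downstream classification. A Weisfeiler–Lehman subtree
kernel provides a purely structural similarity baseline for the same data.

## Tokenized graph encoding

A glycan with $n$ residues and $m = n - 1$ bonds becomes a flat sequence of
$1 + n + m$ tokens: the `[Graph]` summary token, then node tokens in textual
(left-to-right) order, then edge tokens in child-index order. Each token
embedding is the sum of three parts:

* a **content embedding** looked up by token id in one of two disjoint
  dictionaries (monosaccharides and linkages have separate id spaces and
  separate output heads; residue modifications such as `GalNAc3,4,6Ac3`
  remain verbatim single tokens);
* a linear projection of a pair of **orthogonal random feature (ORF) node
  identifiers**: a node $v$ carries $[P_v, P_v]$, an edge $(u, v)$ carries
  $[P_u, P_v]$, where the rows $P_\cdot$ of a seeded, QR-orthonormalized
  Gaussian matrix are orthonormal. Because
  $\langle [P_u,P_v], [P_u,P_w] \rangle = 1 + \delta_{vw}$, attention can
  discover which tokens are incident from inner products alone — no
  message passing or Laplacian eigenvectors are needed;
* a trainable **type embedding** with three types: node, edge, and the
  `[Graph]` token (which carries a zero identifier and its own content
  vector).

The encoder is a stack of post-norm transformer blocks (multi-head
self-attention and a 4$d$ GELU MLP, each followed by a residual connection
and LayerNorm), with full $O((n+m+1)^2)$ attention — cheap at glycan sizes.
Four named scales are provided: ss = 2 layers x 64 dims x 4 heads,
small = 4x128x4, medium = 8x256x8, large = 12x512x16. The exact
depth/width/heads of each scale are package defaults, overridable in
`modelConfig()`.

One consequence of sharing a single identifier bank across graphs (rows
assigned by canonical node index) is that the encoder is exactly invariant
to *token order* permutations — identifiers travel with tokens — but not to
node *relabeling*; canonical node order is fixed by the parser, so this
never matters in practice.

## Pretraining objective

Training masks a fixed count `round(r_n * n_nodes)` of node tokens and
`round(r_e * n_eligible)` of edge tokens per glycan (uniformly, without
replacement, reseeded every epoch), replaces their content by `[MASK]`
while keeping identifiers and types visible, and minimizes

$$\mathcal{L} = \overline{CE}_{\text{nodes}} + \lambda\,
\overline{CE}_{\text{edges}}, \qquad \lambda = 0.5,$$

the means running over the masked positions of each batch. Masked inputs
always become `[MASK]`; there is no BERT-style random-replacement noise,
which keeps training aligned with the completion use-case. Fixed-count
masking (rather than per-token Bernoulli draws) makes every plan
deterministic under its seed.

**Terminal linkages** — bonds incident to a degree-1 non-root residue — are
excluded from masking targets: with a leaf on one side they lack two-sided
context. (A variant that also counts a degree-1 *root* as an end is
available via `encodeGlycan(rootEdgeTerminal = TRUE)`.) Under the
all-linkages-masked completion scenario terminal edges are still *hidden*
from the model, since real ambiguous entries hide them, but they are never
*scored*.

The optimizer is AdamW (default learning rate 1e-6, weight decay 0.01 on
weight matrices, gradient clipping at global norm 1.0, batch size 32) with
optional linear warmup. A 90/10 train/validation split with early stopping
on mean validation loss (patience 15 epochs for ss/small, 30 for
medium/large) selects the epoch count; by default the model is then
re-initialized and refit on the full corpus for that many epochs
(`refitFull`), which measurement-oriented runs switch off so validation
stays held out. The default learning rate matches large-corpus pretraining;
for the toy experiments below, a d = 64 model on 2000 short sequences, all
tests use 4e-3 with a 150-update warmup — chosen once as a standard Adam
rate for this width (2e-3 converges but too slowly for a 50-epoch budget;
5e-3 without warmup oscillates).

Masking modes: `balanced` (the default 35%/35% on nodes and edges),
and the single-modality ablations `node_only` (70%/0%) and `edge_only`
(0%/70%), keeping the total masked fraction comparable.
`attentionSummary()` reduces final-layer attention (head-averaged) to a
3x3 node/edge/graph block matrix for inspecting modality-specific focus.

## The synthetic grammar: what it emulates, and what it does not

Because the real repositories cannot be bundled, `toyGrammar()` defines a
probabilistic grammar over 10 residue symbols and 8 linkage symbols that
emulates the *statistical shape* of glycan corpora: branched rooted trees
(branching probability 0.3, depth cap 6, leaf probability 0.25 below the
root), sizes concentrated in the 2–25 residue range, and — crucially —
context-determined tokens:

* the linkage of a (parent, child) pair is a **deterministic function** of
  the pair, so a model that can read both endpoint residues has a
  Bayes-optimal masked-linkage accuracy of 1;
* each parent admits 4 child residues under a fixed 0.4/0.3/0.2/0.1
  categorical, so masked residues are predictable above the 1/10 chance
  level but not perfectly — mimicking real compositional ambiguity.

Within a parent's four allowed children the linkage map is injective for
most parents (a wrap-around in the child window makes a single collision
for some), so a visible incident linkage usually pins a masked child
exactly.

Two caveats documented deliberately. First, under *joint* balanced masking
a masked edge sometimes has its parent residue masked too; if that parent
is a degree-1 root there is no remaining context that determines the
linkage, so the exact ceiling for edge accuracy under the joint 35%/35%
plan is well below 1 (the trained ss model plateaus near 0.90 there, while
reaching ~0.98 when residues are visible). Learnability of the linkage rule
is therefore assessed in the endpoint-visible regime, where the ceiling
argument applies; the joint-plan accuracy is reported alongside. Second,
passing these tests shows the architecture can extract the grammar's
context — it does not certify accuracy on real glycan corpora, whose label
distributions are far more skewed and whose ambiguity is not independent of
structure. Relatedly, the family signal (root residue) is linearly present
in the `[Graph]` embeddings only weakly (~3–4x chance for a linear probe):
MLM gives the summary token no direct supervision, so strong class
separation of embeddings should not be expected from the toy setup.

## Completion scenarios and hit@K

Two scenarios mirror empirical ambiguity patterns: (i) linkages intact
with 10–90% of monosaccharides masked; (ii) all linkages masked with
0–90% of monosaccharides masked. For every masked, scored position the
model ranks the full content vocabulary of its type by softmax
probability; hit@K (K = 1, 2, 3, 5, 10, 20, 30) is the micro-averaged
fraction of positions whose true token ranks within the top K, reported
separately for node and edge targets (a macro, per-glycan average is
available via a flag). Ties — which occur only in degenerate models, e.g.
an untrained one whose zero-initialized heads emit exactly uniform
probabilities — are broken by a seeded random permutation, which also makes
the untrained model's hit@K sit on the K/|vocab| chance line in
expectation.

## WL subtree kernel

`wlKernel()` labels nodes by monosaccharide identity only (linkage labels
stay out of the relabeling; edges contribute undirected adjacency), runs
h = 3 refinement iterations by default, sums histogram dot products over
iterations 0..h, and normalizes to unit diagonal. The implementation uses
globally compressed integer relabeling per iteration; the test suite checks
it against an explicit uncompressed-multiset reimplementation and against a
frozen matrix computed by an independent implementation of the same
definition in another language. Average-linkage clustering on 1 - K is
provided as a reporting aid, and `pcaKmeans()` (50 components, k = 6,
seeded) supplies the cluster inputs used for embedding interpretation.

## Downstream harness

`benchmarkClassify()` follows a fixed train/validation/test split.
Hyperparameters are selected by randomized search with 3-fold
cross-validation on train + validation — 10 iterations for the SVM (RBF or
linear; C ~ logU(1e-3, 1e2), gamma ~ logU(1e-4, 1e-1)) and 15 for the
gradient-boosted trees (n_estimators 100–1000, learning rate
logU(0.01, 0.3), 20–150 leaves, depth 5–20, L1/L2 logU(1e-2, 1e1), column
and row subsampling U(0.6, 1)) — with class-balanced weights throughout;
the winner is refit on train + validation and evaluated once on the test
split, and the whole procedure repeats over three seeds to give
mean ± s.d. of Macro-F1, accuracy, and (binary tasks) AUPRC. The boosted
trees run on xgboost with histogram/loss-guided growth, the package's
gradient-boosting implementation of that search space. Macro-F1 averages
per-class F1 over classes present in either vector; AUPRC integrates the
step-interpolated precision envelope over recall, validated against
exhaustive threshold enumeration.

## Numerical choices and degenerate inputs

* LayerNorm epsilon 1e-5; GELU in tanh form; MLM heads are
  zero-initialized (uniform initial predictions, which also anchors the
  analytic untrained loss at ln 10 + 0.5 ln 8 = 3.34 on the toy vocab).
* All randomness flows through explicit integer seeds; derived seeds stay
  below 2^31. Two runs with equal seeds are bit-identical end to end
  (corpus, loss curves, hit@K tables).
* A glycan with more residues than the identifier bank raises a capacity
  error (`embedCorpus()` records it as skipped instead of failing the
  batch). Empty masking plans yield loss 0 with a warning. Strings with
  `?` are rejected at curation; `/` outside a linkage is a validation
  error; expansion is capped at 16 variants per entry with a warning.
* Serialization normalizes branch order (main chain through the
  lexicographically greatest linkage; remaining branches bracketed in
  ascending order), making `parse(serialize(g))` a labeled-tree
  isomorphism and `serialize(parse(s))` a fixed point.

## Problem sizes used by the test suite

The learnability experiment pretrains the ss scale on 2000 generated
glycans for at most 50 epochs; the ablation trio uses 600 glycans for 20
epochs; the reproducibility check uses 120 glycans for 4 epochs; kernel
and parser properties run on 20–1000 structures. These sizes were chosen
so each property is measured with comfortable statistical margin while the
whole suite stays convenient to run on a laptop-class single core.

## Known limitations

* The toy grammar has no unknown tokens, no label noise, and a uniform
  root distribution; `[UNK]` handling is exercised only by unit tests.
* Early stopping monitors mean validation loss, not completion accuracy;
  for small corpora the two can diverge by a few epochs.
* The identifier bank caps addressable residues (default 64) — ample for
  glycans, but polysaccharide-scale inputs must raise `dP`.
* The completion evaluation mirrors the MLM objective; high hit@K here
  demonstrates contextual recovery, not resolution of chemically
  ambiguous structures.
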