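---
title: "Methods: local and global graph representations for DTI prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: local and global graph representations for DTI prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`lgdti` predicts drug–target interactions (DTIs) by binary classification of
drug–protein pairs. The universe is a bipartite graph `G = (V, E)`:
`V = [v_1, …, v_n, …, v_{n+m}]` lists `n` drugs followed by `m` proteins
(each class sorted lexicographically, so indices are stable across runs),
and `E` holds the known interactions. Three per-node representations feed
the classifier:

**Intrinsic attributes.** Drugs: Morgan circular fingerprints at radius 2,
folded to 64 bits, computed by the RDKit backend (invoked as a batch
subprocess; the bit layout is backend-defined but deterministic for a fixed
version). Proteins: the 20 amino acids are reduced to four physicochemical
groups — hydrophobic {A,V,L,I,M,F,W,P}, polar {G,S,T,C,N,Q,Y}, basic
{R,K,H}, acidic {D,E} — and the sequence is summarized by the frequency of
each of the 4³ = 64 reduced 3-mers over its `L − 2` overlapping windows.
Both representations are 64-dimensional because they share one stacked
matrix `X = [X_d; X_p]` that the graph convolution multiplies by a single
64×64 weight matrix. The 3-mer slot index is big-endian base 4
(`Σ g_i · 4^{k−i}`); any fixed bijection would do, this one is documented
and tested.

**Local structure (GF).** One graph-convolution layer

> `GF = T( ReLU( D̃^{-1/2} Ã D̃^{-1/2} X W ), X )`

with `Ã = A + I_{n+m}` (every node gets a self-loop, so no degree is zero),
`D̃` its degree matrix, and `W` a 64×64 Glorot-uniform matrix that is drawn
once from a seed and **never trained** — the layer is a random-projection
neighborhood aggregator; all supervised learning happens downstream. `T`
re-injects the raw attributes after the convolution to counter
over-smoothing. Its published description ("added node features") is
ambiguous between concatenation and summation; both are implemented, and
concatenation is the default because it preserves `X` verbatim and keeps
the aggregated and intrinsic signals linearly separable downstream. The
re-injected argument is the *original* `X` at every layer (the update rule
names a literal `X`, not the previous layer's output). One layer is the
default and the tested configuration; `n_layers > 1` is supported
mechanically with `mode = "sum"`.

**Global structure (ψ).** DeepWalk: per epoch, the node set is shuffled and
one truncated random walk of length `t` starts from every node, stepping to
a uniformly random neighbor. Self-loops are *excluded* from walks — they
exist only for the GCN normalization; letting a walker loop in place would
corrupt context statistics. The walk corpus trains a skip-gram model: for
every center node and every context node within `w` positions, SGD
minimizes `−log Pr(context | ψ(center))` with hierarchical softmax over a
Huffman tree built from corpus node frequencies (the published algorithm
explicitly builds a binary tree); negative sampling (5 draws from the
unigram^0.75 distribution) is available as `objective = "ns"`. The loop
bound `μ` in the published pseudo-code is read as the epoch count `γ` (the
symbols are used inconsistently there). Training is single-threaded with a
self-contained xorshift RNG, so embeddings are bit-reproducible per seed
and platform-independent.

**Pair model.** A pair's feature row is the drug block concatenated with
the protein block under one of three modes: `attribute` (X only, 128
columns), `gf` (256), `lgdti` (GF ⊕ ψ per node, 384). Positives are the
graph's edges; negatives are sampled uniformly without replacement from
non-edges at 1:1 (the convention of this literature; the source experiment
does not state its policy). Classifiers: random forest (default), gradient
boosting, logistic regression, k-NN — defaults mirror scikit-learn's
(100 trees with √p feature subsampling; 100 depth-3 rounds at shrinkage
0.1; unpenalized ML; k = 5).

## Tunable parameters

| parameter | default | why |
|---|---|---|
| fingerprint radius / bits | 2 / 64 | radius 2 (ECFP4-like) is the field default; 64 bits forced by the shared 64×64 `W` |
| k-mer `k` | 3 | 4³ = 64 matches the drug block |
| `gcn.layers` | 1 | deeper stacks over-smooth; the design fixes one layer |
| `gcn.combine` | concat | preserves raw attributes verbatim |
| walk length `t` | 30 | published pseudo-code gives symbols, no values; 30/5/10/64/0.025 are the community defaults for DeepWalk-style embedding |
| window `w` | 5 | idem |
| epochs `γ` | 10 | idem |
| embed dim `d` | 64 | symmetric with the other 64-dim blocks |
| learning rate α | 0.025 → α/100 | word2vec convention, linear decay |
| negatives : positives | 1:1 | comparator convention |
| decision threshold | 0.5 | unstated in the source; standard |
| folds `k` | 5 | the evaluation protocol |

## Cross-validation and leakage

Folds are stratified over pairs (shuffle within each label class, deal
round-robin), so per-fold class balance is within one pair of global.
Whether the source experiment removed held-out test edges from the graph
before computing structural features is not stated; whole-graph embeddings
see the test edges and leak label information. Both protocols ship:

* `leakage = "strict"` (default): per fold, GF and ψ are recomputed on the
  graph with that fold's positive test edges removed. Honest, slower.
* `leakage = "paper"`: representations computed once on the full graph —
  the protocol most whole-graph embedding papers use implicitly.

A regression test asserts `paper` never scores below `strict` on the
fixture, which is the direction the leak must push.

## The synthetic world

No public benchmark is redistributable here (the original interaction set
is licensed), so the package carries a planted-partition generator: drugs
and proteins are assigned round-robin to `B` blocks and a drug–protein edge
is drawn with probability `p_in` within a block, `p_out` across. The
default fixture is 60×40, 2 blocks, `p_in = 0.3`, `p_out = 0.02` — a
desk-scale miniature (~400 edges) of the real 984×635/11,396-edge network.
Molecules are assembled from a valence-safe SMILES fragment vocabulary
(plain concatenation of the fragments is always parseable); protein
sequences are uniform over the 20 residues.

This world is chosen so the feature families dissociate: intrinsic
attributes are independent of block structure (no signal), GF carries it
indirectly (aggregated neighbor attributes cluster by block), ψ captures it
directly (walks rarely cross blocks). The published feature-ablation
ordering — full model ≥ local-only ≥ attributes-only — therefore emerges as
a testable property, and does (mean 5-fold AUROC ≈ 0.67 / 0.51 / 0.49 over
five replicates under the strict protocol).

What a green suite does **not** establish: absolute performance on real
data. Within a planted block, held-out edges and non-edges are
exchangeable, capping strict-protocol AUROC near 0.75 on this fixture; real
DTI networks are far richer (degree heterogeneity, overlapping communities,
attribute–structure correlation — none of which the generator emulates), and
the published experiment reports AUROC ≈ 0.95 there. Synthetic attributes
also carry no chemistry: fingerprint diversity is tested, drug-likeness is
not.

## Numerical choices

* Tie-aware trapezoidal AUROC over tie-grouped ROC points — exactly the
  Mann–Whitney pairwise estimator with half credit for ties (tested against
  a brute-force oracle at 1e−9).
* AUPR is the step-wise, non-interpolated precision integral
  (`Σ (R_i − R_{i−1}) P_i` over descending-score tie groups), so
  cross-implementation differences with interpolating variants are
  explainable.
* MCC returns 0 when its denominator is 0; precision is `NA` when nothing
  is predicted positive.
* Target ranking breaks score ties by protein id, making reports stable.
* Degenerate inputs: edgeless graphs refuse walk-corpus construction;
  length-1 walks (isolated nodes) are discarded and such nodes get zero
  embeddings with a warning; sequences shorter than `k` after cleaning,
  unparseable SMILES, single-class folds and exhausted non-edges are all
  hard errors naming the offender.
* One global seed fans out to per-stage seeds by fixed offsets, so stages
  are independently reproducible; seeded functions restore the caller's RNG
  state.

## Design decisions that were genuinely open

* **Trees from scratch.** The host environment provides no tree-ensemble
  package, so rf/gbdt are built on an in-package CART grower (compiled):
  variance-reduction splits, which coincide with Gini impurity for 0/1
  labels, bootstrap + √p feature subsampling for the forest, depth-3
  residual fitting with shrinkage for boosting (gradient, not Newton,
  steps — adequate for ranking scores).
* **Fingerprints via subprocess.** Rather than reimplement Morgan hashing,
  the package shells out to the same RDKit the original pipeline names, one
  batched process call per molecule table.
* **Acceptance probe.** The block-recovery check uses a ridge-penalized
  logistic probe (`glmnet`, α = 0, λ = 0.05): with ~70 training nodes and
  64 embedding dimensions an unpenalized probe is ill-posed and its failures
  reflect the probe, not the embedding.
* **Hierarchical softmax as default** (the pseudo-code builds the tree);
  negative sampling kept as an alternative because it is what most modern
  reimplementations use.

## Known limitations

Dense adjacency matrices cap practical size at a few thousand nodes (the
target scale); the GCN is untrained by design; walks are unweighted and
unbiased (no node2vec p/q); the CLI is a thin wrapper without parallelism;
fingerprints require a Python RDKit on the PATH at run time.
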