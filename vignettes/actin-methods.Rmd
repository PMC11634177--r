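---
title: "ACTIN: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ACTIN: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Given a drug molecule and a landmark gene, ACTIN predicts a bounded
interaction score `S_ij` that tracks how strongly the drug perturbs the
gene's expression in one cell line. Training data are L1000-style
perturbation tables: one log2 fold change (logFC) per (drug, cell line,
gene). Because cell lines respond heterogeneously, one model is trained
per cell line — the cell line is the provenance of a dataset, never an
input feature — and training needs only a few hundred perturbation
instances per line.

## Architecture

**Drug encoder.** A SMILES string becomes an undirected heavy-atom graph
over a fixed 14-element vocabulary (C, N, O, Cl, Ca, S, F, Br, I, P, Au,
B, Si, Hg); bonds are plain edges (no bond-type features, and no
hydrogens — the vocabulary has none). Atoms are one-hot encoded and
linearly embedded to width `d` (256 by default). Two stages of GATv2
convolution + TopK pooling follow. Per head `h`, the GATv2 score of edge
(i, j) is `a_h' LeakyReLU(Wl_h x_i + Wr_h x_j)` (slope 0.2), normalized
by a softmax over `N(i) ∪ {i}`; a self-loop is always added so isolated
survivors of pooling still aggregate. Four heads of width `d/4` are
concatenated, keeping the width constant. TopK pooling scores nodes by a
learned projection (`X p / ||p||`), keeps the top `ceiling(0.8 n)` per
graph, and gates kept features by `tanh(score)`. After each pooling
stage a `[mean || max]` readout over the surviving nodes is taken; the
two stage readouts are concatenated (the "multiscale global features")
and affinely projected to `d`. No extra nonlinearity is inserted between
the GAT stages: the attention itself is nonlinear, and keeping the stack
lean makes the brute-force forward oracle in the tests exact.

**Gene projection.** Genes are embedded from a PPI network with a
node2vec procedure (below) into 128 dimensions, then mapped by a
two-layer perceptron (128 → d → d, ReLU) into the common space.

**Transpositional interfusion.** The pair `[G_j; D_i]` forms a two-token
sequence processed by `N` transformer encoder blocks (N = 6, 4 heads,
`d_k = d/4` by default) in the *pre*-layer-norm convention: layer norm
before attention and before the FFN, shortcut additions around both, and
— as is standard for pre-LN stacks — one final layer norm before the
head. That final norm matters numerically: without it the residual
stream grows with depth and the tanh output saturates, killing
gradients. Per head, `Q = X W_Q`, `K = X W_K`, `V = X W_V`,
`X' = softmax(QK'/√d_k) V`; the 2×2 row softmax is computed as a
logistic of the score difference, which is algebraically identical and
numerically stable. Head outputs are concatenated and mixed by
`W_o ∈ R^{4 d_k × d}`. The FFN is `d → 4d → d` with ReLU.

**Head.** The two fused tokens are flattened (`2d`) and passed through a
perceptron (`2d → d → 1`, ReLU) with a final tanh, so predictions live
in (−1, 1) — exactly the range of the regression targets.

## Mapping expression to targets

Raw logFC is mapped by a three-interval "step function"
`SF(x) = w·tanh(s1·x)` for `|x| ≤ t` and
`SF(x) = sign(x)·(w·tanh(s1·t) + (1 − w·tanh(s1·t))·tanh(s2·(|x| − t)))`
beyond; defaults `w = 0.1`, `s1 = s2 = 1`, `t = 1` (logFC units; `t = 1`
is the conventional two-fold-change cut). The exact functional form of
the published step function is not printed in the text we re-implement
from, so this parameterization was chosen to satisfy every property it
states — odd, continuous, strictly increasing, bounded in (−1, 1),
flat inside the |logFC| < 1 dead band and saturating outside — with all
four constants exposed in the configuration. Class labels use strict
inequalities (`Up` iff logFC > t; values exactly at ±t are `None`), and
predicted labels threshold at `SF(±t)` so that
`predicted_label(SF(x)) = label(x)` away from the thresholds.

## Gene embeddings

`node2vec_embed()` performs biased second-order random walks
(`walk_length = 80`, `walks_per_node = 10`, `window = 5`, `p = q = 1` by
default — standard published defaults) and trains skip-gram with 5
negative samples by seeded mini-batch SGD. Within a batch, per-node
gradients are aggregated with `rowsum` and norm-clipped at 1; clipping
is what keeps tiny graphs stable, where a node can recur hundreds of
times in one batch. Vectors are deliberately *not* length-normalized —
the downstream projection learns the scale. Embeddings are invariant to
edge-list row order (adjacency lists are sorted) and bit-reproducible
given the seed.

## Training

Samples are (drug, gene) pairs, one per perturbation record, with target
`SF(logFC)`. Splitting happens at the perturbation-instance level (all
genes of one treatment share a fold): every fold except the last gets
`floor(fraction·n)` instances, the remainder goes to the last, which
reproduces 393 training instances for 492 at the 8:2 ratio. The loss is
smooth-L1 (`β = 1`), the optimizer Adam (`lr = 1e-4` by default; the
objective text we follow states only mini-batch gradient descent, so the
optimizer and rate are package choices), batch size 1000, shuffled each
epoch with a seeded generator. When a validation fold exists, training
early-stops after 10 stale epochs and restores the best parameters.
Gradients are computed by a small reverse-mode tape written in R and
validated against central finite differences in the test suite; all
forward/backward work is vectorized across whole batches (molecules are
stacked into one disjoint-union graph), so a training step is a handful
of dense matrix products.

A subtle determinism point: TopK pooling ranks nodes by score, and
structurally equivalent atoms tie *exactly* (a carbon surrounded only by
carbons receives the same GATv2 output as any other such carbon, because
attention weights sum to 1 over identical messages). Ties are therefore
broken by a canonical Weisfeiler–Lehman rank of the atom (element label
refined over neighbourhoods), then by index, and scores are quantized at
1e-9 before ranking so floating-point summation noise cannot flip the
order. This makes `encode_drug` exactly permutation invariant in
practice.

## Synthetic studies

The generator builds random valence-respecting trees (optionally one
ring closure) over the 14-element vocabulary; per molecule, each element
is included with a configurable prevalence (carbon always; common
heteroatoms 0.2–0.7; halogens 0.05–0.2; metals ≤ 0.02 — chosen once as a
plausible screening-library profile). The perturbation model is additive:
`logFC(d, g) = Σ_e direction·β·[d contains element e]·[g targeted by e]
+ N(0, noise_sd²)`. This is the simplest structure under which recovery
of the planted chemistry is well posed. What it does *not* emulate:
dose/time covariates, correlated gene modules beyond the planted ones,
realistic chemistry (aromaticity, stereochemistry), or the heavy-tailed
noise of real L1000 data — so green tests here demonstrate that the
machinery works, not that real-data accuracies transfer.

The bundled parameter-recovery benchmark fixes the study conditions: 200
drugs, 100 genes, one planted effect (S up-regulates genes g0001–g0020,
β = 2.5), noise sd 0.3, generator seed 42; reduced model width d = 64
(d_k = 16), 2 interfusion blocks, 2 GAT stages; Adam lr 1e-3, 25 epochs
at batch 1000 on an 8:2 split; node2vec is run with shortened walks
(length 20, 5 per node, 3 epochs) since the benchmark needs
distinguishable gene vectors rather than a converged embedding. These
sizes keep the full benchmark in the minutes range on one CPU. The
trained model reaches held-out up-regulation ROC-AUC of 0.95 or better
(0.95–0.99 across the seeds we ran). The
down-regulation AUC sits near 0.5 *by construction*: no down effect is
planted, so down-labels arise only from noise tails and are inherently
unpredictable.

## Interpretability

**Element disparity.** For a family of per-cell-line models, the 14 × d
element-embedding matrices are stacked, PCA-reduced (128 components by
default, clipped to the available rank; PCA is fit jointly on the
stacked models × elements rows), and per element the range (max − min)
and sd of its reduced coordinates across models are summed over
components. Elements are ranked by descending cumulative range (a flag
switches to sd). On the bundled two-cell-line family with different planted
elements (S vs P, 120 shared drugs, 25 training epochs per line, both
lines initialized from the same seed), the planted elements are pulled
apart by line-specific gradients and rank near the top of 14 — across
the seeds we ran, one planted element tops the ranking while the other
lands 4th–5th (seed 7: P 1st, S 5th; seed 1: S 2nd, P 4th) — but rare
elements (B, Si, Ca, Hg, I at ≤ 5% prevalence) receive few, noisy
gradient updates whose direction differs across lines by chance, and
their cumulative range can edge past a genuinely shifted common
element. Disparity rankings from small
families should therefore be read as enrichment near the top, with the
seed stated, not as an exact ordering.
Elements absent from the molecule set keep identical (initialized)
embeddings and show zero disparity.

**Attention element importance.** For one model, the drug encoder is run
over a molecule library and the incoming GATv2 attention mass
`α_h(i, j)` is accumulated by the element of the attended atom j
(self-loops included), normalized per head to sum to 1, with a mean row
over heads; the stage is a flag (stage 1, closest to raw chemistry, by
default). A caveat this package's own benchmark makes measurable: on the
synthetic study the trained attention distribution is statistically
indistinguishable from the untrained baseline, i.e. attention mass
simply tracks atom frequency (carbon ≈ 0.73). The planted element is
recovered through the element embeddings and the mean/max readout, which
give the network a path to the answer that requires no attention
concentration — so the attention-importance table should be read as a
descriptive lens, not as a guaranteed recovery mechanism at this scale.

## Screening

A trained model predicts a bounded score per gene for each library drug;
the reversal score against a disease signature is
`−Pearson(ŝ, SF(signature))` over the overlapping genes (both vectors on
the same bounded scale; Spearman or dot-product variants would be easy
additions but Pearson on SF-mapped values is the default). Candidates
are ranked descending, ties broken by drug id; negating the signature
exactly reverses the ranking. Signature genes without embeddings error
in the API and are dropped (with a count) in the CLI.

## Evaluation choices

ROC-AUC uses the Mann–Whitney rank form (ties half-credit; equal to
all-pairs concordance, which the tests verify by brute force). PR-AUC is
average precision. Up and down regulation are scored as separate
one-vs-rest problems (down uses negated scores). Pearson correlation is
computed per perturbation instance over its genes and averaged
unweighted (a pooled mode exists); zero-variance instances are excluded
with a warning. The confusion matrix is 3 × 3 over {Up, Down, None}; the
error rate counts completely opposite calls with the true-Up/Down pairs
as denominator (switchable to all pairs — the published description is
ambiguous on this point). Cross-model aggregation is the
sample-size-weighted mean, reported to 4 decimals, with the unweighted
sd alongside, labelled as such: the published ± values match neither the
weighted nor the unweighted sd exactly, so no spread is asserted.

## Known limitations

* The SMILES parser covers the subset needed here (organic atoms,
  brackets, branches, ring closures, aromatic lowercase); charges,
  isotopes and stereochemistry are accepted syntactically but ignored.
* Checkpoints are JSON — self-describing and text-only, at the cost of
  file size; fine for models of this scale.
* Per-cell-line training is embarrassingly parallel but the package
  runs single-threaded for reproducibility.
* The disparity analysis compares models initialized from the same seed;
  with different initializations the PCA picks up init noise and the
  ranking degrades accordingly.
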