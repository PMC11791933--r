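---
title: "Contrastive sequence-structure alignment at desk scale: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contrastive sequence-structure alignment at desk scale: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(struclip)
```

## The problem

Protein language models trained on sequences alone absorb structural
information only implicitly. A direct route is to *align* a sequence
encoder with a structure encoder by contrastive learning: embed the
amino-acid sequence and the backbone C-alpha contact map of the same
protein, project both to a shared space, and train so that the two views of
one protein agree while views of different proteins disagree -- the
CLIP/SimCLR recipe adapted to the sequence/structure pair, with the extra
twist that *intra*-modality repulsion (sequence vs. sequence, structure vs.
structure) is part of the loss.

`struclip` implements that whole training framework at desk scale: tiny
configurable twin transformers, the exact loss, the lightweight-tuning
toolbox (top-K fine-tuning, LoRA, serial/parallel bottleneck adapters with
exact parameter accounting), downstream task heads, the embedding
evaluation suite, and a seeded synthetic-corpus generator, so every claim
in the package is checkable on one CPU in minutes. The full-scale recipe
(a 33-layer, 1280-wide ESM2-class encoder against a Swin-class image
encoder over 500K AlphaFold structures) is represented by a "full"
profile that is used for parameter accounting only and is never trained
here.

## Input representations

**Sequences** are tokenized over the 20 canonical amino acids plus `X`
(any non-canonical letter maps to `X` with a warning), wrapped in
`BEGIN`/`END` tokens, padded with `PAD` when batched, and truncated to the
first `max_len = 512` residues (1022 for the secondary-structure task
preset). The validity mask marks real residues only; `BEGIN`, `END` and
`PAD` are excluded from pooling.

**Structures** enter as C-alpha coordinates (PDB or mmCIF via `bio3d`, or
a plain `index/x/y/z` table). The raw pairwise-distance matrix `C` is
turned into a bounded similarity, per channel,

$$\mathrm{map} = \frac{d - \mathrm{CLIP}(C, d)}{d},$$

where `CLIP` saturates distances at the threshold `d`. The default is
`d = 22` angstrom on all three channels (the value AlphaFold uses for its
distogram cutoff); three channels exist to satisfy image-encoder input
conventions, and per-channel thresholds are configurable because three
identical channels are otherwise redundant. Values are 1 on the diagonal
and 0 at or beyond the threshold; the transform is monotone in distance
and invariant to rigid motions. Maps are truncated to the same `max_len`
residues as the sequence, so the pair stays index-aligned; they are then
zero-padded (with an explicit patch-coverage mask) or bilinearly
downscaled (`EBImage`) to the encoder's input resolution.

## Encoders, pooling, projectors

The sequence encoder is a pre-norm transformer (token embedding + learned
positions, multi-head self-attention, ReLU feed-forward, final layer
norm). The structure encoder is a small vision transformer over contact-map
patches: the specification here is a *contract* -- any patch encoder with
masked pooling satisfies it -- and a plain patch transformer keeps the
desk-scale artifact simple; windowed hierarchical attention is not needed
at a 32-pixel input. Patches excluded by the coverage mask are masked out
of both attention keys and pooling, so padding content can never leak into
an embedding.

Protein-level embeddings are the arithmetic mean of residue (or patch)
embeddings over the validity mask. Each modality then owns a projector of
two dense layers (ReLU between; the nonlinearity is unstated in the
reference description, and ReLU is the package default) with output
dimension 256.

Learned positional embeddings are initialized at sd 0.02 (the standard
BERT/ViT convention). This matters more than it looks: with large fixed
positional signals, every pooled embedding shares a dominant common
component, all cosines start near 1, and contrastive training spends most
of its budget undoing that collinearity before any alignment happens.

Two profiles are built in:

| profile | layers | width | FFN | heads | patch | side |
|---------|-------|-------|-----|-------|-------|------|
| `tiny`  | 2     | 32    | 64  | 4     | 8     | 32   |
| `full`  | 33    | 1280  | 5120| 20    | 4     | 256  |

`tiny` is sized so that full contrastive pretraining on the default
synthetic corpus runs in CPU minutes; `full` exists solely so that
trainable-parameter accounting can reproduce the published counts, and is
never instantiated.

## The multi-view contrastive loss

For a batch of `N` paired projections $(E^{seq}_i, E^{str}_i)$ and
temperature $\tau$ (default 0.05), the per-protein loss is

$$L_i = -\log
\frac{\exp(\mathrm{sim}(E^{seq}_i, E^{str}_i)/\tau)}
{\sum_{k \ne i}\exp(\mathrm{sim}(E^{seq}_i, E^{str}_k)/\tau)
 + \sum_{k \ne i}\exp(\mathrm{sim}(E^{seq}_i, E^{seq}_k)/\tau)
 + \sum_{k \ne i}\exp(\mathrm{sim}(E^{str}_i, E^{str}_k)/\tau)},$$

with cosine similarity throughout, and the batch loss is the mean over
`i`. As written in the reference description the indicator $1_{k\ne i}$
applies to all three denominator sums, i.e. the positive pair is *not* in
the denominator -- this differs from standard NT-Xent. The package
implements the literal form by default and provides
`include_positive_in_denominator = TRUE` for the standard variant; both are
oracle-tested, and which one the original released code used cannot be
determined from the equation alone. The loss is sequence-anchored (one
term per protein, not symmetrized over modalities); a `symmetrize` flag
exists, default off. Everything is computed through log-sum-exp with max
subtraction, and the analytic gradient (`multiview_loss_grad`) is verified
against central finite differences.

Useful closed forms used in the tests: if all four embeddings of an `N = 2`
batch coincide, $L = \log 3$ regardless of $\tau$; for two orthogonal
pairs at $\tau = 1$, $L = \log 3 - 1$; as $\tau \to \infty$,
$L \to \log 3(N-1)$.

## Lightweight tuning

Three strategies adapt the (frozen) sequence encoder:

* **`finetune_topK`** -- the top `K` transformer layers train, everything
  else is frozen. At `K = n_layers` the embedding tables, final layer norm
  and projector unfreeze too (full fine-tune limit); for `K < n_layers`
  only the layers' internal parameters count, which is the convention that
  reproduces the published 42M-parameter count for `K = 2` with a
  1943-way head.
* **LoRA** -- trainable rank-`r` updates $\Delta W = B A$ scaled by
  $\alpha/r$ on the query/key/value/output projections of the top `K`
  layers. `A` is Gaussian-initialized and `B` zero, so training starts
  exactly at the base model (initialization is unstated in the reference;
  this is the original LoRA convention). With $\alpha = r$ the forward
  pass reduces to $(W_0 + BA)x$.
* **Adapters** -- bottleneck modules $a(h) = W_{up}\,\sigma(W_{down}h +
  b_{down}) + b_{up}$ ($\sigma$ = ReLU) inserted twice per top-`K` layer
  (post-attention and post-feed-forward) under a shared skip connection
  $h' = h + \sum_i a_i(h)$ over `N` parallel adapters, of which at most
  one (the new-task adapter) trains. `W_up` and biases start at zero, so
  an untrained adapter is exactly the identity. The *Structure-Aware
  Module* used during contrastive pretraining is this serial adapter with
  the base encoder frozen; downstream tasks add one parallel adapter
  (`N = 2`).

Because the base weights are frozen and every injected module can be
bypassed, disabling the modules after any amount of training reproduces
the base encoder bit-for-bit -- the no-catastrophic-forgetting guarantee is
structural, and the test suite asserts it at identity precision.

Parameter accounting counts biases and layer-norm vectors; LoRA matrices
carry no biases. A closed-form count (`count_trainable_profile`) agrees
exactly with flag-based counting on instantiated models and, on the
`full` profile, reproduces the published trainable-parameter table:
top-2 fine-tuning with GO BP/MF/CC heads gives 41.8M/40.0M/39.8M (printed
as 42M/40M/40M), LoRA (`K = 16`, `r = 2`) gives 2.8M/0.95M/0.74M (printed
3M/1M/0.7M), and adapter tuning at bottleneck 640 gives 55M/53M/53M. The
adapter bottleneck is never printed in the source; `embed_dim/2` (640 at
width 1280) is back-derived from that table and documented as an estimate.

## Pretraining loop

Two SGD optimizers (momentum 0.9), one per encoder backbone; weight decay
5e-4; global gradient-norm clipping at 1.0; batch size 20 with incomplete
trailing batches dropped (the loss needs `N >= 2`); a sawtooth cyclic
learning rate `lr = lr_max * (1 - (step mod 100)/100)` decaying from
`lr_max` to 0 over each 100-step cycle with instant restart; per-epoch
shuffling from the config seed; per-step TSV logging. All of these
defaults mirror the reference training recipe, including
`lr_max = 0.001`. Mixed precision is named in the configuration for
interface compatibility but rejected: this implementation computes in
double precision for determinism.

One deliberate deviation applies to the *toy alignment study* (below):
`lr_max = 0.01`. The reference value 0.001 belongs to a schedule of
hundreds of thousands of steps; a 300-step toy run under gradient clipping
at 1.0 can move any parameter by at most `lr` per step, so the published
rate cannot traverse the required distance in the toy budget. The package
default remains 0.001; the toy study passes 0.01 explicitly.

Backward passes skip gradient computation for frozen parameters, and when
every layer below the first adapted layer is frozen (the usual
adapter/LoRA setting), activations under that frozen prefix are computed
once per protein and cached for the whole run.

## Synthetic corpus

The generator (`synth_config`, `generate_proteins`) emulates the paired
sequence/structure corpus structure: `n_families = 8` families of
`proteins_per_family = 25` members. Each family draws a segment layout
(helix/strand segments with loop linkers), one sequence motif per segment
class (helix-favoring, strand-favoring, loop pools of amino acids), and an
idealized backbone: helical segments rise 1.5 angstrom per residue on a
2.3-angstrom-radius helix (100 degrees per residue), extended segments rise
3.5 angstrom with an alternating offset, giving ~3.8 angstrom consecutive
C-alpha spacing; segments join at exactly 3.8 angstrom along a
family-specific direction. Members mutate the archetype sequence at
`mutation_rate = 0.1` per residue (structure untouched) and jitter the
backbone with isotropic Gaussian noise of sd `coordinate_noise = 0.3`
angstrom (sequence untouched), so sequence and structure share exactly
family-level mutual information. Family lengths are evenly spaced over
30-600 residues with small seeded jitter -- stratified rather than iid so
that every default corpus contains families beyond the 512-residue
truncation limit and the truncation path is always exercised. Everything
is a pure function of the seed.

What the generator does *not* emulate: self-avoidance and packing of real
backbones, realistic substitution matrices, domain architecture, or any
relation between a family's motifs and those of another family. Passing
tests on this corpus show that the training machinery and metrics behave
as designed -- not that the method reaches any particular quality on real
proteins.

## Evaluation suite

* `displacement_distribution` -- per-protein Euclidean distance between
  embeddings before and after training, in the original embedding space.
* `knn_conservation` -- average overlap of each point's K nearest
  neighbours before vs. after (Euclidean, self excluded, ties broken by
  index order). Sanity anchors: exactly 1.0 under any rigid transform plus
  uniform scaling; about `1/(n-1)` for independent random clouds at
  `K = 1`.
* `adjusted_rand_index` -- closed-form permutation-model ARI, cross-checked
  against `mclust::adjustedRandIndex` to 1e-8.
* `calinski_harabasz` -- `[tr(B)/(k-1)] / [tr(W)/(n-k)]`, cross-checked
  against a per-dimension ANOVA decomposition to 1e-8.
* `cluster_ari` -- seeded K-means (10 restarts, `k` = number of
  ground-truth labels) on the raw embeddings or after a seeded 2-D
  principal-component reduction. The reference clustering protocol reduces
  to 2-D (with t-SNE) before K-means; the package uses principal
  components for that step because the reduction must be deterministic and
  dependency-free here, and reports ARI on both representations.

## The toy alignment study

The package's end-to-end check mirrors the qualitative claims of the
full-scale system on the default synthetic corpus (8 x 25 proteins, fixed
seed), tiny profile, 30 epochs (15 for the adapter-only run), `lr_max =
0.01`, all other training defaults as above:

1. **Alignment** (run A, top-layer fine-tuning): after training, the mean
   cosine similarity of positive pairs in the projected space exceeds the
   mean negative-pair similarity by a clear margin (>= 0.2).
2. **Family structure** (run A): K-means ARI of the protein-level
   sequence embeddings against family labels strictly improves over the
   untrained encoder. Run A fine-tunes the top transformer layer (plus
   final norm and projector) rather than adapters only, because the
   improvement must show up *before* the projector, where adapters alone
   barely move the pooled geometry.
3. **Asymmetric displacement** (run C, Structure-Aware adapters only,
   base frozen): the median displacement of protein-level sequence
   embeddings is smaller than that of structure embeddings -- the frozen
   base plus small adapters can only move sequence embeddings so far,
   while the fully trainable structure encoder reorganizes freely.

Numbers for these checks are computed at run time by
`tests/testthat/test-acceptance.R` and `scripts/acceptance.R`, never
stored. The conserved-KNN figures of the full-scale system (69%/89% at
`K = 10`) require the released 650M-parameter model and are out of reach
by construction; the KNN operation itself is verified through its isometry
and random-cloud anchors instead.

## Numerical choices and degenerate inputs

* Layer norm epsilon 1e-5; log-sum-exp max subtraction everywhere an
  exponential appears; focal-loss probabilities clamped at 1e-12.
* K-nearest-neighbour ties break by index order (documented, stable).
* `fmax` follows the protein-centric CAFA convention: precision averages
  over proteins with at least one predicted label at the threshold;
  recall averages over all proteins; a zero score never counts as a
  prediction, so all-zero score matrices give Fmax 0 rather than an
  undefined precision. The default grid is 0 to 1 in steps of 0.01.
* Empty masks, all-masked patch grids, zero vectors in cosine similarity,
  `N = 1` contrastive batches, `K >= n` neighbour queries, and
  sub-2-label CHI queries are rejected with errors, not silently patched.
* Checkpoints are single-file RDS archives of config plus weights;
  save/load round-trips are bit-exact.

## Known limitations

* The encoders are deliberately small; nothing here demonstrates
  full-scale behaviour (650M parameters, 500K structures).
* The structure encoder is a plain patch transformer, not a hierarchical
  windowed one; the specification treats the encoder as a contract and the
  windowing as an implementation detail of scale.
* The 2-D reduction used in the clustering report is PCA, not t-SNE; at
  full scale the choice matters for the absolute ARI values, which is
  exactly why the raw-space ARI is reported alongside.
* Training runs single-threaded in R; the point is verifiability, not
  throughput.
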