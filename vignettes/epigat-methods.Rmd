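---
title: "Predicting enhancer-promoter interactions with dynamic graph attention"
author: "epigat authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting enhancer-promoter interactions with dynamic graph attention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Enhancers regulate gene expression by physically contacting gene
promoters, often across tens to hundreds of kilobases. Predicting which
enhancer-promoter pairs interact (EPIs) from one-dimensional epigenomic
data is a long-standing problem, and most predictors treat each
candidate pair in isolation. Real regulatory wiring is not pairwise:
one enhancer can drive several promoters, several enhancers can
converge on one promoter, and these relationships form small, densely
wired regulatory neighbourhoods. `epigat` treats EPI prediction as
**edge classification on a bipartite graph**: enhancers and promoters
are nodes, candidate pairs are edges, and a graph neural network with
dynamic (GATv2-style) attention decides, per edge, whether the pair
interacts.

## Data model and preprocessing

The pipeline consumes three inputs: enhancer intervals (BED, 0-based
half-open), gene TSS annotations (TSV with 1-based positions, converted
on read), and seven epigenomic peak tracks (narrowPeak-style BED with
`signalValue` in column 7) for H3K27me3, H3K36me3, H3K4me1, H3K4me3,
H3K9me3, CTCF and DNase. Candidate labels come from a BENGI-style pair
table.

Preprocessing (`prepare_samples()`):

1. **Positive selection** keeps experimentally supported pairs
   (label 1) and collapses duplicate evidence lines.
2. **Promoter mapping** converts each gene to a single promoter
   interval, 1500 bp upstream to 500 bp downstream of its first
   annotated TSS, read in the transcription direction. On the plus
   strand this is `[TSS-1500, TSS+500)`; on the minus strand
   `[TSS-500, TSS+1500)`.
3. **Distance filtering** retains pairs whose enhancer-midpoint-to-TSS
   distance lies in the closed interval [42 kb, 500 kb]. We use the
   midpoint because it is stable under the large length variation of
   enhancers; the bounds are inclusive because the filter describes a
   range of retained distances, not an open window.
4. **Negative sampling** draws, for each positively interacting
   enhancer, as many negatives as it has positives, from promoters in
   the same distance range that show **no observed interaction at
   all**. This interpretation matters: if negatives were allowed to
   reuse promoters that interact with *other* enhancers, both endpoints
   of most negative pairs would carry active chromatin signal and
   per-element epigenomic features could not separate the classes (on
   our synthetic fixture the node-level separability ceiling drops to
   AUC ~0.62). Sampling interaction-free promoters matches both the
   biological notion of a negative (a promoter without evidence of
   regulation in that range) and the observed performance of
   feature-based EPI predictors. The quota rule caps negatives at the
   positive count per enhancer; when candidates run out the negative
   set is smaller and a warning is raised.

## Feature matrices

Each element is summarised by a **7 x 21 matrix**: seven marker rows
and 21 window columns. Window 0 is the element interval itself
(variable length); ten abutting 2 kb windows extend from each boundary
(the 2 kb width equals the promoter length). Windows are clamped at
chromosome ends; fully clamped windows are kept as zero-width columns
so the shape never changes.

Within each window, all other annotated elements are **masked out**, so
a promoter sitting inside an enhancer's flank does not contaminate the
enhancer's profile. The remaining sub-intervals are aggregated per
track as an overlap-length-weighted (per-base) mean of peak
`signalValue`, with uncovered bases contributing zero; a zero-width or
fully masked window scores 0, indistinguishable from "no signal", which
is the intended semantics.

Normalization is fitted on the **training split only** and applied
everywhere: per marker, a z-score (training mean/sd) followed by a
min-max rescale of the z-scores to [0, 1] (training extremes), with
out-of-range values clipped and sd-zero markers mapped to 0. Fitting on
train alone prevents information from held-out elements leaking into
the scaling.

## Graph construction and the connectivity split

One undirected graph is built per chromosome. Nodes carry their feature
matrix, raw degree in the sample graph, and a one-hot type
(promoter `(1,0)`, enhancer `(0,1)`). Both positive and negative
samples become edges, each carrying two features: the pair distance
rescaled linearly from [42 kb, 500 kb] to [0, 1], and the edge type.

Random pair-level splits leak information: the same enhancer (or its
graph neighbourhood) appears on both sides of the split. We instead
assign whole **connected components** (computed over positive and
negative edges together, which makes the no-sharing guarantee strict)
to train/validation/test, targeting 3:1:1 edge shares per chromosome by
a greedy largest-first assignment to the most-deficient split.
Components of equal size are taken in seed-shuffled order; a chromosome
with fewer than three components goes entirely to training with a
warning. The result is checked, not assumed: tests assert zero shared
nodes and edges between any two splits.

On held-out edges the type feature is replaced by the sentinel 0.5 (the
uninformative midpoint of the train encodings 0 and 1) before anything
reaches the model; labels are kept outside the graph for evaluation
only. We mask validation edges exactly like test edges so that model
selection cannot exploit label information either.

## The model

All neural components are implemented in base R (vectorised forward
pass and hand-derived backpropagation), with correctness pinned by two
independent mechanisms in the test suite: a straight-line loop
implementation of the whole forward pass, and central finite-difference
checks of every parameter gradient.

**Per-node CNN encoders.** Enhancers and promoters get independent
CNNs (`cnn_e`, `cnn_p`). The convolution kernel is `(1, k)` — it
slides along the 21-window axis only, never mixing markers, so each
channel learns positional patterns of a single mark. The stack is
convolution, LeakyReLU (slope 0.2), max-pool along the window axis,
flatten, dense projection to a 32-dimensional embedding:

$$x_{conv} = \mathrm{LeakyReLU}(W_{conv} * x + b), \quad
  x_{pool} = \mathrm{MaxPool}(x_{conv}), \quad
  x_{cnn} = W_{fc}\,\mathrm{Flatten}(x_{pool}) + b_{fc}.$$

**Node input.** The embedding is concatenated with the raw degree and
the one-hot type: $x = [x_{cnn}; x_{deg}; x_{type}]$. The degree is
passed unscaled; its magnitude (1-10 on realistic graphs) is within
the range the attention layer handles without normalisation.

**Dynamic attention (GATv2 ordering).** For a directed message
$j \to i$ with edge features $e_{ij}$, the score is

$$s(x_i, x_j) = a^{\top} \mathrm{LeakyReLU}(W\,[x_i; x_j; e_{ij}]),
  \qquad \alpha_{ij} = \mathrm{softmax}_{j \in N(i)}\, s(x_i, x_j).$$

Applying the nonlinearity *before* the attention projection $a$ is the
key difference from the original GAT: the ranking of neighbours then
depends on the query node $i$ (dynamic attention), which the tests
demonstrate constructively. The node update per head is
$x_i' = \mathrm{ELU}\big(\sum_{j} \alpha_{ij} W [x_i; x_j; e_{ij}]\big)$,
with $H$ heads aggregated by concatenation (default, $H = 4$ heads of
8 units) or averaging. No self-loops are added: the neighbourhood is
exactly the sample edges.

**Edge attention classifier.** For edge $(i, j)$, oriented enhancer
first, $e'_{ij} = [x_i'; x_j'; e_{ij}]$ is weighted elementwise by a
learned attention vector $a_e$, passed through an ELU and a linear
layer: $p = W_{clas}\,\mathrm{ELU}(a_e \odot e'_{ij}) + b_{clas}$. We
chose elementwise weighting over a scalar dot-product gate because it
lets the classifier modulate individual feature channels; the
orientation convention is fixed so undirected edges always present the
same face to the classifier.

**Choices where the architecture was open.** Hidden sizes (8 conv
channels, kernel 3, pool 2, embedding 32, 4 heads of 8), the ELU as
the update nonlinearity (consistent with the classifier's ELU), and
LeakyReLU slope 0.2 are conventional defaults, all exposed in
`model_config()` and recorded in checkpoints.

## Training and evaluation

The loss blends binary cross-entropy on $\sigma(p)$ with a hinge loss
on the raw logit under the $\pm 1$ label map $y' = 2y - 1$:

$$L(p, y) = w\,\mathrm{BCE}(\sigma(p), y) +
  (1 - w)\,\mathrm{mean}\,\max(0,\, 1 - y' p),$$

with $w = 0.5$ by default. The hinge term pushes confident margins for
borderline edges; the limits $w = 1$ and $w = 0$ recover the pure
losses exactly (tested as closed forms).

One model is shared across all chromosome subgraphs. Each epoch
iterates the chromosomes, runs a full-subgraph forward pass (the
subgraphs are small enough that neighbour sampling is unnecessary),
computes the loss **on training edges only**, and applies one Adam
update (lr $10^{-3}$) per subgraph. Because splits are whole
components, messages never cross split boundaries, so held-out edges
contribute no gradient — a property the tests verify by deleting the
held-out components outright and recovering the identical training
trajectory. Validation AUC drives early stopping (patience 20) and the
returned checkpoint is the best-validation epoch.

Evaluation reports AUC by trapezoidal integration of the ROC curve
(equivalent to the Mann-Whitney statistic with half-credit for ties,
cross-checked against both a brute-force pair count and an independent
ROC implementation), AUPR by step integration of the precision-recall
curve, and TPR, FPR and precision at probability threshold 0.5. FPR is
computed as FP/(FP+TN), the standard definition of the false positive
rate.

## The synthetic fixture generator

The generator builds a complete toy study in the package's input
formats, with known ground truth:

- **Elements in loci.** Elements are placed in loci of 6-10 elements
  spaced 45-80 kb apart, with inter-locus gaps larger than 520 kb —
  beyond the 500 kb pairing radius — so regulatory neighbourhoods are
  confined and the EPI network forms many discrete connected
  subgraphs, the archipelago structure characteristic of real EPI
  networks. A 42 kb chromosome-end margin keeps all 21 windows
  unclamped.
- **Planted topology.** Components are grown per seed enhancer from a
  configurable mix of one-to-one, one-to-many (in either direction) and
  many-to-many patterns; a second pass attaches most remaining
  enhancers to already-regulated promoters, reproducing the skew seen
  in real data where most enhancers regulate one or two promoters while
  some promoters accumulate high degrees. Ground-truth component ids
  are recorded per pair and verified against a brute-force census.
- **Signal planting.** Tracks are narrowPeak files whose peaks tile
  each element's 21 windows. Signal is a baseline of 1.0 plus Gaussian
  noise (`noise_sd`); elements participating in a positive pair
  additionally receive `signal_effect` on the active markers (H3K4me1,
  H3K4me3, CTCF, DNase), decaying linearly over window offsets 0, 1, 2
  — emulating the empirical finding that the central window carries
  the most discriminative signal. Repressive marks stay at noise
  level, giving the feature-importance analysis a known null.

The benchmark configuration (`benchmark_config()`) uses 4 chromosomes
of 33 Mb, 250 enhancers and 500 promoters (roughly 700 elements, ~650
of which enter the sample graph), yielding about 350-400 positive and
as many negative pairs, with `signal_effect = 2.5` against
`noise_sd = 0.5` — a five-standard-deviation planted effect. These
sizes give each chromosome 25-35 connected components, enough for the
3:1:1 split to be meaningful, while a full train-and-evaluate cycle
stays around half a minute.

**What the fixture does not emulate.** Peaks are aligned to windows and
never overlap; real peaks straddle window boundaries and replicates
disagree. Signal enrichment is binary (interacting or not) rather than
graded by activity. Distances are uniform within loci rather than
following the empirical contact-frequency decay. Chromatin context
(e.g. repressive domains) is absent. Passing the synthetic benchmark
therefore demonstrates that the machinery — featurisation, leakage-free
splitting, the network, and training — recovers a planted signal of
realistic geometry; it does not certify real-data accuracy.

A negative control re-runs the identical pipeline with permuted sample
labels; held-out AUC collapses to chance (~0.5), confirming that the
pipeline offers the model no route to the labels other than the
planted signal. The control is evaluated on the union of validation
and test edges: the best-validation checkpoint is a maximum over many
noisy epochs, so judging the control on a single small split would
confound selection noise with leakage.

## Network topology statistics

Topology statistics are computed on positive edges only — negatives
are sampling artifacts, not regulatory structure:

- **Degree distributions** per node type, with quantiles.
- **Bipartite clustering coefficient (BCC)** per node, using the
  pairwise intersection-over-union form: for same-type nodes at
  distance 2, $cc(u,v) = |N(u) \cap N(v)| / |N(u) \cup N(v)|$,
  averaged over $u$'s distance-2 neighbours. This form has the two
  anchor behaviours a BCC needs here: 0 for an isolated interaction
  pair, 1 inside a complete bipartite cluster.
- **Connected-subgraph statistics**: node count, edge count and average
  degree $2E/V$ per component. (Note that for a bipartite component,
  $2E/V$ above ~6 requires dozens of nodes per side; isolated reports
  of higher averages on small subgraphs usually indicate averaging over
  a node subset.)
- **Cross-dataset intersection** of pair sets keyed by
  (enhancer, gene): per-dataset unique proportions, pairwise shared
  counts, and the list of universally shared interactions.
- **Random-forest feature importance**: elements are labelled by
  whether they participate in a positive interaction, the 7 x 21
  matrix is flattened to 147 predictors, and mean-decrease-in-Gini
  importances are reshaped back to marker x window and normalised to
  sum to 1. On the fixture, the planted central windows of active
  markers dominate, and pure-noise features yield near-uniform
  importances.

## Numerical and degenerate-input conventions

- Coordinates are 0-based half-open internally and in BED; TSS TSVs are
  1-based and converted on read.
- The distance metric (midpoint-to-TSS) and all filter bounds are
  recorded in the fixture manifest so alternates can be configured.
- Softmax scores are max-shifted before exponentiation; attention rows
  sum to 1 within 1e-6.
- Components are labelled canonically by their lexicographically
  smallest member, making labels invariant to node order.
- Equal-size components tie-break by seed-shuffled order; all sampling
  runs under private RNG streams (`withr`-style seed save/restore), so
  package functions never perturb the caller's RNG state.
- A single-class evaluation subset yields `NA` AUC with a warning
  rather than an arbitrary number.
- Checkpoints serialise to JSON at full precision; reloading reproduces
  predictions bit-for-bit to numerical tolerance.

## Known limitations

- The trainer is CPU-bound, single-threaded R; it is sized for graphs
  of a few thousand edges per chromosome, not genome-scale atlases.
- One promoter per gene (the first annotated TSS) ignores alternative
  promoters.
- Trans (cross-chromosome) pairs are rejected rather than modelled.
- The 42 kb lower distance bound excludes proximal regulation by
  construction; it is applied as a hard filter.
- Negative quotas cannot exceed per-enhancer positives, so datasets
  where negatives outnumber positives per cell line cannot arise from
  this sampler.
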