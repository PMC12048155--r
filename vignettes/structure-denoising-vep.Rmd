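---
title: "Denoising a residue graph: the model behind structvep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Denoising a residue graph: the model behind structvep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(structvep)
```

## The problem

Zero-shot variant effect prediction ranks amino-acid substitutions of a
protein without any assay-specific labels: a self-supervised model is trained
once on wild-type proteins, and the plausibility it assigns to a mutant
residue, relative to the wild type, is used as a fitness surrogate.
Sequence-only language models capture long-range statistical constraints but
encode a residue's spatial microenvironment only implicitly; structvep couples
per-residue sequence encodings with an explicitly geometric, equivariant graph
network over the backbone structure, pre-trained by recovering residues from
noisy observations.

## Protein representation

A parsed backbone (`parse_structure()`) yields, per residue, the N, CA, C and
O atoms (O reconstructed from ideal peptide geometry when absent) and a
C-beta, virtual where no side chain is present, so glycine participates in all
distance features. The protein becomes a directed k-nearest-neighbour graph
over residues (`build_residue_graph()`): each residue connects to its (up to)
`k` spatially closest peers by CA–CA distance, restricted to 30 Å; node
coordinates are the CA positions.

Each edge carries a 93-dimensional attribute vector built from three
ingredient families:

* **25 inter-atomic distances** — all pairs between the {N, CA, C, O, CB}
  atoms of the two residues, in Å, clipped at the 30 Å cutoff;
* **12 local-frame coordinates** — the N and C atoms of both residues
  expressed in the orthonormal frame constructed from (N, CA, C) of the
  source residue;
* **a 56-wide sinusoidal encoding** of the signed sequence offset
  (transformer-style interleaved sin/cos over geometrically spaced
  frequencies).

Only the total dimension (93) and the three families are pinned down by the
design; the exact 25/12/56 split is this package's reconstruction and each
block is independently configurable (`graph_config(pe_dims = ...)`). All
blocks are functions of internal geometry and sequence offsets only, so the
edge attributes are invariant under rigid motions — verified directly in the
test suite.

Node attributes come from an `embedding_provider()`: either a plain one-hot
encoding over the 33-token vocabulary (20 canonical residues, ambiguity and
gap symbols, and special tokens including `<mask>`), or a precomputed
per-protein table of hidden representations exported from a frozen protein
language model. Running a language model in-process is deliberately out of
scope; the provider interface is the contract.

## Equivariant message passing

Layer `l` updates node features `w_i` and coordinates `x_i` as

```
m_ij     = phi_e(w_i, w_j, ||x_i - x_j||^2, a_ij)
x_i[l+1] = x_i[l] + (1/n) * sum_{j in N(i)} (x_i - x_j) * phi_x(m_ij)
w_i[l+1] = phi_v(w_i, sum_{j in N(i)} m_ij)
```

with `a_ij` the static edge attributes (read-only throughout). `phi_e`,
`phi_x`, `phi_v` are two-layer perceptrons with a smooth (SiLU) nonlinearity;
`phi_x` emits a raw scalar gate with no final nonlinearity. Because every
geometric quantity enters through squared distances and relative difference
vectors, node features are invariant and coordinates equivariant under
rotations and translations, and all outputs are permutation-equivariant under
node relabelling.

Design points that were genuinely open, and how they were settled:

* **Aggregation support.** Messages are summed over the kNN in-neighbourhood,
  not over all ordered pairs: the graph is what restricts communication.
* **Coordinate normaliser.** The update divides by the node count `n` as the
  rule is written; a per-node in-degree normaliser is available behind
  `egnn_config(coord_norm = "indegree")` as a stability option.
* **Input projection.** Whether the first layer consumes the raw node
  attribute width directly is unspecified; the package projects `d -> h` with
  a learned linear map before layer 1.
* **Topology is static.** Coordinates move during message passing, but the
  edge list is computed once from the input structure and never rewired:
  no re-wiring rule is part of the model.
* **Readout.** After `L` layers (default 6), updated coordinates are
  discarded; the final node features alone feed a linear 33-class readout
  whose row softmax is the per-site token distribution.
* **Residuals/normalisation layers** default to off (a residual flag exists).

### Numerical choices

Geometric inputs are Å-scale (distances up to the 30 Å cutoff, squared
distances up to its square) while weights are initialised for unit-scale
inputs, so the message MLP standardises its geometric inputs by fixed
constants (squared distances × 0.01, distance and local-frame blocks × 0.1)
before the first weight layer. The raw attributes stored on the graph are
untouched. Initialisation is Xavier-uniform with two deliberate rescalings:
the gate output layer starts at 1e-3 of Xavier scale so early coordinate
updates are small, and the readout starts at 1e-2 so an untrained model sits
at the uniform-guess loss, ln 33 ≈ 3.497. kNN ties in distance break toward
the lower residue index; degenerate geometry (collinear backbone atoms, < 2
residues) raises errors rather than propagating NaNs.

## Denoising pre-training

Training emulates random mutation pressure: every epoch, every sequence is
independently re-perturbed and re-encoded, and the model is asked to recover
the wild-type residues. The perturbation distribution redraws each site with
probability `p` from a replacement distribution over the 20 canonical
residues (possibly redrawing the same residue); the replacement distribution
defaults to the residue frequencies of the training corpus, recomputed at
corpus load, and `p` defaults to 0.15 — the value is described only as
tunable, and 0.15 mirrors the masking convention below. Alternative
strategies are implemented behind the same interface:

* **mask** — BERT-style: 15% of sites selected; 80% replaced by `<mask>`,
  10% by a random other residue, 10% left unchanged;
* **gaussian** — white noise of variance 0.5 added to the embedding rows;
* **global average** — a perturbed site's embedding row is replaced by the
  mean of the unperturbed rows of the same (post-perturbation) residue
  identity within the protein;
* **sliding window** — the mean of the size-3 centred window, truncated at
  the boundaries.

The loss is the summed softmax cross-entropy of the 33-class readout against
the wild-type one-hot sequence, computed at **all** positions (the objective
sums over the whole sequence; a flag restricts it to perturbed sites for
experimentation). Optimisation is Adam at learning rate 1e-4 by default with
conventional moment defaults; one gradient step per batch, no schedule, no
early stopping. Batches are filled greedily after a seeded shuffle up to
8192 residues; proteins longer than 2000 residues are removed from the corpus
up front. Gradients are hand-derived reverse-mode for this fixed architecture
— including the path through the coordinate updates, whose squared distances
feed every later layer — and are checked against central finite differences
in the test suite.

## Zero-shot scoring

For a wild-type protein, one forward pass on the unperturbed input yields
per-site log-probabilities over the 33 tokens — the reference state shared by
all mutants of that protein. A mutant with sites `T` scores

```
F = sum_{t in T} [ log p(mutant residue at t) - log p(wild-type residue at t) ]
```

Self-mutants score exactly zero, uniform rows score zero, and scores are
additive over disjoint site sets (epistasis enters through the joint
representation, not through sequential conditioning). Ensembles over model
configurations (the grids k in {10, 20, 30} and hidden width in
{512, 768, 1280} at full scale) are combined by the arithmetic mean of raw
scores; whether to average scores or ranks is unspecified in the design, so
mean-of-scores is the default with a rank-averaging flag.

## Benchmark curation and evaluation

Thermostability assay tables are curated per protein × condition group:

* melting-temperature mode drops multi-site (continuous) mutants and names
  assays `protein-pH` (pH printed with one decimal, e.g. `O00095-8.0`);
* free-energy mode drops records whose stated wild-type residue cannot be
  aligned with the reference sequence extracted from the structure, and names
  assays `protein-pH-temperature` (integer Celsius);
* in both modes, groups with fewer than 10 surviving mutants are dropped.

Evaluation is Spearman's rank correlation per assay (average ranks for ties;
constant vectors are an error, not an NA), with the unweighted macro mean
across assays. The bootstrap summary resamples 50% of the **assays** per run,
without replacement, for 10 independent runs, and reports the mean and
standard deviation of the run means. Whether the published procedure
resamples assays or mutants, with or without replacement, is not stated; the
assay-level/without-replacement reading is the default because the reported
spread is across assay-level aggregates, and both a per-mutant mode and a
with-replacement mode are provided behind flags.

## What the fixtures emulate — and what they do not

`make_helix_structure()` builds backbones from ideal internal coordinates
(bond lengths 1.458 / 1.525 / 1.329 Å, helical dihedrals phi = -57°,
psi = -47°, omega = 180°), giving the characteristic 3.8 Å consecutive CA
spacing and i → i+3/i+4 spatial contacts that exercise the local-environment
pathway — a random coil would make the kNN graph nearly chain-like. The
default corpus applies a rigid per-residue Gaussian displacement of 0.3 Å
(thermal-displacement scale): it breaks the helix's periodic self-similarity,
which matters because a mathematically perfect helix makes interior residues
geometrically indistinguishable, while intra-residue geometry stays ideal.
Sequences are uniform-random over the canonical alphabet.

Planted-signal assays (`make_synthetic_assay()`) draw random single-site
mutants and score them under a known log-probability table plus Gaussian
noise, so a scorer holding the planted table achieves rank correlation 1 at
zero noise and the correlation decays monotonically with the noise level —
both properties are tested.

What passing these tests does **not** show: fixture helices have no tertiary
packing, no beta sheets, no side-chain chemistry, and their sequences carry
no evolutionary statistics, so desk-scale results say nothing about
correlation levels attainable on real deep-mutational-scanning data — that
requires full-scale pre-training on a real structure corpus with a frozen
language-model embedding provider, which this package supports as a recipe
(table-mode provider + the training CLI) but does not reproduce.

## Desk-scale problem sizes

The shipped tests and the pipeline run at sizes chosen to exercise every code
path on a single CPU: corpora of 3 proteins × 30 residues, hidden widths
16–64, k = 10, and a few hundred training epochs (the desk-scale runs use a
learning rate of 2e-3 — Adam's per-parameter step scales with the learning
rate, and at ~10^5 parameters and ~10^2 epochs the full-scale default of 1e-4
would barely move the weights). Because each epoch re-perturbs the corpus,
the per-epoch loss is itself a noisy estimate; converged behaviour is read
from the tail average of the trace.

```{r, eval = FALSE}
corpus <- make_corpus(fixture_spec(n_proteins = 3, length_range = c(30, 30),
                                   seed = 1))
model <- train_denoiser(
  corpus,
  graph_conf = graph_config(k = 10),
  egnn_conf = egnn_config(layers = 6, hidden = 64, input_dim = 33,
                          message_dim = 64),
  train_conf = train_config(lr = 2e-3, epochs = 600, seed = 1)
)
autoplot(model)
recovery_rate(model, corpus)
```

## Known limitations

* Pure-R training: practical for desk-scale corpora and for studying the
  method, not for pre-training on tens of thousands of structures.
* The 25/12/56 edge-attribute split is a reconstruction; an upstream
  featurisation may differ in detail while keeping the same total width.
* "Closest" neighbours are measured CA–CA; that metric choice is an
  assumption.
* Multi-chain files are supported by concatenation in file order; sequence
  offsets across chain boundaries use raw residue-order differences.
* Insertions and deletions are not scored (substitutions only), and the
  autoregressive likelihood-ratio scoring used by generative baselines is out
  of scope.
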