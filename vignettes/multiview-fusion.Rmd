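---
title: "Multiview graph attention fusion for spatial transcriptomics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiview graph attention fusion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Spatially resolved transcriptomics (SRT) measures a count vector per spot
(a capture spot or a single cell) together with the spot's position in the
tissue, and often a histology image. Spatial-domain detection asks for a
partition of spots into spatially coherent regions that share expression
and morphology. `spotfuse` builds one low-dimensional embedding per spot by
fusing four information sources — expression, histology, location, and
gene–gene association — and uses that embedding for domain detection,
denoising, 3D multi-slice analysis, and the discovery of *spatial dark
genes* (SDGs): genes whose spatial organisation is invisible at the
per-spot level but emerges after neighbourhood averaging.

# Feature extraction

## Expression features: a negative binomial autoencoder

Counts for the top-`hvg_count` variable genes (variance of log
size-factor-normalised counts, deterministic gene-id tie-break) are encoded
by an MLP autoencoder with frame `[G, 1000, 50, 1000, G]` (`G` = number of
selected genes). The reconstruction likelihood is negative binomial: the
decoder's mean head emits per-gene proportions through a row softmax,
scaled by the spot's library size, so the reconstructed means live on the
count scale and a per-slice global library shift cannot enter the latent
space; the dispersion head is a softplus, so both NB parameters are
positive for any latent value. The per-entry loss is

$$-\log \mathrm{NB}(x;\,u,\,\theta) = -\left[\log\Gamma(x+\theta)
 - \log\Gamma(\theta) - \log\Gamma(x+1)
 + \theta\log\tfrac{\theta}{\theta+u} + x\log\tfrac{u}{\theta+u}\right],$$

verified against an independent log-pmf to 1e-8 relative error. Training
is full-batch Adam (published operating point: learning rate 8e-5, weight
decay 1e-6) with dropout and batch normalisation on the hidden layers. The
mean head is config-switchable to a plain softplus; the softmax/library
parameterisation is the default because the softmax appears in the model's
published description and the library factor makes it well defined. The
published description writes the objective as an expectation over an
encoder distribution but specifies neither sampling nor a KL term; the
encoder is therefore deterministic here.

The same architecture embeds the conditional degree matrix (below) to
produce the node features of the gene-association view — degrees are
non-negative integers, so the NB likelihood applies unchanged.

## Visual features: contrastive learning on patches

Per-spot image tiles are augmented twice (random crop with
nearest-neighbour resize back, per-channel colour jitter, Gaussian blur)
and embedded so that the two views of the same tile agree: the NT-Xent
loss with cosine similarities at temperature `tau`,

$$\ell(i,j) = -\log\frac{\exp(s_{ij})}{\sum_{k \ne i}\exp(s_{ik})},$$

averaged over both orderings of every pair. Tests pin the hand-computed
value $\log(e+2)-1$ for two orthogonal pairs at `tau = 1`, rotation
invariance, and the forced zero for a single pair. When labels exist, the
encoder is fine-tuned from the first of the three projection layers (the
"kept half" of the head) with cross-entropy; an optional distillation step
trains a smaller student on the teacher's softened class probabilities
(the distillation loss minus the teacher entropy is a KL divergence, and
is non-negative by construction).

At the 32-pixel patch scale this package targets, the encoder is a
multilayer perceptron over block-mean-downsampled pixels rather than a
convolutional stack: on solid-colour-plus-noise tiles the MLP reaches the
same linear-probe accuracy at a small fraction of the CPU cost, and every
loss, contract and test is independent of the encoder family. The printed
similarity formula is typographically ambiguous about whether the
temperature multiplies or divides; the NT-Xent standard (cosine divided by
temperature) is used.

# View graphs

All three views share one graph format: nodes are spots carrying a feature
matrix, and each edge carries a multidimensional strictly positive feature
vector. Edges are the symmetric k-nearest-neighbour pairs (default 6)
under the view's natural metric — cosine distance on visual features
(HSG), Euclidean distance on coordinates (SLG), cosine distance on
expression features (GAG) — with distance ties broken by spot index.

* **HSG / GAG channels**: cosine similarity, `exp(-||a-b||_2)`, and Pearson
  correlation (0 for a constant vector). The printed denominator of the
  first channel is ambiguous between a product and a sum of norms; cosine
  (the product) is used.
* **SLG channels**: planar dot product over planar distance, the indicator
  of distance `<= lambda`, and the indicator of `|dy| <= mu`. The
  within-`mu` direction is printed twice and its opposite once in the
  source material; the twice-printed form is the default with a config
  flag to flip. The published operating point is `lambda = 200`,
  `mu = 10`, in the units of the coordinate file (no pixel convention is
  imposed). In 3D mode a fourth indicator `|dz| <= xi` connects adjacent
  slices; `xi` defaults to the smallest inter-slice gap.

The graph attention encoder requires strictly positive edge features.
Correlation-type channels are mapped by the affine `(x+1)/2 + eps`
(monotone, invertible); binary and already-positive channels are shifted
by `eps`; the unbounded SLG dot-product channel is rescaled by its maximum
absolute value before the affine map.

## The gene-association view

For every cell `k`, gene pair `(x, y)` and conditioning gene `z`, the
conditional association statistic is

$$\rho^{(k)}_{xy|z} = \frac{n_{xyz}}{n_z}
  - \frac{n_{xz}}{n_z}\cdot\frac{n_{yz}}{n_z},$$

where the `n` terms count cells falling in expression windows (width
`boxsize` per-gene standard deviations, centred on cell `k`'s value,
truncated at zero). The statistic is standardized by the null sd
`sqrt(n_{xz} n_{yz} (n_z-n_{xz})(n_z-n_{yz}))/(n_z^2 sqrt(n_z-1))` — the
same form used by cell-specific network methods — and an edge is drawn
when the standardized value exceeds the upper normal quantile at level
`alpha` (defaults `alpha = 0.5`, `boxsize = 1.5`, `kk = 1`). Conditioning
genes default to the top-`kk` hubs of an unconditional pass; with several
conditioning genes an edge must be significant under each of them. The
genes-by-cells matrix of per-cell degrees is embedded by the autoencoder
to give the GAG node features, while expression features supply its edge
features. The per-cell network is restricted to the top `gag_genes`
(default 100) variable genes: the statistic costs `O(genes^2)` per cell,
and association hubs concentrate in the high-variance set.

# The edge-feature graph attention encoder

Each layer computes attention logits
`f_ij = exp(LeakyReLU(a^T [W x_i || W x_j]))` (clamped to `[-30, 30]`
before exponentiation as an overflow guard), modulates them channel-wise
by the incoming edge features, and normalizes every channel to a doubly
stochastic matrix:

$$\tilde{E}_{ijp} = \frac{\hat{E}_{ijp}}{\sum_k \hat{E}_{ikp}}, \qquad
  E_{ijp} = \sum_k \frac{\tilde{E}_{ikp}\tilde{E}_{jkp}}
  {\sum_v \tilde{E}_{vkp}}.$$

Both stages use the row-normalised matrix; this is the only reading under
which the output is symmetric with unit row sums, which is asserted per
channel in tests. The normalised attention aggregates transformed node
features per channel; the channel concatenation (ELU activation) is the
layer output, and the attention tensor becomes the next layer's edge
features, so edge information adapts across layers. Normalisation runs on
the graph support at the first layer (off-support entries are zero); deeper
layers operate on the support the attention itself induces.

Training combines an inner-product adjacency decoder
`A' = sigmoid(R R^T)` under mean binary cross-entropy over all `n^2` pairs
with a weight-8 cross-entropy over the weakly labeled spots (the printed
reconstruction term is a self-entropy, constant in the parameters; it is
read as the stated "cross-entropy between the adjacency matrices", which
is the gradient-bearing form). Class predictions go through a linear head
before the softmax so the latent width is not forced to equal the number
of classes. Two layers with output widths 128 and 32 are the default; the
desk-scale fixtures in the tests use 32 and 16.

The implementation is dense (masked matrices); an independent brute-force
loop implementation is kept in the test suite and the two are required to
agree to 1e-5 on all random graphs with up to 6 nodes.

# Fusion

The per-view embeddings are linearly projected to a common width (default
32), stacked as the channels of a `C x spots x width` map, and passed
through channel attention (a per-position two-layer MLP over channels with
reduction ratio `gamma`, sigmoid gate) followed by spatial attention (a
channel-reducing convolution along the spot axis composed with a
channel-restoring convolution along the latent axis, sigmoid gate). The
fused representation is the channel sum of the gated map, trained jointly
with a linear softmax head by cross-entropy on the labeled spots. Image
convolutions presuppose a raster; a spot sequence has none, so the kernels
run along the spot axis in input-file order and along the latent axis —
an explicitly arbitrary but shape-preserving choice, documented here and
configurable by sorting spots by coordinates beforehand. With all gates
forced open the fused map reduces exactly to the sum of projections,
which is pinned in a test.

The fusion attention is trained purely by label cross-entropy. In a fully
unsupervised run there is nothing to train it with, and its untrained
forward pass is an arbitrary random mixture; the pipeline therefore fuses
by z-scored concatenation of the view embeddings when no labels exist.

# Downstream analyses

**Clustering.** k-means (10 restarts, seeded) on the fused embedding;
when the cluster count is unknown the Davies–Bouldin index selects it over
a candidate range (ties to the smaller k). DBI and average silhouette
width are implemented as reusable functions and verified against naive
textbook implementations to 1e-8.

**Spatial pseudo-expression (SPE).** Each spot's SPE row is the arithmetic
mean of the raw count rows of its 15 nearest neighbours in embedding
space (Euclidean, self excluded, index tie-break). SPE is a convex
combination of raw rows per gene, and for iid-noise genes its per-column
variance is about raw/15 — both asserted.

**SVG / SDG calling.** Per gene and cluster, one-vs-rest Wilcoxon
rank-sum tests (normal approximation, tie-corrected) run on raw counts and
on SPE, with BH correction within each modality. A gene is an SVG when
significant on raw counts, an SPVG when significant on SPE, and an SDG
when SPE-significant but not raw-significant. No fold-change gate is
applied by default (`lfc_min = 0`, configurable): a spatial offset at the
per-spot noise floor produces arbitrarily small fold changes — count
quantisation and zero-truncation compress them further — so a fold-change
gate silently removes exactly the genes the SDG definition targets.

A statistical caveat documented deliberately: SPE values of nearby spots
share neighbours and are positively correlated, so the rank-sum test on
the SPE modality treats dependent observations as independent and its
p-values are anticonservative under the null. This is intrinsic to the
method — the extra sensitivity of the SPE modality *is* this effect. Two
calibrated alternatives were evaluated and rejected: permuting cluster
labels collapses when clusters derive from the same embedding as the
neighbourhoods (SPE is then near-constant within clusters), and permuting
spots per gene is exact but provably removes all extra power of the SPE
modality, because SPE is a linear map of the raw column. SDG calls should
therefore be read as a screening list ranked by spatial coherence, to be
validated downstream, not as a calibrated error rate.

# The simulators and what passing tests show

`simulate_srt` places spots on a jittered square grid (spacing 100
coordinate units, so the default `lambda = 200` spans about two rings) and
assigns domains by the Voronoi regions of random seed points, giving
contiguous domains of known membership. A fifth of the genes are SVGs with
a 4-fold NB mean shift in one domain (dispersion 2, baseline mean 5);
patches are solid domain colours plus pixel noise; labels are the domain
truth. `plant_dark_genes` redraws selected null genes as
`round(base + amplitude * [in domain] + N(0, noise_sd))` clamped at zero
(baseline 10, amplitude 0.5, noise sd 5), and verifies at generation time
that the median raw rank-sum p across planted genes exceeds 0.2 while the
neighbourhood average of the true mean field separates the domains.
`simulate_multislice` replicates one domain geometry across slices with a
per-slice `exp(N(0, sd))` library shift and `z = slice * z_gap`.

What the fixtures do *not* emulate: dropout/zero inflation, cell-type
mixtures within spots, realistic H&E texture, irregular spot layouts, and
per-gene batch effects. Passing tests therefore demonstrate the
correctness of the machinery and recovery under idealised conditions, not
performance on real tissue.

Two structural consequences of the generator design are worth stating
plainly. First, the multi-slice batch effect is a per-slice scalar library
shift, much of which the autoencoder's size-factor normalisation removes;
whether the 2D mode degrades under it is therefore seed-dependent in
unsupervised runs (when residual slice structure leaks into the embedding,
cross-slice edges repair it and 3D wins clearly; otherwise both modes
saturate), and with weak labels both modes are equally perfect. Second,
the planted dark-gene conditions (amplitude 0.5
against noise sd 5 at 400 spots) put the optimal achievable detection
z-statistic at about 1.0 — the planted signal sits at the statistical
detection floor, and any sensitivity above it reflects the
anticonservative SPE testing described above.

# Numerical and reproducibility choices

* All trainable components run on a small reverse-mode automatic
  differentiation engine over dense matrices included in the package;
  gradients are property-tested against central finite differences.
* Desk-scale problem sizes used throughout tests and the acceptance
  script: 150–400 spots, 100–200 genes, autoencoder 64/16, encoder widths
  32/16, 50–100 epochs. Defaults in `spotfuse_config()` reflect the
  published full-scale operating point.
* Every stochastic step derives its seed from `config$seed` with fixed
  offsets; k-means restarts, dropout masks, augmentations and weak-label
  subsampling are all seeded. A run's manifest (config, seed, mode, views)
  reproduces every TSV artifact bit for bit via `run_from_manifest()`.
* Degenerate inputs have defined behaviour: constant genes rank last in
  HVG selection and are excluded from testing; isolated graph nodes raise
  an error (the doubly stochastic normalisation is undefined); coincident
  spots raise an error in the SLG distance channel; empty label sets fall
  back to unsupervised operation with a warning.

# Known limitations

Cluster-count selection by DBI inherits k-means' spherical bias; the
spatial-attention axis order is arbitrary for unordered spots; SDG calls
are screening calls (see above); and the conditional network cost grows
quadratically in genes, which is why it runs on a restricted variable-gene
set.
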