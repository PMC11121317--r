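---
title: "Scoring paratope–epitope pairs from interface images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring paratope–epitope pairs from interface images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epipair)
```

## The problem and the model

Whether a given antibody binds a given antigen surface region is decided
almost entirely at the paratope–epitope interface: a few dozen residues on
either side whose shapes and physicochemistry must be complementary. epipair
scores this compatibility by reducing each side of a candidate interface to a
small 2D image and classifying the *pair* of images with a compact residual
convolutional network.

The pipeline is:

1. **Coarse-grained residue representation.** Every residue is represented by
   its Cμ pseudoatom: the arithmetic mean of its heavy side-chain atom
   coordinates, with the Cα standing in for glycine and for residues whose
   side chain is not resolved. Working at the Cμ level removes atomic noise
   while keeping side-chain placement.
2. **Interface definition.** An antibody residue belongs to the paratope (an
   antigen residue to the epitope) iff its Cμ lies within 6 Å of some partner
   residue's Cμ. Because large antigens can also graze the antibody far from
   the antigen-binding site, members farther than 40 Å from the geometric
   centre of the CDRs are removed. When no CDR annotation is supplied the
   centre falls back to the centroid of the antibody interface residues —
   the CDRs are by definition the loops at the antigen interface, so
   interface residues are their natural proxy.
3. **Projection.** A principal component analysis of each patch's points
   defines an oriented plane; residues are drawn at their in-plane
   coordinates as filled circles whose radius reflects residue size
   (`r = (3V/4π)^{1/3}` from mean residue volumes), coloured by
   min–max-scaled polarizability (red), isoelectric point (green) and
   hydrophobicity (blue), with the residue's distance to the plane mapped to
   transparency. A per-atom mode draws each heavy side-chain atom as a
   1 Å circle instead.
4. **Classification.** The two 100×100 (or 64×64) RGB images are stacked into
   a six-channel tensor and scored by two stacked ResNet blocks
   (3×3 convolutions, 32 kernels, leaky-ReLU activations, a 1×1-projection
   skip on the first block), parallel max- and average-pooling with window 4,
   a dropout-regularised dense head and a sigmoid. Ten models trained in
   stratified cross-validation score jointly as the mean of their sigmoid
   outputs.

## Geometric conventions

PCA planes have sign ambiguities that would otherwise make images depend on
the input orientation. epipair fixes them deterministically:

* the normal `n` points from the patch centroid towards the partner patch;
* `e1` is flipped so the third central moment of the projected u-coordinates
  is non-negative (an exact tie falls back to a lexicographic rule on residue
  identifiers);
* `e2 = n × e1`, giving a right-handed orthonormal frame.

The two patches of a cognate pair are projected in their *own* frames, each
looking at the other, so they are rendered as two opposed views; the epitope
image is therefore mirrored about the u axis so that spatially corresponding
residues land on corresponding pixels. The mirror is applied to the epitope
(not the paratope) as a fixed, arbitrary convention.

With these rules the image pair of a complex is exactly invariant under
rigid motions of the whole structure. To make that invariance *bit-exact*
despite floating-point noise in the eigendecomposition, the rasteriser
quantises coordinates, depths and opacities to 10⁻⁶ Å — far below any
physical precision (PDB files carry 10⁻³ Å), far above numerical noise.
Rasterisation itself is analytic (a pixel is covered iff its centre lies in
the circle; hard edges; painter's algorithm drawing the farthest-from-plane
circle first so interface-proximal residues win overlaps), which keeps
renders reproducible across platforms, unlike a plotting backend.

## Feature tables

The physicochemical scales are taken from the `aaindex` collection
shipped with seqinr: Charton–Charton side-chain polarizability
(`CHAM820101`), the Zimmerman isoelectric point (`ZIMJ680104`) and the
Kyte–Doolittle hydropathy index (`KYTJ820101`), each min–max scaled to
[0, 1] over the 20 standard amino acids. Circle radii derive from
Zamyatnin-type mean residue volumes. All four tables are returned by
`feature_table()` and can be swapped via the YAML configuration; unknown
residue codes render white and are logged. Ablation switches expose the
distance-toggle (all circles opaque), a four-colour scheme (aromatics green,
positive red, negative blue, rest white) and per-channel knock-outs that
force one of P/I/H to zero.

Transparency uses the linear map `α = clamp(1 − D/d_max, α_min, 1)` with
`d_max = 6` Å and `α_min = 0.1`. Only the mechanism (depth as transparency)
is fixed by the science; the linear form is the minimal choice and both
constants are configurable.

## Dataset construction

Cognate complexes are the positive class. Negatives come from three
generators, all operating on the *native* per-complex renders:

* **non-cognate** — the paratope image of one complex with the epitope image
  of another (never from the same similarity cluster, and always drawn within
  one side of the train/test split);
* **rotated** — the cognate epitope re-rendered with an in-plane rotation
  that is a multiple of 30° with magnitude ≥ 60°. Smaller rotations are
  excluded because the screening binder rule treats ±30° as still-binding;
* **translated** — the cognate epitope displaced by ≥ 8 Å, larger than a
  typical residue circle so the pose is unambiguously wrong.

Zero-rotation and zero-translation "negatives" are unconstructible by
contract: they would duplicate the positive bit-for-bit. The default ratio is
one negative of each kind per positive (3:1 overall); class imbalance is
known not to matter much for this task, so the default favours desk-scale
training.

Splits operate at the complex level: 80 % of complexes train, 20 % test, and
the train side is partitioned into ten folds (so each cross-validation round
uses 90 %/10 % subtrain/validation). Samples inherit the assignment of their
paratope-source complex; since every complex contributes the same
positive:negative composition, per-fold stratification is exact by
construction.

## Training

Kaiming-normal initialisation is used for convolutional layers (matched to
the leaky-ReLU gain) and Xavier-normal for the dense head. Training minimises
binary cross-entropy (scores clipped at 10⁻⁷) with Adam at learning rate
10⁻³, batch size 32, a plateau scheduler (×0.1 after 5 stagnant epochs) and
early stopping after 10 stagnant epochs, tracking the validation loss; the
best-on-validation parameters are returned. The dropout rate on the flattened
feature vector is 0.75. Where the architecture description is ambiguous, the
following choices were made:

* a single parallel max/avg pooling stage after the two-block stack (the
  attribution pipeline's 25×25×64 tensor is only consistent with this
  placement, not with pooling after every block);
* the first block's skip connection uses a 1×1 convolution to lift the
  6-channel input to 32 channels (standard ResNet practice); the second
  block's skip is the identity;
* dropout acts on the flattened pooled vector immediately before the dense
  product;
* early stopping monitors the validation cross-entropy.

The convolution, pooling and unpooling primitives are implemented in
C++ (im2col + BLAS GEMM) with exact double-precision arithmetic; the test
suite holds them to ≤ 10⁻⁶ against direct triple-loop evaluation, and the
backward pass is validated against numerical gradients.

## Attribution maps

The dense head computes a logit as `w · f`, which equals the sum over the
Hadamard product `w ∘ f`. Each element of `w ∘ f` is thus that feature's
signed, exact contribution to the logit. Reshaping the product to the pooled
grid, splitting it into its max- and average-pooling halves, unpooling each
(max: value placed at the cached argmax, zeros elsewhere; avg: value/16
spread over the window, conserving mass) and averaging over the 32 feature
channels yields two image-resolution maps. They are **summed** into the final
map, which conserves the total contribution; a mean-of-two alternative is
exposed via `combine = "mean"`. Average unpooling divides by the window area
rather than replicating, otherwise the reconstruction sum would be inflated
16-fold. Red regions mark pro-binding, blue regions anti-binding pixels.

## Applications

**Pose rescoring** images and scores every docking pose of a complex and
ranks them by descending score (ties broken by pose id); the near-native
pose's rank, averaged over complexes, is the figure of merit. Poses with no
interface under the 6 Å rule receive score 0 and the worst tied rank.

**Library screening** re-renders a target epitope at the twelve multiples of
30° and scores every (paratope, angle) combination. A paratope counts as a
binder if it clears the threshold τ = 0.5 at 0°, +30° and −30°
(configurable); the library ranking metric is the maximum over the twelve
angle scores, with the mean available via configuration. Rotations are
applied in coordinate space before rasterising, so no pixel interpolation is
involved and the 0° entry is bit-identical to the plain cognate score.

## The synthetic data generator

Real antibody–antigen corpora cannot ship with the package, so the fixtures
module generates toy complexes: two roughly planar residue clouds facing each
other 4–6 Å apart, the paratope split across a heavy and a light chain, plus
a non-interface antigen scaffold that brings the antigen above the 50-residue
curation rule. The clouds are anisotropic and deliberately skewed along their
major axis so the PCA frame conventions are stably determined. In *matched*
mode the epitope layout mirrors the paratope and charged residues face their
opposite charge (Arg/Lys ↔ Asp/Glu, aromatics face aromatics), giving
positives the same shape-and-colour complementarity signal that real
interfaces carry; *mismatched* mode draws both sides independently. Residues
get minimal atom sets (a Cα plus 1–3 pseudo side-chain atoms arranged so
their mean is exactly the intended Cμ); no attempt is made at backbone
geometry, loop conformations or energetics.

Consequently, passing the synthetic benchmarks demonstrates that the
pipeline's geometry, rendering, training and ranking machinery work
end-to-end and that the model can learn shape/colour complementarity — it
does not demonstrate performance on real antibody–antigen structures, which
have richer composition, flexible loops and far subtler negatives.

## The desk-scale benchmark

`run_synthetic_benchmark()` is the package's reproducible experiment: 100
matched toy complexes, 64×64 images, 400 samples (1:1:1 negatives), one
cross-validation fold, early stopping. The 64-pixel size and the short
schedule in `benchmark_net_config()` (learning rate 2×10⁻³, at most 16
epochs, early-stop patience 4) are sized for this easy, cleanly separable
task; they are not the defaults recommended for real data, which remain in
`net_config()`. Held-out balanced accuracy and AUROC on this task are
typically around 0.9 and 0.95–0.98, though slow-converging seeds land
lower — the score ranking (AUROC) is more stable across seeds than the
threshold-dependent metrics. `run_screen_benchmark()` (50-paratope
libraries, ten seeded repeats) and `run_rescore_benchmark()` (12 poses per
complex, decoys rotated ≥ 60° about the interface axis) reuse the trained
model; `scripts/acceptance.R` re-runs all of them from scratch.

## Numerical and degenerate-input choices

* Alternate locations: the highest-occupancy conformer wins, ties going to
  altloc "A".
* Residues with no resolved side-chain heavy atoms use their Cα; structures
  are never "repaired".
* Collinear patches (no well-defined plane) raise an error rather than
  guessing a frame.
* Sequence identity for redundancy removal is matches / max(sequence length)
  on a global alignment (match 1, mismatch 0, small gap-extension cost);
  clustering is greedy longest-antigen-first with ties broken by id, so the
  kept set is invariant under permutation of the input.
* Equal-depth circles draw in identifier order; equal-score poses rank in
  pose-id order.
* The channel knock-out invariant (knocked channel exactly zero on covered
  pixels) holds under full opacity; with transparency enabled the knocked
  channel still receives the white background's contribution, which is the
  correct compositing behaviour.

## Known limitations

* The geometric CDR-centre fallback can shift borderline members of very
  large interfaces compared to an annotation-derived centre.
* Per-patch PCA frames with the mirror convention align cognate pairs
  exactly for opposed planar patches; strongly curved interfaces align only
  approximately.
* The greedy identity clustering reproduces the redundancy-removal contract,
  not CD-HIT's word-filter heuristics; borderline clusters near the 0.8/0.9
  thresholds may differ from a CD-HIT run.
* Nanobodies and scFvs (single-chain antibodies) are out of scope; the
  parser requires separate heavy and light chains.
* mmCIF input, hydrogens and structure repair are not supported.
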