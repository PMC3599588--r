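---
title: "A two-layer V1-style model of bottom-up saliency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-layer V1-style model of bottom-up saliency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 5,
                      fig.height = 5, eval = FALSE)
```

## The model

Pre-attentive ("bottom-up") saliency is the stimulus-driven conspicuity that
makes an orientation singleton pop out of a field of distractors before any
task-directed attention is deployed. This package implements a two-layer
network that stays close to the known physiology of the primary visual
cortex and asks how three coding principles — learned overcomplete filters,
invariant (complex-cell style) pooling, and non-classical receptive-field
surround competition — shape saliency detection.

The stages, each an exported function:

1. **Whitened patch statistics.** Square patches are sampled from training
   images, DC-centred, and whitened by PCA: with patch covariance
   $C = V U V^\top$, the transform $W = U_k^{-1/2} V_k^\top$ keeps the top
   $k$ principal components and equalizes their variance
   (`sample_patches()`, `fit_whitening()`, `whiten()`).
2. **Layer 1 — learned topographic filters.** Filters $\Phi_i$ live on a 2-D
   torus grid and are learned from whitened patches by stochastic gradient
   ascent on a topographic energy objective,
   $\sum_p G\!\big(\sum_{i \in p} (\Phi_i^\top z)^2\big)$ with
   $G(u) = -\sqrt{u + \varepsilon}$, where the pools $p$ are 5×5 torus
   neighbourhoods centred on every grid node, followed by symmetric
   orthogonalization (`learn_basis()`). This is the topographic-ICA family
   of estimators: it yields Gabor-like filters whose orientation and
   frequency drift smoothly across the grid, so that grid neighbours have
   correlated energies. (The pairwise-cumulant topographic learner that
   inspired this stage is reported to behave like topographic ICA; we use
   the ICA-style objective directly, since every downstream stage depends
   only on the topography and tuning of the result, not on the estimator.)
   Responses to an image are computed by correlation with the unit-norm
   pixel filters, then rectified to $[0,1)$ (`extract_features()`,
   `rectify()`).
3. **Layer 2 — invariant descriptors.** 5×5 pools tile the torus with a
   stride of 3 (adjacent pools share 2 filters per axis), giving the
   characteristic pool counts 16, 25, 36, 50, 64 for grids of 100, 196,
   256, 392, 576 filters (`build_pools()`). Each pool is refined by the
   energy correlation
   $\rho_{ic} = \mathrm{corr}(SF_i^2, SF_c^2)$ with its centre filter,
   keeping members with $\rho \ge 0.1$ (`refine_pools()`), and pooled
   pixelwise by the energy rule
   $CF_j = \big(\sum_{i \in \Omega_j} SF_i^2\big)^{1/2}$
   (`pool_features()`). Squaring discards phase, so the descriptor responds
   like a complex cell: invariant to exact bar position and tolerant to
   small orientation changes.
4. **Within-feature competition.** Each invariant map is suppressed by its
   own surround: $s_j = \lvert CF_j - \alpha\, (CF_j \otimes \omega)
   \rvert_{\ge 0}$, where $\omega$ is the non-negative, $L_1$-normalized
   form of the difference of Gaussians
   $\mathrm{DoG} = G(\sigma_{ex}) - G(\sigma_{inh})$
   (`dog_kernel()`, `inhibition_weights()`, `suppress()`). Homogeneous
   texture cancels itself; isolated structure survives.
5. **Combination.** Conspicuity maps are merged by iterative sharpening —
   $s \leftarrow \lvert s + s \otimes \mathrm{DoG} - C_{inh}\rvert_{\ge 0}$
   repeated `n_iterations` times per map, then summed
   (`combine_iterate()`). Above 10 maps the clustered variant groups maps
   by their pairwise energy correlation with K-means, average-pools each
   cluster, and iterates the cluster maps (`combine_clustered()`). The
   normalized sum and pixelwise max are kept as baselines (`combine_sum()`,
   `combine_max()`).

Three comparison architectures share layer 1 (`run_variant()`): the
*no-invariance* model suppresses each rectified filter map directly (a
layer-2 receptive field of one), the *fully connected* network pools every
filter into a single orientation-blind map, and the *randomly connected*
network pools random fixed-size filter groups.

## Parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| `patch_side` | 16 (8 in tests) | px | layer-1 RF size; should exceed the inter-element spacing of fine texture |
| `retained_dim` | 196 of 256 | dims | PCA cut; discards the highest-frequency, noise-dominated components |
| `pool_side`, `overlap` | 5, 2 | filters | layer-2 RF size and tiling; 3×3–7×7 behave similarly after refinement |
| `correlation_threshold` | 0.1 | — | refinement cut on the energy correlation with the pool centre |
| `sigma_ex` | 2 | × RF size | excitation bandwidth of the suppression DoG; below 1× RF the competition outruns the feature scale and detection degrades |
| `sigma_inh` | 4 × `sigma_ex` | px | inhibition bandwidth (fixed ratio) |
| `alpha` | 1.8 | — | suppression strength; too small leaves distractors, too large erases the target |
| `n_iterations` | 10 | — | sharpening rounds in combination |
| `C_inh` | 0.02 | map units | constant bias that slowly drains regions where excitation and inhibition balance |
| `n_clusters` | 8 | — | K-means clusters for large stacks |

`sigma_ex` can equivalently be given in pixels or as a fraction of the
image size (`unit = "frac"`, the natural choice for dense edge images,
around 0.018–0.03); `resolve_suppression()` converts.

## Numerical choices

* **Correlation, not convolution.** Layer-1 maps are cross-correlations with
  the unit-norm filters ("same" size), so a map peaks where its filter
  matches the image; for the symmetric DoG kernels the distinction is void.
* **Boundary handling** mirrors the image at its borders everywhere, which
  avoids spurious edge responses from zero padding.
* **Kernel truncation.** Suppression kernels are cut at `3 * sigma_inh`
  (<0.3% of the Gaussian mass). Under the `"center"` convention the
  weights `omega` are additionally cropped to their exact support (they
  vanish beyond the DoG zero-crossing at roughly `2.06 * sigma_ex` for
  the default ratio), which is lossless and much cheaper to convolve.
* **Rectification** uses the zero-preserving sigmoid
  $r(x) = 2/(1+e^{-|x|}) - 1$: an empty background stays at exactly zero
  response, which the downstream half-rectified stages presume. The
  literal logistic (range $[0.5, 1)$) is available as `mode = "logistic"`.
* **Eigenvalue floor.** Whitening refuses directions below $10^{-10}$ of
  the leading eigenvalue rather than amplifying them.
* **Refinement ensemble.** Pool refinement correlations are computed once
  over the training-patch responses cached on the basis (a fixed model
  artifact); a per-image mode exists (`pool_similarity()` on a
  `feature_stack`) for exploratory use.
* **Ties.** The saliency argmax breaks ties in row-major order with a
  warning; K-means clusters are re-ordered by smallest member index so a
  seeded run is bit-reproducible.

## Design choices that were genuinely open

* **Iteration count and pre-iteration normalization.** The combination
  literature fixes the DoG shape (`c_ex = 0.5`, `sigma_ex` 2% of width,
  `c_inh = 1.5`, `sigma_inh` 25% of width, `C_inh = 0.02`) but not how many
  rounds to run nor whether maps are rescaled first. We run 10 rounds:
  winner-take-all between peaks a quarter-image apart has visibly not
  settled after 5 at these kernel scales. Maps are max-normalized before
  iterating, so the dynamics depend only on each map's peak *structure* — a
  map with one dominant peak grows, a map of many comparable peaks
  extinguishes itself — and not on the arbitrary scale a map inherits from
  its pool size or filter gains.
* **Boundary handling in the iteration.** The Eq.-style sharpening update
  computes its DoG as the difference of two *border-corrected* Gaussian
  smoothings (zero-padded convolution divided by the kernel mass that fell
  inside the image). Mirrored padding would reflect a map onto itself and
  up to quadruple self-excitation in the corners; plain zero padding lets
  border pixels escape the inhibition-dominant surround. Either artifact
  promotes border activity to the global maximum; the mass-renormalized
  form treats a constant map identically at the centre and the corners.
* **Order of whitening operations.** DC removal is per patch and happens
  before whitening; PCA reduction and whitening are a single map
  ($U_k^{-1/2} V_k^\top$). Both are configurable.
* **The suppression-weight convention.** Three readings of how the signed
  DoG becomes non-negative weights are implemented. The default takes the
  absolute value, $\omega = |\mathrm{DoG}| / \lVert\mathrm{DoG}\rVert_{L1}$,
  which has unit mass: on a homogeneous field the suppression term then
  equals $\alpha$ times the local activity, so any $\alpha > 1$ cancels
  uniform texture *exactly* — the mechanism behind the fully connected
  network producing a blank map on texture stimuli — while an isolated
  peak only loses the small self-overlap mass and survives. Half-
  rectification (`"center"`, central lobe only) keeps mass ≈ 0.5, so even
  $\alpha = 3.2$ leaves a sizeable homogeneous residue; it and the
  surround-lobe `"annulus"` reading from the non-classical-RF literature
  remain available for comparison.
* **Learning vs pooling neighbourhoods.** The learning objective uses a
  5×5 neighbourhood around *every* grid node (the standard topographic-ICA
  layout, which keeps the topography smooth everywhere); the layer-2
  readout uses the strided 5×5 tiling. Both share the neighbourhood size,
  as the model requires.
* **Random groups** in the randomly connected network are drawn without
  replacement within a group; groups may overlap.

## What the synthetic data emulates

The stimulus module generates the classic psychophysics batteries with
machine-readable ground truth: orientation-singleton arrays (8×8 elements
on a 256×256 canvas, anti-aliased bars, positions jittered within cells;
distractors orthogonal to the target plus uniform orientation noise up to
±45°), composite-element arrays, solid/illusory/noisy s-contours, and
object-in-texture edge images (procedural closed-contour "fruit-like"
objects of ~30 segments over procedural texture line fields, subsampled to
a chosen object:background segment ratio on a 64×64 canvas — synthetic
stand-ins for photographic object and texture edges). The training-texture
generator produces block-structured oriented line fields; patches drawn
from them carry oriented structure at all orientations, which is what the
basis learner needs.

What these generators do *not* emulate: the 1/f spectral statistics,
occlusions, and mixed contrasts of photographs, or human fixation
behaviour. Passing the behavioural tests therefore demonstrates the
mechanisms (pop-out, invariance to orientation noise, homogeneity
suppression, contour continuity, the non-monotone SNR curve) on controlled
stimuli; it does not certify fixation-prediction accuracy on natural
images, which additionally depends on the training corpus and on color and
intensity channels this model does not encode.

## Problem sizes used by the test-suite experiments

The packaged experiments run on a 49-filter basis (7×7 torus, 8×8 patches,
20 000 training patches, 800 learning steps of batch 1000) — deliberately
desk-scale; the pipeline is unchanged at 196 or 392 filters, only slower.
Pop-out experiments use 20 scenes per noise level; the SNR curve uses 18
scenes (3 objects × 6 textures) per ratio in 1:2 … 1:4. The chance level
of the top-`m` criterion is the binomial expression
$\binom{10}{7} p^7 (1-p)^3$, $p = m/(m+n)$; under a truly uniform ranking
the exact law of "object hits among the top 10" is hypergeometric, and the
tests document that the binomial form is an approximation to it (the two
differ by ~20% at $m{=}30, n{=}90$ but both stay far below any observed
detection rate).

## Known limitations

* The procedural object-in-texture scenes are *more* suppressible than
  photographic edge images: the regular textures carry no incidental
  collinear structure at high density and little isolated-segment pop-out
  at low density, so in the strong-suppression regime the top-m detection
  rate sits at its ceiling across the whole tested SNR range instead of
  falling off at the flanks. The interior-maximum property holds, but only
  non-strictly.

* Single scale: no image pyramids; the layer-1 RF size must roughly match
  the stimulus texture scale.
* Grayscale only; saliency caused purely by color contrast is invisible.
* The learned basis (and so every detection rate) depends on the training
  corpus; the procedural textures produce oriented, topographic filters
  but not the full diversity of filters learned from photographs.
* The fully/randomly connected baselines share the combination stage but
  a single pooled map skips it by construction, so their outputs are on
  the conspicuity scale rather than the summed-map scale; comparisons
  should use argmax location or normalized values, as the evaluation
  module does.
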