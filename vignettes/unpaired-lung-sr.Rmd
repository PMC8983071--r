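---
title: "Unpaired super-resolution of lung CT: model, losses, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unpaired super-resolution of lung CT: model, losses, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srcycle)
```

## The problem

Clinical chest CT resolves the lung at roughly 0.6 mm per voxel; micro-CT of
resected lung specimens resolves it at roughly 50 um — about eight times
finer, enough to see alveolar texture and bronchiolar walls that clinical CT
cannot. Super-resolving clinical CT toward the micro-CT scale would let
clinicians see near-microscopic structure in vivo, but there is a
fundamental obstacle: clinical and micro-CT images of the same tissue cannot
be registered into aligned pairs (the specimen is resected, fixed and
deformed before micro-CT), so supervised super-resolution — which trains on
aligned low-resolution/high-resolution (LR/HR) pairs — is not applicable.

`srcycle` implements an unpaired approach built on cycle-consistent
adversarial translation between the two domains, with two asymmetric
generators:

* **G1** (super-resolution): maps an `n x n` clinical patch to a
  `2^k n x 2^k n` micro-CT-scale patch. It keeps feature maps at the input
  resolution throughout (no downsampling blocks — a 32x32 input squeezed
  through three stride-2 blocks would leave 4x4 feature maps and destroy the
  spatial detail the task is trying to amplify), and upscales only at the
  end via `k` sub-pixel shuffling stages.
* **G2** (downscaling): maps a micro-CT patch down to clinical scale with
  `k` stride-2 downblocks.

Two PatchGAN discriminators judge realism in each domain, and a
cycle-consistency loss ties the round trips `G2(G1(x)) ~ x` and
`G1(G2(y)) ~ y`.

## Why plain cycle-consistent translation fails here

The two domains differ not only in resolution but drastically in intensity
distribution: clinical CT is on the Hounsfield scale with lung content
spread broadly over roughly [-1000, 500] H.U., while micro-CT intensities
are scanner-specific and concentrated in a high band. An adversarial
objective alone rewards *looking like* micro-CT; nothing ties the output to
the *input's* anatomy, and in practice the translation hallucinates: vessels
and bronchi move, deform or vanish. The package's contribution-level loss,
the **multi-modality super-resolution (MMSR) loss**, adds direct
cross-resolution constraints between input and output:

* **SSIM loss** `1 - SSIM(x, f_down(x_sr))` (and symmetrically
  `1 - SSIM(y, f_up(y_lr))`): structural agreement between the input and the
  output brought back to the input's size. `f_down` is non-overlapping
  average pooling; `f_up` is nearest-neighbour upsampling — the pair is
  chosen so that `f_down(f_up(x)) = x` exactly.
* **Downsample loss** `mean((x - f_down(x_sr))^2)`: pixel-wise intensity
  agreement on the G1 side.
* **Upsample loss** `mean((y - f_up(y_lr))^2)`: the same on the G2 side.

The total objective is the weighted sum

```
L = l1*LS1 + l2*LS2 + l3*LD + l4*LU + l5*Lgan(G1) + l6*Lgan(G2) + l7*Lcyc
```

with default weights (1.0, 1.0, 0.7, 0.3, 1.0, 1.0, 1.0) — SSIM terms
weighted highest, pixel terms lower, reflecting that structural agreement
contributes most.

## Interpretation choices in the loss layer

Several formulas admit more than one reading; the package pins them as
follows and treats these as design decisions:

* **SSIM numerator.** The luminance factor is implemented in the standard
  Wang et al. form `(2 mu_a mu_b + C1)`. A variant sometimes printed as
  `(mu_a mu_b + C1)` would violate the defining property `SSIM(x, x) = 1`,
  which both the loss's zero-case and the metric rely on.
* **SSIM constants.** `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2` with data range
  `L = 2` for `[-1, 1]` images — the conventional choice; no other values
  are documented for this setting.
* **Adversarial form.** Least-squares GAN (discriminator:
  `0.5 mean((D(real)-1)^2) + 0.5 mean(D(fake)^2)`; generator:
  `mean((D(fake)-1)^2)`), the stable default of the cycle-consistent
  lineage; a log-form objective is available as a configuration switch
  (`kind = "bce"` in `adversarial_loss()`).
* **Squared-norm terms.** Cycle, downsample and upsample losses are squared
  L2 norms of differences *averaged per pixel* (not summed), so the lambda
  weights are resolution-independent.
* **Global vs. windowed SSIM.** The training loss uses single-window
  (whole-patch moments) SSIM, which is cheap, smooth and defined for tiny
  patches; the evaluation metric uses the conventional 11x11 Gaussian
  (sigma 1.5) windowed SSIM. Both are exposed; evaluation reports log both.

## Architecture choices

* Feature width is 64 channels (constant through the residual blocks) in the
  main configuration, following the CycleGAN convention. Parameter totals
  therefore depend on this choice.
* Generator head: 3x3 then 7x7 convolutions, each followed by
  normalization (batch by default, instance optional) and ReLU; 9 residual
  blocks (two 3x3 convolutions, norm, ReLU after the first, additive skip);
  reflection padding throughout; a 7x7 output convolution with tanh keeps
  outputs in `(-1, 1)`.
* Each upsampling stage is conv(64 -> 256) + sub-pixel shuffle (r = 2) +
  ReLU. Sub-pixel shuffling is a bijective channel-to-space rearrangement —
  cheaper than deconvolution and free of checkerboard artifacts.
* Discriminators are PatchGANs (stride-2 kernel-4 stages, LeakyReLU 0.2)
  emitting a score map of local real/fake decisions: 4 stride-2 stages at
  the 256-pixel domain. For smaller domains the number of stride-2 stages
  scales down proportionally (`floor(log2(size/16))`), keeping the score
  map dense (~14x14 at every size). This matters beyond architecture
  aesthetics: adversarial losses are means over the score map, so a
  near-global map with a handful of elements would make the per-element
  adversarial gradient orders of magnitude stronger relative to the
  per-pixel MMSR gradients than at full scale, upsetting the balance the
  default loss weights encode.
* Two ablation generators are buildable: `sr_with_downblocks` (downblocks
  before the residual trunk, then 2k shuffling stages) and
  `upblocks_baseline` (the conventional translation generator with k extra
  upblocks). Upblocks are realized as nearest-upsample + convolution
  (resize-conv), the standard artifact-free equivalent of strided
  deconvolution.
* Weight initialization: zero-mean Gaussian, sd 0.02, seeded.

## The training engine

No deep-learning framework is required: convolutions (im2col + BLAS),
batch/instance normalization, activations, sub-pixel shuffling and their
exact analytic backward passes are implemented in R with Rcpp/Armadillo
kernels, and optimization is a hand-written Adam (betas 0.5/0.999). Every
gradient path — including the SSIM loss through average pooling and the
adversarial term through a frozen discriminator — is differentiated
analytically and verified against finite differences in the test suite.
This keeps the whole toolkit runnable and exactly reproducible on one CPU;
it is not intended to compete with GPU frameworks at full scale.

Training alternates one joint generator update (G1 and G2 on the total
objective) with one update per discriminator; discriminators train against
a 50-image history pool of past fakes (disable with `pool_size = 0`), the
usual stabilizer for unpaired adversarial training. The learning rate is
1e-5, flat for 100 epochs then linearly decayed to 0 at epoch 200;
mini-batch 4. An epoch is one pass over the extracted patch set (10,000
patches in the main configuration). Batch-norm layers use running statistics
at inference, so inference is deterministic.

## Imaging layer

* **Normalization.** Clinical intensities are clipped to [-1000, 2500] H.U.
  (air to bone) and micro-CT to [0, 15000] scanner units (air to dense
  tumour tissue), then mapped affinely onto [-1, 1]. Both windows are
  scanner conventions, hence configurable. The map is exactly invertible on
  the clipped range.
* **Lung masking.** Voxels below -400 H.U. are grown into 6-connected
  components; components touching an in-plane border are discarded as
  outside-body air (axial faces are not used — lungs commonly span the
  cropped axial extent); remaining components are closed by per-slice
  morphological hole filling so intrapulmonary vessels stay inside the
  mask. The -400 H.U. threshold sits in the wide gap between aerated lung
  (around -800) and soft tissue (around 0).
* **Patch extraction** samples top-left corners uniformly across axial
  slices; with a mask, a patch must have at least 50% of its pixels inside
  the mask, which keeps all-background patches out while still allowing
  pleural-boundary patches. Identical seeds give identical patch sets.
* **Bicubic resampling** is pinned to the Keys cubic-convolution kernel
  (a = -0.5, 4x4 support) with half-pixel centre alignment and reflective
  boundaries; constants and degree-1 ramps are reproduced exactly, and each
  interior output sample depends on exactly 16 source pixels.
* **Tiled inference** super-resolves overlapping tiles (default 32 px,
  8 px overlap) and blends with linear feathering; accumulated weights are
  normalized to sum to one at every output pixel, so stitching is exact
  where tiles agree and seam-free on constant inputs.

## The phantom generator

Real clinical/micro-CT pairs cannot ship with a package, so `phantom_spec()`
defines a fully synthetic study system with the statistical structure the
method assumes:

* The **micro-domain phantom** places bright vessel disks and bronchial
  annuli (dark lumen, bright wall) over a granular two-mode alveolar
  background — tissue mode at 0.55 and air mode at -0.15 of the normalized
  range — giving the upper-concentrated intensity histogram characteristic
  of micro-CT.
* The **clinical forward model** degrades a micro phantom by Gaussian blur
  (sigma 1.5 HR pixels), average pooling by the scale factor, a fixed
  monotone piecewise-linear intensity remap onto a broad clinical-like
  distribution, and additive Gaussian noise (sd 0.02), clipped to [-1, 1].
  The remap is monotone so tissue ordering is preserved across domains, as
  it is between Hounsfield and scanner units. Pooled-pixel histograms of
  the two domains are statistically well separated (two-sample KS statistic
  above 0.2), encoding the premise that makes the MMSR loss necessary.
* **Unpaired training sets** draw the two domains from disjoint phantom
  seed pools, so there is no hidden pairing; **paired evaluation sets**
  (`hr`, `lr = degrade(hr)`) exist only for oracle evaluation.

What the phantoms do *not* emulate: CT reconstruction physics (beam
hardening, ring artifacts, noise correlation), anatomy beyond
disk/annulus/texture idealizations, and 3-D continuity across slices.
Passing phantom experiments therefore demonstrates that the optimization,
losses and architecture behave as designed — not clinical performance.

## Desk-scale experiment conditions

The shipped experiments (tests and the acceptance script) use a deliberately
small instantiation so a full unpaired training run finishes in minutes on
one CPU: 64-pixel HR phantoms at 4x scale (16x16 LR patches), 8-channel
generators with 2 residual blocks, 8-channel discriminators, batch 4,
learning rate 5e-4 (appropriate for networks this small; the 1e-5 of the
full-scale schedule is matched to 64-channel networks and hundreds of
epochs), a 20-image pool, and at most 500 optimization steps over 48 + 48
unpaired phantom patches. The desk-scale phantoms are structure-dominant:
6-10 vessels, 2-4 bronchi, a sparse (15% air) alveolar background with
6-pixel grain. Two considerations drive this. First, texture finer than the
LR grid is unrecoverable in principle — every method can only hallucinate
it, so metrics dominated by such texture cannot separate methods; with
partially resolvable, sparse texture, preserving input structure is
measurably rewarded, which is the regime the method targets (its qualitative
claims are about vessels and bronchial walls staying put and getting
sharper). Second, the discriminator's locality must scale with the domain
(see the architecture notes): a near-global score map makes the
mean-normalized adversarial gradient orders of magnitude stronger per
element than at full scale and destroys the default weight balance.
Held-out evaluation compares the trained G1, bicubic upsampling, and an
ablation trained with the MMSR weights zeroed, on paired phantoms
(`lr = degrade(hr)`).

## Numerical notes and degenerate inputs

* Zero-MSE PSNR is reported as a 100 dB cap so set means stay finite.
* SSIM variances are computed as population moments; batch-norm variances
  are floored at 0 before the epsilon (1e-5) is added.
* Average pooling requires exact divisibility and refuses anything else;
  `f_up` with factor 1 is the identity.
* Pooling/upsampling gradients are exact adjoints (`f_up/ s^2` and block
  sum respectively), verified against finite differences.
* All randomness (weight init, patch sampling, pool decisions, phantom
  content, noise) flows from user-supplied integer seeds; checkpoints store
  the RNG state, so resuming reproduces the uninterrupted trajectory
  bit-for-bit.

## Known limitations

* CPU training at the full 8x/64-channel configuration is functional but
  slow; the configuration exists for completeness and for shape/contract
  verification, not routine use.
* DICOM series input is not supported (no DICOM reader in the dependency
  set); NIfTI and MetaImage are.
* The micro-CT cylinder ROI is assumed already cropped; no automatic ROI
  detection is attempted.
* No registration between domains is attempted anywhere — the method's
  premise is that registration is infeasible.
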