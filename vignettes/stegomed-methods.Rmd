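---
title: "Hiding patient data in the background of medical images: model and design"
author: "stegomed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hiding patient data in the background of medical images: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stegomed)
```

## The problem

Medical images travel between institutions separated from the patient
record that gives them meaning. Steganography re-attaches that record by
hiding it *inside* the image, in regions that carry no diagnostic content
— the near-black background (the region of non-interest, RONI) of a CT or
MR slice — so that the stored file remains an ordinary DICOM image and the
diagnostic region is untouched, bit for bit.

`stegomed` implements such a scheme end to end: the payload is rendered as
a QR symbol, mapped into 4×4 blocks, and embedded into the 4×4 block DCT
coefficients of background tiles by quantization-index modulation;
extraction needs only the stego image, a small manifest (the key), and a
segmentation of the stego image itself.

## The embedding model

**Normalization.** A cover with pixels $I$ is min–max normalized,
$\mathrm{Norm}(I) = (I - \min I)/(\max I - \min I) \in [0,1]$, and
de-normalized with the same (stored) extrema after embedding, rounding
half-away-from-zero so results are bit-reproducible across platforms.

**Message adjustment.** QR bits $b \in \{0,1\}$ are mapped to levels
$\{\alpha,\, 1-\alpha\}$ with $\alpha = 0.02$ by default. The levels stay
strictly inside the open unit interval, which keeps embedded coefficients
strictly inside their quantization cells.

**Transform.** Each 4×4 background tile is transformed with the
orthonormal type-II 2D DCT. Orthonormal scaling is the completion under
which a tile of $[0,1]$ pixels has every coefficient magnitude at most 4
(the DC of an all-ones tile is exactly 4), so the quantizer below
partitions the magnitude range $[0, 4]$.

**Quantization embedding.** With $\beta$ intervals of width $4/\beta$, a
cover coefficient $c$ lies in cell
$k = \min(\lfloor |c|\beta/4 \rfloor, \beta - 1)$. Embedding keeps the
cell and replaces the within-cell position with the message level $m$:
$$\mathrm{Qun}(c, m) \;=\; \mathrm{sign}(c)\,\Bigl(\tfrac{4k}{\beta} + \tfrac{4}{\beta}m\Bigr),$$
so the perturbation is below one cell width $4/\beta$. Extraction reads
the position back:
$\mathrm{IQun}(s) = |s|\beta/4 - k$, an exact left inverse. Each of the
16 coefficients of a tile carries one message value, giving one bit per
insignificant pixel. A larger $\beta$ means smaller perturbations and a
higher-fidelity stego image; the defaults are $\beta = 1000$,
$\alpha = 0.02$.

Three conventions deserve a note, because the quantizer is sometimes
stated with gaps or a restricted index range:

* cells form the gapless partition $[4k/\beta,\, 4(k+1)/\beta)$, ties at
  boundaries resolving downward;
* $k = 0$ is allowed — near-zero coefficients are the *common* case in a
  black background, and excluding the zeroth cell would make background
  tiles unembeddable;
* the coefficient's sign is preserved and carries no message; extraction
  uses magnitudes only.

**Bit decision.** Recovered values are decided at the midpoint: bit 1 iff
$v \ge 0.5$, the maximum-margin rule for levels $\{\alpha, 1-\alpha\}$,
with the (measure-zero) tie going to 1.

## Surviving integer pixels: margins, headroom, and tile repair

The stego image is stored as integers, so every coefficient is perturbed
by pixel rounding. The decision margin of the quantizer is
$\alpha \cdot 4/\beta$ in coefficient units (a level sits $4\alpha/\beta$
from its cell wall, beyond which the recovered bit flips). Under the
orthonormal DCT, rounding to a grid of step $h$ perturbs a coefficient by
at most $4h$ in the worst case. Three design choices follow:

1. **12-bit covers are written as 16-bit stegos via an exact 4-bit shift**
   (pixel values ×16). On the 12-bit grid, $h = 0.5/4095$ exceeds the
   margin at $\beta = 1000$ — bit-exact recovery is impossible, not
   merely hard. The shift refines the grid 16-fold, comfortably below the
   margin, while untouched pixels remain exactly recoverable and every
   intensity ratio is preserved. 16-bit covers keep the exact inverse
   mapping, so untouched pixels are bit-identical.
2. **Clamping happens in the integer domain** to $[0, 2^{16}-1]$, not to
   normalized $[0,1]$: the cover maximum is below the representable peak,
   and that headroom absorbs the IDCT overshoot of quantized tiles.
3. **Tiles whose quantized pixels would still leave the representable
   range are repaired.** A near-black tile carrying many 1-bits must
   acquire coefficient energy $\gtrsim 4(1-\alpha)/\beta$ per
   coefficient; at small $\beta$ its IDCT swings below zero and clamping
   would destroy the embedded cells. Repair proceeds in three stages,
   cheapest first: flip the signs of AC coefficients (signs carry no
   message; for a near-zero cover coefficient the original sign is noise)
   to shrink the waveform's range; then lift the DC coefficient to the
   next valid quantizer level that brings every pixel inside the range —
   exact, and leaving the other 15 recovered values untouched; finally,
   for the rare remaining tiles, alternate projections between the pixel
   box and the per-coefficient bands of bit-correct positions (any cell
   with the right half-cell position decodes to the right bit, so the
   feasible set is periodic and generous).

With these three mechanisms, embedding is bit-exact through DICOM
write/read for $\beta$ from 10 to 1000 at both bit depths — verified by
an internal extraction pass after every embedding (`manifest$verified`).

## The mask: a deterministic stand-in with a stability obligation

The published protocol obtains the significant/insignificant mask from a
trained segmentation network, applied independently to the cover (at
embedding) and to the stego (at extraction); the mask is never
transmitted. The stand-in provider must therefore not merely segment well
— it must produce the *same* mask from cover and stego, else the
embedder's and extractor's tile plans desynchronize and every bit after
the first disagreement is lost.

`threshold_mask()` is designed around that obligation:

* the threshold is an **absolute** fraction of the representable peak
  $R$ (default $0.3R$), not of the image's own min–max range. Embedding
  legitimately moves the stego's extrema (overshoot headroom), so any
  histogram-derived scale shifts the derived threshold and races it
  across the organ's edge pixels. An absolute threshold classifies the
  untouched significant pixels identically on cover and stego, by
  construction.
* a morphological **opening** (radius 3) removes what embedding texture
  pushes above the threshold in the background — supra-threshold speckle
  never forms solid structures the size of the opening kernel — followed
  by the usual closing (radius 5) and a minimum component area (256 px)
  that removes any isolated lump that survives.
* `plan_tiles()` adds a **guard ring** (8 px): no tile is planned within
  it, so embedding never writes next to the organ boundary and residual
  single-pixel jitter there cannot change the plan.

On the synthetic study conditions this yields masks that are
pixel-identical between cover and stego across every $\beta \ge 10$
tested, which is strictly stronger than the NCC/IoU ≥ 0.99 the
evaluation demands. An external segmenter (e.g. a trained network) can
replace the provider through `external_mask_adapter()`, provided it
meets the same stability obligation.

## Payload path

Patient text is rendered as a byte-mode QR symbol (versions 1–10,
error-correction level M by default — a balance of capacity against the
noise robustness exercised by the attack harness), at `module_scale = 4`
pixels per module so QR modules align exactly with embedding tiles.
Decoding reduces the bitmap to its module grid by per-module majority
vote — a tile corrupted by noise must mis-decide more than half of its
16 pixels before its module flips — and then applies Reed–Solomon
correction. The QR codec, including GF(256) arithmetic and
Berlekamp–Massey decoding, is implemented in the package and validated
by construction tests (field identities, error-injection up to the
correction budget, the format-information BCH identity).

Messages are padded with the bit-0 level to multiples of 4 before
tiling; the padding geometry travels in the manifest. Min–max
normalization of a $\{0,1\}$ bitmap is the identity, so no separate
normalization pass is applied to the QR image.

## Evaluation harness

* **Fidelity**: MSE and PSNR ($10\log_{10}(R^2/\mathrm{MSE})$, with $R$
  the bit-depth peak; infinite for identical images), mask agreement by
  NCC and IoU. PSNR is non-decreasing in $\beta$; absolute values depend
  on the cover's background statistics and are not comparable across
  datasets.
* **Capacity**: one bit per insignificant pixel; `capacity_report()`
  counts plannable tiles × 16. With the embedder's guard ring the margin
  tiles drop out of the usable capacity; guard-free accounting
  (`guard_radius = 0`) gives the raw one-bit-per-background-pixel figure.
* **Robustness**: seeded Gaussian, uniform and salt-and-pepper attacks
  (`apply_attack()`), with `robustness_trial()` running
  embed → attack → re-segment → extract and reporting the continuous
  message correlation, bit accuracy and decode success. At
  $\beta = 1000$ the decision margin is a few gray levels, so additive
  noise beyond roughly $10^{-4} R$ randomizes recovered values — message
  correlation falls from 1 toward 0 across that range, monotonically on
  average, while salt-and-pepper damage grows in proportion to the
  number of corrupted tiles. Error-correction plus module majority
  voting tolerates the low end of these regimes.

## The synthetic phantoms

`generate_phantom()` emulates abdominal slices at desk scale: 512×512
16-bit CT-like or 256×256 12-bit MR-like frames; 1–3 rotated elliptical
blobs with a bright plateau (58–66% of $R$, textured by low-frequency
cosines) and a sharp ~2 px edge; background noise bounded by 2% of $R$
(truncated Gaussian around a small positive baseline, as real air/detector
noise is); foreground fraction retried into [0.3, 0.6]. The exact blob
support is returned as ground truth, and the plateau peak leaves 16-bit
headroom for embedding overshoot.

What the phantoms deliberately do *not* model: anatomy, Hounsfield
calibration, inter-slice structure, scanner-specific noise spectra, or
the failure modes of a learned segmenter (partial organs, ambiguous
boundaries). Passing the test suite therefore establishes the
correctness and internal robustness of the embedding system under its
stated contract — identical masks, sufficient background, bounded
coefficients — not clinical performance; on real data the mask-stability
obligation shifts to the segmentation model, whose agreement between
cover and stego should be verified (the embed-time verification pass
reports exactly this).

## Problem sizes and numerical choices

The test suite runs 20 phantoms × 5 values of $\beta$ through full
DICOM round-trips, 1000-block transform oracles, $10^4$ quantizer
inversions across $\beta \in [2, 2000]$, and 3 attacks × 5 strengths ×
20 seeds for the robustness trend; the acceptance script reruns the
pipeline at the default configuration from a single command-line seed.
Tolerances: transforms match the brute-force double sum to $10^{-10}$;
quantizer inversion to $10^{-9}$ (floating-point association only);
bit-exactness is asserted exactly. Repair bands are inset to
$[0.08, 0.42]$ of a cell (and mirrored for bit 1) so integer rounding
cannot cross a bit boundary after projection; the repair's safety margin
is two integer steps.

## Known limitations

* Tile order synchronizes embedder and extractor; a segmenter that does
  not reproduce its mask on the stego image breaks extraction beyond the
  first disagreeing tile. The optional `tile_order_seed` permutes tiles
  as key material but does not remove this dependence.
* No robustness against geometric or compression attacks is claimed —
  additive/impulse noise only.
* Multi-frame and color DICOM, signed pixel data and compressed transfer
  syntaxes are out of scope; the DICOM codec is deliberately minimal.
* At $\beta = 10$ the stego background is visibly textured (PSNR ~20 dB);
  small $\beta$ exists for the fidelity sweep, not for practical use.
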