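# stegomed

High-capacity data hiding for 12/16-bit grayscale medical images, for
engineers and researchers who need to bind a patient record to the image
that it describes without touching a single diagnostically relevant
pixel. The payload (free text, typically demographics) is rendered as a
QR symbol and concealed in the *insignificant region* — the near-black
background of a CT or MR slice — and recovered exactly from the stego
DICOM file alone, given a small manifest that acts as the key.

## Method

Embedding is quantization-index modulation in the 4×4 block DCT domain
of the background:

1. the cover is min–max normalized,
   `Norm(I) = (I − min I) / (max I − min I)`;
2. a binary significant/insignificant mask is computed (a deterministic
   threshold-morphology provider stands in for a trained segmenter; an
   adapter accepts external masks) and the background is tiled into 4×4
   blocks, transformed with the orthonormal type-II 2D DCT, under which
   every coefficient magnitude of a `[0,1]` tile lies in `[0, 4]`;
3. QR bits are mapped to levels `{α, 1−α}` (α = 0.02) and each of the 16
   coefficients of a tile carries one value — one bit per background
   pixel. With β quantization intervals on `[0, 4]`, a coefficient `c`
   in cell `k = min(⌊|c|β/4⌋, β−1)` becomes

   ```
   Qun(c, m) = sign(c) · (4k/β + (4/β) · m)
   ```

   and extraction inverts it with `IQun(s) = |s|β/4 − k`. Larger β means
   smaller perturbation and higher stego fidelity (defaults β = 1000,
   α = 0.02);
4. the stego image is de-normalized back to integers (12-bit covers are
   written into 16 bits by an exact 4-bit shift) and verified by an
   internal extraction pass. Extraction re-derives the mask from the
   stego image itself — masks are never transmitted.

Fidelity is reported as MSE/PSNR (`PSNR = 10·log10(R²/MSE)`, R the
bit-depth peak), mask agreement as NCC/IoU, and robustness under seeded
Gaussian, uniform and salt-and-pepper noise attacks. A synthetic phantom
generator (CT-like 512×512 16-bit, MR-like 256×256 12-bit, with
ground-truth masks and fictitious patient records) makes the whole
pipeline testable without any clinical data.

## Worked example

```r
library(stegomed)

ph   <- generate_phantom(ct_phantom_spec(seed = 42))
ph$image
#> <medical_image> 512x512, 16-bit, modality CT, range [119, 45689]

mask <- threshold_mask(ph$image)
mask
#> <binary_mask> 512x512, 35.0% significant

record <- generate_patient_record(42)
record
#> "Name: Alex Novak; ID: P00000042; Age: 82; Mod: CT; Date: 2024-10-04"

qr     <- text_to_qr(record)          # 37x37-module QR at 4 px/module -> 148x148
blocks <- blockify_message(adjust_message(qr))
res    <- embed_payload(ph$image, mask, blocks, embedding_key(beta = 1000))
res$manifest$verified                 # internal extraction check
#> TRUE
res$manifest$tiles_used               # 1369 tiles = 21904 embedded bits
#> 1369

compute_psnr(ph$image, res$stego)     # imperceptibility at beta = 1000
#> 66.87                               # dB; MSE 883.9
capacity_report(mask)$capacity_bpp    # embeddable fraction of this cover
#> 0.606                               # = 158976 bits

# receiver side: stego + manifest only; the mask is recomputed
key <- embedding_key(beta = 1000, message_shape = res$manifest$message_shape)
rec <- extract_payload(res$stego, threshold_mask(res$stego), key,
                       c(res$manifest$norm_min, res$manifest$norm_max),
                       module_scale = 4)
qr_to_text(unblockify_and_decide(rec))
#> "Name: Alex Novak; ID: P00000042; Age: 82; Mod: CT; Date: 2024-10-04"
```

The numbers mean: about 61% of this cover's pixels can carry one bit
each; the 21904-bit payload perturbs the image so little that the stego
is ~67 dB from the cover at 16 bits; and recovery is bit-exact, so the
decoded record equals the original. A 4-row shell session does the same:

```sh
exec/stegomed phantom --style CT --seed 42 --out cover.dcm
exec/stegomed embed   --cover cover.dcm --text "ID: P42" --out stego.dcm
exec/stegomed extract --stego stego.dcm --manifest stego.dcm.manifest.json
exec/stegomed evaluate --cover cover.dcm --out sweep.csv   # beta sweep table
```

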