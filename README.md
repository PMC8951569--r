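# corotrack

Dye-free tracking of coronary arteries in cine-angiography.

## What problem this solves

A coronary angiogram only shows the arteries while radio-opaque contrast dye
fills them. Yet some clinically interesting structures — calcifications,
stents — are best assessed in the *dye-free* frames, where the dye does not
mask them. Every acquisition contains at least one dye-free cardiac cycle
before injection, and cardiac motion is periodic, so every dye-free frame has
a contrasted "template" frame showing the heart in nearly the same
configuration.

`corotrack` locates the coronary tree in dye-free frames by:

1. **Segmenting** each contrasted frame with a multi-scale Hessian (Frangi)
   vesselness filter: with Hessian eigenvalues |λ₁| ≤ |λ₂|, blobness
   R_B = λ₁/λ₂ and structureness S = √(λ₁² + λ₂²),

   V_σ = exp(−R_B²/2β²) · (1 − exp(−S²/2c²)),  V = max over σ,

   zeroed where the dark-on-bright sign condition (λ₂ > 0) fails; then Otsu
   thresholding, morphological closing and small-component removal.
2. **Detecting the contrast window** (first injected frame → last
   pre-washout frame) as the longest run of frames whose segmentable
   vessel-pixel count stays ≥ 30% of the peak — manual override available.
3. **Associating** each dye-free frame with its most similar template by
   zero-lag normalized cross-correlation (Pearson r over the template's
   dye-independent *background* region), the arg-max being the cardiac-phase
   association.
4. **Transferring** the winning template's vessel contour onto the dye-free
   frame and rendering color overlays (yellow = predicted, green =
   reference).

A ground-truthed synthetic cine-angiogram simulator (vessel curvature, width
taper, stenoses, periodic motion, bolus wash-in/out, noise) makes the whole
pipeline testable without patient data, and an evaluation module reports
Dice overlap, phase-assignment accuracy and bolus-window error against that
ground truth.

## Worked example

```r
library(corotrack)

cfg <- phantom_config(seed = 7)            # 60 frames, period 20, bolus 20-45
out <- generate_synthetic_cine(cfg)

curve  <- compute_opacity_curve(out$sequence)
window <- detect_contrast_window(curve, fraction = 0.3)
window
#> <contrast_window> frames 20..45 (inclusive, 0-based)

bank <- build_template_bank(out$sequence, window)
bank
#> <template_bank> 26 templates from frames 20..45

results <- track_sequence(out$sequence, bank, dye_free_indices(window, 60))
results[[1]]$best_template_index           # frame 0 matched to template ...
#> [1] 20
round(results[[1]]$score, 3)               # ... with NCC score
#> [1] 0.896

evaluate_tracking(results, out$truth, bank, detected = window)
#> <tracking_report>
#>   frames tracked : 20
#>   mean Dice      : 0.852
#>   phase hit rate : 1.000
#>   bolus window error: start +0, end +0 frames
```

Reading: the bolus window was recovered exactly; every one of the 20 dye-free
frames was assigned a template at the correct cardiac phase (±1 frame); the
transferred contours overlap the true (invisible) vessel masks with mean
Dice 0.85.

On real data, replace the simulator with `read_cine("loop.dcm")` (multi-frame
DICOM or a directory of single-frame files) and use `cmd_track()` /
`write_overlay()` for overlay PNGs, contour JSON and a run report JSON.

## Command line

An installed script in `inst/cli/` wires four subcommands:

```sh
corotrack simulate --out sim/ [--config phantom.yaml] [--seed N]
corotrack track    --input sim/sequence.dcm --out run/ \
                   [--contrast-start N --contrast-end M] [--detect-fraction F]
corotrack segment  --input loop.dcm --frame 25 --out seg/
corotrack evaluate --run run/ --truth sim/
```

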