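# ivmclean

Automated motion-artifact removal for two-photon intravital microscopy
(2P-IVM) time-lapse videos.

Live-animal imaging of the brain, spinal cord, peripheral nerve or gut is
contaminated by cardiac and respiratory cycles and by muscular and vascular
tone: individual frames arrive translated, warped or out of focus. Because
these artifacts are irregular peaks rather than a steady offset, the
practical remedy is to *detect and discard* the corrupted frames before any
quantification, rather than to try to repair them. `ivmclean` implements
that workflow as a tested R library plus a small command-line interface,
together with a seeded synthetic-video generator so every stage can be
validated without animal recordings.

## Method

Every frame *t* of the stack is scored on a user-designated **reference
channel** — a structure that is temporally stable over the session,
typically the blood vessels — by its mean squared difference to a
reference image:

```
D_t = (1 / HW) * sum_xy [ I_t(x, y) - R_t(x, y) ]^2
```

The reference `R_t` is either one fixed frame, or (default) a **rolling
reference**: the average-intensity projection of the window of *n* adjacent
frames centred on *t* (n odd, 5–30 sensible, default 15; windows truncate
at the stack boundaries). Rolling references track slow baseline drift, so
the score trace stays flat for good frames and spikes only on artifacts.

Artifact frames are then removed by two complementary gates:

* **percentile gate** — keep the lowest-scoring *P*% of frames
  (nearest-rank percentile; default *P* = 60);
* **n-neighbor relative-maximum filter** — split the sequence into
  consecutive groups of *n* frames and drop the highest-scoring frame of
  each group. Because one pass removes at most one frame per group, two
  *consecutive* distorted frames require **double filtering** (`passes =
  2`), which re-applies the gate — rebuilding the rolling references — on
  the retained sequence.

Each frame keeps its **origin index** (its position in the original
acquisition) through every removal, so the burned-in timestamp of a
surviving frame is always `origin_index x frame_interval`, no matter how
many neighbours were discarded.

The surviving frames can be registered frame-to-frame (translation, rigid,
scaled rotation, or affine; each frame is estimated against its
already-aligned predecessor and the transforms propagate), cleaned of
channel bleed-through by scaled subtraction, collapsed by grouped
maximum/average intensity projections, or denoised by a causal per-pixel
Kalman stack filter that preserves the frame count.

## Worked example

Generate a synthetic 300-frame recording in which 39.7% of frames carry a
planted full-field translation artifact, score it with rolling references,
and gate at the 60th percentile:

```r
library(ivmclean)

scene  <- generate_scene(scene_separable(T = 300, seed = 1))
scene$stack
#> <frame_stack> 300 frame(s), 64 x 64 px, 3 channel(s) [red, green, blue]
#>   origin indices 0..299, intensity range [0, 255]

series <- score_stack(scene$stack, channel = "red",
                      reference_policy("rfg", window = 15))
series
#> <score_series> 300 frames, channel 'red', mode rfg (window 15)
#>   score range [326.8, 5778], median 708.6

res <- gate_stack(scene$stack, "red", reference_policy("rfg", window = 15),
                  gate_config(percentile_cutoff = 60))
evaluate_gating(res$selection, scene$truth)
#> $n_frames               300
#> $n_artifacts            119
#> $n_kept                 180
#> $artifact_rate_before   0.397
#> $residual_artifact_rate 0
#> $recall                 1
#> $false_positive_rate    0.00552
```

All 119 artifact frames score above every good frame and are removed
(recall 1, residual artifact rate 0); the price is a handful of good
frames (false-positive rate 0.55%), which is the intended trade-off of
percentile gating. `res$stack` holds the 180 surviving frames with their
origin indices intact; `align_stack()`, `kalman_filter()` and
`timestamp_overlay()` continue the pipeline from there, or
`run_pipeline()` drives the whole flow from one YAML/JSON config.

A command-line wrapper with subcommands `synth`, `score`, `filter`,
`align`, `enhance`, `annotate`, `run` and `benchmark` is installed at
`inst/cli/ivmclean.R`:

```sh
Rscript inst/cli/ivmclean.R synth --out video.tif --frames 1000 \
    --preset separable --seed 1
Rscript inst/cli/ivmclean.R filter --input video.tif --percentile 60 \
    --out-dir filtered/
```

## Scope

The package processes 8-bit, up to 3-channel 2D time-lapse stacks
(multipage TIFF, or a directory of numbered TIFF/PNG frames). Out of
scope by design: 16-bit/float acquisitions, proprietary microscope
formats, elastic (non-rigid) motion correction, z-drift correction, 4D
stacks, and interpolation of removed frames. See the methods vignette
(`vignettes/ivmclean-methods.Rmd`) for the model, parameter guidance and
limitations.
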