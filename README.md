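# gcunet

Cell-nuclei instance segmentation for stained cytology and histology
images, for image-analysis researchers who need a fully self-contained,
CPU-only, offline-testable implementation. The package provides:

- **GC-UNet**, an encoder–decoder CNN with a densely connected encoder and
  three global-context components — context gating residual (CGR) blocks,
  a global context attention (GCA) block and multipath residual pooling
  (MRP) — in the bottleneck, plus residual context attention (RCA) modules
  in each decoder stage;
- **instance-level evaluation**: aggregated Jaccard index (AJI), Dice
  coefficient and panoptic quality (PQ), each verified against brute-force
  oracles;
- a **seeded synthetic-scene generator** producing smear-like images
  (overlapping elliptical nuclei, stain palette, blur, noise) with exact
  instance ground truth, so everything is testable without any dataset
  download;
- a training/prediction/evaluation **pipeline and CLI**, including a small
  tape-based autograd engine (no external deep-learning framework is
  required — or available — in the target environment).

## The model in brief

The encoder downsamples ×32 with dense connectivity, exposing four skip
maps. The deepest map goes through CGR → GCA → MRP → 1×1 fusion:

- CGR: `out = x + Σ_k σ(f_k(x)) ⊙ x` over kernel sizes k ∈ {3,5,7,9},
  each `f_k` two same-padding convolutions;
- GCA: context vector `c = Σ_p softmax_p(w·x_p) x_p`, added back as
  `x + W₂ ReLU(LN(W₁ c))` (bottleneck ratio r = 16, W₂ zero-initialized so
  the block starts as the identity);
- MRP: max pooling at windows {2,3,5,7}, 1×1-compressed, upsampled,
  concatenated (C → C+4).

Four decoder stages (4×4 stride-2 transposed conv, skip concat, two 3×3
conv+BN+ReLU, then RCA pyramid pooling over bins {1,2,3,6}) and a bilinear
×2 + 1×1 head produce a per-pixel probability map. Training loss:
`BCE + (1 − smooth Dice)`, Adam, lr 1e-4, batch 8.

Evaluation: AJI (Kumar-style consumed-prediction bookkeeping),
Dice = 2|G∩P|/(|G|+|P|), PQ = SQ·RQ under unique IoU > 0.5 matching.

## Worked example

```r
library(gcunet)

## a reproducible synthetic smear scene with exact ground truth
sp <- scene_spec(height = 64, width = 64, n_nuclei = c(3, 6),
                 radius_px = c(5, 10), blur_sigma_px = 0.8, seed = 7)
s <- generate_scene(sp)
s$n_nuclei
#> [1] 4

model <- build_model(model_config(seed = 1))
model
#> GC-UNet (densenet_lite encoder, decoder widths 128/64/32/16): 5477617 parameters

## 80 Adam steps on this one image (abridged; see train() for the real loop)
#> step  1 loss 1.902
#> step 40 loss 0.822
#> step 80 loss 0.511

p <- forward(model, s$image)          # 64 x 64 probability map in [0,1]
evaluate_pair(s$instances, p, threshold = 0.5, min_size = 10)
#> AJI 0.3583  Dice 0.9386  PQ 0.1820 (SQ 0.5459 RQ 0.3333)  TP/FP/FN 1/1/3
```

After 80 steps on a single image the binary overlap is already high
(Dice 0.94) while the instance-level scores lag (AJI 0.36, PQ 0.18):
touching nuclei are still merged into one component, which costs matched
pairs under the IoU > 0.5 rule. Longer training on more scenes separates
them — the end-to-end test trains 100 epochs on 12 scenes and requires
held-out mean Dice ≥ 0.7 and AJI ≥ 0.4.

## Command line

```sh
gcunet synth    --config cfg.json --n 100 --seed 1 --out data/synth
gcunet train    --images data/synth --out runs/a --epochs 100 --image-size 64
gcunet predict  --images data/test --model runs/a/ckpt_epoch_0100.rds --out preds
gcunet evaluate --gt data/test --pred preds --out report.json
```

(`gcunet` is the launcher installed at `inst/cli/gcunet`; equivalently
`Rscript -e 'gcunet::gcunet_main()' synth ...`.) Configuration files are
JSON with sections `model`/`train`/`augment`/`synth`/`eval`; flags
override config keys. Rasters are uncompressed TIFF: 8-bit RGB images,
16-bit instance maps, 32-bit float probability maps.

## Documentation

`vignettes/gcunet-methods.Rmd` describes the model, the synthetic-data
generator and every numerical/design choice, including what a passing test
does and does not establish.
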