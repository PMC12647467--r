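# dunet

Semantic segmentation of plant branches into **background**, **stem/branch**
and **leaf** pixels, built around DU-Net: a fusion architecture that runs a
DeepLabV3+-style atrous-pyramid branch and a U-Net-style skip decoder over
one shared, width-scalable residual encoder. Stem/leaf masks are the raw
material of forage phenotyping (e.g. the leaf-to-stem ratio of alfalfa), and
the two parent architectures fail in complementary ways on such imagery:
atrous-pyramid decoders fragment thin petioles, while plain U-Nets
misclassify bright background speckles between leaves under high-light
conditions. DU-Net fuses both feature streams at full resolution; its
lightweight variant **DU-Net-L** scales every channel width by 4/8 on a
ResNet-34 encoder.

The package is a complete desk-scale laboratory for this model family:

* **model zoo** — explicit layer graphs for DU-Net (ResNet-18/34, VGG-16/19
  encoders, n/8 width scaling with n = 2..8, optional CBAM attention) and
  the classical U-Net baseline, with exact integer parameter accounting.
  Model size is `params x 4 / 1e6` MB (32-bit weights): the pinned
  conventions reproduce the family's reference sizes exactly
  (U-Net **138.05 MB**, DU-Net-L **25.42 MB**).
* **training engine** — a seeded CPU implementation of convolution
  (im2col/offset-GEMM with single-precision BLAS cores), batch
  normalization, pooling, bilinear resizing, backpropagation and Adam;
  the reference protocol (batch 5, lr 0.001, optional 0.95^epoch decay,
  per-epoch test evaluation, best-5-epoch selection) on top.
* **evaluation** — pixel accuracy, per-class IoU `TP/(TP+FP+FN)`, mean IoU,
  cross-entropy and soft Dice losses.
* **augmentation** — the two dataset strategies: 10-fold geometric/colour
  augmentation with mask-consistent transforms, and background-reducing
  crops.
* **annotation io** — labelme-style JSON polygons to label masks
  (scanline even-odd fill at pixel centers), mask PNG I/O, resizing,
  7:3 train/validation splits with a held-out test set.
* **synthetic data** — a generator of schematic branch scenes (thin curved
  stems, petioles, trifoliate leaflet clusters, dark cloth background,
  high-light speckle variant) with exact ground truth, so everything above
  is testable without any external dataset.

## Worked example

```r
library(dunet)

# the two table rows the size accounting pins down
architecture_summary(build_unet_baseline(3))
#> <architecture_summary> 35 layers, 34,513,475 params, 138.05 MB
architecture_summary(build_dunet(model_config("resnet34", 4)))
#> <architecture_summary> 124 layers, 6,354,283 params, 25.42 MB

# a small synthetic-scene training run (DU-Net-L at width 2/8, 96x160)
bench <- run_fixture_benchmark(n_train = 20, n_test = 8, epochs = 10, seed = 0)
round(c(accuracy = bench$metrics$accuracy, miou = bench$metrics$miou), 4)
#> accuracy     miou
#>   0.9509   0.5427
round(bench$metrics$class_iou, 3)
#>     0     1     2
#> 0.949 0.001 0.677
```

Ten epochs on 20 scenes already separate background (IoU 0.95) and leaves
(0.68) while the rare stem class is still unlearned — the class-imbalance
signature this data is designed to exhibit. At the package's benchmark scale
(200 scenes, 20 epochs) the same model passes mIoU 0.90 within a few epochs;
see `run_fixture_benchmark()` and the methods vignette.

A command-line interface (`inst/cli/dunet`) wraps the same functions:
`synth`, `convert`, `augment`, `audit`, `train`, `eval`, `predict`.

```sh
Rscript inst/cli/dunet audit --variant dunet_l --input-size 480x1024
Rscript inst/cli/dunet synth --n 20 --out scenes/ --seed 0
```

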