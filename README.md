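# rfilm

Evaluation of residual plastic-film pollution on the surface of pre-sowing
cotton fields from low-altitude UAV RGB imagery.

After harvest, straw crushing and ploughing, polyethylene mulch ends up as
small bright film fragments scattered over the soil. `rfilm` segments those
fragments per pixel with a compact U-shaped encoder–decoder network whose
down-sampling stages are multiscale *inception blocks* (parallel 1×1 and
1×1→3×3 branches, channel-concatenated, reduced by a 1×1 convolution), and
summarises pollution as the areal coverage rate

L = Σ p(x, y) / (M × N) × 100 %,

the percentage of film pixels in an M × N frame. The package provides:

- `scene_config()` / `render_scene()` / `generate_dataset()` — a synthetic
  UAV-scene generator with exact ground-truth masks: textured brown soil
  with straw and clod confusers, sunny-day specular highlights, and
  blur/scale degradation growing with flight height (5–9 m);
- `load_pair()`, `resize_pair()`, `split_dataset()` — image/mask I/O,
  working-resolution resizing (bilinear image, nearest-neighbour mask), and
  the seeded 0.8/0.1/0.1 partition (600 images → 480/60/60);
- `augment_config()` / `epoch_stream()` — the four training augmentations
  (random crop, left-right flip, up-down flip, brightness), one fresh
  variant per pair per epoch with an auditable yield counter;
- `build_modified_unet()` / `train_model()` — the network (3,261,826
  trainable parameters with default widths, ~1/10 of a classic U-Net) and
  its training loop: per-pixel cross-entropy, Adam (lr 0.001, batch 6),
  best-checkpoint selection by validation loss; forward/backward passes are
  implemented in the package with RcppArmadillo kernels and verified
  against finite differences;
- `confusion()` / `panel()` / `miou_over_set()` / `evaluate_model()` —
  exact confusion-count metrics (accuracy, precision, recall, F1, two-class
  mean IoU), overall and stratified by weather or height;
- `coverage_rate()` / `regression_eval()` / `pollution_report()` — the
  pollution statistic and its regression validation (prediction R², RMSE,
  MRE) of predicted vs. true coverage;
- a command-line wrapper (`inst/cli/rfilm.R`) with `simulate`, `train`,
  `evaluate`, `coverage` and `regress` subcommands.

## Worked example

Generate a small high-contrast synthetic campaign, train a reduced-width
network for 12 epochs, and evaluate segmentation and pollution recovery:

```r
library(rfilm)

easy <- function(seed) scene_config(
  image_height_px = 256L, image_width_px = 256L, weather = "cloudy",
  height_m = 5, film_brightness_range = c(230, 255),
  film_alpha_range = c(0.85, 1), seed = seed)
pairs <- function(n, s0) lapply(seq_len(n), function(i) {
  sc <- render_scene(easy(s0 + i))
  list(image = sc$image, mask = sc$mask, id = paste0("s", s0 + i))
})
train_pairs <- pairs(64, 1000); val_pairs <- pairs(8, 5000)
test_pairs <- pairs(8, 9000)

model <- build_modified_unet(
  model_config(encoder_channels = c(8L, 16L, 32L), bottleneck_channels = 64L),
  seed = 11)
fit <- train_model(model, train_pairs, val_pairs,
                   augment_config(crop_width = 128L, crop_height = 128L, seed = 21),
                   train_config(epochs = 12L, seed = 31))

evaluate_model(fit, test_pairs)
#>     group n_images accuracy precision   recall       f1 miou_per_image_mean
#> 1 overall        8 99.38965  97.25195 94.17924 95.69093            94.57478
#>   miou_pooled
#> 1    95.54158

pollution_report(fit, test_pairs)$regression
#> <regression n=8: R2=0.9957 RMSE=0.2420 MRE=5.05% fit: y=1.0160x-0.3427>
```

The metric table reports percentages: 99.4 % of test pixels are classified
correctly, and the mean two-class IoU (the average of the film-class and
background-class Jaccard indices, averaged over images) is 94.6 %. The
pollution section regresses predicted coverage L₁ on true coverage L₂ over
the test images: R² = 0.996 means predicted coverage explains nearly all
variation in true coverage, with a root-mean-square coverage error of 0.24
percentage points and a mean relative error of 5 %.

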