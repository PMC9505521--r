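# Shared fixtures: tiny in-memory pairs, the high-contrast "easy" synthetic
# study conditions, and a memoized smoke-trained model reused by the
# end-to-end and stratification tests.

tiny_pair <- function(h = 32, w = 32, seed = 1) {
  set.seed(seed)
  img <- array(round(runif(h * w * 3, 0, 255)), c(h, w, 3))
  msk <- matrix(rbinom(h * w, 1, 0.3), h, w)
  list(image = field_image(img), mask = binary_mask(msk))
}

# high-contrast film over cloudy 5 m soil: the easy end-to-end conditions
# (weather/height overridable for the stratified degradation checks)
easy_scene_config <- function(seed, weather = "cloudy", height_m = 5) {
  scene_config(image_height_px = 256L, image_width_px = 256L,
               weather = weather, height_m = height_m,
               film_brightness_range = c(230, 255),
               film_alpha_range = c(0.85, 1), seed = seed)
}

easy_pairs <- function(n, seed0, cfg_fun = easy_scene_config, ...) {
  lapply(seq_len(n), function(i) {
    sc <- render_scene(cfg_fun(seed0 + i, ...))
    list(image = sc$image, mask = sc$mask, id = sprintf("s%04d", seed0 + i),
         weather = sc$image$weather, height_m = sc$image$height_m,
         true_coverage_pct = sc$realized_coverage_pct)
  })
}

smoke_model_config <- function() {
  model_config(encoder_channels = c(8L, 16L, 32L), bottleneck_channels = 64L)
}

# train once per test run; shared by the recovery and stratification suites
.smoke_env <- new.env(parent = emptyenv())

get_smoke_fit <- function() {
  if (is.null(.smoke_env$fit)) {
    train_pairs <- easy_pairs(64, 1000)
    val_pairs <- easy_pairs(8, 5000)
    model <- build_modified_unet(smoke_model_config(), seed = 11)
    aug <- augment_config(crop_width = 128L, crop_height = 128L, seed = 21)
    tc <- train_config(epochs = 12L, seed = 31)
    .smoke_env$fit <- train_model(model, train_pairs, val_pairs, aug, tc)
  }
  .smoke_env$fit
}
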