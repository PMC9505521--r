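test_that("scene_config validates its fields", {
  expect_error(scene_config(image_height_px = 0), "positive")
  expect_error(scene_config(fragment_area_px_range = c(100, 10)), "ordered")
  expect_error(scene_config(target_coverage_pct = 120), "\\[0, 100\\]")
  expect_error(scene_config(height_m = -1), "height_m")
})

test_that("degenerate background is flat soil with bounded noise", {
  cfg <- scene_config(straw_density = 0, clod_density = 0, weather = "cloudy",
                      image_height_px = 64L, image_width_px = 64L, seed = 4)
  bg <- make_background(cfg)
  # no straw/clod structure: per-channel spread stays within the tone range
  # plus the granular-noise amplitude
  expect_lt(max(bg$pixels), 200)
  expect_gt(min(bg$pixels), 20)
  expect_lt(stats::sd(bg$pixels[, , 1]), 25)
})

test_that("backgrounds are bit-identical under a repeated config/seed", {
  cfg <- scene_config(seed = 9)
  expect_identical(make_background(cfg)$pixels, make_background(cfg)$pixels)
})

test_that("sunny scenes have strictly more near-saturated pixels than cloudy", {
  for (s in c(2, 17)) {
    sunny <- make_background(scene_config(weather = "sunny", seed = s))
    cloudy <- make_background(scene_config(weather = "cloudy", seed = s))
    expect_gt(sum(sunny$pixels > 240), sum(cloudy$pixels > 240))
  }
})

test_that("fragment count is Poisson and zero mean gives no fragments", {
  expect_length(sample_fragments(scene_config(fragment_count_mean = 0)), 0)
  counts <- vapply(1:1000, function(i) {
    length(sample_fragments(scene_config(fragment_count_mean = 4, seed = i)))
  }, numeric(1))
  # sample mean within 3 standard errors of the rate
  expect_lt(abs(mean(counts) - 4), 3 * sqrt(4 / 1000))
})

test_that("fragment areas scale with (5 / height)^2 between 5 m and 9 m", {
  f5 <- sample_fragments(scene_config(height_m = 5, seed = 3))
  f9 <- sample_fragments(scene_config(height_m = 9, seed = 3))
  expect_equal(length(f5), length(f9))
  for (i in seq_along(f5)) {
    expect_equal(f9[[i]]$area_px / f5[[i]]$area_px, (5 / 9)^2,
                 tolerance = 1e-10)
    # the polygon itself realizes the sampled area (shoelace)
    a <- rfilm:::polygon_area(f5[[i]]$x, f5[[i]]$y)
    expect_equal(a, f5[[i]]$area_px, tolerance = 1e-8)
  }
})

test_that("mean rasterized fragment area decreases over heights 5 -> 7 -> 9", {
  mean_area <- function(h) {
    cfg <- scene_config(height_m = h, seed = 12, fragment_count_mean = 10)
    frs <- sample_fragments(cfg)
    mean(vapply(frs, function(f) {
      length(rfilm:::rasterize_polygon(f, 256L, 256L))
    }, numeric(1)))
  }
  a <- vapply(c(5, 7, 9), mean_area, numeric(1))
  expect_true(a[1] > a[2] && a[2] > a[3])
})

test_that("rendered scenes have exact mask/coverage consistency", {
  for (s in c(5, 6)) {
    sc <- render_scene(scene_config(seed = s))
    lab <- sc$mask$labels
    expect_identical(sc$realized_coverage_pct, 100 * sum(lab) / length(lab))
    expect_identical(dim(lab), dim(sc$image$pixels)[1:2])
    expect_true(all(lab %in% c(0L, 1L)))
  }
})

test_that("render_scene is deterministic and honours target coverage", {
  cfg <- scene_config(target_coverage_pct = 10, seed = 7)
  sc <- render_scene(cfg)
  expect_lte(abs(sc$realized_coverage_pct - 10), 0.5)
  sc2 <- render_scene(cfg)
  expect_identical(sc$image$pixels, sc2$image$pixels)
  expect_identical(sc$mask$labels, sc2$mask$labels)

  s0 <- render_scene(scene_config(target_coverage_pct = 0, seed = 7))
  expect_identical(sum(s0$mask$labels), 0L)
  expect_identical(s0$realized_coverage_pct, 0)
})

test_that("generate_dataset writes a balanced grid with a reproducible manifest", {
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  unlink(c(d1, d2), recursive = TRUE)
  cfg <- scene_config(image_height_px = 48L, image_width_px = 48L)
  m1 <- generate_dataset(6, cfg, d1, seed = 3)
  expect_identical(nrow(m1), 6L)
  expect_identical(unname(as.vector(table(m1$weather, m1$height_m))),
                   rep(1L, 6))
  expect_identical(names(m1), c("filename", "split", "weather", "height_m",
                                "true_coverage_pct", "seed"))
  # regeneration is byte-identical
  m2 <- generate_dataset(6, cfg, d2, seed = 3)
  expect_identical(readBin(file.path(d1, "manifest.csv"), "raw", 1e5),
                   readBin(file.path(d2, "manifest.csv"), "raw", 1e5))
  expect_identical(readBin(file.path(d1, "scene_0001.png"), "raw", 1e6),
                   readBin(file.path(d2, "scene_0001.png"), "raw", 1e6))
  # written mask reproduces the manifest coverage exactly
  pr <- load_pair(file.path(d1, m1$filename[1]),
                  file.path(d1, rfilm:::mask_filename(m1$filename[1])))
  expect_equal(coverage_rate(pr$mask)$L_pct, m1$true_coverage_pct[1],
               tolerance = 1e-6)
})
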