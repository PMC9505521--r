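#' Configuration for a synthetic pre-sowing cotton-field scene
#'
#' Describes one synthetic UAV scene: frame size, weather condition, flight
#' height, the film-fragment population (Poisson count, log-uniform areas at
#' the 5 m reference height), film appearance, and the soil/straw/clod
#' background confusers.  Fragment areas scale with `(5 / height_m)^2` to
#' emulate the ground-sampling-distance change between 5 and 9 m flights, and
#' rendering blur grows with height.  Sunny scenes receive a global contrast
#' boost and near-white specular highlights on soil clods — the known
#' false-positive inducers.
#'
#' @param image_height_px,image_width_px frame size in pixels.
#' @param weather `"sunny"` or `"cloudy"`.
#' @param height_m flight height in metres (nominally 5, 7, or 9).
#' @param fragment_count_mean Poisson mean of the fragment count.
#' @param fragment_area_px_range ordered pair: log-uniform area bounds in
#'   pixels at the 5 m reference height.
#' @param film_brightness_range pair in `[0, 255]`: film base brightness.
#' @param film_alpha_range pair in `[0, 1]`: film opacity over soil
#'   (partial alpha lets soil texture bleed through).
#' @param target_coverage_pct optional target film coverage in percent; the
#'   renderer adds/removes fragments until realized coverage is within
#'   0.5 percentage points.
#' @param soil_palette 3 x 3 matrix of base soil RGB tones (rows = tones).
#' @param straw_density,clod_density expected confuser counts per 10^4 px.
#' @param drip_belts draw long thin dark drip-irrigation strips (off by
#'   default).
#' @param seed integer seed; identical configs render bit-identical scenes.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(image_height_px = 256L, image_width_px = 256L,
                         weather = c("cloudy", "sunny"), height_m = 5,
                         fragment_count_mean = 8,
                         fragment_area_px_range = c(40L, 4000L),
                         film_brightness_range = c(190, 255),
                         film_alpha_range = c(0.55, 0.95),
                         target_coverage_pct = NULL,
                         soil_palette = default_soil_palette(),
                         straw_density = 4, clod_density = 4,
                         drip_belts = FALSE, seed = 1L) {
  weather <- match.arg(weather)
  if (image_height_px < 1 || image_width_px < 1) {
    stop_input("invalid configuration: image dimensions must be positive")
  }
  if (height_m <= 0) stop_input("invalid configuration: height_m must be > 0")
  if (fragment_count_mean < 0) {
    stop_input("invalid configuration: fragment_count_mean must be >= 0")
  }
  if (length(fragment_area_px_range) != 2 ||
      any(fragment_area_px_range <= 0) ||
      fragment_area_px_range[1] > fragment_area_px_range[2]) {
    stop_input("invalid configuration: fragment_area_px_range must be an ordered pair of positive values")
  }
  if (any(film_brightness_range < 0) || any(film_brightness_range > 255) ||
      film_brightness_range[1] > film_brightness_range[2]) {
    stop_input("invalid configuration: film_brightness_range must be ordered within [0, 255]")
  }
  if (!is.null(target_coverage_pct) &&
      (target_coverage_pct < 0 || target_coverage_pct > 100)) {
    stop_input("invalid configuration: target_coverage_pct must lie in [0, 100]")
  }
  structure(
    list(image_height_px = as.integer(image_height_px),
         image_width_px = as.integer(image_width_px),
         weather = weather, height_m = height_m,
         fragment_count_mean = fragment_count_mean,
         fragment_area_px_range = fragment_area_px_range,
         film_brightness_range = film_brightness_range,
         film_alpha_range = film_alpha_range,
         target_coverage_pct = target_coverage_pct,
         soil_palette = soil_palette,
         straw_density = straw_density, clod_density = clod_density,
         drip_belts = drip_belts, seed = as.integer(seed)),
    class = "scene_config"
  )
}

default_soil_palette <- function() {
  rbind(c(122, 96, 68), c(138, 112, 84), c(104, 82, 58))
}

# Bilinear upsampling of a coarse control grid to H x W (low-frequency
# soil-tone variation).
bilinear_upsample <- function(g, H, W) {
  kh <- nrow(g); kw <- ncol(g)
  if (kh < 2 || kw < 2) return(matrix(g[1, 1], H, W))
  yi <- seq(1, kh, length.out = H)
  xi <- seq(1, kw, length.out = W)
  y0 <- pmin(floor(yi), kh - 1); x0 <- pmin(floor(xi), kw - 1)
  fy <- yi - y0; fx <- xi - x0
  g[y0, x0] * outer(1 - fy, 1 - fx) +
    g[y0 + 1, x0] * outer(fy, 1 - fx) +
    g[y0, x0 + 1] * outer(1 - fy, fx) +
    g[y0 + 1, x0 + 1] * outer(fy, fx)
}

# Linear indices (into an H x W matrix) of pixels inside an axis-rotated
# ellipse centred at (cy, cx) with semi-axes a (along angle) and b.
ellipse_pixels <- function(cy, cx, a, b, angle, H, W) {
  r <- ceiling(max(a, b)) + 1
  i0 <- max(1, floor(cy - r)); i1 <- min(H, ceiling(cy + r))
  j0 <- max(1, floor(cx - r)); j1 <- min(W, ceiling(cx + r))
  if (i0 > i1 || j0 > j1) return(integer(0))
  ii <- rep(i0:i1, times = j1 - j0 + 1)
  jj <- rep(j0:j1, each = i1 - i0 + 1)
  dy <- ii - cy; dx <- jj - cx
  u <- dx * cos(angle) + dy * sin(angle)
  v <- -dx * sin(angle) + dy * cos(angle)
  keep <- (u / a)^2 + (v / b)^2 <= 1
  ii[keep] + (jj[keep] - 1L) * H
}

#' Render the soil background of a synthetic scene
#'
#' Produces brown textured soil with low-frequency tone variation, fine
#' granular noise, bright straw-like line segments and elliptical clods.
#' Under sunny weather the global contrast is increased and a subset of clods
#' receives near-white specular highlights — the confusers that cause soil to
#' be misjudged as film; under cloudy weather illumination is flat.
#'
#' @param config a [scene_config()].
#' @param seed optional override of the background sub-seed (derived from
#'   `config$seed` by default).
#' @return A [field_image()] carrying the config's weather/height metadata.
#' @export
make_background <- function(config, seed = NULL) {
  H <- config$image_height_px; W <- config$image_width_px
  seed <- seed %||% derive_seed(config$seed, 11L)
  with_seed(seed, {
    # low-frequency mix of the three soil tones
    wts <- array(runif(6 * 6 * 3, 0.05, 1), c(6, 6, 3))
    fields <- lapply(1:3, function(t) bilinear_upsample(wts[, , t], H, W))
    tot <- fields[[1]] + fields[[2]] + fields[[3]]
    img <- array(0, c(H, W, 3))
    for (ch in 1:3) {
      for (t in 1:3) {
        img[, , ch] <- img[, , ch] +
          fields[[t]] / tot * config$soil_palette[t, ch]
      }
    }
    # granular noise: shared luminance component + small chromatic jitter
    lum <- matrix(rnorm(H * W, 0, 6), H, W)
    for (ch in 1:3) img[, , ch] <- img[, , ch] + lum + rnorm(H * W, 0, 2)

    # straw-like bright line segments
    n_straw <- rpois(1, config$straw_density * H * W / 1e4)
    if (n_straw > 0) {
      for (k in seq_len(n_straw)) {
        cy <- runif(1, 1, H); cx <- runif(1, 1, W)
        ang <- runif(1, 0, pi); len <- runif(1, 8, 36)
        col <- clip255(c(205, 182, 118) + rnorm(3, 0, 8))
        col <- pmin(col, 235)  # flat-light straw stays below saturation
        t_steps <- seq(-len / 2, len / 2, by = 0.5)
        ii <- round(cy + t_steps * sin(ang)); jj <- round(cx + t_steps * cos(ang))
        keep <- ii >= 1 & ii <= H & jj >= 1 & jj <= W
        idx <- ii[keep] + (jj[keep] - 1) * H
        for (ch in 1:3) {
          pl <- img[, , ch]; pl[idx] <- col[ch]; img[, , ch] <- pl
        }
      }
    }

    # elliptical soil clods (darker or lighter patches)
    n_clod <- rpois(1, config$clod_density * H * W / 1e4)
    clod_centers <- NULL
    if (n_clod > 0) {
      clod_centers <- cbind(runif(n_clod, 1, H), runif(n_clod, 1, W))
      for (k in seq_len(n_clod)) {
        a <- runif(1, 3, 12); b <- a * runif(1, 0.5, 1)
        shade <- sample(c(-1, 1), 1) * runif(1, 10, 28)
        idx <- ellipse_pixels(clod_centers[k, 1], clod_centers[k, 2], a, b,
                              runif(1, 0, pi), H, W)
        if (length(idx) == 0) next
        for (ch in 1:3) {
          pl <- img[, , ch]; pl[idx] <- pl[idx] + shade; img[, , ch] <- pl
        }
      }
    }

    if (config$drip_belts) {
      n_belt <- max(1L, round(W / 200))
      for (k in seq_len(n_belt)) {
        jc <- runif(1, 1, W)
        jj <- round(jc + seq(-1, 1))
        jj <- jj[jj >= 1 & jj <= W]
        img[, jj, ] <- img[, jj, ] * 0.45
      }
    }

    if (config$weather == "sunny") {
      # harsher illumination: contrast stretch + specular glints on clods
      img <- (img - 128) * 1.2 + 136
      if (!is.null(clod_centers)) {
        shiny <- which(runif(nrow(clod_centers)) < 0.5)
        for (k in shiny) {
          idx <- ellipse_pixels(clod_centers[k, 1] + rnorm(1, 0, 1),
                                clod_centers[k, 2] + rnorm(1, 0, 1),
                                runif(1, 1.5, 3.5), runif(1, 1, 2.5),
                                runif(1, 0, pi), H, W)
          if (length(idx) == 0) next
          glint <- runif(1, 245, 255)
          for (ch in 1:3) {
            pl <- img[, , ch]; pl[idx] <- glint; img[, , ch] <- pl
          }
        }
      }
    }
    img <- round(clip255(img))
  })
  field_image(img, weather = config$weather, height_m = config$height_m)
}

# Polygon area by the shoelace formula.
polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# One irregular film fragment: a radially perturbed, rotated ellipse whose
# shoelace area is rescaled to hit the sampled target area exactly.
sample_one_fragment <- function(config, max_area_ref = NULL) {
  lo <- config$fragment_area_px_range[1]
  hi <- config$fragment_area_px_range[2]
  area_ref <- exp(runif(1, log(lo), log(hi)))
  if (!is.null(max_area_ref)) area_ref <- min(area_ref, max(lo, max_area_ref))
  scale2 <- (5 / config$height_m)^2
  area <- area_ref * scale2

  aspect <- runif(1, 0.35, 1)
  a <- sqrt(area / (pi * aspect)); b <- a * aspect
  th <- seq(0, 2 * pi, length.out = 25)[-25]
  pert <- rep(1, length(th))
  for (h in 2:5) pert <- pert + runif(1, 0, 0.12) * cos(h * th + runif(1, 0, 2 * pi))
  px <- a * pert * cos(th); py <- b * pert * sin(th)
  phi <- runif(1, 0, pi)
  rx <- px * cos(phi) - py * sin(phi)
  ry <- px * sin(phi) + py * cos(phi)
  s <- sqrt(area / polygon_area(rx, ry))
  cx <- runif(1, 1, config$image_width_px)
  cy <- runif(1, 1, config$image_height_px)
  list(x = cx + rx * s, y = cy + ry * s, area_px = area,
       brightness = runif(1, config$film_brightness_range[1],
                          config$film_brightness_range[2]),
       alpha = runif(1, config$film_alpha_range[1], config$film_alpha_range[2]))
}

#' Sample film-fragment polygons for a scene
#'
#' Draws a Poisson-distributed number of irregular fragment polygons
#' (perturbed rotated ellipses) with areas log-uniform over
#' `fragment_area_px_range`, scaled by `(5 / height_m)^2` so apparent
#' fragment size shrinks with flight height, positioned uniformly over the
#' frame (overlaps allowed).
#'
#' @param config a [scene_config()].
#' @param seed optional sub-seed override.
#' @return A list of fragments, each with vertex vectors `x`, `y` (frame
#'   coordinates: x = column, y = row), the analytic `area_px`, and the film
#'   appearance draws used at render time.
#' @export
sample_fragments <- function(config, seed = NULL) {
  seed <- seed %||% derive_seed(config$seed, 23L)
  with_seed(seed, {
    n <- rpois(1, config$fragment_count_mean)
    lapply(seq_len(n), function(k) sample_one_fragment(config))
  })
}

# Even-odd ray-casting rasterization; returns linear indices into H x W.
rasterize_polygon <- function(poly, H, W) {
  vx <- poly$x; vy <- poly$y
  j0 <- max(1, floor(min(vx))); j1 <- min(W, ceiling(max(vx)))
  i0 <- max(1, floor(min(vy))); i1 <- min(H, ceiling(max(vy)))
  if (i0 > i1 || j0 > j1) return(integer(0))
  jj <- rep(j0:j1, each = i1 - i0 + 1)
  ii <- rep(i0:i1, times = j1 - j0 + 1)
  inside <- rep(FALSE, length(ii))
  n <- length(vx)
  kprev <- n
  for (k in seq_len(n)) {
    crosses <- (vy[k] > ii) != (vy[kprev] > ii)
    if (any(crosses)) {
      xint <- vx[k] + (ii - vy[k]) * (vx[kprev] - vx[k]) / (vy[kprev] - vy[k])
      inside <- xor(inside, crosses & (jj < xint))
    }
    kprev <- k
  }
  ii[inside] + (jj[inside] - 1L) * H
}

#' Render a complete synthetic scene with its exact ground-truth mask
#'
#' Composites film fragments over a [make_background()] raster with
#' near-white film colour, partial alpha (soil texture bleeds through) and a
#' specular streak per fragment, then applies Gaussian blur with
#' `sigma = 0.4 * height_m / 5` so higher flights are softer.  The mask is
#' the exact union of rasterized fragment supports and is never blurred.
#' When `target_coverage_pct` is set, fragments are added or removed (up to
#' 200 attempts) until realized coverage is within 0.5 percentage points.
#'
#' @param config a [scene_config()].
#' @return An object of class `scene`: list with `image` ([field_image()]),
#'   `mask` ([binary_mask()]), `realized_coverage_pct` (exactly
#'   `100 * foreground / total` of the mask) and `config_used`.
#' @export
render_scene <- function(config) {
  bg <- make_background(config)
  H <- config$image_height_px; W <- config$image_width_px
  img <- bg$pixels * 1.0
  total_px <- H * W
  target <- config$target_coverage_pct

  frag_seed <- derive_seed(config$seed, 23L)
  frags <- list(); frag_idx <- list()
  mask <- matrix(0L, H, W)

  if (is.null(target)) {
    frags <- sample_fragments(config)
    frag_idx <- lapply(frags, rasterize_polygon, H = H, W = W)
    for (idx in frag_idx) mask[idx] <- 1L
  } else if (target > 0) {
    with_seed(frag_seed, {
      scale2 <- (5 / config$height_m)^2
      attempts <- 0L
      repeat {
        cov <- 100 * sum(mask) / total_px
        if (abs(cov - target) <= 0.5) break
        if (attempts >= 200L) {
          stop_input("generation failure: could not reach target coverage %.2f%% within 200 attempts (achieved %.3f%%)",
                     target, cov)
        }
        attempts <- attempts + 1L
        if (cov < target) {
          deficit_px <- (target - cov) / 100 * total_px
          fr <- sample_one_fragment(config,
                                    max_area_ref = 1.1 * deficit_px / scale2)
          idx <- rasterize_polygon(fr, H, W)
          frags[[length(frags) + 1L]] <- fr
          frag_idx[[length(frag_idx) + 1L]] <- idx
          mask[idx] <- 1L
        } else {
          # drop a random fragment and rebuild the union
          drop <- sample.int(length(frags), 1)
          frags <- frags[-drop]; frag_idx <- frag_idx[-drop]
          mask <- matrix(0L, H, W)
          for (idx in frag_idx) mask[idx] <- 1L
        }
      }
    })
  }

  # composite fragments (deterministic streak placement from the fragment
  # geometry itself, so no RNG is consumed here)
  for (k in seq_along(frags)) {
    fr <- frags[[k]]; idx <- frag_idx[[k]]
    if (length(idx) == 0) next
    v <- fr$brightness; al <- fr$alpha
    col <- c(v, v * 0.985, v * 0.96)
    for (ch in 1:3) {
      pl <- img[, , ch]
      pl[idx] <- al * col[ch] + (1 - al) * pl[idx]
      img[, , ch] <- pl
    }
    # specular streak: a thin band across the fragment
    rows <- ((idx - 1L) %% H) + 1L
    band <- idx[abs(rows - round(mean(rows))) <= 1]
    if (length(band) > 0) {
      for (ch in 1:3) {
        pl <- img[, , ch]
        pl[band] <- pmin(255, pl[band] + 18)
        img[, , ch] <- pl
      }
    }
  }

  sigma <- 0.4 * config$height_m / 5
  img <- blur_rgb(img, sigma)
  img <- round(clip255(img))

  realized <- 100 * sum(mask) / total_px
  structure(
    list(image = field_image(img, weather = config$weather,
                             height_m = config$height_m),
         mask = binary_mask(mask),
         realized_coverage_pct = realized,
         config_used = config),
    class = "scene"
  )
}

# Channel-wise Gaussian blur via EBImage.
blur_rgb <- function(img, sigma) {
  if (sigma <= 0) return(img)
  H <- dim(img)[1]; W <- dim(img)[2]
  out <- img
  for (ch in 1:3) {
    e <- EBImage::Image(t(img[, , ch]) / 255)
    b <- EBImage::gblur(e, sigma = sigma)
    out[, , ch] <- t(EBImage::imageData(b)) * 255
  }
  out
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene %dx%d px, %s, %g m, coverage %.3f%%>\n",
              x$config_used$image_width_px, x$config_used$image_height_px,
              x$config_used$weather, x$config_used$height_m,
              x$realized_coverage_pct))
  invisible(x)
}

#' Generate a synthetic dataset on disk with a manifest
#'
#' Writes `n_images` image/mask PNG pairs plus a `manifest.csv` with header
#' `filename,split,weather,height_m,true_coverage_pct,seed`.  Weather and
#' height are assigned in a balanced grid over `weathers x heights`
#' (mirroring a balanced flight-campaign design), and the train/validation/
#' test split follows [split_dataset()] with ratios 0.8/0.1/0.1, so 600
#' images partition into 480/60/60.  Fully reproducible from `seed`.
#'
#' @param n_images number of scenes to generate.
#' @param base_config a [scene_config()]; weather/height/seed are overridden
#'   per image.
#' @param out_dir output directory (created if missing).
#' @param seed master seed.
#' @param heights,weathers the balanced-grid levels.
#' @return The manifest as a data.frame (invisibly written to
#'   `out_dir/manifest.csv`).
#' @export
generate_dataset <- function(n_images, base_config, out_dir, seed = 1L,
                             heights = c(5, 7, 9),
                             weathers = c("sunny", "cloudy")) {
  if (n_images < 1) stop_input("n_images must be >= 1")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop_input("cannot create output directory '%s'", out_dir)

  cells <- expand.grid(weather = weathers, height_m = heights,
                       stringsAsFactors = FALSE)
  rows <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    cell <- cells[((i - 1L) %% nrow(cells)) + 1L, ]
    cfg <- base_config
    cfg$weather <- cell$weather
    cfg$height_m <- cell$height_m
    cfg$seed <- derive_seed(seed, 1000L + i)
    sc <- render_scene(cfg)
    fname <- sprintf("scene_%04d.png", i)
    save_pair(sc$image, sc$mask,
              file.path(out_dir, fname),
              file.path(out_dir, mask_filename(fname)))
    rows[[i]] <- data.frame(filename = fname, weather = cell$weather,
                            height_m = cell$height_m,
                            true_coverage_pct = sc$realized_coverage_pct,
                            seed = cfg$seed, stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  sp <- split_dataset(manifest$filename, c(0.8, 0.1, 0.1), seed = seed)
  manifest$split <- "train"
  manifest$split[manifest$filename %in% sp$validation] <- "validation"
  manifest$split[manifest$filename %in% sp$test] <- "test"
  manifest <- manifest[, c("filename", "split", "weather", "height_m",
                           "true_coverage_pct", "seed")]
  manifest$true_coverage_pct <- sprintf("%.6f", manifest$true_coverage_pct)
  write.csv(manifest, file.path(out_dir, "manifest.csv"),
            row.names = FALSE, quote = FALSE)
  manifest$true_coverage_pct <- as.numeric(manifest$true_coverage_pct)
  manifest
}

mask_filename <- function(image_filename) {
  sub("\\.png$", "_mask.png", image_filename)
}
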