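test_that("inception block preserves spatial size and hits out_channels", {
  spec <- inception_spec(5, 4, 7)
  blk <- build_inception_block(spec, seed = 2)
  x <- array(rnorm(10 * 12 * 5), c(10, 12, 5))
  out <- inception_forward(blk, x)
  expect_identical(dim(out), c(10L, 12L, 7L))
  # two builds from the same spec/seed have identical parameters
  blk2 <- build_inception_block(spec, seed = 2)
  expect_identical(blk$params, blk2$params)
})

test_that("inception block parameter count matches the closed form", {
  for (case in list(c(3, 4, 8), c(16, 8, 16), c(7, 3, 5))) {
    blk <- build_inception_block(inception_spec(case[1], case[2], case[3]))
    expect_identical(count_params(blk),
                     inception_param_count(case[1], case[2], case[3]))
  }
  expect_error(inception_spec(0, 4, 8), "positive")
})

test_that("default network lands in the ~3.14M parameter budget", {
  m <- build_modified_unet()
  n <- count_params(m)
  expect_gte(n, 0.85 * 3.14e6)
  expect_lte(n, 1.15 * 3.14e6)
  # under 1/8 of the classic U-Net reference (4 poolings, base 64, two
  # 3x3 convolutions per stage)
  expect_lt(n / classic_unet_param_count(), 1 / 8)
})

test_that("parameter count scales roughly quadratically with width", {
  narrow <- model_config(encoder_channels = c(16L, 32L, 64L),
                         bottleneck_channels = 128L)
  wide <- model_config(encoder_channels = c(32L, 64L, 128L),
                       bottleneck_channels = 256L)
  r <- count_params(build_modified_unet(wide)) /
    count_params(build_modified_unet(narrow))
  expect_gt(r, 3.5)
  expect_lt(r, 4.5)
})

test_that("forward pass yields per-pixel probabilities of the input shape", {
  m <- build_modified_unet(model_config(encoder_channels = c(4L, 8L, 16L),
                                        bottleneck_channels = 32L), seed = 3)
  x <- array(runif(48 * 64 * 3, 0, 255), c(48, 64, 3))
  p <- predict_probs(m, x)
  expect_identical(dim(p), c(48L, 64L, 2L))
  expect_equal(p[, , 1] + p[, , 2], matrix(1, 48, 64), tolerance = 1e-12)
  # determinism: two forward passes agree exactly
  expect_identical(p, predict_probs(m, x))
})

test_that("indivisible inputs error in the raw forward but pad in predict_mask", {
  m <- build_modified_unet(model_config(encoder_channels = c(4L, 8L, 16L),
                                        bottleneck_channels = 32L), seed = 3)
  x <- array(runif(47 * 63 * 3, 0, 255), c(47, 63, 3))
  expect_error(rfilm:::unet_forward(m, x / 255), "divisible")
  mk <- predict_mask(m, x)
  expect_identical(dim(mk$labels), c(47L, 63L))
})

test_that("argmax decoding breaks ties toward background", {
  # equal logits everywhere -> probabilities exactly 0.5/0.5 -> background
  probs <- array(0.5, c(4, 4, 2))
  dec <- matrix(as.integer(probs[, , 2] > probs[, , 1]), 4, 4)
  m <- build_modified_unet(model_config(encoder_channels = c(2L, 4L, 6L),
                                        bottleneck_channels = 8L), seed = 1)
  # zero out the head so every pixel gets identical class scores
  m$params$head$w[] <- 0
  m$params$head$b[] <- 0
  mk <- predict_mask(m, array(runif(16 * 16 * 3, 0, 255), c(16, 16, 3)))
  expect_true(all(mk$labels == 0L))
  expect_true(all(dec == 0L))
})

test_that("analytic gradients match finite differences through the whole net", {
  set.seed(42)
  m <- build_modified_unet(model_config(encoder_channels = c(2L, 4L, 6L),
                                        bottleneck_channels = 8L), seed = 7)
  # jitter biases: zero-initialized biases put ReLU-dead pixels exactly on
  # the kink where the subgradient is ambiguous
  for (sn in names(m$params)) {
    for (pn in names(m$params[[sn]])) {
      if (grepl("b$", pn)) {
        m$params[[sn]][[pn]] <- rnorm(length(m$params[[sn]][[pn]]), 0, 0.1)
      }
    }
  }
  x <- array(runif(8 * 8 * 3), c(8, 8, 3))
  lab <- matrix(rbinom(64, 1, 0.4), 8, 8)
  fw <- rfilm:::unet_forward(m, x, keep_cache = TRUE)
  sc <- rfilm:::softmax_ce(fw$logits, lab)
  gr <- rfilm:::unet_backward(m, fw$cache, sc$glogits)
  lossfun <- function(mm) {
    rfilm:::softmax_ce(rfilm:::unet_forward(mm, x)$logits, lab)$loss
  }
  eps <- 1e-6
  set.seed(1)
  for (rep in 1:40) {
    sn <- sample(names(m$params), 1)
    pn <- sample(names(m$params[[sn]]), 1)
    k <- sample(length(m$params[[sn]][[pn]]), 1)
    mp <- m; mp$params[[sn]][[pn]][k] <- mp$params[[sn]][[pn]][k] + eps
    mm <- m; mm$params[[sn]][[pn]][k] <- mm$params[[sn]][[pn]][k] - eps
    num <- (lossfun(mp) - lossfun(mm)) / (2 * eps)
    ana <- gr[[sn]][[pn]][k]
    expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-4)
  }
})

test_that("checkpoints round-trip bit-exactly", {
  m <- build_modified_unet(model_config(encoder_channels = c(2L, 4L, 6L),
                                        bottleneck_channels = 8L), seed = 5)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  back <- load_checkpoint(path)
  expect_identical(back$params, m$params)
  expect_identical(back$config, m$config)
})
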