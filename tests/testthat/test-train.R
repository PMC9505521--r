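small_model <- function(seed = 1) {
  build_modified_unet(model_config(encoder_channels = c(4L, 8L, 16L),
                                   bottleneck_channels = 32L), seed = seed)
}

small_pairs <- function(n, seed0 = 100, h = 32, w = 32) {
  lapply(seq_len(n), function(i) tiny_pair(h, w, seed = seed0 + i))
}

test_that("training honours the epoch contract and writes a checkpoint", {
  tr <- small_pairs(8)
  va <- small_pairs(2, seed0 = 200)
  aug <- augment_config(crop_width = 32L, crop_height = 32L, seed = 1)
  fit <- train_model(small_model(), tr, va, aug,
                     train_config(epochs = 2L, seed = 2))
  expect_identical(nrow(fit$history), 2L)
  expect_true(file.exists(fit$checkpoint_path))
  expect_identical(fit$samples_streamed, 16L)
  expect_true(fit$best_epoch %in% 1:2)
})

test_that("reloading the checkpoint reproduces the best recorded val_loss", {
  tr <- small_pairs(6)
  va <- small_pairs(2, seed0 = 300)
  aug <- augment_config(crop_width = 32L, crop_height = 32L, seed = 3)
  fit <- train_model(small_model(2), tr, va, aug,
                     train_config(epochs = 3L, seed = 4))
  best <- min(fit$history$val_loss)
  reloaded <- load_checkpoint(fit$checkpoint_path)
  re_eval <- rfilm:::eval_loss_acc(reloaded, va)
  expect_equal(unname(re_eval["loss"]), best, tolerance = 1e-12)
  expect_equal(fit$history$val_loss[fit$best_epoch], best)
})

test_that("a zero learning rate leaves the weights unchanged", {
  tr <- small_pairs(4)
  va <- small_pairs(2, seed0 = 400)
  aug <- augment_config(crop_width = 32L, crop_height = 32L, seed = 5)
  m <- small_model(3)
  fit <- train_model(m, tr, va, aug,
                     train_config(learning_rate = 0, epochs = 1L, seed = 6))
  expect_identical(fit$model$params, m$params)
})

test_that("divergence aborts with a diagnostic naming the epoch", {
  tr <- small_pairs(4)
  va <- small_pairs(2, seed0 = 500)
  aug <- augment_config(crop_width = 32L, crop_height = 32L, seed = 7)
  m <- small_model(4)
  m$params$head$w[] <- 1e308  # force an immediate overflow
  expect_error(
    train_model(m, tr, va, aug, train_config(epochs = 1L, seed = 8)),
    "epoch 1")
})

test_that("evaluate_model stratifies by metadata and a perfect predictor is 100%", {
  pairs <- lapply(1:4, function(i) {
    p <- tiny_pair(16, 16, seed = 600 + i)
    p$weather <- if (i %% 2 == 0) "sunny" else "cloudy"
    p$height_m <- c(5, 9)[(i > 2) + 1]
    p
  })
  preds <- lapply(pairs, `[[`, "mask")  # truth fed as prediction
  tab <- evaluate_model(NULL, pairs, group_by = "weather", predictions = preds)
  expect_identical(nrow(tab), 3L)  # overall + 2 weather rows
  expect_true(all(tab$miou_per_image_mean == 100))
  expect_true(all(tab$miou_pooled == 100))

  tab_h <- evaluate_model(NULL, pairs, group_by = "height_m",
                          predictions = preds)
  expect_identical(tab_h$group, c("overall", "height_m=5", "height_m=9"))
  expect_error(evaluate_model(NULL, pairs, group_by = "bogus",
                              predictions = preds), "unknown group_by")

  csv <- tempfile(fileext = ".csv")
  evaluate_model(NULL, pairs, predictions = preds, csv_path = csv)
  expect_true(file.exists(csv))
  expect_identical(read.csv(csv)$group[1], "overall")
})

test_that("unet_fit methods print, summarise, plot and predict", {
  tr <- small_pairs(4)
  va <- small_pairs(2, seed0 = 700)
  aug <- augment_config(crop_width = 32L, crop_height = 32L, seed = 9)
  fit <- train_model(small_model(5), tr, va, aug,
                     train_config(epochs = 1L, seed = 10))
  expect_output(print(fit), "unet_fit")
  expect_output(summary(fit), "Training history")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
  mk <- predict(fit, tr[[1]]$image)
  expect_s3_class(mk, "binary_mask")
  pr <- predict(fit, tr[[1]]$image, type = "prob")
  expect_identical(dim(pr), c(32L, 32L, 2L))
})
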