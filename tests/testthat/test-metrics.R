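test_that("confusion counts match trivially constructed cases", {
  ones <- matrix(1L, 10, 10)
  ct <- confusion(ones, ones)
  expect_identical(c(ct$TP, ct$TN, ct$FP, ct$FN), c(100L, 0L, 0L, 0L))

  truth <- matrix(c(1L, 1L, 0L, 0L), 2, 2)
  ct2 <- confusion(1L - truth, truth)
  expect_identical(c(ct2$TP, ct2$TN, ct2$FP, ct2$FN), c(0L, 0L, 2L, 2L))

  expect_error(confusion(matrix(0L, 2, 2), matrix(0L, 3, 3)), "shapes differ")
})

test_that("confusion agrees with the double-loop oracle on random masks", {
  set.seed(10)
  pred <- matrix(rbinom(64 * 64, 1, 0.5), 64, 64)
  truth <- matrix(rbinom(64 * 64, 1, 0.3), 64, 64)
  ct <- confusion(pred, truth)
  oc <- oracle_confusion(pred, truth)
  expect_identical(ct$TP, oc$TP)
  expect_identical(ct$TN, oc$TN)
  expect_identical(ct$FP, oc$FP)
  expect_identical(ct$FN, oc$FN)
})

test_that("metric panel reproduces the hand-computed example", {
  ct <- structure(list(TP = 50, TN = 30, FP = 10, FN = 10),
                  class = "confusion_counts")
  p <- panel(ct)
  expect_equal(p$accuracy, 0.80)
  expect_equal(p$precision, 50 / 60, tolerance = 1e-12)
  expect_equal(p$recall, 50 / 60, tolerance = 1e-12)
  expect_equal(p$f1, 50 / 60, tolerance = 1e-12)
  expect_equal(p$iou, 0.5 * (50 / 70 + 30 / 50), tolerance = 1e-12)
})

test_that("vacuously absent classes score 1, perfect masks score 1 everywhere", {
  empty_film <- panel(structure(list(TP = 0, TN = 100, FP = 0, FN = 0),
                                class = "confusion_counts"))
  expect_equal(empty_film$accuracy, 1)
  expect_equal(empty_film$iou, 1)
  expect_equal(empty_film$precision, 1)

  perfect <- panel(structure(list(TP = 40, TN = 60, FP = 0, FN = 0),
                             class = "confusion_counts"))
  expect_true(all(unlist(perfect[c("accuracy", "precision", "recall",
                                   "f1", "iou")]) == 1))
})

test_that("panel agrees with the brute-force oracle on 100 random 64x64 pairs", {
  set.seed(77)
  for (rep in 1:100) {
    pred <- matrix(rbinom(64 * 64, 1, runif(1)), 64, 64)
    truth <- matrix(rbinom(64 * 64, 1, runif(1)), 64, 64)
    p <- panel(confusion(pred, truth))
    o <- oracle_panel(oracle_confusion(pred, truth))
    for (nm in names(o)) expect_lt(abs(p[[nm]] - o[[nm]]), 1e-12)
  }
})

test_that("two-class IoU is symmetric under label swap", {
  set.seed(4)
  for (rep in 1:20) {
    pred <- matrix(rbinom(256, 1, runif(1)), 16, 16)
    truth <- matrix(rbinom(256, 1, runif(1)), 16, 16)
    a <- panel(confusion(pred, truth))$iou
    b <- panel(confusion(1L - pred, 1L - truth))$iou
    expect_equal(a, b, tolerance = 1e-14)
  }
})

test_that("accuracy dominates each class proportion", {
  set.seed(8)
  for (rep in 1:20) {
    pred <- matrix(rbinom(100, 1, runif(1)), 10, 10)
    truth <- matrix(rbinom(100, 1, runif(1)), 10, 10)
    ct <- confusion(pred, truth)
    acc <- panel(ct)$accuracy
    expect_gte(acc, ct$TP / 100)
    expect_gte(acc, ct$TN / 100)
  }
})

test_that("miou_over_set averages per image and pools counts correctly", {
  # pred marks the first a pixels film, truth the first k (k <= a)
  mk <- function(a, k) {
    pred <- matrix(0L, 10, 10); truth <- matrix(0L, 10, 10)
    pred[seq_len(a)] <- 1L
    truth[seq_len(k)] <- 1L
    list(pred = pred, truth = truth)
  }
  p1 <- mk(40, 20); p2 <- mk(30, 25)
  i1 <- panel(confusion(p1$pred, p1$truth))$iou
  i2 <- panel(confusion(p2$pred, p2$truth))$iou
  expect_equal(i1, 0.5 * (20 / 40 + 60 / 80), tolerance = 1e-12)
  expect_equal(miou_over_set(list(p1, p2)), mean(c(i1, i2)), tolerance = 1e-12)

  # single image: both modes equal the image value
  expect_equal(miou_over_set(list(p1), "per_image_mean"),
               miou_over_set(list(p1), "pooled"), tolerance = 1e-12)

  # pooled mode equals the panel of elementwise-summed counts
  set.seed(12)
  pairs <- lapply(1:10, function(i) {
    list(pred = matrix(rbinom(64, 1, 0.5), 8, 8),
         truth = matrix(rbinom(64, 1, 0.5), 8, 8))
  })
  cts <- lapply(pairs, function(p) oracle_confusion(p$pred, p$truth))
  summed <- structure(list(TP = sum(sapply(cts, `[[`, "TP")),
                           TN = sum(sapply(cts, `[[`, "TN")),
                           FP = sum(sapply(cts, `[[`, "FP")),
                           FN = sum(sapply(cts, `[[`, "FN"))),
                      class = "confusion_counts")
  expect_equal(miou_over_set(pairs, "pooled"), panel(summed)$iou,
               tolerance = 1e-12)
  expect_error(miou_over_set(list()), "empty")
})
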