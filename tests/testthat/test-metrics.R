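test_that("dice and jaccard match hand counts, identities, and each other", {
  x <- matrix(0, 4, 4); x[1:2, 1:2] <- 1 # |X| = 4
  y <- matrix(0, 4, 4); y[2:3, 1:2] <- 1 # |Y| = 4, overlap 2
  expect_equal(dice_coefficient(x, y), 0.5)
  expect_equal(jaccard_index(x, y), 2 / 6)
  expect_equal(dice_coefficient(x, x), 1)
  expect_equal(jaccard_index(y, y), 1)
  z <- matrix(0, 4, 4); z[4, 4] <- 1
  expect_equal(dice_coefficient(x, z), 0)
  expect_warning(v <- dice_coefficient(matrix(0, 2, 2), matrix(0, 2, 2)), "empty")
  expect_equal(v, 1)
})

test_that("overlap metrics agree with counting oracles and J = D/(2-D)", {
  set.seed(10)
  for (i in 1:100) {
    x <- random_blob_mask(16L)
    y <- random_blob_mask(16L)
    d <- dice_coefficient(x, y)
    j <- jaccard_index(x, y)
    expect_equal(d, oracle_dice(x, y), tolerance = 1e-9)
    expect_equal(j, oracle_jaccard(x, y), tolerance = 1e-9)
    expect_equal(j, d / (2 - d), tolerance = 1e-12)
    expect_gte(d, j)
  }
})

test_that("sensitivity and specificity follow the confusion-count formulas", {
  expect_equal(sensitivity_specificity(confusion_counts(tp = 9, fp = 0, tn = 1, fn = 1))$sensitivity, 0.9)
  r <- sensitivity_specificity(confusion_counts(tp = 88, fp = 14, tn = 86, fn = 12))
  expect_equal(r$sensitivity, 0.88)
  expect_equal(r$specificity, 0.86)
  expect_error(sensitivity_specificity(confusion_counts(tp = 1, fp = 0, tn = 0, fn = 0)),
               "specificity")
  expect_error(sensitivity_specificity(confusion_counts(tp = 0, fp = 2, tn = 1, fn = 0)),
               "sensitivity")
})

test_that("AUC matches the all-pairs oracle and its symmetries", {
  expect_equal(auc_roc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc_roc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  set.seed(11)
  for (i in 1:30) {
    scores <- round(runif(20), 2) # rounding forces ties
    labels <- rbinom(20, 1, 0.5)
    if (length(unique(labels)) < 2) next
    a <- auc_roc(scores, labels)
    expect_equal(a, oracle_auc(scores, labels), tolerance = 1e-12)
    expect_equal(auc_roc(1 - scores, labels), 1 - a, tolerance = 1e-12)
  }
  expect_error(auc_roc(1:3, c(1, 1, 1)), "both classes")
})

test_that("hd95 identities: zero on equality, distance between singletons", {
  m <- matrix(0, 10, 10); m[4:6, 4:6] <- 1
  expect_equal(hd95(m, m), 0)
  a <- matrix(0, 10, 10); a[5, 2] <- 1
  b <- matrix(0, 10, 10); b[5, 7] <- 1
  expect_equal(hd95(a, b), 5)
  expect_equal(hd95(a, b, spacing = c(1, 2)), 10)
  expect_error(hd95(a, matrix(0, 10, 10)), "non-empty")
})

test_that("hd95 matches the exhaustive distance-matrix oracle and is symmetric", {
  set.seed(12)
  for (i in 1:50) {
    x <- random_blob_mask(16L)
    y <- random_blob_mask(16L)
    h <- hd95(x, y)
    expect_equal(h, oracle_hd95(x, y), tolerance = 1e-9)
    expect_equal(hd95(y, x), h, tolerance = 1e-12)
    expect_gte(h, 0)
  }
})

test_that("metrics are invariant to joint translation of interior masks", {
  set.seed(13)
  x <- matrix(0, 20, 20); x[6:10, 6:9] <- 1
  y <- matrix(0, 20, 20); y[7:11, 7:10] <- 1
  shift <- function(m, dr, dc) {
    out <- matrix(0, nrow(m), ncol(m))
    idx <- which(m > 0, arr.ind = TRUE)
    out[cbind(idx[, 1] + dr, idx[, 2] + dc)] <- 1
    out
  }
  for (d in list(c(2, 3), c(-3, 1), c(0, 5))) {
    xs <- shift(x, d[1], d[2]); ys <- shift(y, d[1], d[2])
    expect_equal(dice_coefficient(xs, ys), dice_coefficient(x, y))
    expect_equal(jaccard_index(xs, ys), jaccard_index(x, y))
    expect_equal(hd95(xs, ys), hd95(x, y), tolerance = 1e-12)
  }
})

test_that("dataset evaluation averages per-sample metrics and pools pixels", {
  set.seed(14)
  preds <- replicate(10, random_blob_mask(12L), simplify = FALSE)
  truths <- replicate(10, random_blob_mask(12L), simplify = FALSE)
  rep <- evaluate_dataset(preds, truths)
  expect_equal(rep$dice,
               mean(mapply(oracle_dice, preds, truths)), tolerance = 1e-12)
  expect_equal(rep$jaccard,
               mean(mapply(oracle_jaccard, preds, truths)), tolerance = 1e-12)
  expect_equal(rep$hd95,
               mean(mapply(oracle_hd95, preds, truths)), tolerance = 1e-9)
  expect_equal(rep$n_samples, 10L)
  tp <- sum(mapply(function(p, g) sum(p > 0 & g > 0), preds, truths))
  fn <- sum(mapply(function(p, g) sum(p == 0 & g > 0), preds, truths))
  expect_equal(rep$sensitivity, tp / (tp + fn))
})

test_that("perfect, empty, and misaligned predictions follow the conventions", {
  g <- matrix(0, 8, 8); g[3:5, 3:5] <- 1
  rep <- evaluate_dataset(list(g), list(g))
  expect_equal(rep$dice, 1)
  expect_equal(rep$jaccard, 1)
  expect_equal(rep$hd95, 0)
  # empty prediction vs non-empty truth: dice 0, hd95 skipped and flagged
  rep2 <- evaluate_dataset(list(matrix(0, 8, 8)), list(g))
  expect_equal(rep2$dice, 0)
  expect_true(is.na(rep2$hd95))
  expect_equal(rep2$hd95_skipped, 1L)
  expect_error(evaluate_dataset(list(g), list(g, g)), "aligned")
})

test_that("classification block reports accuracy, AUC, and gate confusion", {
  g1 <- matrix(0, 8, 8); g1[2:4, 2:4] <- 1
  g0 <- matrix(0, 8, 8)
  rep <- evaluate_dataset(
    predictions = list(g1, g0, g0, g1),
    ground_truths = list(g1, g0, g0, g0),
    class_probs = c(0.9, 0.2, 0.6, 0.8),
    class_labels = c("tumor", "non_tumor", "non_tumor", "non_tumor")
  )
  expect_equal(rep$classification$accuracy, 0.5)
  expect_equal(rep$classification$confusion$tp, 1)
  expect_equal(rep$classification$confusion$fp, 2)
  expect_equal(rep$auc_roc, oracle_auc(c(0.9, 0.2, 0.6, 0.8), c(1, 0, 0, 0)))
})
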