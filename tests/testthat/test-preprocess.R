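test_that("z-score normalization matches direct arithmetic and is idempotent", {
  out <- zscore_normalize(matrix(c(1, 2, 3, 4), 2, 2))
  expect_equal(sort(as.vector(out$image)),
               c(-1.3416408, -0.4472136, 0.4472136, 1.3416408),
               tolerance = 1e-6)
  expect_equal(mean(out$image), 0, tolerance = 1e-6)
  expect_equal(sqrt(mean(out$image^2)), 1, tolerance = 1e-6)
  again <- zscore_normalize(out$image)
  expect_equal(again$image, out$image, tolerance = 1e-6)
  expect_error(zscore_normalize(matrix(5, 3, 3)), "degenerate")
})

test_that("normalization is invariant to positive affine intensity maps", {
  set.seed(2)
  x <- matrix(rnorm(64), 8, 8)
  for (i in 1:5) {
    a <- runif(1, 0.1, 10)
    b <- runif(1, -5, 5)
    expect_equal(zscore_normalize(a * x + b)$image, zscore_normalize(x)$image,
                 tolerance = 1e-6)
  }
})

test_that("resize identities, constants, and the 2x block-mean oracle", {
  set.seed(3)
  x <- matrix(rnorm(64), 8, 8)
  expect_identical(resize_image(x, 8L), x)
  expect_equal(resize_image(matrix(2.5, 6, 6), 12L), matrix(2.5, 12, 12))
  # 2x bilinear downsample of a 4x4 image = mean of each 2x2 block
  y <- matrix(rnorm(16), 4, 4)
  down <- resize_image(y, 2L, method = "bilinear")
  manual <- matrix(c(mean(y[1:2, 1:2]), mean(y[3:4, 1:2]),
                     mean(y[1:2, 3:4]), mean(y[3:4, 3:4])), 2, 2)
  expect_equal(down, manual, tolerance = 1e-12)
  # nearest keeps masks binary
  m <- matrix(rbinom(64, 1, 0.4), 8, 8)
  up <- resize_image(m, 32L, method = "nearest")
  expect_true(all(up %in% c(0, 1)))
  expect_error(resize_image(x, 0L), "positive")
})

test_that("augmentation identity, involution, and exact translation", {
  set.seed(4)
  img <- matrix(rnorm(256), 16, 16)
  msk <- matrix(0, 16, 16); msk[8, 8] <- 1
  p0 <- augmentation_params(rotation_deg_max = 0, translate_px_max = 0,
                            hflip = FALSE, vflip = FALSE, seed = 1L)
  out <- augment_pair(img, msk, p0, 1L)
  expect_equal(out$image, img, tolerance = 1e-12)
  expect_equal(out$mask, msk)

  # a horizontal flip applied twice recovers the input
  flip1 <- tumorseg:::affine_sample(img, 0, 0, 0, TRUE, FALSE, "bilinear")
  flip2 <- tumorseg:::affine_sample(flip1, 0, 0, 0, TRUE, FALSE, "bilinear")
  expect_equal(flip2, img, tolerance = 1e-12)

  # translation (+3, 0): the positive pixel moves exactly 3 columns
  shifted <- tumorseg:::affine_sample(msk, 0, 3, 0, FALSE, FALSE, "nearest")
  expect_equal(which(shifted > 0, arr.ind = TRUE)[1, ],
               c(row = 8L, col = 11L))

  expect_error(augment_pair(img, matrix(0, 4, 4), p0), "match")
})

test_that("augmentation draws are deterministic and preserve mask binarity/area", {
  p <- augmentation_params(seed = 77L)
  spec <- phantom_spec(image_size = 32L, tumor_prevalence = 1,
                       tumor_radius_range = c(4, 6), seed = 5L)
  s <- generate_phantom(spec, 1L, 1L)
  a1 <- augment_pair(s$image, s$mask, p, 9L)
  a2 <- augment_pair(s$image, s$mask, p, 9L)
  expect_identical(a1, a2)
  expect_true(all(a1$mask %in% c(0, 1)))
  # pure flips and translations of an interior tumor preserve its pixel count
  pt <- augmentation_params(rotation_deg_max = 0, translate_px_max = 4,
                            hflip = TRUE, vflip = TRUE, seed = 3L)
  for (k in 1:10) {
    ak <- augment_pair(s$image, s$mask, pt, k)
    expect_equal(sum(ak$mask), sum(s$mask))
  }
})

test_that("stratified split allocates 6/2/2 subjects and is reproducible", {
  spec <- phantom_spec(n_subjects = 10L, slices_per_subject = 2L,
                       tumor_prevalence = 0.5, seed = 8L)
  ds <- generate_dataset(spec)
  sp <- split_spec(fractions = c(0.6, 0.2, 0.2), seed = 42L)
  s1 <- stratified_subject_split(ds$manifest, sp)
  counts <- vapply(s1[c("train", "val", "test")],
                   function(m) length(unique(m$subject_id)), integer(1))
  expect_equal(unname(counts), c(6L, 2L, 2L))
  for (nm in c("train", "val", "test")) {
    expect_setequal(unique(s1[[nm]]$label), c("tumor", "non_tumor"))
  }
  s2 <- stratified_subject_split(ds$manifest, sp)
  expect_identical(s1$assignment, s2$assignment)
  d1 <- file.path(tempdir(), "sp1"); d2 <- file.path(tempdir(), "sp2")
  write_split(s1, d1); write_split(s2, d2)
  for (f in c("train.csv", "val.csv", "test.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("splits are always subject-disjoint and exhaustive", {
  set.seed(99)
  for (rep in 1:1000) {
    n_pos <- sample(3:12, 1)
    n_neg <- sample(3:12, 1)
    man <- data.frame(
      subject_id = c(paste0("p", 1:n_pos), paste0("n", 1:n_neg)),
      label = c(rep("tumor", n_pos), rep("non_tumor", n_neg))
    )
    man <- man[rep(seq_len(nrow(man)), each = 2), ] # two slices per subject
    sp <- stratified_subject_split(man, split_spec(seed = rep))
    subs <- lapply(sp[c("train", "val", "test")],
                   function(m) unique(m$subject_id))
    expect_length(intersect(subs$train, subs$val), 0L)
    expect_length(intersect(subs$train, subs$test), 0L)
    expect_length(intersect(subs$val, subs$test), 0L)
    expect_setequal(unlist(subs), unique(man$subject_id))
  }
})

test_that("split validation: mixed-label subjects and tiny classes are rejected", {
  man <- data.frame(subject_id = c("a", "a", "b", "c", "d"),
                    label = c("tumor", "non_tumor", "tumor", "tumor", "non_tumor"))
  expect_error(stratified_subject_split(man), "mixed labels")
  man2 <- data.frame(subject_id = c("a", "b", "c", "d"),
                     label = c("tumor", "tumor", "tumor", "non_tumor"))
  expect_error(stratified_subject_split(man2), "stratification")
})

test_that("split proportions reproduce the 0.622/0.155/0.223 design at scale", {
  man <- data.frame(subject_id = sprintf("s%03d", 1:200),
                    label = rep(c("tumor", "non_tumor"), each = 100))
  sp <- stratified_subject_split(man, split_spec())
  frac <- vapply(sp[c("train", "val", "test")], nrow, integer(1)) / nrow(man)
  expect_equal(unname(frac), c(0.622, 0.155, 0.223), tolerance = 0.02)
})
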