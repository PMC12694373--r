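# synthetic scene generation, augmentation, noise, serialization

test_that("generated datasets honour counts, bounds and the seed", {
  spec <- scene_spec(n_categories = 9, clutter = "clean",
                     image_size = 64, seed = 11)
  ds <- generate_dataset(spec, category_counts = rep(2L, 9))
  expect_equal(unname(index_counts(ds$index)), rep(2L, 9))
  expect_length(ds$samples, 18L)
  for (s in ds$samples) {
    expect_true(nrow(s$boxes) >= 1)
    expect_true(all(s$boxes[, 1] >= 0 & s$boxes[, 2] >= 0 &
                    s$boxes[, 3] <= 64 & s$boxes[, 4] <= 64))
    expect_true(all(s$boxes[, 1] < s$boxes[, 3]))
    expect_true(all(s$image >= 0 & s$image <= 255))
  }
  # cluttered scenes carry several leaves
  spec2 <- scene_spec(n_categories = 3, clutter = "cluttered",
                      image_size = 64, seed = 12)
  ds2 <- generate_dataset(spec2, category_counts = c(3L, 3L, 3L))
  expect_gte(max(vapply(ds2$samples, function(s) nrow(s$boxes),
                        numeric(1))), 2)
  # a single total is distributed across categories
  ds3 <- generate_dataset(spec, 20)
  expect_equal(sum(index_counts(ds3$index)), 20L)
  expect_error(generate_dataset(spec, rep(-1L, 9)), "non-negative")
})

test_that("identical seeds give byte-identical annotation files", {
  spec <- scene_spec(n_categories = 2, image_size = 48, seed = 21)
  d1 <- file.path(tempdir(), "synth_a"); d2 <- file.path(tempdir(), "synth_b")
  generate_dataset(spec, c(2L, 2L), dir = d1)
  generate_dataset(spec, c(2L, 2L), dir = d2)
  expect_identical(readLines(file.path(d1, "annotations.json")),
                   readLines(file.path(d2, "annotations.json")))
  for (f in list.files(file.path(d1, "labels")))
    expect_identical(readLines(file.path(d1, "labels", f)),
                     readLines(file.path(d2, "labels", f)))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("COCO and YOLO serializations round-trip the boxes", {
  spec <- scene_spec(n_categories = 3, image_size = 80, seed = 31)
  ds <- generate_dataset(spec, c(2L, 2L, 2L))
  dir <- file.path(tempdir(), "synth_rt")
  write_dataset(ds, dir)
  back <- read_coco(file.path(dir, "annotations.json"))
  for (s in ds$samples) {
    b <- back$samples[[s$id]]
    expect_equal(b$boxes, unname(s$boxes))
    expect_equal(b$labels, s$labels)
    y <- read_yolo(file.path(dir, "labels", paste0(s$id, ".txt")),
                   width = 80, height = 80)
    expect_equal(y$labels, s$labels)
    expect_true(max(abs(y$boxes - s$boxes)) <= 0.5)   # half-pixel
  }
  expect_equal(unname(index_counts(back$index)),
               unname(index_counts(ds$index)))
  unlink(dir, recursive = TRUE)
})

test_that("augmentation transforms boxes exactly", {
  spec <- scene_spec(n_categories = 2, image_size = 100, seed = 41)
  s <- generate_dataset(spec, c(1L, 0L))$samples[[1]]
  # horizontal flip is an involution on boxes and image
  ff <- augment(augment(s, "hflip"), "hflip")
  expect_equal(ff$boxes, s$boxes)
  expect_equal(ff$image, s$image)
  # quarter-turn corner mapping: (10,20,30,40) in 100x100 -> (20,70,40,90)
  sq <- detection_sample(s$image, matrix(c(10, 20, 30, 40), 1), 0L, "sq")
  r90 <- augment(sq, "rotate", list(angle = 90))
  expect_equal(unname(r90$boxes), matrix(c(20, 70, 40, 90), 1))
  # four quarter turns restore boxes and image
  r360 <- sq
  for (i in 1:4) r360 <- augment(r360, "rotate", list(angle = 90))
  expect_equal(r360$boxes, sq$boxes)
  expect_equal(r360$image, sq$image)
  # photometric ops leave boxes untouched
  expect_equal(augment(s, "brightness", list(factor = 1.5))$boxes, s$boxes)
  expect_equal(augment(s, "blur", list(sigma = 2))$boxes, s$boxes)
  # arbitrary-angle rotation: hull of rotated corners, clipped in-frame
  r15 <- augment(sq, "rotate", list(angle = 15))
  expect_true(all(r15$boxes >= 0 & r15$boxes <= 100))
  expect_true(all(r15$boxes[, 3] - r15$boxes[, 1] >=
                  sq$boxes[, 3] - sq$boxes[, 1]))
  expect_error(augment(s, "sharpen"), "unknown")
})

test_that("salt noise alters a binomial fraction of pixels", {
  spec <- scene_spec(n_categories = 1, image_size = 100, seed = 51)
  img <- generate_dataset(spec, 1L)$samples[[1]]$image
  img <- pmin(img, 254)                    # ensure salt is identifiable
  expect_identical(salt_noise(img, 0, seed = 1), img)
  expect_true(all(salt_noise(img, 1, seed = 1) == 255))
  for (p in seq(0.025, 0.25, by = 0.025)) {
    noised <- salt_noise(img, p, seed = 7)
    altered <- sum(noised[, , 1] == 255)
    expect_lt(abs(altered - 10000 * p), 3 * sqrt(10000 * p * (1 - p)))
  }
  # determinism and error handling
  expect_identical(salt_noise(img, 0.1, seed = 3),
                   salt_noise(img, 0.1, seed = 3))
  expect_error(salt_noise(img, 1.5), "\\[0, 1\\]")
})

test_that("split-first-then-augment never leaks into the test set", {
  spec <- scene_spec(n_categories = 3, image_size = 48, seed = 61)
  ds <- generate_dataset(spec, c(5L, 5L, 5L))
  out <- split_then_augment(ds, test_fraction = 0.2, seed = 3)
  n_train_orig <- sum(index_counts(out$train_index))
  # four default ops: originals plus four variants each
  expect_length(out$train, n_train_orig * 5L)
  expect_length(out$test, 3L)
  # leakage: no augmented variant of a test id may appear in training
  test_ids <- vapply(out$test, `[[`, character(1), "id")
  train_sources <- sub("_(blur|brightness|rotate|hflip).*$", "",
                       vapply(out$train, `[[`, character(1), "id"))
  expect_length(intersect(test_ids, train_sources), 0)
  # the held-out samples are the untouched originals
  for (id in test_ids)
    expect_identical(out$test[[id]], ds$samples[[id]])
})
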