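test_that("generation is deterministic for a fixed (params, label, seed)", {
  p <- tiny_params()
  a <- generate_colony(p, "good", 1)
  b <- generate_colony(p, "good", 1)
  expect_identical(a$pixels, b$pixels)
  expect_identical(a$label, "good")
  expect_true(all(a$pixels >= 0 & a$pixels <= 1))

  ds1 <- generate_dataset(3, 2, p, seed = 7)
  ds2 <- generate_dataset(3, 2, p, seed = 7)
  expect_identical(lapply(ds1$items, `[[`, "pixels"),
                   lapply(ds2$items, `[[`, "pixels"))
})

test_that("separation = 0 collapses the two phenotype classes", {
  p0 <- tiny_params(separation = 0)
  expect_identical(p0$classes$good, p0$classes$bad)
  g <- generate_colony(p0, "good", 7)
  b <- generate_colony(p0, "bad", 7)
  expect_identical(g$pixels, b$pixels)   # only the label differs
  expect_identical(g$label, "good")
  expect_identical(b$label, "bad")
})

test_that("invalid generator parameters raise errors naming the field", {
  expect_error(generator_params(separation = 1.2), "separation")
  expect_error(generator_params(good = list(packing_fraction = 0)),
               "packing_fraction")
  expect_error(generator_params(bad = list(eccentricity = 1)),
               "eccentricity")
  expect_error(generator_params(noise_sd = -1), "noise_sd")
  expect_error(generator_params(good = list(nonsense = 1)), "nonsense")
  expect_error(generate_colony(tiny_params(), "ugly", 1), "label")
  expect_error(generate_dataset(-1, 2, tiny_params(), 1), "n_good")
})

test_that("dataset composition and counts are exact and order-stable", {
  p <- tiny_params()
  expect_identical(length(generate_dataset(0, 0, p, 1)), 0L)
  expect_identical(unname(class_counts(generate_dataset(0, 0, p, 1))),
                   c(0L, 0L))

  ds <- generate_dataset(10, 10, p, seed = 5)
  set.seed(42)
  shuffled <- dataset_subset(ds, sample(length(ds)))
  expect_identical(unname(class_counts(shuffled)), c(10L, 10L))

  # the i-th good image must not depend on how many bad images exist
  a <- generate_dataset(2, 1, p, seed = 5)
  b <- generate_dataset(2, 5, p, seed = 5)
  expect_identical(a$items[[1]]$pixels, b$items[[1]]$pixels)
  expect_identical(a$items[[2]]$pixels, b$items[[2]]$pixels)
})

test_that("looser packing yields more inter-cell background inside the colony", {
  # oracle: fraction of non-cell pixels inside the ground-truth colony mask
  p <- generator_params(image_size_px = 128,
                        good = list(packing_fraction = 0.9),
                        bad = list(packing_fraction = 0.5))
  bg_frac <- function(label, seed) {
    img <- generate_colony(p, label, seed, return_masks = TRUE)
    inside <- attr(img, "colony_mask")
    mean(!attr(img, "cell_mask")[inside])
  }
  seeds <- 1:25
  good_bg <- vapply(seeds, function(s) bg_frac("good", s), numeric(1))
  bad_bg <- vapply(seeds, function(s) bg_frac("bad", 1000 + s), numeric(1))
  expect_gt(mean(bad_bg), mean(good_bg))
})

test_that("a fixed downstream classifier's accuracy is non-decreasing in separation", {
  acc_at <- function(sep, seed) {
    p <- generator_params(image_size_px = 64, separation = sep)
    ds <- generate_dataset(30, 30, p, seed = seed)
    sp <- split_dataset(ds, c(1, 1), seed = seed)
    feature_classifier_accuracy(sp$train, sp$validation)
  }
  seeds <- c(11, 22, 33)
  acc <- vapply(c(0, 0.5, 1), function(s)
    mean(vapply(seeds, function(sd) acc_at(s, sd), numeric(1))), numeric(1))
  tol <- 0.10   # Monte-Carlo slack over 3 seeds x 30 validation images
  expect_gte(acc[2], acc[1] - tol)
  expect_gte(acc[3], acc[2] - tol)
  expect_gt(acc[3], 0.9)        # full separation is easily classified
  expect_lt(abs(acc[1] - 0.5), 0.2)  # identical classes are at chance
})

test_that("manifest write/read round-trips labels, counts and pixels", {
  ds <- generate_dataset(12, 8, tiny_params(), seed = 3)
  dir <- withr::local_tempdir()
  write_manifest(ds, dir)
  back <- read_manifest(file.path(dir, "manifest.csv"))
  expect_identical(class_counts(back), class_counts(ds))
  expect_identical(dataset_labels(back), dataset_labels(ds))
  # PNG is 8-bit: round-trip exact to 1/255
  expect_lt(max(abs(back$items[[1]]$pixels - ds$items[[1]]$pixels)), 1 / 255)
  # JSON mirror carries the same counts
  js <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  expect_equal(js$n_good, 12)
  expect_equal(js$n_bad, 8)
})

test_that("empty datasets and unknown labels are handled at the manifest boundary", {
  dir <- withr::local_tempdir()
  write_manifest(colony_dataset(), dir)
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_identical(nrow(man), 0L)
  expect_identical(names(man), c("path", "label"))

  writeLines(c("path,label", "a.png,good", "b.png,mediocre", "c.png,odd"),
             file.path(dir, "bad.csv"))
  expect_error(read_manifest(file.path(dir, "bad.csv")), "2, 3")
})
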