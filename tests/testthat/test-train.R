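test_that("a 4:1 split of 269 labeled images yields a 54-image validation set", {
  ds <- label_only_dataset(c(rep("good", 137), rep("bad", 132)))
  sp <- split_dataset(ds, c(4, 1), seed = 1)
  expect_identical(length(sp$validation), 54L)
  expect_identical(length(sp$train), 215L)
})

test_that("splits partition the dataset for any seed and stay deterministic", {
  ds <- label_only_dataset(rep(c("good", "bad"), c(13, 10)))
  for (seed in c(1, 7, 99)) {
    sp <- split_dataset(ds, c(4, 1), seed = seed)
    expect_identical(sort(c(sp$train_idx, sp$val_idx)), 1:23)
    expect_length(intersect(sp$train_idx, sp$val_idx), 0)
    sp2 <- split_dataset(ds, c(4, 1), seed = seed)
    expect_identical(sp$val_idx, sp2$val_idx)
  }
  tiny <- split_dataset(label_only_dataset(rep("good", 5)), c(4, 1),
                        seed = 2, stratified = FALSE)
  expect_identical(length(tiny$validation), 1L)
  expect_identical(length(tiny$train), 4L)
})

test_that("stratification keeps class balance and falls back gracefully", {
  ds <- label_only_dataset(rep(c("good", "bad"), c(40, 10)))
  sp <- split_dataset(ds, c(4, 1), seed = 3, stratified = TRUE)
  val_labels <- dataset_labels(sp$validation)
  expect_identical(sum(val_labels == "good"), 8L)
  expect_identical(sum(val_labels == "bad"), 2L)
  solo <- label_only_dataset(rep("good", 10))
  expect_warning(split_dataset(solo, c(4, 1), seed = 1, stratified = TRUE),
                 "unstratified")
})

test_that("binary cross-entropy matches hand evaluation and the element-wise oracle", {
  expect_equal(bce_loss(c(1, 0), c(0.5, 0.5)), log(2), tolerance = 1e-12)
  expect_equal(bce_loss(c(1, 1, 0, 0), c(0.9, 0.8, 0.1, 0.2)),
               mean(-c(log(0.9), log(0.8), log(0.9), log(0.8))),
               tolerance = 1e-12)
  expect_lt(bce_loss(1, 1 - 1e-12), 1e-6)    # perfect-prediction limit
  expect_error(bce_loss(c(1, 0), 0.5), "length")

  oracle <- function(y, p) {
    eps <- 1e-7
    total <- 0
    for (i in seq_along(y)) {
      pi <- min(max(p[i], eps), 1 - eps)
      total <- total + y[i] * log(pi) + (1 - y[i]) * log(1 - pi)
    }
    -total / length(y)
  }
  set.seed(8)
  for (rep in 1:10) {
    n <- sample(3:40, 1)
    y <- rbinom(n, 1, 0.5)
    p <- runif(n)
    expect_equal(bce_loss(y, p), oracle(y, p), tolerance = 1e-10)
  }
})

test_that("training is bit-reproducible under identical configuration and seeds", {
  ds <- generate_dataset(10, 10, generator_params(image_size_px = 32),
                         seed = 4)
  sp <- split_dataset(ds, c(4, 1), seed = 1)
  cfg <- train_config(epochs = 2, batch_size = 8, learning_rate = 1e-3,
                      seed = 12, early_stop_patience = NULL)
  run <- function() {
    m <- build_model("VGG12", 32, seed = 2, width_factor = 1 / 16)
    fit(m, sp$train, sp$validation, cfg,
        augment = augment_spec(use_rotation = TRUE))
  }
  r1 <- run()
  r2 <- run()
  expect_identical(r1$history, r2$history)
  expect_identical(r1$model$head$W1, r2$model$head$W1)
})

test_that("validation data is never augmented", {
  # with a vanishing learning rate the model stays at its initialization,
  # so validation metrics must be identical whether augmentation is on or
  # off -- which can only hold if augmentation never touches validation
  ds <- generate_dataset(8, 8, generator_params(image_size_px = 32),
                         seed = 6)
  sp <- split_dataset(ds, c(1, 1), seed = 1)
  run <- function(aug) {
    m <- build_model("VGG12", 32, seed = 3, width_factor = 1 / 16)
    cfg <- train_config(epochs = 2, batch_size = 8, learning_rate = 1e-30,
                        seed = 5, early_stop_patience = NULL)
    fit(m, sp$train, sp$validation, cfg, augment = aug)$history
  }
  h_off <- run(NULL)
  h_on <- run(augment_spec(use_crop = TRUE, crop_fraction = 0.6,
                           use_rotation = TRUE))
  expect_equal(h_on$val_loss, h_off$val_loss, tolerance = 1e-12)
  expect_equal(h_on$val_accuracy, h_off$val_accuracy, tolerance = 1e-12)
})

test_that("training loss decreases on the separable synthetic task", {
  p <- generator_params(image_size_px = 32)
  drops <- vapply(c(21, 22, 23), function(seed) {
    ds <- generate_dataset(20, 20, p, seed = seed)
    sp <- split_dataset(ds, c(4, 1), seed = seed)
    m <- build_model("VGG12", 32, seed = seed, width_factor = 1 / 16)
    cfg <- train_config(epochs = 5, batch_size = 8, learning_rate = 1e-3,
                        seed = seed, early_stop_patience = NULL)
    h <- fit(m, sp$train, sp$validation, cfg)$history
    h$train_loss[1] - min(h$train_loss)
  }, numeric(1))
  expect_gt(median(drops), 0)
})

test_that("invalid training configurations are rejected", {
  expect_error(train_config(batch_size = 0), "batch_size")
  expect_error(train_config(learning_rate = 0), "learning_rate")
  expect_error(train_config(split_ratio = c(4, 0)), "split_ratio")
  ds <- label_only_dataset(c("good", "bad"))
  expect_error(split_dataset(ds, c(-1, 1), 1), "ratio")
  expect_error(split_dataset(colony_dataset(), c(4, 1), 1), "empty")
})
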