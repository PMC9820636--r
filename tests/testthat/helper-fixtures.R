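# Shared fixtures: everything is generated in code at test time.

# Small, fast generator setups.
tiny_params <- function(...) {
  generator_params(image_size_px = 48, ...)
}

# A dataset of 1x1 placeholder images with given labels: cheap scaffolding
# for split/count bookkeeping tests that never look at pixels.
label_only_dataset <- function(labels) {
  colony_dataset(lapply(seq_along(labels), function(i)
    colony_image(matrix(0.5, 1, 1), label = labels[i],
                 source_id = sprintf("ph_%d", i))))
}

random_image <- function(side = 16, channels = 1, range01 = TRUE,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  px <- if (channels == 1) matrix(runif(side * side), side, side)
    else array(runif(side * side * channels), c(side, side, channels))
  if (!range01) {
    px <- px * 255
    return(colony_image(px, range = c(0, 255)))
  }
  colony_image(px, range = c(0, 1))
}

# Summary-statistic features + logistic regression: a fixed, cheap
# downstream classifier used for separability properties of the generator.
feature_classifier_accuracy <- function(train, test) {
  feats <- function(ds) t(vapply(ds$items, function(it) {
    px <- it$pixels
    gy <- px[-1, ] - px[-nrow(px), ]
    c(m = mean(px), s = sd(px), g = mean(abs(gy)))
  }, numeric(3)))
  df_tr <- data.frame(feats(train), y = dataset_labels(train) == "good")
  df_te <- data.frame(feats(test), y = dataset_labels(test) == "good")
  fit <- suppressWarnings(glm(y ~ m + s + g, data = df_tr,
                              family = binomial()))
  p <- predict(fit, newdata = df_te, type = "response")
  mean((p >= 0.5) == df_te$y)
}
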