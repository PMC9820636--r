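#' Cut an image into four equal quadrants
#'
#' Quadrants are non-overlapping, cover the input exactly, inherit the
#' parent's label, physical pixel size and (suffixed) source id, and so
#' have half the physical extent per axis. Odd dimensions are first padded
#' by edge replication (with a message).
#'
#' @param img A [colony_image()].
#' @return List of 4 `colony_image` quadrants in order top-left,
#'   top-right, bottom-left, bottom-right.
#' @export
#' @examples
#' q <- quarter(generate_colony(generator_params(image_size_px = 64), "good", 1))
#' dim(q[[1]]$pixels)
quarter <- function(img) {
  stopifnot(inherits(img, "colony_image"))
  px <- img$pixels
  d <- dim(px)
  if (d[1] %% 2L || d[2] %% 2L) {
    message("padding odd-sized image by edge replication before quartering")
    ri <- c(seq_len(d[1]), if (d[1] %% 2L) d[1])
    ci <- c(seq_len(d[2]), if (d[2] %% 2L) d[2])
    px <- if (length(d) == 3L) px[ri, ci, , drop = FALSE] else
      px[ri, ci, drop = FALSE]
    d <- dim(px)
  }
  h2 <- d[1] / 2L
  w2 <- d[2] / 2L
  take <- function(rs, cs, tag) {
    sub <- if (length(d) == 3L) px[rs, cs, , drop = FALSE] else
      px[rs, cs, drop = FALSE]
    colony_image(sub, um_per_px = img$um_per_px, range = img$range,
                 label = img$label,
                 source_id = paste0(img$source_id, tag))
  }
  list(take(1:h2, 1:w2, "_q1"),
       take(1:h2, (w2 + 1):d[2], "_q2"),
       take((h2 + 1):d[1], 1:w2, "_q3"),
       take((h2 + 1):d[1], (w2 + 1):d[2], "_q4"))
}

#' Scale-level descriptor
#'
#' @param k Pyramid depth (0 = full image).
#' @param base_px Integer pair: full-image size in pixels (rows, cols).
#' @param base_um Numeric pair: full-image physical extent in micrometres.
#' @param base_n Number of full images.
#' @return An object of class `scale_level` with fields `k`, `crop_px`
#'   (`base_px / 2^k`), `crop_um` (`base_um / 2^k`) and `n_images`
#'   (`base_n * 4^k`).
#' @export
scale_level <- function(k, base_px, base_um, base_n) {
  assert_scalar_num(k, "k", lower = 0)
  structure(list(k = as.integer(k),
                 crop_px = base_px / 2^k,
                 crop_um = base_um / 2^k,
                 n_images = as.integer(base_n * 4^k)),
            class = "scale_level")
}

#' Linear crop size in micrometres at pyramid depth k
#'
#' The linear scale of a level-k crop is the full-image width divided by
#' `2^k`: quartering halves the physical extent per axis at every level.
#'
#' @param k Nonnegative integer pyramid depth.
#' @param base_um_width Full-image width in micrometres (> 0).
#' @return `base_um_width / 2^k`.
#' @export
#' @examples
#' crop_size_um(1, 290)   # 145
crop_size_um <- function(k, base_um_width) {
  if (any(k < 0)) param_error("k", "must be nonnegative")
  assert_scalar_num(base_um_width, "base_um_width", lower = 0,
                    lower_open = TRUE)
  base_um_width / 2^k
}

#' Build the recursive quartering pyramid of a dataset
#'
#' Level k holds `n * 4^k` images, each `1/2^k` of the original extent per
#' axis, with labels inherited from the parents, so the class balance is
#' identical at every level. Stops early (with a warning) if images become
#' too small to quarter.
#'
#' @param ds A [colony_dataset()].
#' @param max_k Deepest level to build.
#' @return List with one element per level: `list(level = scale_level,
#'   dataset = colony_dataset)`.
#' @export
build_pyramid <- function(ds, max_k) {
  stopifnot(inherits(ds, "colony_dataset"))
  assert_scalar_num(max_k, "max_k", lower = 0)
  base_d <- dim(ds$items[[1]]$pixels)[1:2]
  base_um <- base_d * ds$items[[1]]$um_per_px
  out <- list(list(level = scale_level(0, base_d, base_um, length(ds)),
                   dataset = ds))
  cur <- ds
  for (k in seq_len(max_k)) {
    d <- dim(cur$items[[1]]$pixels)[1:2]
    if (any(d < 2L)) {
      warning(sprintf("images at level %d are too small to quarter; stopping",
                      k - 1L))
      break
    }
    items <- unlist(lapply(cur$items, quarter), recursive = FALSE)
    cur <- colony_dataset(items)
    out[[k + 1L]] <- list(level = scale_level(k, base_d, base_um,
                                              length(ds)),
                          dataset = cur)
  }
  out
}

#' Scan classification quality across spatial scales
#'
#' Reruns the full train/evaluate cycle at every pyramid level: the
#' train/validation split is made once per seed at level 0 and propagated
#' down (all crops of one parent image stay on one side, so no information
#' leaks between the splits via shared parents). At each level a fresh
#' model is trained on that level's training crops and evaluated on that
#' level's validation crops; accuracy and F1 per level and seed are
#' collected, together with the best level per seed (ties go to the
#' shallower level).
#'
#' @param ds A labeled [colony_dataset()] of full images.
#' @param max_k Deepest quartering level.
#' @param model_name Registry architecture name.
#' @param train_cfg A [train_config()] (its `seed` is replaced by each scan
#'   seed).
#' @param preprocess A [preprocess_spec()]; crops at every level are
#'   resized to its `target_side_px` before training.
#' @param augment Optional [augment_spec()].
#' @param seeds Integer vector of run seeds (>= 1 seed).
#' @param width_factor Channel width multiplier for the trained models.
#' @return An object of class `scale_scan`: `$table` (data.frame with
#'   columns level, crop_px, crop_um, seed, accuracy, f1) and
#'   `$argmax_level` (named by seed). Levels whose training diverged are
#'   recorded as `NA` rows and skipped in the argmax.
#' @export
scale_scan <- function(ds, max_k, model_name = "VGG13",
                       train_cfg = train_config(), preprocess = NULL,
                       augment = NULL, seeds = 1L, width_factor = 1) {
  stopifnot(inherits(ds, "colony_dataset"), length(seeds) >= 1L)
  if (is.null(preprocess))
    preprocess <- preprocess_spec("none", target_side_px = 32L)
  side <- preprocess$target_side_px
  base_w_um <- dim(ds$items[[1]]$pixels)[2] * ds$items[[1]]$um_per_px[2]
  rows <- list()
  argmax <- setNames(rep(NA_integer_, length(seeds)), seeds)
  for (s_i in seq_along(seeds)) {
    seed <- seeds[s_i]
    sp <- split_dataset(ds, train_cfg$split_ratio, seed = seed,
                        stratified = TRUE)
    pyr_tr <- build_pyramid(sp$train, max_k)
    pyr_va <- build_pyramid(sp$validation, max_k)
    accs <- rep(NA_real_, max_k + 1L)
    for (k in 0:max_k) {
      if (k + 1L > length(pyr_tr)) break
      lvl_tr <- pyr_tr[[k + 1L]]$dataset
      lvl_va <- pyr_va[[k + 1L]]$dataset
      cfg_k <- train_cfg
      cfg_k$seed <- child_seed(seed, k + 7L)
      res <- tryCatch({
        mdl <- build_model(model_name, input_side = side,
                           seed = child_seed(seed, 100L + k),
                           width_factor = width_factor)
        tr <- fit(mdl, lvl_tr, lvl_va, cfg_k, preprocess = preprocess,
                  augment = augment)
        evaluate_model(tr$model, lvl_va, preprocess = preprocess)
      }, error = function(e) {
        warning(sprintf("level %d, seed %d failed: %s", k, seed,
                        conditionMessage(e)))
        NULL
      })
      crop_px <- dim(lvl_tr$items[[1]]$pixels)[2]
      rows[[length(rows) + 1L]] <- data.frame(
        level = k, crop_px = crop_px,
        crop_um = crop_size_um(k, base_w_um), seed = seed,
        accuracy = if (is.null(res)) NA_real_ else res$accuracy,
        f1 = if (is.null(res)) NA_real_ else res$f1)
      if (!is.null(res)) accs[k + 1L] <- res$accuracy
    }
    if (any(is.finite(accs)))
      argmax[s_i] <- which.max(accs) - 1L   # ties resolve to shallower k
  }
  structure(list(table = do.call(rbind, rows), argmax_level = argmax),
            class = "scale_scan")
}

#' @export
print.scale_scan <- function(x, ...) {
  cat("<scale_scan>\n")
  print(x$table, row.names = FALSE)
  cat("best level per seed:",
      paste(sprintf("seed %s -> k=%d", names(x$argmax_level),
                    x$argmax_level), collapse = ", "), "\n")
  invisible(x)
}
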