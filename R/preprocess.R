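#' Preprocessing specification
#'
#' Describes the single preprocessing operator applied to every image before
#' it reaches the network, plus the square input side the image is resized
#' to. Methods mirror the classical operators used for phase-contrast
#' colony classification: grayscale conversion, min-max intensity
#' normalization, fixed-threshold (or Otsu) binarization, and global
#' histogram equalization.
#'
#' @param method One of `"none"`, `"gray"`, `"normalize"`, `"binarize"`,
#'   `"equalize"`.
#' @param binarize_threshold Threshold in (0, 1) on the unit intensity
#'   scale, or `"otsu"` for a per-image Otsu threshold (default).
#' @param target_side_px Square network input side the image is resized to.
#' @return An object of class `preprocess_spec`.
#' @export
preprocess_spec <- function(method = c("none", "gray", "normalize",
                                       "binarize", "equalize"),
                            binarize_threshold = "otsu",
                            target_side_px = 256L) {
  method <- match.arg(method)
  if (!identical(binarize_threshold, "otsu")) {
    assert_scalar_num(binarize_threshold, "binarize_threshold", 0, 1,
                      lower_open = TRUE, upper_open = TRUE)
  }
  assert_scalar_num(target_side_px, "target_side_px", lower = 8)
  structure(list(method = method, binarize_threshold = binarize_threshold,
                 target_side_px = as.integer(target_side_px)),
            class = "preprocess_spec")
}

#' Apply a preprocessing spec to one image
#'
#' Pipeline order: resize to the square input side, then the selected
#' intensity operator. All operators are pure and leave the input object
#' untouched.
#'
#' @param img A [colony_image()].
#' @param spec A [preprocess_spec()].
#' @return The transformed `colony_image`.
#' @export
apply_preprocess <- function(img, spec) {
  stopifnot(inherits(spec, "preprocess_spec"))
  out <- resize_to_input(img, spec$target_side_px)
  switch(spec$method,
    none = out,
    gray = to_gray(out),
    normalize = minmax_normalize(out),
    binarize = binarize(out, spec$binarize_threshold),
    equalize = equalize_histogram(out))
}

# Area-overlap resampling matrix mapping n_in pixels onto n_out pixels.
# Row i averages the input interval that output pixel i covers, with exact
# fractional-overlap weights, so the global mean is preserved.
area_weights <- function(n_in, n_out) {
  r <- n_in / n_out
  A <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    lo <- (i - 1) * r
    hi <- i * r
    j0 <- floor(lo) + 1
    j1 <- min(ceiling(hi), n_in)
    for (j in j0:j1) {
      ov <- min(hi, j) - max(lo, j - 1)
      if (ov > 0) A[i, j] <- ov / r
    }
  }
  A
}

#' Resize an image to a square network input
#'
#' Direct (anisotropic) resize to `side` x `side` using exact area
#' interpolation: every output pixel is the mean of the input area it
#' covers, which antialiases on downsampling and preserves the global mean
#' intensity. The per-axis physical pixel size is rescaled accordingly, so
#' the field of view in micrometres is unchanged.
#'
#' @param img A [colony_image()].
#' @param side Target side in pixels (>= 8).
#' @return A `side` x `side` `colony_image` in the same intensity range.
#' @export
#' @examples
#' img <- colony_image(matrix(runif(1280 * 960), 960, 1280),
#'                     um_per_px = 290 / 1280)
#' out <- resize_to_input(img, 256)
#' out$um_per_px[2] * 256   # field of view width in um, unchanged: 290
resize_to_input <- function(img, side) {
  stopifnot(inherits(img, "colony_image"))
  assert_scalar_num(side, "side", lower = 8)
  side <- as.integer(side)
  d <- dim(img$pixels)
  if (d[1] == side && d[2] == side) return(img)
  Ah <- area_weights(d[1], side)
  Aw <- area_weights(d[2], side)
  resize_plane <- function(m) Ah %*% m %*% t(Aw)
  if (length(d) == 3L) {
    out <- array(0, c(side, side, d[3]))
    for (c in seq_len(d[3])) out[, , c] <- resize_plane(img$pixels[, , c])
  } else {
    out <- resize_plane(img$pixels)
  }
  # exact-area averaging can overshoot the declared range only by rounding
  out[out < img$range[1]] <- img$range[1]
  out[out > img$range[2]] <- img$range[2]
  update_pixels(img, out,
                um_per_px = img$um_per_px * (d[1:2] / side))
}

#' Convert an image to grayscale luminance
#'
#' Applies the ITU-R BT.601 luma transform `Y = 0.299 R + 0.587 G + 0.114 B`
#' per pixel. The coefficients sum to exactly 1, so neutral pixels (R = G =
#' B) and grayscale inputs are fixed points. Values stay floating point;
#' rounding happens only on export.
#'
#' @param img A [colony_image()] with 1 or 3 channels.
#' @return A single-channel `colony_image` in the same declared range.
#' @export
to_gray <- function(img) {
  stopifnot(inherits(img, "colony_image"))
  ch <- n_channels(img)
  if (ch == 1L) return(img)
  if (ch != 3L) stop("to_gray expects 1 or 3 channels, got ", ch,
                     call. = FALSE)
  y <- 0.299 * img$pixels[, , 1] + 0.587 * img$pixels[, , 2] +
    0.114 * img$pixels[, , 3]
  dim(y) <- dim(img$pixels)[1:2]
  update_pixels(img, y)
}

#' Min-max intensity normalization
#'
#' Linearly rescales intensities so the minimum maps to 0 and the maximum
#' to 1. A constant image maps to all zeros (declared convention for the
#' degenerate zero-range case). Idempotent.
#'
#' @param img A [colony_image()].
#' @return A `colony_image` with declared range `[0, 1]`.
#' @export
minmax_normalize <- function(img) {
  stopifnot(inherits(img, "colony_image"))
  px <- img$pixels
  lo <- min(px)
  hi <- max(px)
  out <- if (hi > lo) (px - lo) / (hi - lo) else array(0, dim(px))
  dim(out) <- dim(px)
  update_pixels(img, out, range = c(0, 1))
}

# Otsu threshold on the unit scale, 256-bin histogram.
otsu_threshold <- function(x) {
  as.numeric(EBImage::otsu(EBImage::Image(x), range = c(0, 1), levels = 256))
}

#' Binarize an image against a fixed or Otsu threshold
#'
#' Intensities are taken on the unit scale (a 0..255 image is divided by
#' 255 first); pixels `>= threshold` become 1, the rest 0 (inclusive
#' boundary by declared convention). With `threshold = "otsu"` the
#' threshold is chosen per image by Otsu's method. Idempotent for any
#' threshold in (0, 1].
#'
#' @param img A [colony_image()].
#' @param threshold Numeric in (0, 1), or `"otsu"`.
#' @return A `colony_image` with values in \{0, 1\} and range `[0, 1]`.
#' @export
binarize <- function(img, threshold = "otsu") {
  stopifnot(inherits(img, "colony_image"))
  px <- img$pixels
  if (identical(img$range, c(0, 255))) px <- px / 255
  if (identical(threshold, "otsu")) {
    thr <- if (length(dim(px)) == 3L) otsu_threshold(px[, , 1]) else
      otsu_threshold(px)
  } else {
    assert_scalar_num(threshold, "threshold", 0, 1, lower_open = TRUE,
                      upper_open = TRUE)
    thr <- threshold
  }
  out <- (px >= thr) * 1
  dim(out) <- dim(px)
  update_pixels(img, out, range = c(0, 1))
}

#' Global histogram equalization
#'
#' Classic CDF remap on a 256-bin histogram: each intensity is replaced by
#' the empirical cumulative fraction of pixels at or below it, stretching
#' the histogram over the unit interval. The mapping is monotone
#' non-decreasing, so the intensity order of any two pixels is preserved.
#' Multichannel images are equalized per channel.
#'
#' @param img A [colony_image()].
#' @return A `colony_image` with declared range `[0, 1]`.
#' @export
equalize_histogram <- function(img) {
  stopifnot(inherits(img, "colony_image"))
  px <- img$pixels
  if (identical(img$range, c(0, 255))) px <- px / 255
  eq_plane <- function(m) {
    bins <- pmin(255L, pmax(0L, as.integer(floor(m * 256))))
    h <- tabulate(bins + 1L, nbins = 256L)
    cdf <- cumsum(h) / length(m)
    out <- cdf[bins + 1L]
    dim(out) <- dim(m)
    out
  }
  d <- dim(px)
  if (length(d) == 3L) {
    out <- array(0, d)
    for (c in seq_len(d[3])) out[, , c] <- eq_plane(px[, , c])
  } else {
    out <- eq_plane(px)
  }
  update_pixels(img, out, range = c(0, 1))
}
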