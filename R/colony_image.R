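#' Colony image container
#'
#' A `colony_image` wraps a numeric pixel array together with the metadata
#' the pipeline needs to keep physical units honest: the declared intensity
#' range, the physical pixel size per axis (micrometres per pixel), an
#' optional phenotype label and a source identifier used to trace crops back
#' to their parent image.
#'
#' @param pixels Numeric matrix (H x W) or array (H x W x C) with C in
#'   \{1, 3\}.
#' @param um_per_px Positive numeric of length 1 or 2: micrometres per pixel
#'   along (row, column) axes. A scalar is recycled to both axes.
#' @param range Declared intensity range, either `c(0, 1)` or `c(0, 255)`.
#'   If `NULL`, inferred from the pixel values (max > 1 implies 0..255).
#' @param label One of `"good"`, `"bad"`, `"unlabeled"`.
#' @param source_id Free-form string identifying the image's origin.
#'
#' @return An object of class `colony_image`.
#' @export
#' @examples
#' img <- colony_image(matrix(runif(64), 8, 8), um_per_px = 1.13)
#' dim(img$pixels)
colony_image <- function(pixels, um_per_px = c(1, 1), range = NULL,
                         label = "unlabeled", source_id = "") {
  if (!is.numeric(pixels) || !(length(dim(pixels)) %in% c(0L, 2L, 3L)))
    param_error("pixels", "must be a numeric matrix or 3-d array")
  if (is.null(dim(pixels))) param_error("pixels", "must have dimensions")
  d <- dim(pixels)
  if (d[1] < 1L || d[2] < 1L) param_error("pixels", "H and W must be >= 1")
  if (length(d) == 3L && !(d[3] %in% c(1L, 3L)))
    param_error("pixels", "channel count must be 1 or 3")
  if (length(um_per_px) == 1L) um_per_px <- rep(um_per_px, 2L)
  if (length(um_per_px) != 2L || any(!is.finite(um_per_px)) ||
      any(um_per_px <= 0))
    param_error("um_per_px", "must be 1 or 2 positive finite values")
  if (is.null(range)) {
    range <- if (max(pixels, na.rm = TRUE) > 1) c(0, 255) else c(0, 1)
  }
  if (!identical(as.numeric(range), c(0, 1)) &&
      !identical(as.numeric(range), c(0, 255)))
    param_error("range", "must be c(0, 1) or c(0, 255)")
  if (!(is.character(label) && length(label) == 1L &&
        label %in% c("good", "bad", "unlabeled")))
    param_error("label", "must be good, bad or unlabeled")
  obj <- structure(
    list(pixels = pixels, um_per_px = as.numeric(um_per_px),
         range = as.numeric(range), label = label,
         source_id = as.character(source_id)),
    class = "colony_image")
  validate_colony_image(obj)
}

#' Validate a colony_image's invariants
#'
#' Checks that the declared intensity range actually contains the pixel
#' values and that the geometry fields are consistent.
#'
#' @param img A `colony_image`.
#' @return `img`, invisibly usable, after validation; errors otherwise.
#' @export
validate_colony_image <- function(img) {
  stopifnot(inherits(img, "colony_image"))
  px <- img$pixels
  lo <- min(px)
  hi <- max(px)
  tol <- 1e-8
  if (lo < img$range[1] - tol || hi > img$range[2] + tol)
    stop(sprintf(
      "pixel values [%.4g, %.4g] fall outside the declared range [%g, %g]",
      lo, hi, img$range[1], img$range[2]), call. = FALSE)
  img
}

#' @export
print.colony_image <- function(x, ...) {
  d <- dim(x$pixels)
  ch <- if (length(d) == 3L) d[3] else 1L
  cat(sprintf(
    "<colony_image> %d x %d px, %d channel(s), range [%g, %g]\n", d[1], d[2],
    ch, x$range[1], x$range[2]))
  cat(sprintf("  %.4g x %.4g um/px, label: %s, source: %s\n",
              x$um_per_px[1], x$um_per_px[2], x$label,
              if (nzchar(x$source_id)) x$source_id else "<none>"))
  invisible(x)
}

#' Number of channels of a colony image
#' @param img A `colony_image`.
#' @return Integer, 1 or 3.
#' @export
n_channels <- function(img) {
  d <- dim(img$pixels)
  if (length(d) == 3L) d[3] else 1L
}

#' Physical field of view in micrometres
#' @param img A `colony_image`.
#' @return Numeric length 2: extent along (row, column) axes in um.
#' @export
field_of_view_um <- function(img) {
  d <- dim(img$pixels)[1:2]
  d * img$um_per_px
}

# Replace the pixel array, keeping metadata unless overridden.
update_pixels <- function(img, pixels, range = img$range,
                          um_per_px = img$um_per_px) {
  colony_image(pixels, um_per_px = um_per_px, range = range,
               label = img$label, source_id = img$source_id)
}
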