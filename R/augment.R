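#' Augmentation specification
#'
#' Training-time stochastic augmentation: random cropping (a random
#' sub-window of a fixed linear fraction of the side, resized back to the
#' original side) and the 8-element dihedral family of a square (four
#' right-angle rotations, horizontal/vertical flips, the two
#' transpositions). Augmentation is applied online to training items only;
#' validation data is never augmented.
#'
#' @param use_crop Enable random cropping.
#' @param crop_fraction Linear fraction of the side retained by the crop,
#'   in (0, 1]; 1 makes cropping the identity.
#' @param use_rotation Enable the random dihedral transform.
#' @param seed Seed for the augmentation RNG stream (used by
#'   [compose_augment()] consumers such as the training loop).
#' @return An object of class `augment_spec`.
#' @export
augment_spec <- function(use_crop = FALSE, crop_fraction = 0.875,
                         use_rotation = FALSE, seed = 1L) {
  assert_scalar_num(crop_fraction, "crop_fraction", 0, 1, lower_open = TRUE)
  structure(list(use_crop = isTRUE(use_crop),
                 crop_fraction = crop_fraction,
                 use_rotation = isTRUE(use_rotation),
                 seed = as.integer(seed)),
            class = "augment_spec")
}

#' Random crop, resized back to the input side
#'
#' Selects a square window of side `round(fraction * side)` at an offset
#' drawn uniformly over all valid positions (inclusive of both extremes),
#' then resizes the window back to the original side with area
#' interpolation. Draws from R's global RNG stream, so results are
#' reproducible under `set.seed()`. The chosen zero-based offset is
#' attached as attribute `crop_offset`.
#'
#' @param img A square [colony_image()].
#' @param crop_fraction Linear fraction in (0, 1]; 1 is the identity.
#' @return A `colony_image` of the original size.
#' @export
random_crop <- function(img, crop_fraction) {
  stopifnot(inherits(img, "colony_image"))
  assert_scalar_num(crop_fraction, "crop_fraction", 0, 1, lower_open = TRUE)
  d <- dim(img$pixels)
  if (crop_fraction == 1) return(img)
  sh <- max(1L, as.integer(round(crop_fraction * d[1])))
  sw <- max(1L, as.integer(round(crop_fraction * d[2])))
  oy <- sample.int(d[1] - sh + 1L, 1L) - 1L   # zero-based offsets
  ox <- sample.int(d[2] - sw + 1L, 1L) - 1L
  win <- if (length(d) == 3L)
    img$pixels[oy + seq_len(sh), ox + seq_len(sw), , drop = FALSE]
  else img$pixels[oy + seq_len(sh), ox + seq_len(sw), drop = FALSE]
  cropped <- update_pixels(img, win,
                           um_per_px = img$um_per_px)  # same um/px: true crop
  out <- resize_to_input(cropped, d[1])
  attr(out, "crop_offset") <- c(oy, ox)
  out
}

# The eight transforms of the dihedral group D4 acting on a square image:
# j = 0..3: counterclockwise rotations by 0/90/180/270 degrees;
# j = 4: horizontal flip; 5: vertical flip; 6: transpose (main diagonal);
# 7: anti-transpose. Pure pixel permutations.
rot90_plane <- function(m) t(m)[ncol(m):1, , drop = FALSE]

apply_plane_transform <- function(m, j) {
  switch(j + 1L,
    m,
    rot90_plane(m),
    m[nrow(m):1, ncol(m):1, drop = FALSE],
    rot90_plane(rot90_plane(rot90_plane(m))),
    m[, ncol(m):1, drop = FALSE],
    m[nrow(m):1, , drop = FALSE],
    t(m),
    t(m)[nrow(m):1, ncol(m):1, drop = FALSE])
}

#' Apply one named dihedral transform
#'
#' @param img A square [colony_image()].
#' @param j Integer 0..7 selecting the group element: 0-3 are rotations by
#'   0, 90, 180, 270 degrees; 4 horizontal flip; 5 vertical flip;
#'   6 transpose; 7 anti-transpose.
#' @return The transformed `colony_image`; the pixel multiset is preserved
#'   exactly.
#' @export
dihedral_transform <- function(img, j) {
  stopifnot(inherits(img, "colony_image"))
  if (!(length(j) == 1L && j %in% 0:7))
    param_error("j", "must be an integer in 0..7")
  d <- dim(img$pixels)
  if (d[1] != d[2])
    stop("dihedral transforms require a square image, got ",
         d[1], " x ", d[2], call. = FALSE)
  j <- as.integer(j)
  if (length(d) == 3L) {
    out <- array(0, d)
    for (c in seq_len(d[3])) out[, , c] <- apply_plane_transform(
      img$pixels[, , c], j)
  } else {
    out <- apply_plane_transform(img$pixels, j)
  }
  update_pixels(img, out)
}

#' Random dihedral transform
#'
#' Draws one of the eight square symmetries uniformly from R's global RNG
#' stream and applies it. The chosen element index is attached as attribute
#' `dihedral_element`.
#'
#' @param img A square [colony_image()].
#' @return The transformed `colony_image`.
#' @export
random_dihedral <- function(img) {
  j <- sample.int(8L, 1L) - 1L
  out <- dihedral_transform(img, j)
  attr(out, "dihedral_element") <- j
  out
}

#' Compose an augmentation spec into a single transform
#'
#' Returns a function applying crop then dihedral (fixed order; the two
#' commute distributionally) from one shared RNG stream. With both parts
#' disabled the transform is the identity.
#'
#' @param spec An [augment_spec()].
#' @return A function `colony_image -> colony_image`.
#' @export
#' @examples
#' tf <- compose_augment(augment_spec(use_rotation = TRUE))
#' set.seed(1)
#' img <- generate_colony(generator_params(image_size_px = 64), "good", 1)
#' out <- tf(img)
#' sort(out$pixels) == sort(img$pixels)  # pixel multiset preserved
compose_augment <- function(spec) {
  stopifnot(inherits(spec, "augment_spec"))
  function(img) {
    if (spec$use_crop) img <- random_crop(img, spec$crop_fraction)
    if (spec$use_rotation) img <- random_dihedral(img)
    img
  }
}
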