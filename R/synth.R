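#' Parameters of the synthetic colony-image generator
#'
#' The generator renders pseudo-phase-contrast colony images: dark
#' anti-aliased elliptical cell bodies packed inside a radial-polygon colony
#' outline, inter-cell space at a controllable brightness, a Gaussian-blurred
#' bright halo rim along the colony edge, and additive Gaussian noise.
#' Each phenotype class has its own morphological preset; the presets encode
#' the visual criteria used to phenotype real hPSC colonies:
#' tightly packed, nearly round cells and a smooth, well-defined edge for
#' the good class; loosely packed elongated cells with phase-bright
#' inter-cell gaps and a spiky outline for the bad class.
#'
#' The `separation` knob interpolates the effective bad-class preset between
#' the good preset (`separation = 0`, classes identical) and the full bad
#' preset (`separation = 1`), giving a controllable effect size for
#' benchmarking classifiers.
#'
#' @param image_size_px Integer pair, output height and width in pixels.
#' @param um_per_px Physical pixel size in micrometres (scalar, isotropic).
#'   The default puts a whole ~290 um field of view in a 256 px frame.
#' @param cell_diameter_um Mean cell diameter in micrometres.
#' @param good,bad Named lists overriding entries of the per-class presets:
#'   `eccentricity` (ellipse eccentricity in \[0, 1)), `packing_fraction`
#'   (target cell-area fraction inside the colony, in (0, 1\]), `size_cv`
#'   (coefficient of variation of cell size), `edge_spikiness` (relative
#'   per-vertex radial noise of the colony outline, >= 0), `gap_brightness`
#'   (intensity of inter-cell space, in \[0, 1\]).
#' @param noise_sd Standard deviation of additive Gaussian pixel noise.
#' @param separation Effect size in \[0, 1\]: 0 collapses the two classes
#'   onto the good preset, 1 uses the full bad preset.
#' @return An object of class `generator_params`.
#' @export
#' @examples
#' p <- generator_params(separation = 0.5)
#' p$classes$bad$packing_fraction   # halfway between the two presets
generator_params <- function(image_size_px = c(256L, 256L),
                             um_per_px = 290 / 256,
                             cell_diameter_um = 15,
                             good = list(),
                             bad = list(),
                             noise_sd = 0.02,
                             separation = 1) {
  if (length(image_size_px) == 1L) image_size_px <- rep(image_size_px, 2L)
  if (length(image_size_px) != 2L || any(image_size_px < 8) ||
      any(image_size_px != round(image_size_px)))
    param_error("image_size_px", "must be two integers >= 8")
  assert_scalar_num(um_per_px, "um_per_px", lower = 0, lower_open = TRUE)
  assert_scalar_num(cell_diameter_um, "cell_diameter_um", lower = 0,
                    lower_open = TRUE)
  assert_scalar_num(noise_sd, "noise_sd", lower = 0)
  assert_scalar_num(separation, "separation", lower = 0, upper = 1)

  preset_good <- list(eccentricity = 0.25, packing_fraction = 0.90,
                      size_cv = 0.15, edge_spikiness = 0.05,
                      gap_brightness = 0.60)
  preset_bad <- list(eccentricity = 0.75, packing_fraction = 0.55,
                     size_cv = 0.40, edge_spikiness = 0.40,
                     gap_brightness = 0.88)
  preset_good <- merge_class_preset(preset_good, good, "good")
  preset_bad <- merge_class_preset(preset_bad, bad, "bad")
  validate_class_preset(preset_good, "good")
  validate_class_preset(preset_bad, "bad")

  # effective bad preset: component-wise interpolation from the good preset
  eff_bad <- mapply(function(g, b) g + separation * (b - g),
                    preset_good, preset_bad, SIMPLIFY = FALSE)

  structure(list(
    image_size_px = as.integer(image_size_px),
    um_per_px = um_per_px,
    cell_diameter_um = cell_diameter_um,
    noise_sd = noise_sd,
    separation = separation,
    presets = list(good = preset_good, bad = preset_bad),
    classes = list(good = preset_good, bad = eff_bad)),
    class = "generator_params")
}

merge_class_preset <- function(preset, override, class_name) {
  if (length(override) == 0L) return(preset)
  unknown <- setdiff(names(override), names(preset))
  if (length(unknown))
    param_error(paste0(class_name, "$", unknown[1]), "unknown preset field")
  modifyList(preset, override)
}

validate_class_preset <- function(p, cls) {
  pre <- function(f) paste0(cls, "$", f)
  assert_scalar_num(p$eccentricity, pre("eccentricity"), 0, 1,
                    upper_open = TRUE)
  assert_scalar_num(p$packing_fraction, pre("packing_fraction"), 0, 1,
                    lower_open = TRUE)
  assert_scalar_num(p$size_cv, pre("size_cv"), lower = 0)
  assert_scalar_num(p$edge_spikiness, pre("edge_spikiness"), lower = 0)
  assert_scalar_num(p$gap_brightness, pre("gap_brightness"), 0, 1)
  invisible(p)
}

#' @export
print.generator_params <- function(x, ...) {
  cat(sprintf("<generator_params> %d x %d px @ %.3f um/px, separation %.2f\n",
              x$image_size_px[1], x$image_size_px[2], x$um_per_px,
              x$separation))
  for (cls in c("good", "bad")) {
    p <- x$classes[[cls]]
    cat(sprintf(
      "  %s: ecc %.2f, packing %.2f, size_cv %.2f, spikiness %.2f, gaps %.2f\n",
      cls, p$eccentricity, p$packing_fraction, p$size_cv, p$edge_spikiness,
      p$gap_brightness))
  }
  invisible(x)
}

#' Generate one synthetic colony image
#'
#' Renders a single colony of the requested phenotype. Deterministic for a
#' fixed `(params, label, seed)` triple. When `return_masks = TRUE` the
#' returned image carries two logical ground-truth attributes: `cell_mask`
#' (pixels belonging to a cell body) and `colony_mask` (pixels inside the
#' colony outline).
#'
#' @param params A [generator_params()] object.
#' @param label `"good"` or `"bad"`.
#' @param seed Integer seed; the global RNG state is left untouched.
#' @param return_masks Attach ground-truth masks as attributes.
#' @return A [colony_image()] with intensities in `[0, 1]`.
#' @export
#' @examples
#' img <- generate_colony(generator_params(image_size_px = 64), "good", 1)
#' range(img$pixels)
generate_colony <- function(params, label, seed, return_masks = FALSE) {
  stopifnot(inherits(params, "generator_params"))
  if (!(is.character(label) && length(label) == 1L &&
        label %in% c("good", "bad")))
    param_error("label", "must be \"good\" or \"bad\"")
  p <- params$classes[[label]]
  H <- params$image_size_px[1]
  W <- params$image_size_px[2]

  withr::with_seed(as.integer(seed) %% 2147483629L, {
    # --- colony outline: radial polygon with smooth + spiky components ----
    cy <- H / 2 + runif(1, -0.05, 0.05) * H
    cx <- W / 2 + runif(1, -0.05, 0.05) * W
    r0 <- 0.36 * min(H, W) * (1 + runif(1, -0.08, 0.08))
    nv <- 72L
    theta_v <- seq(0, 2 * pi, length.out = nv + 1L)[-(nv + 1L)]
    # low-frequency lobes shared by both classes (colonies are not circles)
    lobes <- rep(0, nv)
    for (m in 2:4)
      lobes <- lobes + runif(1, 0, 0.06) * sin(m * theta_v + runif(1, 0, 2 * pi))
    spikes <- p$edge_spikiness * 0.5 * runif(nv, -1, 1)
    rad_v <- r0 * pmax(0.25, 1 + lobes + spikes)

    yy <- matrix(seq_len(H), H, W) - cy
    xx <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
    rr <- sqrt(yy^2 + xx^2)
    ang <- atan2(xx, -yy) %% (2 * pi)  # arbitrary but fixed angular origin
    # linear interpolation of the polygon radius at each pixel's angle
    seg <- ang / (2 * pi) * nv
    i0 <- floor(seg) %% nv
    frac <- seg - floor(seg)
    rad_px <- rad_v[i0 + 1L] * (1 - frac) + rad_v[(i0 + 1L) %% nv + 1L] * frac
    colony_mask <- rr <= rad_px

    # --- background with a mild illumination gradient ----------------------
    g_ang <- runif(1, 0, 2 * pi)
    grad <- (yy * cos(g_ang) + xx * sin(g_ang)) / max(H, W)
    canvas <- 0.72 + 0.03 * grad
    canvas[colony_mask] <- p$gap_brightness

    # --- cell placement: jittered square grid at the target packing -------
    r_px <- (params$cell_diameter_um / 2) / params$um_per_px
    spacing <- r_px * sqrt(pi / p$packing_fraction)
    gy <- seq(cy - r0 * 1.4, cy + r0 * 1.4, by = spacing)
    gx <- seq(cx - r0 * 1.4, cx + r0 * 1.4, by = spacing)
    centers <- expand.grid(y = gy, x = gx)
    centers$y <- centers$y + runif(nrow(centers), -0.3, 0.3) * spacing
    centers$x <- centers$x + runif(nrow(centers), -0.3, 0.3) * spacing
    # keep sites whose center lies inside the outline (slightly shrunk)
    seg_c <- (atan2(centers$x - cx, -(centers$y - cy)) %% (2 * pi)) /
      (2 * pi) * nv
    ic <- floor(seg_c) %% nv
    fr <- seg_c - floor(seg_c)
    rad_c <- rad_v[ic + 1L] * (1 - fr) + rad_v[(ic + 1L) %% nv + 1L] * fr
    keep <- sqrt((centers$y - cy)^2 + (centers$x - cx)^2) <= rad_c - 0.4 * r_px
    centers <- centers[keep, , drop = FALSE]

    cell_mask <- matrix(FALSE, H, W)
    n_cells <- nrow(centers)
    if (n_cells > 0) {
      ecc <- p$eccentricity
      ax_ratio <- sqrt(1 - ecc^2)   # b/a for the rendered ellipse
      sizes <- pmax(0.35, 1 + p$size_cv * rnorm(n_cells))
      orients <- runif(n_cells, 0, pi)
      shades <- 0.34 + 0.05 * rnorm(n_cells)
      for (k in seq_len(n_cells)) {
        # equal-area ellipse: a*b = r^2
        a <- r_px * sizes[k] / sqrt(ax_ratio)
        b <- r_px * sizes[k] * sqrt(ax_ratio)
        ylo <- max(1L, floor(centers$y[k] - a - 1))
        yhi <- min(H, ceiling(centers$y[k] + a + 1))
        xlo <- max(1L, floor(centers$x[k] - a - 1))
        xhi <- min(W, ceiling(centers$x[k] + a + 1))
        if (ylo > yhi || xlo > xhi) next
        ys <- ylo:yhi
        xs <- xlo:xhi
        dy <- matrix(ys - centers$y[k], length(ys), length(xs))
        dx <- matrix(xs - centers$x[k], length(ys), length(xs), byrow = TRUE)
        co <- cos(orients[k]); si <- sin(orients[k])
        u <- (dy * co + dx * si) / a
        v <- (-dy * si + dx * co) / b
        d <- sqrt(u^2 + v^2)
        alpha <- pmin(1, pmax(0, (1 - d) * b))  # ~1 px anti-aliased edge
        sub <- canvas[ys, xs, drop = FALSE]
        canvas[ys, xs] <- sub * (1 - alpha) + shades[k] * alpha
        cell_mask[ys, xs] <- cell_mask[ys, xs] | (d < 1)
      }
    }
    cell_mask <- cell_mask & colony_mask

    # --- phase halo: bright blurred ring along the colony rim --------------
    ring <- (rr <= rad_px + 1.5) & (rr >= rad_px - 1.5)
    halo <- gaussian_blur(ring * 1, sigma = 1.6)
    canvas <- canvas + 0.45 * halo * (0.98 - canvas)

    canvas <- gaussian_blur(canvas, sigma = 0.6)
    canvas <- canvas + params$noise_sd * rnorm(H * W)
    canvas[canvas < 0] <- 0
    canvas[canvas > 1] <- 1

    img <- colony_image(canvas, um_per_px = params$um_per_px,
                        range = c(0, 1), label = label,
                        source_id = sprintf("synth_%s_%d", label, seed))
    if (return_masks) {
      attr(img, "cell_mask") <- cell_mask
      attr(img, "colony_mask") <- colony_mask
    }
    img
  })
}

gaussian_blur <- function(m, sigma) {
  EBImage::imageData(EBImage::gblur(m, sigma = sigma))
}

#' Generate a labeled synthetic dataset
#'
#' Each item gets its own child seed derived from `(seed, class, index)`, so
#' the i-th good image is identical whatever `n_bad` is, and vice versa.
#'
#' @param n_good,n_bad Nonnegative class counts.
#' @param params A [generator_params()] object.
#' @param seed Master seed.
#' @param return_masks Attach ground-truth masks to every item.
#' @return A [colony_dataset()] with good items first, then bad.
#' @export
#' @examples
#' ds <- generate_dataset(3, 2, generator_params(image_size_px = 64), seed = 1)
#' class_counts(ds)
generate_dataset <- function(n_good, n_bad, params = generator_params(),
                             seed = 1L, return_masks = FALSE) {
  if (length(n_good) != 1L || n_good < 0 || n_good != round(n_good))
    param_error("n_good", "must be a nonnegative integer")
  if (length(n_bad) != 1L || n_bad < 0 || n_bad != round(n_bad))
    param_error("n_bad", "must be a nonnegative integer")
  items <- vector("list", n_good + n_bad)
  for (i in seq_len(n_good))
    items[[i]] <- generate_colony(params, "good", child_seed(seed, i),
                                  return_masks = return_masks)
  for (j in seq_len(n_bad))
    items[[n_good + j]] <- generate_colony(params, "bad",
                                           child_seed(seed, 500000L + j),
                                           return_masks = return_masks)
  colony_dataset(items)
}
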