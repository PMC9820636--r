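test_that("resize keeps physical units honest and is identity at matching size", {
  # full-frame geometry: 1280 x 960 px covering 290 x 218 um^2
  set.seed(1)
  big <- colony_image(matrix(runif(960 * 1280), 960, 1280),
                      um_per_px = c(218 / 960, 290 / 1280))
  out <- resize_to_input(big, 256)
  expect_identical(dim(out$pixels), c(256L, 256L))
  expect_equal(out$um_per_px[2], (290 / 1280) * (1280 / 256))
  expect_equal(out$um_per_px[1], (218 / 960) * (960 / 256))
  expect_equal(field_of_view_um(out), field_of_view_um(big))
  # area interpolation preserves the global mean exactly
  expect_equal(mean(out$pixels), mean(big$pixels), tolerance = 1e-12)

  sq <- random_image(64, seed = 2)
  expect_identical(resize_to_input(sq, 64)$pixels, sq$pixels)

  one <- colony_image(matrix(0.37, 1, 1))
  up <- resize_to_input(one, 32)
  expect_true(all(up$pixels == 0.37))
  expect_error(resize_to_input(sq, 4), "side")
})

test_that("grayscale conversion follows the BT.601 luma weights", {
  px <- function(r, g, b) colony_image(array(c(r, g, b), c(1, 1, 3)),
                                       range = c(0, 255))
  expect_equal(as.numeric(to_gray(px(100, 100, 100))$pixels), 100)
  expect_equal(as.numeric(to_gray(px(255, 0, 0))$pixels), 76.245)
  expect_equal(as.numeric(to_gray(px(0, 0, 255))$pixels), 29.07)
  expect_equal(0.299 + 0.587 + 0.114, 1)   # gray images are fixed points
  g <- random_image(8, range01 = FALSE, seed = 3)
  expect_identical(to_gray(g)$pixels, g$pixels)
  rgb <- random_image(8, channels = 3, range01 = FALSE, seed = 4)
  out <- to_gray(rgb)
  expect_identical(dim(out$pixels), c(8L, 8L))
  expect_true(all(out$pixels >= 0 & out$pixels <= 255))
})

test_that("min-max normalization maps the range onto [0, 1] and is idempotent", {
  img <- colony_image(matrix(c(0, 128, 255), 1, 3), range = c(0, 255))
  expect_equal(as.numeric(minmax_normalize(img)$pixels),
               c(0, 128 / 255, 1), tolerance = 1e-12)
  const <- colony_image(matrix(7, 4, 4), range = c(0, 255))
  expect_true(all(minmax_normalize(const)$pixels == 0))
  r <- random_image(16, range01 = FALSE, seed = 5)
  once <- minmax_normalize(r)
  twice <- minmax_normalize(once)
  expect_equal(twice$pixels, once$pixels, tolerance = 1e-12)
  expect_equal(range(once$pixels), c(0, 1))
})

test_that("binarization thresholds inclusively and is idempotent", {
  img <- colony_image(matrix(c(0.2, 0.5, 0.8), 1, 3))
  expect_equal(as.numeric(binarize(img, 0.5)$pixels), c(0, 1, 1))
  zeros <- colony_image(matrix(0, 3, 3))
  expect_true(all(binarize(zeros, 0.9)$pixels == 0))
  r <- random_image(16, seed = 6)
  once <- binarize(r, 0.4)
  expect_true(all(once$pixels %in% c(0, 1)))
  expect_identical(binarize(once, 0.4)$pixels, once$pixels)
  expect_identical(binarize(binarize(r, "otsu"), "otsu")$pixels,
                   binarize(r, "otsu")$pixels)
  expect_error(binarize(r, 1.5), "threshold")
  expect_error(binarize(r, 0), "threshold")
})

test_that("histogram equalization follows the CDF remap and preserves order", {
  # two-valued image, half at 10 and half at 200 (0..255 scale):
  # CDF(10) = 0.5, CDF(200) = 1.0
  px <- matrix(c(rep(10, 8), rep(200, 8)), 4, 4)
  eq <- equalize_histogram(colony_image(px, range = c(0, 255)))
  expect_setequal(unique(as.numeric(eq$pixels)), c(0.5, 1.0))
  expect_true(all(eq$pixels[px == 10] == 0.5))

  # an exactly uniform histogram is (within one bin) the min-max stretch
  u <- colony_image(matrix((0:255) / 255, 16, 16), range = c(0, 1))
  eq_u <- equalize_histogram(u)
  expect_lt(max(abs(eq_u$pixels - (minmax_normalize(u)$pixels))), 1 / 256 + 1e-9)

  # monotone order preservation on random images
  for (seed in 1:5) {
    r <- random_image(12, seed = seed)
    e <- equalize_histogram(r)
    o <- order(as.numeric(r$pixels))
    expect_true(all(diff(as.numeric(e$pixels)[o]) >= -1e-12))
  }
})

test_that("preprocess operators are pure and respect their range contracts", {
  for (seed in 1:4) {
    r <- random_image(20, range01 = FALSE, seed = seed)
    before <- r$pixels
    g <- to_gray(r)
    mm <- minmax_normalize(r)
    bz <- binarize(r, 0.5)
    eq <- equalize_histogram(r)
    expect_identical(r$pixels, before)   # inputs never mutated
    expect_true(all(g$pixels >= 0 & g$pixels <= 255))
    expect_true(all(mm$pixels >= 0 & mm$pixels <= 1))
    expect_true(all(bz$pixels %in% c(0, 1)))
    expect_true(all(eq$pixels >= 0 & eq$pixels <= 1))
  }
})

test_that("apply_preprocess chains resize with the selected operator", {
  img <- generate_colony(generator_params(image_size_px = 48), "good", 2)
  for (m in c("none", "gray", "normalize", "binarize", "equalize")) {
    out <- apply_preprocess(img, preprocess_spec(m, target_side_px = 32))
    expect_identical(dim(out$pixels)[1:2], c(32L, 32L))
  }
  expect_error(preprocess_spec("sharpen"), "arg")
  expect_error(preprocess_spec("binarize", binarize_threshold = 2),
               "binarize_threshold")
})
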