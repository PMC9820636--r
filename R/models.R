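#' Registry of the five VGG-family architectures
#'
#' Each entry fixes the convolutional stage layout (number of 3x3
#' convolutions and output channels per stage, each stage followed by a
#' max-pool), the first pooling size (2 by default, 4 for the `FirstPool4`
#' variants, which shrink the feature maps earlier and so carry fewer
#' parameters into the head), and whether residual skip connections wrap
#' each stage. `VGG13` follows the canonical configuration-B layout
#' (2x64, 2x128, 2x256, 2x512, 2x512) with a compact two-layer head ending
#' in a single sigmoid unit; `VGG12` drops the second convolution of the
#' last stage; `Res+VGG13` adds a 1x1-projection skip around every stage.
#'
#' @return Named list of architecture descriptions.
#' @export
arch_registry <- function() {
  base13 <- list(n_convs = c(2L, 2L, 2L, 2L, 2L),
                 channels = c(64L, 128L, 256L, 512L, 512L))
  base12 <- list(n_convs = c(2L, 2L, 2L, 2L, 1L),
                 channels = c(64L, 128L, 256L, 512L, 512L))
  list(
    "VGG13" = c(base13, first_pool = 2L, residual = FALSE),
    "VGG13-FirstPool4" = c(base13, first_pool = 4L, residual = FALSE),
    "VGG12" = c(base12, first_pool = 2L, residual = FALSE),
    "VGG12-FirstPool4" = c(base12, first_pool = 4L, residual = FALSE),
    "Res+VGG13" = c(base13, first_pool = 2L, residual = TRUE))
}

#' Declarative architecture specification
#'
#' Resolves a registry name into concrete layer shapes for a given input
#' side and width factor, including the spatial feature-map size after
#' every pooling stage and the flattened feature count entering the head.
#'
#' @param name One of the registry names (see [arch_registry()]).
#' @param input_side Square input side in pixels; must be divisible by the
#'   product of the pooling strides.
#' @param width_factor Multiplier on all channel widths (and the hidden
#'   head width); 1 is the canonical network, smaller values give reduced
#'   models for fast experiments on small synthetic images.
#' @param in_channels Input image channels (1 grayscale, 3 RGB).
#' @return An object of class `architecture_spec`.
#' @export
#' @examples
#' sp <- architecture_spec("VGG13", input_side = 64, width_factor = 1 / 8)
#' sp$map_sides
architecture_spec <- function(name, input_side = 256L, width_factor = 1,
                              in_channels = 1L) {
  reg <- arch_registry()
  if (!name %in% names(reg))
    stop("unknown architecture `", name, "`; valid names: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  a <- reg[[name]]
  assert_scalar_num(width_factor, "width_factor", lower = 0, lower_open = TRUE)
  pools <- c(a$first_pool, rep(2L, length(a$n_convs) - 1L))
  stride_prod <- prod(pools)
  if (input_side %% stride_prod != 0)
    param_error("input_side",
                sprintf("must be divisible by %d for %s", stride_prod, name))
  ch <- pmax(1L, as.integer(round(a$channels * width_factor)))
  hidden <- max(4L, as.integer(round(256L * width_factor)))
  map_sides <- as.integer(input_side / cumprod(pools))
  structure(list(
    name = name, input_side = as.integer(input_side),
    width_factor = width_factor, in_channels = as.integer(in_channels),
    n_convs = a$n_convs, channels = ch, pools = pools,
    residual = a$residual, map_sides = map_sides,
    flat_features = map_sides[length(map_sides)]^2 * ch[length(ch)],
    head_hidden = hidden), class = "architecture_spec")
}

#' @export
print.architecture_spec <- function(x, ...) {
  cat(sprintf("<architecture_spec> %s, input %d, width x%.3g\n",
              x$name, x$input_side, x$width_factor))
  for (i in seq_along(x$n_convs))
    cat(sprintf("  stage %d: %d conv(s) x %d ch %s-> pool %d -> %d px\n",
                i, x$n_convs[i], x$channels[i],
                if (x$residual) "+ skip " else "", x$pools[i],
                x$map_sides[i]))
  cat(sprintf("  head: %d -> %d -> 1 (sigmoid)\n", x$flat_features,
              x$head_hidden))
  invisible(x)
}

he_uniform <- function(nrow, ncol, fan_in) {
  lim <- sqrt(6 / fan_in)
  matrix(runif(nrow * ncol, -lim, lim), nrow, ncol)
}

#' Build an initialized model from the registry
#'
#' Weights are He-uniform initialized from `seed` (drawn in a fixed layer
#' order, so the same `(name, input_side, width_factor, seed)` always gives
#' identical weights). The handle records its total parameter count,
#' computed from the actual weight arrays.
#'
#' @inheritParams architecture_spec
#' @param seed Initialization seed.
#' @return An object of class `colony_model`.
#' @export
#' @examples
#' m <- build_model("VGG12", input_side = 64, seed = 1, width_factor = 1 / 8)
#' m$parameter_count
build_model <- function(name, input_side = 256L, seed = 0L,
                        width_factor = 1, in_channels = 1L) {
  spec <- architecture_spec(name, input_side, width_factor, in_channels)
  withr::with_seed(as.integer(seed) %% 2147483629L, {
    stages <- vector("list", length(spec$n_convs))
    cin <- spec$in_channels
    for (i in seq_along(spec$n_convs)) {
      cout <- spec$channels[i]
      convs <- vector("list", spec$n_convs[i])
      cc <- cin
      for (j in seq_len(spec$n_convs[i])) {
        convs[[j]] <- list(w = he_uniform(cout, 9L * cc, 9L * cc),
                           b = rep(0, cout))
        cc <- cout
      }
      skip <- NULL
      if (spec$residual)
        skip <- list(w = he_uniform(cout, cin, cin), b = rep(0, cout))
      stages[[i]] <- list(convs = convs, skip = skip, pool = spec$pools[i])
      cin <- cout
    }
    head <- list(
      W1 = he_uniform(spec$head_hidden, spec$flat_features,
                      spec$flat_features),
      b1 = rep(0, spec$head_hidden),
      W2 = he_uniform(1L, spec$head_hidden, spec$head_hidden),
      b2 = 0)
  })
  model <- structure(list(architecture = spec, stages = stages, head = head,
                          init_seed = as.integer(seed)),
                     class = "colony_model")
  model$parameter_count <- count_parameters(model)
  model
}

count_parameters <- function(model) {
  n <- 0L
  for (st in model$stages) {
    for (cv in st$convs) n <- n + length(cv$w) + length(cv$b)
    if (!is.null(st$skip)) n <- n + length(st$skip$w) + length(st$skip$b)
  }
  n + length(model$head$W1) + length(model$head$b1) +
    length(model$head$W2) + length(model$head$b2)
}

#' @export
print.colony_model <- function(x, ...) {
  cat(sprintf("<colony_model> %s, input %d, %s parameters, seed %d\n",
              x$architecture$name, x$architecture$input_side,
              format(x$parameter_count, big.mark = ","), x$init_seed))
  invisible(x)
}

#' List the registry with canonical parameter counts
#'
#' @param input_side Input side used for the head-size arithmetic.
#' @return A data.frame with one row per architecture.
#' @export
list_models <- function(input_side = 256L) {
  nms <- names(arch_registry())
  data.frame(
    model = nms,
    parameters = vapply(nms, function(nm)
      build_model(nm, input_side = input_side, seed = 0L)$parameter_count,
      integer(1)),
    row.names = NULL)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

stage_forward <- function(stage, x, keep_cache = FALSE) {
  x_in <- x
  acts <- list(x)
  nconv <- length(stage$convs)
  for (j in seq_len(nconv)) {
    z <- .conv3x3_forward(x, stage$convs[[j]]$w, stage$convs[[j]]$b)
    if (j < nconv) {
      x <- relu(z)
      acts[[j + 1L]] <- x
    } else {
      pre <- z
    }
  }
  if (!is.null(stage$skip))
    pre <- pre + .conv1x1_forward(x_in, stage$skip$w, stage$skip$b)
  a <- relu(pre)
  pl <- .maxpool_forward(a, stage$pool)
  out <- pl$out
  cache <- if (keep_cache)
    list(acts = acts, pre = pre, argmax = pl$argmax, a_dim = dim(a)) else NULL
  list(out = out, cache = cache)
}

stage_backward <- function(stage, cache, g_out) {
  g_a <- .maxpool_backward(g_out, cache$argmax, cache$a_dim)
  g <- g_a * (cache$pre > 0)
  grads <- list(convs = vector("list", length(stage$convs)), skip = NULL)
  if (!is.null(stage$skip)) {
    bs <- .conv1x1_backward(cache$acts[[1]], g, stage$skip$w)
    grads$skip <- list(w = bs$gw, b = bs$gb)
    g_skip_in <- bs$gx
  }
  nconv <- length(stage$convs)
  for (j in rev(seq_len(nconv))) {
    bk <- .conv3x3_backward(cache$acts[[j]], g, stage$convs[[j]]$w)
    grads$convs[[j]] <- list(w = bk$gw, b = bk$gb)
    g <- bk$gx
    if (j > 1L) g <- g * (cache$acts[[j]] > 0)
  }
  if (!is.null(stage$skip)) g <- g + g_skip_in
  list(g_in = g, grads = grads)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Forward pass: class probabilities for a batch
#'
#' Runs the network in evaluation mode on a batch of images and returns
#' the predicted probability that each image shows a good colony.
#'
#' @param model A [build_model()] handle.
#' @param batch Either a H x W x C x N numeric array matching the model's
#'   input side and channels, a single [colony_image()], or a
#'   [colony_dataset()] (items are stacked in order).
#' @return Numeric vector of length N with values strictly in (0, 1).
#' @export
forward <- function(model, batch) {
  stopifnot(inherits(model, "colony_model"))
  x <- as_batch(batch, model$architecture$input_side,
                model$architecture$in_channels)
  fw <- forward_full(model, x, keep_cache = FALSE)
  as.numeric(fw$p)
}

forward_full <- function(model, x, keep_cache = FALSE) {
  caches <- vector("list", length(model$stages))
  for (i in seq_along(model$stages)) {
    sf <- stage_forward(model$stages[[i]], x, keep_cache)
    x <- sf$out
    caches[[i]] <- sf$cache
  }
  flat_dim <- dim(x)
  Xf <- matrix(x, nrow = prod(flat_dim[1:3]), ncol = flat_dim[4])
  hz <- model$head$W1 %*% Xf + model$head$b1
  h <- relu(hz)
  logit <- model$head$W2 %*% h + model$head$b2
  p <- sigmoid(logit)
  list(p = p, caches = caches, Xf = Xf, hz = hz, h = h,
       flat_dim = flat_dim)
}

# Backward pass from per-sample probability gradient dL/dlogit = (p - y)/N.
backward_full <- function(model, fw, glogit) {
  hd <- model$head
  gW2 <- glogit %*% t(fw$h)
  gb2 <- sum(glogit)
  gh <- t(hd$W2) %*% glogit
  ghz <- gh * (fw$hz > 0)
  gW1 <- ghz %*% t(fw$Xf)
  gb1 <- rowSums(ghz)
  gX <- t(hd$W1) %*% ghz
  g <- array(gX, fw$flat_dim)
  stage_grads <- vector("list", length(model$stages))
  for (i in rev(seq_along(model$stages))) {
    sb <- stage_backward(model$stages[[i]], fw$caches[[i]], g)
    stage_grads[[i]] <- sb$grads
    g <- sb$g_in
  }
  list(stages = stage_grads,
       head = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2))
}

#' Stack a dataset or image into a network input batch
#'
#' @param batch A 4-d array, `colony_image`, list of images, or
#'   `colony_dataset`.
#' @param side Expected square side.
#' @param channels Expected channel count.
#' @return A `side x side x channels x N` numeric array.
#' @export
as_batch <- function(batch, side, channels = 1L) {
  if (is.array(batch) && length(dim(batch)) == 4L) {
    d <- dim(batch)
    if (d[1] != side || d[2] != side || d[3] != channels)
      stop(sprintf("batch shape %s does not match expected %d x %d x %d x N",
                   paste(d, collapse = " x "), side, side, channels),
           call. = FALSE)
    return(batch)
  }
  items <- if (inherits(batch, "colony_dataset")) batch$items
    else if (inherits(batch, "colony_image")) list(batch)
    else if (is.list(batch)) batch
    else stop("cannot interpret batch input", call. = FALSE)
  n <- length(items)
  out <- array(0, c(side, side, channels, n))
  for (i in seq_len(n)) {
    px <- items[[i]]$pixels
    d <- dim(px)
    if (d[1] != side || d[2] != side)
      stop(sprintf(
        "image %d is %d x %d but the model expects %d x %d (preprocess first)",
        i, d[1], d[2], side, side), call. = FALSE)
    ch <- if (length(d) == 3L) d[3] else 1L
    if (ch != channels) {
      if (ch == 3L && channels == 1L) {
        px <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
      } else if (ch == 1L && channels == 3L) {
        px <- array(rep(as.numeric(px), 3L), c(side, side, 3L))
      } else stop("channel mismatch", call. = FALSE)
    }
    out[, , , i] <- px
  }
  out
}
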