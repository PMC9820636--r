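#' Training configuration
#'
#' @param split_ratio Train:validation ratio as a length-2 positive numeric
#'   (default `c(4, 1)`).
#' @param epochs Maximum number of epochs.
#' @param batch_size Minibatch size (>= 1).
#' @param learning_rate Adam step size (> 0).
#' @param optimizer Only `"adam"` is implemented.
#' @param seed Seed driving shuffling and augmentation inside [fit()].
#' @param early_stop_patience Stop after this many epochs without a new
#'   best validation loss; `NULL` disables early stopping.
#' @param positive_label Label mapped to y = 1 in the loss (fixed
#'   convention: `"good"`).
#' @return An object of class `train_config`.
#' @export
train_config <- function(split_ratio = c(4, 1), epochs = 50L,
                         batch_size = 16L, learning_rate = 1e-4,
                         optimizer = "adam", seed = 1L,
                         early_stop_patience = 10L,
                         positive_label = "good") {
  if (length(split_ratio) != 2L || any(split_ratio <= 0))
    param_error("split_ratio", "must be two positive numbers")
  assert_scalar_num(epochs, "epochs", lower = 1)
  assert_scalar_num(batch_size, "batch_size", lower = 1)
  assert_scalar_num(learning_rate, "learning_rate", lower = 0,
                    lower_open = TRUE)
  optimizer <- match.arg(optimizer, "adam")
  if (!is.null(early_stop_patience))
    assert_scalar_num(early_stop_patience, "early_stop_patience", lower = 1)
  structure(list(split_ratio = as.numeric(split_ratio),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, optimizer = optimizer,
                 seed = as.integer(seed),
                 early_stop_patience = early_stop_patience,
                 positive_label = positive_label),
            class = "train_config")
}

#' Split a dataset into training and validation parts
#'
#' The validation size is `round(n * val / sum(ratio))`. Under
#' stratification (the default) per-class validation quotas are assigned by
#' largest remainders so they sum exactly to that size; if a class is
#' absent the split falls back to unstratified with a warning.
#'
#' @param ds A [colony_dataset()].
#' @param ratio Length-2 positive ratio, train first (default 4:1).
#' @param seed Split seed.
#' @param stratified Stratify by label (default `TRUE`).
#' @return List with elements `train`, `validation` (datasets) and
#'   `train_idx`, `val_idx` (indices into `ds`).
#' @export
#' @examples
#' ds <- generate_dataset(8, 7, generator_params(image_size_px = 32), 1)
#' sp <- split_dataset(ds, c(4, 1), seed = 1)
#' length(sp$validation)
split_dataset <- function(ds, ratio = c(4, 1), seed = 1L,
                          stratified = TRUE) {
  stopifnot(inherits(ds, "colony_dataset"))
  n <- length(ds)
  if (n == 0L) stop("cannot split an empty dataset", call. = FALSE)
  if (length(ratio) != 2L || any(ratio <= 0))
    param_error("ratio", "must be two positive numbers")
  n_val <- round(n * ratio[2] / sum(ratio))
  labels <- dataset_labels(ds)
  val_idx <- withr::with_seed(as.integer(seed) %% 2147483629L, {
    if (stratified && all(c("good", "bad") %in% labels)) {
      classes <- sort(unique(labels))
      raw <- vapply(classes, function(cl) sum(labels == cl) * n_val / n,
                    numeric(1))
      quota <- floor(raw)
      rem <- n_val - sum(quota)
      if (rem > 0) {
        extra <- order(raw - quota, decreasing = TRUE)[seq_len(rem)]
        quota[extra] <- quota[extra] + 1
      }
      unlist(lapply(seq_along(classes), function(i) {
        pool <- which(labels == classes[i])
        sample(pool, min(quota[i], length(pool)))
      }), use.names = FALSE)
    } else {
      if (stratified)
        warning("a class is absent; falling back to unstratified split")
      sample.int(n, n_val)
    }
  })
  val_idx <- sort(val_idx)
  train_idx <- setdiff(seq_len(n), val_idx)
  list(train = dataset_subset(ds, train_idx),
       validation = dataset_subset(ds, val_idx),
       train_idx = train_idx, val_idx = val_idx)
}

#' Binary cross-entropy loss
#'
#' `L = -(1/N) * sum(y * log(p) + (1 - y) * log(1 - p))`, with
#' probabilities clamped to `[1e-7, 1 - 1e-7]` to avoid `log(0)`.
#'
#' @param y Numeric 0/1 labels.
#' @param p Predicted probabilities, same length.
#' @return Nonnegative scalar; 0 only in the perfect-prediction limit.
#' @export
#' @examples
#' bce_loss(c(1, 0), c(0.5, 0.5))   # log(2)
bce_loss <- function(y, p) {
  if (length(y) != length(p))
    stop("y and p must have equal length", call. = FALSE)
  if (length(y) == 0L) stop("empty input", call. = FALSE)
  eps <- 1e-7
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

adam_init <- function(par) lapply(par, function(x) {
  list(m = array(0, dim(x) %||% length(x)),
       v = array(0, dim(x) %||% length(x)))
})

adam_step <- function(par, grad, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (k in seq_along(par)) {
    g <- grad[[k]]
    state[[k]]$m <- beta1 * state[[k]]$m + (1 - beta1) * g
    state[[k]]$v <- beta2 * state[[k]]$v + (1 - beta2) * g * g
    mhat <- state[[k]]$m / (1 - beta1^t)
    vhat <- state[[k]]$v / (1 - beta2^t)
    par[[k]] <- par[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, state = state)
}

# Flatten model parameters into a named list (and back) so the optimizer
# can treat them uniformly.
collect_params <- function(model) {
  out <- list()
  for (i in seq_along(model$stages)) {
    st <- model$stages[[i]]
    for (j in seq_along(st$convs)) {
      out[[sprintf("s%d_c%d_w", i, j)]] <- st$convs[[j]]$w
      out[[sprintf("s%d_c%d_b", i, j)]] <- st$convs[[j]]$b
    }
    if (!is.null(st$skip)) {
      out[[sprintf("s%d_skip_w", i)]] <- st$skip$w
      out[[sprintf("s%d_skip_b", i)]] <- st$skip$b
    }
  }
  out$head_W1 <- model$head$W1
  out$head_b1 <- model$head$b1
  out$head_W2 <- model$head$W2
  out$head_b2 <- model$head$b2
  out
}

collect_grads <- function(model, grads) {
  out <- list()
  for (i in seq_along(model$stages)) {
    st <- model$stages[[i]]
    for (j in seq_along(st$convs)) {
      out[[sprintf("s%d_c%d_w", i, j)]] <- grads$stages[[i]]$convs[[j]]$w
      out[[sprintf("s%d_c%d_b", i, j)]] <- grads$stages[[i]]$convs[[j]]$b
    }
    if (!is.null(st$skip)) {
      out[[sprintf("s%d_skip_w", i)]] <- grads$stages[[i]]$skip$w
      out[[sprintf("s%d_skip_b", i)]] <- grads$stages[[i]]$skip$b
    }
  }
  out$head_W1 <- grads$head$W1
  out$head_b1 <- grads$head$b1
  out$head_W2 <- grads$head$W2
  out$head_b2 <- grads$head$b2
  out
}

restore_params <- function(model, par) {
  for (i in seq_along(model$stages)) {
    for (j in seq_along(model$stages[[i]]$convs)) {
      model$stages[[i]]$convs[[j]]$w <- par[[sprintf("s%d_c%d_w", i, j)]]
      model$stages[[i]]$convs[[j]]$b <-
        as.numeric(par[[sprintf("s%d_c%d_b", i, j)]])
    }
    if (!is.null(model$stages[[i]]$skip)) {
      model$stages[[i]]$skip$w <- par[[sprintf("s%d_skip_w", i)]]
      model$stages[[i]]$skip$b <-
        as.numeric(par[[sprintf("s%d_skip_b", i)]])
    }
  }
  model$head$W1 <- par$head_W1
  model$head$b1 <- as.numeric(par$head_b1)
  model$head$W2 <- par$head_W2
  model$head$b2 <- as.numeric(par$head_b2)
  model
}

labels_to_y <- function(labels, positive = "good") {
  as.numeric(labels == positive)
}

#' Train a model on a labeled dataset
#'
#' Minimizes binary cross-entropy with Adam. Preprocessing (resize + the
#' selected operator) is applied once to both sets; stochastic augmentation
#' is re-applied to the training items every epoch and never touches the
#' validation set. The returned model is the checkpoint with the best
#' validation loss. Fully reproducible given the model's init seed and
#' `cfg$seed`.
#'
#' @param model A [build_model()] handle.
#' @param train_set,val_set [colony_dataset()] objects.
#' @param cfg A [train_config()].
#' @param preprocess A [preprocess_spec()]; its `target_side_px` must match
#'   the model input side. Default: plain resize to the model input.
#' @param augment An [augment_spec()] or `NULL` for no augmentation.
#' @param verbose Print one line per epoch.
#' @return List with elements `model` (best checkpoint) and `history`
#'   (data.frame: epoch, train_loss, val_loss, val_accuracy; attribute
#'   `best_epoch`).
#' @export
fit <- function(model, train_set, val_set, cfg = train_config(),
                preprocess = NULL, augment = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "colony_model"),
            inherits(train_set, "colony_dataset"),
            inherits(val_set, "colony_dataset"),
            inherits(cfg, "train_config"))
  side <- model$architecture$input_side
  if (is.null(preprocess))
    preprocess <- preprocess_spec("none", target_side_px = side)
  if (preprocess$target_side_px != side)
    param_error("preprocess$target_side_px",
                sprintf("must equal the model input side (%d)", side))
  tr_items <- lapply(train_set$items, apply_preprocess, spec = preprocess)
  va_items <- lapply(val_set$items, apply_preprocess, spec = preprocess)
  y_tr <- labels_to_y(vapply(tr_items, `[[`, "", "label"),
                      cfg$positive_label)
  y_va <- labels_to_y(vapply(va_items, `[[`, "", "label"),
                      cfg$positive_label)
  chans <- model$architecture$in_channels
  x_va <- as_batch(va_items, side, chans)
  n_tr <- length(tr_items)
  transform <- if (!is.null(augment)) compose_augment(augment) else identity
  augmenting <- !is.null(augment) && (augment$use_crop || augment$use_rotation)

  par <- collect_params(model)
  opt <- adam_init(par)
  t_step <- 0L
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric(), val_accuracy = numeric())
  best <- list(loss = Inf, par = par, epoch = 0L)

  withr::with_seed(cfg$seed %% 2147483629L, {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n_tr)
      ep_loss <- 0
      n_seen <- 0L
      for (b0 in seq(1L, n_tr, by = cfg$batch_size)) {
        idx <- ord[b0:min(b0 + cfg$batch_size - 1L, n_tr)]
        items <- tr_items[idx]
        if (augmenting) items <- lapply(items, transform)
        xb <- as_batch(items, side, chans)
        yb <- y_tr[idx]
        model <- restore_params(model, par)
        fw <- forward_full(model, xb, keep_cache = TRUE)
        pb <- as.numeric(fw$p)
        loss <- bce_loss(yb, pb)
        if (!is.finite(loss))
          stop(sprintf(
            "training diverged at epoch %d (non-finite loss); try a lower learning rate",
            epoch), call. = FALSE)
        glogit <- matrix((pb - yb) / length(yb), nrow = 1L)
        gr <- collect_grads(model, backward_full(model, fw, glogit))
        t_step <- t_step + 1L
        upd <- adam_step(par, gr, opt, cfg$learning_rate, t_step)
        par <- upd$par
        opt <- upd$state
        ep_loss <- ep_loss + loss * length(idx)
        n_seen <- n_seen + length(idx)
      }
      model <- restore_params(model, par)
      p_va <- as.numeric(forward_full(model, x_va)$p)
      val_loss <- bce_loss(y_va, p_va)
      val_acc <- mean((p_va >= 0.5) == (y_va == 1))
      hist[epoch, ] <- list(epoch, ep_loss / n_seen, val_loss, val_acc)
      if (verbose)
        message(sprintf(
          "epoch %3d  train_loss %.4f  val_loss %.4f  val_acc %.3f",
          epoch, ep_loss / n_seen, val_loss, val_acc))
      if (val_loss < best$loss)
        best <- list(loss = val_loss, par = par, epoch = epoch)
      if (!is.null(cfg$early_stop_patience) &&
          epoch - best$epoch >= cfg$early_stop_patience) break
    }
  })
  model <- restore_params(model, best$par)
  attr(hist, "best_epoch") <- best$epoch
  list(model = model, history = hist)
}
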