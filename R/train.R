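#' Multi-class cross-entropy loss
#'
#' Applies a per-pixel softmax over the class scores and returns the mean over
#' pixels of the negative log predicted probability of the true class. The
#' pixel mean (rather than the sum) keeps the learning rate independent of
#' tile size and batch size.
#'
#' @param scores Class-score array `(H, W, K)` or `(H, W, K, N)`.
#' @param target Integer label array `(H, W)` or `(H, W, N)` with values in
#'   `{0, ..., K - 1}`.
#' @param grad Also return the gradient with respect to `scores`.
#' @return The scalar loss, or (with `grad = TRUE`) a list with elements
#'   `loss` and `grad`.
#' @export
cross_entropy_loss <- function(scores, target, grad = FALSE) {
  scores <- as_hwcn(scores)
  d <- dim(scores); K <- d[3]
  if (is.null(dim(target))) dim(target) <- c(d[1], d[2])
  td <- dim(target)
  if (length(td) == 2L) dim(target) <- c(td, 1L)
  td <- dim(target)
  if (!identical(td[1:2], d[1:2]) || td[3] != d[4])
    stop("scores and target are not spatially aligned")
  tv <- as.integer(target)
  if (anyNA(tv) || any(tv < 0L) || any(tv >= K))
    stop("target labels must lie in {0, ..., ", K - 1L, "}")
  m <- matrix(aperm(scores, c(1L, 2L, 4L, 3L)), prod(d[-3]), K)
  mx <- m[, 1]
  for (k in seq_len(K)[-1]) mx <- pmax(mx, m[, k])
  lse <- mx + log(rowSums(exp(m - mx)))
  tr <- m[cbind(seq_len(nrow(m)), tv + 1L)]
  loss <- mean(lse - tr)
  if (!grad) return(loss)
  p <- exp(m - lse)
  p[cbind(seq_len(nrow(m)), tv + 1L)] <-
    p[cbind(seq_len(nrow(m)), tv + 1L)] - 1
  p <- p / nrow(m)
  g <- aperm(array(p, c(d[1], d[2], d[4], K)), c(1L, 2L, 4L, 3L))
  list(loss = loss, grad = g)
}

#' Polynomial learning-rate schedule
#'
#' `lr = base_lr * (1 - epoch / max_epoch) ^ power`, the standard "poly"
#' decay: the full base rate at epoch 0, exactly 0 at `max_epoch`, and
#' monotonically non-increasing in between.
#'
#' @param epoch Current epoch, `0 <= epoch <= max_epoch`.
#' @param base_lr Base learning rate.
#' @param max_epoch Total number of epochs.
#' @param power Polynomial power (0.9 by convention).
#' @return The learning rate for `epoch`.
#' @export
poly_lr <- function(epoch, base_lr = 0.001, max_epoch = 50L, power = 0.9) {
  stopifnot(base_lr > 0, max_epoch >= 1L, power > 0)
  if (any(epoch < 0) || any(epoch > max_epoch))
    stop("epoch must lie in [0, max_epoch]")
  base_lr * (1 - epoch / max_epoch)^power
}

#' Training configuration
#'
#' @param base_lr Base learning rate of the polynomial schedule.
#' @param batch_size Tiles per gradient step.
#' @param max_epoch Number of training epochs.
#' @param power Polynomial decay power.
#' @param adam_beta1,adam_beta2,adam_eps Adam moment decay rates and epsilon.
#' @param seed Global seed; all shuffling, augmentation and initialization
#'   streams are derived from it.
#' @param augment Apply random rotation/mirror/noise augmentation on the fly.
#' @param noise_sd Augmentation noise standard deviation, as a fraction of
#'   each band's value range.
#' @param checkpoint_path Optional path; the best-validation weights are
#'   written there as an RDS checkpoint.
#' @return An object of class `agrinet_train_config`.
#' @export
train_config <- function(base_lr = 0.001, batch_size = 4L, max_epoch = 50L,
                         power = 0.9, adam_beta1 = 0.9, adam_beta2 = 0.999,
                         adam_eps = 1e-8, seed = 1L, augment = TRUE,
                         noise_sd = 0.01, checkpoint_path = NULL) {
  stopifnot(base_lr > 0, batch_size >= 1L, max_epoch >= 1L, power > 0,
            noise_sd >= 0)
  structure(list(base_lr = base_lr, batch_size = as.integer(batch_size),
                 max_epoch = as.integer(max_epoch), power = power,
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 adam_eps = adam_eps, seed = as.integer(seed),
                 augment = isTRUE(augment), noise_sd = noise_sd,
                 checkpoint_path = checkpoint_path),
            class = "agrinet_train_config")
}

adam_init <- function(slots) {
  lapply(slots, function(s) {
    v <- get(s$name, envir = s$env)
    list(m = array(0, dim(v) %||% length(v)),
         v = array(0, dim(v) %||% length(v)))
  })
}

adam_step <- function(state, slots, lr, t, beta1, beta2, eps) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (i in seq_along(slots)) {
    s <- slots[[i]]
    g <- s$env$g[[s$name]]
    if (is.null(g)) next
    st <- state[[i]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g * g
    w <- get(s$name, envir = s$env)
    w <- w - lr * (st$m / bc1) / (sqrt(st$v / bc2) + eps)
    assign(s$name, w, envir = s$env)
    state[[i]] <- st
  }
  state
}

#' Train the segmentation network
#'
#' Runs `config$max_epoch` epochs of Adam on shuffled mini-batches with
#' multi-class cross-entropy loss and the polynomial learning-rate schedule
#' (evaluated at the 0-based epoch index, so epoch 1 trains at the full base
#' rate). Augmentation, when enabled, is applied on the fly with a per-epoch
#' seed derived from the global seed. Validation mIoU/OA/recall are computed
#' every epoch over the aggregated confusion matrix of the validation split,
#' and the weights of the best-mIoU epoch are retained.
#'
#' @param model An [agrinet_model()].
#' @param tiles List of [tile_pair()] objects.
#' @param manifest A [split_tiles()] manifest; if `NULL`, tiles are split
#'   7:3 under `config$seed`.
#' @param config An [train_config()].
#' @param verbose Print a one-line summary per epoch.
#' @return An object of class `agrinet_fit` with elements `model` (weights at
#'   the best validation epoch), `history` (per-epoch data frame), `best_epoch`
#'   and the configurations.
#' @export
train_agrinet <- function(model, tiles, manifest = NULL,
                          config = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "agrinet_model"),
            inherits(config, "agrinet_train_config"), length(tiles) >= 1L)
  ids <- vapply(tiles, function(t) t$tile_id, character(1))
  if (is.null(manifest)) manifest <- split_tiles(tiles, 0.7, config$seed)
  tr_idx <- match(manifest$train_ids, ids)
  va_idx <- match(manifest$val_ids, ids)
  if (anyNA(tr_idx) || anyNA(va_idx))
    stop("manifest refers to tile ids not present in `tiles`")
  if (length(tr_idx) == 0L || length(va_idx) == 0L)
    stop("empty training or validation split")
  K <- model$config$num_classes
  slots <- module_param_slots(model)
  opt <- adam_init(slots)
  hist <- data.frame(epoch = integer(), lr = numeric(),
                     train_loss = numeric(), val_miou = numeric(),
                     val_oa = numeric(), val_recall = numeric())
  best <- list(miou = -Inf, state = NULL, epoch = NA_integer_)
  step <- 0L
  for (epoch in seq_len(config$max_epoch)) {
    lr <- poly_lr(epoch - 1L, config$base_lr, config$max_epoch, config$power)
    eseed <- derive_seed(config$seed, 1000L + epoch)
    order_idx <- with_seed(eseed, sample(tr_idx))
    batches <- split(order_idx, ceiling(seq_along(order_idx) /
                                          config$batch_size))
    losses <- numeric(0)
    for (b in seq_along(batches)) {
      bt <- lapply(seq_along(batches[[b]]), function(j) {
        pair <- tiles[[batches[[b]][j]]]
        if (config$augment)
          pair <- random_augment(pair,
                                 seed = derive_seed(eseed, b * 1000L + j),
                                 noise_sd = config$noise_sd)
        pair
      })
      hwd <- dim(bt[[1]]$image)
      x <- array(0, c(hwd[1], hwd[2], hwd[3], length(bt)))
      y <- array(0L, c(hwd[1], hwd[2], length(bt)))
      for (j in seq_along(bt)) {
        x[, , , j] <- bt[[j]]$image
        y[, , j] <- bt[[j]]$mask
      }
      s <- agrinet_forward(model, x, training = TRUE)
      ce <- cross_entropy_loss(s, y, grad = TRUE)
      if (!is.finite(ce$loss))
        stop("non-finite training loss at epoch ", epoch, ", batch ", b,
             "; try a lower learning rate")
      agrinet_backward(model, ce$grad)
      step <- step + 1L
      opt <- adam_step(opt, slots, lr, step, config$adam_beta1,
                       config$adam_beta2, config$adam_eps)
      losses <- c(losses, ce$loss)
    }
    vm <- evaluate_tiles(model, tiles[va_idx])
    hist <- rbind(hist, data.frame(epoch = epoch, lr = lr,
                                   train_loss = mean(losses),
                                   val_miou = vm$miou, val_oa = vm$oa,
                                   val_recall = vm$recall))
    if (vm$miou > best$miou)
      best <- list(miou = vm$miou, state = module_state(model), epoch = epoch)
    if (verbose)
      cat(sprintf("epoch %3d  lr %.2e  loss %.4f  mIoU %.4f  OA %.4f\n",
                  epoch, lr, mean(losses), vm$miou, vm$oa))
  }
  module_load_state(model, best$state)
  if (!is.null(config$checkpoint_path))
    saveRDS(list(config = model$config, state = best$state,
                 best_epoch = best$epoch, history = hist),
            config$checkpoint_path)
  structure(list(model = model, history = hist, best_epoch = best$epoch,
                 manifest = manifest, train_config = config),
            class = "agrinet_fit")
}

#' Load a trained network from a checkpoint file
#'
#' @param path RDS checkpoint written by [train_agrinet()].
#' @return An [agrinet_model()] with the stored weights.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- agrinet_model(ck$config)
  module_load_state(model, ck$state)
  model
}

#' @export
print.agrinet_fit <- function(x, ...) {
  h <- x$history
  cat("Trained crop-segmentation network\n")
  cat(sprintf("  %d epochs; best validation mIoU %.4f at epoch %d\n",
              nrow(h), max(h$val_miou), x$best_epoch))
  cat(sprintf("  final train loss %.4f; validation OA %.4f, recall %.4f\n",
              h$train_loss[nrow(h)], h$val_oa[which.max(h$val_miou)],
              h$val_recall[which.max(h$val_miou)]))
  invisible(x)
}

#' @export
summary.agrinet_fit <- function(object, ...) {
  print(object)
  cat("\nPer-epoch history (last 5):\n")
  print(utils::tail(object$history, 5), row.names = FALSE)
  invisible(object$history)
}

#' @export
predict.agrinet_fit <- function(object, image, ...) {
  predict(object$model, image, ...)
}

#' @export
plot.agrinet_fit <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
       ylab = "training loss", main = "Loss convergence", ...)
  plot(h$epoch, h$val_miou, type = "l", xlab = "epoch",
       ylab = "validation mIoU", main = "Validation mIoU", ...)
  invisible(x)
}
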