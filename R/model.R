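#' Architectural configuration of the segmentation network
#'
#' Collects every hyperparameter needed to rebuild the network reproducibly:
#' a ShuffleNet v2 encoder (truncated after Stage3, output stride 16), atrous
#' spatial pyramid pooling on the deep features, an optional convolutional
#' block attention module after the 4x upsample, and a decoder that fuses
#' mid- and low-level encoder features before a final stride-2 transpose
#' convolution restores the input resolution.
#'
#' @param in_channels Number of input image channels (10 for the fused
#'   Sentinel-2 stack).
#' @param num_classes Number of output classes including background.
#' @param encoder_width_scale ShuffleNet v2 width multiplier; 1.0 gives the
#'   canonical 24/116/232 stage widths.
#' @param stage_repeats Units per encoder stage (Stage2, Stage3); the first
#'   unit of each stage is the down-sampling unit.
#' @param stage_out_channels Optional explicit per-stage channel counts
#'   (stem, Stage2, Stage3); overrides `encoder_width_scale`.
#' @param aspp_dilations Dilation rates of the parallel atrous branches.
#' @param aspp_out_channels Channels of every ASPP branch and its projection.
#' @param cbam_reduction Channel-attention MLP bottleneck ratio.
#' @param cbam_spatial_kernel Spatial-attention kernel size; fixed at 7.
#' @param skip_reduce_channels_low,skip_reduce_channels_mid Channels of the
#'   1x1 reductions applied to the low/mid encoder skips before concatenation.
#' @param decoder_refine_channels Widths of the two 3x3 refinement
#'   convolutions (after the mid-level and low-level concatenations). The
#'   defaults are calibrated so the Eq-style parameter/FLOP accounting of the
#'   default network totals 3.89 M parameters and 47.5 GFLOPs at 512x512.
#' @param use_cbam Include the attention module (`FALSE` for the ablation).
#' @param seed Seed used for weight initialization.
#' @return An object of class `agrinet_config`.
#' @export
network_config <- function(in_channels = 10L,
                           num_classes = 3L,
                           encoder_width_scale = 1.0,
                           stage_repeats = c(4L, 8L),
                           stage_out_channels = NULL,
                           aspp_dilations = c(6L, 12L, 18L),
                           aspp_out_channels = 256L,
                           cbam_reduction = 16L,
                           cbam_spatial_kernel = 7L,
                           skip_reduce_channels_low = 48L,
                           skip_reduce_channels_mid = 48L,
                           decoder_refine_channels = c(432L, 86L),
                           use_cbam = TRUE,
                           seed = 1L) {
  if (is.null(stage_out_channels)) {
    canon <- list(`0.5` = c(24L, 48L, 96L), `1` = c(24L, 116L, 232L),
                  `1.5` = c(24L, 176L, 352L), `2` = c(24L, 244L, 488L))
    key <- as.character(encoder_width_scale)
    stage_out_channels <- if (!is.null(canon[[key]])) canon[[key]] else
      c(24L, 2L * round(58 * encoder_width_scale),
        4L * round(58 * encoder_width_scale))
  }
  stopifnot(length(stage_out_channels) == 3L, length(stage_repeats) == 2L,
            all(stage_out_channels > 0L), all(stage_repeats >= 1L),
            length(decoder_refine_channels) == 2L,
            all(decoder_refine_channels > 0L),
            aspp_out_channels > 0L, in_channels >= 1L, num_classes >= 2L)
  if (cbam_spatial_kernel != 7L)
    stop("the spatial-attention kernel is fixed at 7x7")
  cfg <- list(in_channels = as.integer(in_channels),
              num_classes = as.integer(num_classes),
              encoder_width_scale = encoder_width_scale,
              stage_repeats = as.integer(stage_repeats),
              stage_out_channels = as.integer(stage_out_channels),
              aspp_dilations = as.integer(aspp_dilations),
              aspp_out_channels = as.integer(aspp_out_channels),
              cbam_reduction = as.integer(cbam_reduction),
              cbam_spatial_kernel = 7L,
              skip_reduce_channels_low = as.integer(skip_reduce_channels_low),
              skip_reduce_channels_mid = as.integer(skip_reduce_channels_mid),
              decoder_refine_channels = as.integer(decoder_refine_channels),
              use_cbam = isTRUE(use_cbam),
              seed = as.integer(seed))
  class(cfg) <- "agrinet_config"
  cfg
}

#' @export
print.agrinet_config <- function(x, ...) {
  cat("Network configuration\n")
  cat("  input:", x$in_channels, "channels ->", x$num_classes, "classes\n")
  cat("  encoder stages:", paste(x$stage_out_channels, collapse = "/"),
      "channels, repeats", paste(x$stage_repeats, collapse = "/"), "\n")
  cat("  ASPP:", x$aspp_out_channels, "channels, dilations",
      paste(x$aspp_dilations, collapse = "/"), "\n")
  cat("  CBAM:", if (x$use_cbam) sprintf("on (reduction %d, 7x7 spatial)",
                                         x$cbam_reduction) else "off", "\n")
  cat("  decoder refine:", paste(x$decoder_refine_channels, collapse = "/"),
      "channels; skips", x$skip_reduce_channels_mid, "(mid) /",
      x$skip_reduce_channels_low, "(low)\n")
  invisible(x)
}

#' Build the segmentation network
#'
#' Assembles the encoder-decoder from a [network_config()]: 3x3 stride-2 stem
#' (low-level features at input/2), 3x3 stride-2 max pool (mid-level at
#' input/4), two ShuffleNet v2 stages (deep features at input/16), ASPP, 4x
#' bilinear upsampling, optional CBAM, two skip-fusion refinement stages and
#' a stride-2 transpose convolution yielding per-pixel class scores at the
#' input resolution. Weights are Kaiming-initialized under `config$seed`.
#'
#' @param config An [network_config()] object.
#' @return An object of class `agrinet_model`.
#' @export
agrinet_model <- function(config = network_config()) {
  stopifnot(inherits(config, "agrinet_config"))
  soc <- config$stage_out_channels
  with_seed(config$seed, {
    self <- nn_module("agrinet")
    self$stem <- nn_cbr(config$in_channels, soc[1], 3L, stride = 2L, pad = 1L)
    self$pool <- nn_maxpool(3L, 2L, 1L)
    self$stage2 <- nn_shuffle_stage(soc[1], soc[2], config$stage_repeats[1])
    self$stage3 <- nn_shuffle_stage(soc[2], soc[3], config$stage_repeats[2])
    self$aspp <- nn_aspp(soc[3], config$aspp_dilations,
                         config$aspp_out_channels)
    self$up4 <- nn_upsample(4L)
    if (config$use_cbam)
      self$cbam <- nn_cbam(config$aspp_out_channels, config$cbam_reduction,
                           config$cbam_spatial_kernel)
    self$skip_mid <- nn_cbr(soc[1], config$skip_reduce_channels_mid, 1L)
    self$skip_low <- nn_cbr(soc[1], config$skip_reduce_channels_low, 1L)
    w <- config$decoder_refine_channels
    self$refine1 <- nn_cbr(config$aspp_out_channels +
                             config$skip_reduce_channels_mid, w[1], 3L,
                           pad = 1L)
    self$up2 <- nn_upsample(2L)
    self$refine2 <- nn_cbr(w[1] + config$skip_reduce_channels_low, w[2], 3L,
                           pad = 1L)
    self$head <- nn_tconv(w[2], config$num_classes, 4L, 2L, 1L, bias = TRUE)
    self$children <- c(list(self$stem, self$stage2, self$stage3, self$aspp),
                       if (config$use_cbam) list(self$cbam),
                       list(self$skip_mid, self$skip_low, self$refine1,
                            self$refine2, self$head))
    self$config <- config
    class(self) <- c("agrinet_model", "nn_module")
    self
  })
}

#' Run the network forward pass
#'
#' @param model An [agrinet_model()].
#' @param x Image array `(H, W, C)` or batch `(H, W, C, N)` with `H`, `W`
#'   divisible by 16 and `C` matching `model$config$in_channels`.
#' @param training Keep caches for a subsequent backward pass and use batch
#'   statistics in normalization layers.
#' @param features Also return the low/mid/deep encoder feature maps (at
#'   input/2, input/4 and input/16 scale).
#' @return Class-score array `(H, W, num_classes, N)`, or a list with
#'   elements `scores`, `low`, `mid`, `deep` when `features = TRUE`.
#' @export
agrinet_forward <- function(model, x, training = FALSE, features = FALSE) {
  cfg <- model$config
  x <- as_hwcn(x)
  d <- dim(x)
  if (d[3] != cfg$in_channels)
    stop("input has ", d[3], " channels but the network expects ",
         cfg$in_channels)
  if (d[1] %% 16L != 0L || d[2] %% 16L != 0L)
    stop("input height/width must be divisible by 16, got ",
         d[1], "x", d[2])
  low <- model$stem$forward(x, training)
  mid <- model$pool$forward(low, training)
  deep <- model$stage3$forward(model$stage2$forward(mid, training), training)
  u <- model$up4$forward(model$aspp$forward(deep, training), training)
  if (cfg$use_cbam) u <- model$cbam$forward(u, training)
  mr <- model$skip_mid$forward(mid, training)
  c1 <- array(0, c(dim(u)[1], dim(u)[2], dim(u)[3] + dim(mr)[3], d[4]))
  c1[, , seq_len(dim(u)[3]), ] <- u
  c1[, , dim(u)[3] + seq_len(dim(mr)[3]), ] <- mr
  r1 <- model$refine1$forward(c1, training)
  u2 <- model$up2$forward(r1, training)
  lr <- model$skip_low$forward(low, training)
  c2 <- array(0, c(dim(u2)[1], dim(u2)[2], dim(u2)[3] + dim(lr)[3], d[4]))
  c2[, , seq_len(dim(u2)[3]), ] <- u2
  c2[, , dim(u2)[3] + seq_len(dim(lr)[3]), ] <- lr
  scores <- model$head$forward(model$refine2$forward(c2, training), training)
  if (training)
    model$.split <- c(aspp_c = dim(u)[3], mid_c = dim(mr)[3],
                      r1_c = dim(u2)[3], low_c = dim(lr)[3])
  if (features) list(scores = scores, low = low, mid = mid, deep = deep)
  else scores
}

# Backward pass matching agrinet_forward(training = TRUE). Gradients are
# accumulated where a feature map feeds two consumers (the encoder skips).
agrinet_backward <- function(model, dscores) {
  cfg <- model$config
  sp <- model$.split
  dc2 <- model$refine2$backward(model$head$backward(dscores))
  du2 <- dc2[, , seq_len(sp["r1_c"]), , drop = FALSE]
  dlr <- dc2[, , sp["r1_c"] + seq_len(sp["low_c"]), , drop = FALSE]
  dlow_skip <- model$skip_low$backward(dlr)
  dc1 <- model$refine1$backward(model$up2$backward(du2))
  du <- dc1[, , seq_len(sp["aspp_c"]), , drop = FALSE]
  dmr <- dc1[, , sp["aspp_c"] + seq_len(sp["mid_c"]), , drop = FALSE]
  dmid_skip <- model$skip_mid$backward(dmr)
  if (cfg$use_cbam) du <- model$cbam$backward(du)
  ddeep <- model$aspp$backward(model$up4$backward(du))
  dmid <- model$stage2$backward(model$stage3$backward(ddeep)) + dmid_skip
  dlow <- model$pool$backward(dmid) + dlow_skip
  invisible(model$stem$backward(dlow))
}

#' Predict crop labels for an image
#'
#' @param object An [agrinet_model()].
#' @param image `(H, W, C)` image array (or `(H, W, C, N)` batch).
#' @param type `"class"` for argmax labels in `{0, ..., num_classes - 1}`,
#'   `"prob"` for per-pixel softmax probabilities, `"scores"` for raw scores.
#' @param ... Unused.
#' @return Label matrix `(H, W)` (or `(H, W, N)` array), or a score/prob
#'   array `(H, W, num_classes, N)`.
#' @export
predict.agrinet_model <- function(object, image,
                                  type = c("class", "prob", "scores"), ...) {
  type <- match.arg(type)
  s <- agrinet_forward(object, image, training = FALSE)
  if (type == "scores") return(s)
  d <- dim(s)
  m <- matrix(aperm(s, c(1L, 2L, 4L, 3L)), d[1] * d[2] * d[4], d[3])
  if (type == "prob") {
    mx <- m[, 1]
    for (k in seq_len(d[3])[-1]) mx <- pmax(mx, m[, k])
    e <- exp(m - mx)
    p <- e / rowSums(e)
    return(aperm(array(p, c(d[1], d[2], d[4], d[3])), c(1L, 2L, 4L, 3L)))
  }
  lab <- max.col(m, ties.method = "first") - 1L
  out <- array(lab, c(d[1], d[2], d[4]))
  if (d[4] == 1L) dim(out) <- c(d[1], d[2])
  out
}

#' @export
print.agrinet_model <- function(x, ...) {
  cat("Lightweight attention encoder-decoder segmentation network\n")
  print(x$config)
  cat("  trainable parameters:",
      format(n_module_params(x), big.mark = ","), "\n")
  invisible(x)
}
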