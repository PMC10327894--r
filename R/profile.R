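# Model-complexity accounting. Convolutions are scored as
#   parameters = K * K * Cin * Cout          (Cin / groups when grouped)
#   FLOPs      = K * K * Cin * Hout * Wout * Cout
# counting one multiply-accumulate per kernel tap, and linear layers as
# Cin * Cout. Bias and batch-norm parameters are outside this convention and
# are itemized separately; pooling, activations and elementwise operations
# contribute no FLOPs. GFLOPs is the FLOP total in units of 1e9.

# Symbolic trace of the architecture: one row per learnable layer, with the
# output spatial size obtained by propagating the input size through the
# network's strides and upsamplings. Must stay in lockstep with
# agrinet_model(); a cross-check against the built model's weight tally is
# part of the test suite.
agrinet_layer_specs <- function(cfg, input_hw = c(512L, 512L)) {
  H <- input_hw[1]; W <- input_hw[2]
  if (H %% 16L != 0L || W %% 16L != 0L)
    stop("input height/width must be divisible by 16")
  rows <- list()
  conv <- function(name, k, cin, cout, hw, groups = 1L, bias = FALSE,
                   kind = "conv", passes = 1L) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, kind = kind, k = k, cin = cin, cout = cout,
      groups = groups, hout = hw[1], wout = hw[2], passes = passes,
      params = k * k * (cin / groups) * cout,
      extra_params = if (bias) cout else 0,
      flops = k * k * (cin / groups) * hw[1] * hw[2] * cout * passes)
  }
  bn <- function(name, c) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, kind = "bn", k = 0L, cin = c, cout = c, groups = 1L,
      hout = NA_integer_, wout = NA_integer_, passes = 1L,
      params = 0, extra_params = 2 * c, flops = 0)
  }
  cbr <- function(name, k, cin, cout, hw, groups = 1L) {
    conv(name, k, cin, cout, hw, groups); bn(paste0(name, ".bn"), cout)
  }
  soc <- cfg$stage_out_channels
  s2 <- c(H, W) / 2L; s4 <- c(H, W) / 4L; s8 <- c(H, W) / 8L
  s16 <- c(H, W) / 16L
  cbr("stem", 3L, cfg$in_channels, soc[1], s2)
  stage <- function(tag, cin, cout, repeats, hw_in, hw_out) {
    h <- cout %/% 2L
    cbr(paste0(tag, ".down.b1.dw"), 3L, cin, cin, hw_out, groups = cin)
    cbr(paste0(tag, ".down.b1.pw"), 1L, cin, h, hw_out)
    cbr(paste0(tag, ".down.b2.pw1"), 1L, cin, h, hw_in)
    cbr(paste0(tag, ".down.b2.dw"), 3L, h, h, hw_out, groups = h)
    cbr(paste0(tag, ".down.b2.pw2"), 1L, h, h, hw_out)
    for (u in seq_len(repeats - 1L)) {
      cbr(sprintf("%s.basic%d.pw1", tag, u), 1L, h, h, hw_out)
      cbr(sprintf("%s.basic%d.dw", tag, u), 3L, h, h, hw_out, groups = h)
      cbr(sprintf("%s.basic%d.pw2", tag, u), 1L, h, h, hw_out)
    }
  }
  stage("stage2", soc[1], soc[2], cfg$stage_repeats[1], s4, s8)
  stage("stage3", soc[2], soc[3], cfg$stage_repeats[2], s8, s16)
  ao <- cfg$aspp_out_channels
  cbr("aspp.b0", 1L, soc[3], ao, s16)
  for (d in cfg$aspp_dilations)
    cbr(sprintf("aspp.atrous_d%d", d), 3L, soc[3], ao, s16)
  cbr("aspp.pool", 1L, soc[3], ao, c(1L, 1L))
  cbr("aspp.proj", 1L, (2L + length(cfg$aspp_dilations)) * ao, ao, s16)
  if (cfg$use_cbam) {
    r <- max(1L, ao %/% cfg$cbam_reduction)
    conv("cbam.cam.fc1", 1L, ao, r, c(1L, 1L), kind = "linear", passes = 2L)
    conv("cbam.cam.fc2", 1L, r, ao, c(1L, 1L), kind = "linear", passes = 2L)
    conv("cbam.sam.conv", cfg$cbam_spatial_kernel, 2L, 1L, s4, bias = TRUE)
  }
  cbr("skip.mid", 1L, soc[1], cfg$skip_reduce_channels_mid, s4)
  cbr("skip.low", 1L, soc[1], cfg$skip_reduce_channels_low, s2)
  w <- cfg$decoder_refine_channels
  cbr("refine1", 3L, ao + cfg$skip_reduce_channels_mid, w[1], s4)
  cbr("refine2", 3L, w[1] + cfg$skip_reduce_channels_low, w[2], s2)
  conv("head.tconv", 4L, w[2], cfg$num_classes, c(H, W), bias = TRUE,
       kind = "tconv")
  do.call(rbind, rows)
}

resolve_config <- function(x) {
  if (inherits(x, "agrinet_model")) x$config
  else if (inherits(x, "agrinet_config")) x
  else stop("expected an agrinet_model or agrinet_config")
}

#' Profile network complexity
#'
#' Produces the per-layer and total parameter and FLOP accounting of the
#' network at a given input size, from a symbolic trace of the forward pass
#' (no weights are touched, so profiling is instant).
#'
#' @param x An `agrinet_model` or `agrinet_config`.
#' @param input_hw Input spatial size (scalar or length-2, divisible by 16).
#' @param name Label used in comparison tables.
#' @return An object of class `complexity_report`: per-layer data frame plus
#'   totals (`params`, `params_m`, `flops`, `gflops`, and the itemized
#'   bias/batch-norm parameter count `extra_params`).
#' @export
complexity_profile <- function(x, input_hw = 512L, name = NULL) {
  cfg <- resolve_config(x)
  if (length(input_hw) == 1L) input_hw <- c(input_hw, input_hw)
  layers <- agrinet_layer_specs(cfg, as.integer(input_hw))
  out <- list(name = name %||% if (cfg$use_cbam) "full" else "no-cbam",
              config = cfg, input_hw = as.integer(input_hw), layers = layers,
              params = sum(layers$params),
              params_m = round(sum(layers$params) / 1e6, 2),
              extra_params = sum(layers$extra_params),
              flops = sum(layers$flops),
              gflops = sum(layers$flops) / 1e9)
  class(out) <- "complexity_report"
  out
}

#' Count network parameters
#'
#' Per-convolution `K * K * Cin/groups * Cout` (linear layers `Cin * Cout`),
#' summed over all learnable layers; biases and normalization parameters are
#' itemized separately in the returned report's `extra_params`.
#'
#' @param x An `agrinet_model` or `agrinet_config`.
#' @param include_extras Add the itemized bias/batch-norm terms to the total
#'   (reconciles with a direct tally of every weight array in the model).
#' @return Total parameter count.
#' @export
count_params <- function(x, include_extras = FALSE) {
  r <- complexity_profile(x)
  r$params + if (include_extras) r$extra_params else 0
}

#' Count network FLOPs
#'
#' Per-convolution `K * K * Cin/groups * Hout * Wout * Cout` (one
#' multiply-accumulate per tap), summed over a symbolic forward trace at the
#' given input size. Pooling, activations, normalization and elementwise
#' operations are excluded.
#'
#' @param x An `agrinet_model` or `agrinet_config`.
#' @param input_hw Input spatial size (divisible by 16).
#' @return Total FLOP count (`/1e9` for GFLOPs).
#' @export
count_flops <- function(x, input_hw = 512L) {
  complexity_profile(x, input_hw)$flops
}

#' Tabulate several complexity reports
#'
#' @param reports List of [complexity_profile()] reports (e.g. the full
#'   network and the attention-ablated one).
#' @return Data frame with name, parameters (M) and GFLOPs per report.
#' @export
compare_configs <- function(reports) {
  if (length(reports) == 0L) stop("no reports to compare")
  if (inherits(reports, "complexity_report")) reports <- list(reports)
  do.call(rbind, lapply(reports, function(r) data.frame(
    name = r$name, params_m = r$params_m, gflops = round(r$gflops, 2),
    input = paste(r$input_hw, collapse = "x"))))
}

#' @export
print.complexity_report <- function(x, ...) {
  cat(sprintf("Complexity report (%s, input %dx%d)\n", x$name,
              x$input_hw[1], x$input_hw[2]))
  cat(sprintf("  parameters: %s (%.2f M), + %s itemized bias/BN\n",
              format(x$params, big.mark = ","), x$params_m,
              format(x$extra_params, big.mark = ",")))
  cat(sprintf("  FLOPs: %s (%.2f GFLOPs)\n",
              format(x$flops, big.mark = ",", scientific = FALSE),
              x$gflops))
  conv <- x$layers[x$layers$kind != "bn", ]
  top <- utils::head(conv[order(-conv$flops), ], 5)
  cat("  heaviest layers (FLOPs):\n")
  for (i in seq_len(nrow(top)))
    cat(sprintf("    %-22s %8.3f G\n", top$name[i], top$flops[i] / 1e9))
  invisible(x)
}
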