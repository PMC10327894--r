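# Independent oracles and small builders shared across tests.

# Literal convolution: nested loops over output pixels, kernel taps and
# channels. Slow but unmistakably correct; also counts multiplications when
# asked, serving as the FLOP oracle.
naive_conv <- function(x, w, stride = 1, pad = 0, dilation = 1,
                       count_mults = FALSE) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  k <- dim(w)[1]; cin_g <- dim(w)[3]; cout <- dim(w)[4]
  depthwise <- cin_g == 1 && cout == C
  xp <- array(0, c(H + 2 * pad, W + 2 * pad, C))
  xp[pad + seq_len(H), pad + seq_len(W), ] <- x
  keff <- (k - 1) * dilation + 1
  Ho <- (H + 2 * pad - keff) %/% stride + 1
  Wo <- (W + 2 * pad - keff) %/% stride + 1
  y <- array(0, c(Ho, Wo, cout))
  mults <- 0
  for (oi in seq_len(Ho)) for (oj in seq_len(Wo)) for (oc in seq_len(cout)) {
    acc <- 0
    chans <- if (depthwise) oc else seq_len(C)
    for (i in seq_len(k)) for (j in seq_len(k)) for (c in chans) {
      wi <- if (depthwise) 1 else c
      acc <- acc + xp[(oi - 1) * stride + (i - 1) * dilation + 1,
                      (oj - 1) * stride + (j - 1) * dilation + 1, c] *
        w[i, j, wi, oc]
      mults <- mults + 1
    }
    y[oi, oj, oc] <- acc
  }
  if (count_mults) list(y = y, mults = mults) else y
}

# Hand-rolled softmax negative log-likelihood over pixels (loss oracle).
naive_softmax_nll <- function(scores, target) {
  d <- dim(scores)
  total <- 0; n <- 0
  nb <- if (length(d) == 4) d[4] else 1
  for (bi in seq_len(nb)) for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    v <- if (length(d) == 4) scores[i, j, , bi] else scores[i, j, ]
    p <- exp(v - max(v)); p <- p / sum(p)
    tv <- if (length(dim(target)) == 3) target[i, j, bi] else target[i, j]
    total <- total - log(p[tv + 1])
    n <- n + 1
  }
  total / n
}

# Brute-force segmentation metrics by explicit per-class set operations.
naive_metrics <- function(pred, truth, n_classes) {
  ious <- recs <- numeric(0)
  for (k in 0:(n_classes - 1)) {
    P <- which(pred == k); G <- which(truth == k)
    if (length(P) == 0 && length(G) == 0) next
    ious <- c(ious, length(intersect(P, G)) / length(union(P, G)))
    if (length(G) > 0)
      recs <- c(recs, length(intersect(P, G)) / length(G))
  }
  list(miou = mean(ious), oa = mean(pred == truth), recall = mean(recs))
}

# Directional finite-difference check of a module's parameter gradients.
# Returns the worst relative error over `nslots` randomly chosen slots.
dir_gradcheck <- function(layer, x, eps = 1e-4, nslots = Inf) {
  y <- layer$forward(x, training = TRUE)
  ws <- array(stats::rnorm(length(y)), dim(y))
  layer$forward(x, training = TRUE)
  layer$backward(ws)
  slots <- agrinet:::module_param_slots(layer)
  if (length(slots) > nslots) slots <- sample(slots, nslots)
  worst <- 0
  for (s in slots) {
    w <- get(s$name, envir = s$env)
    ga <- s$env$g[[s$name]]
    v <- array(stats::rnorm(length(w)), dim(w) %||% length(w))
    v <- v / sqrt(sum(v^2))
    assign(s$name, w + eps * v, envir = s$env)
    fp <- sum(layer$forward(x, training = TRUE) * ws)
    assign(s$name, w - eps * v, envir = s$env)
    fm <- sum(layer$forward(x, training = TRUE) * ws)
    assign(s$name, w, envir = s$env)
    worst <- max(worst, abs((fp - fm) / (2 * eps) - sum(ga * v)) /
                   max(1e-6, abs(sum(ga * v))))
  }
  worst
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A deliberately tiny network configuration for fast structural tests.
tiny_config <- function(...) {
  network_config(stage_out_channels = c(8L, 16L, 32L),
                 stage_repeats = c(2L, 2L),
                 aspp_dilations = c(1L, 2L), aspp_out_channels = 16L,
                 cbam_reduction = 4L,
                 skip_reduce_channels_low = 8L, skip_reduce_channels_mid = 8L,
                 decoder_refine_channels = c(16L, 8L), ...)
}

# A 13-band synthetic raw scene (10 m grid) around a generated labelled scene:
# the 10 retained bands carry the scene, B1/B9/B10 carry junk.
raw13_from_scene <- function(scene_stack) {
  ids <- names(agrinet:::SENTINEL2_BANDS)
  bands <- lapply(ids, function(b) {
    if (b %in% agrinet:::RETAINED_BANDS) scene_stack$bands[[b]]
    else matrix(7, nrow(scene_stack$bands[[1]]), ncol(scene_stack$bands[[1]]))
  })
  band_stack(bands, ids, resolution_m = 10)
}
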