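# Atrous spatial pyramid pooling: parallel 1x1 convolution, 3x3 atrous
# convolutions at several dilation rates (padding = dilation keeps the spatial
# size), and a global-pooling branch, concatenated and projected back to
# `cout` channels by a 1x1 convolution. Captures multi-scale context at the
# deepest encoder scale without further downsampling.

nn_aspp <- function(cin, dilations = c(6L, 12L, 18L), cout = 256L) {
  self <- nn_module("aspp")
  self$b0 <- nn_cbr(cin, cout, 1L)
  self$atrous <- lapply(dilations, function(d)
    nn_cbr(cin, cout, 3L, pad = d, dilation = d))
  self$bpool <- nn_cbr(cin, cout, 1L)
  nb <- 2L + length(dilations)
  self$proj <- nn_cbr(nb * cout, cout, 1L)
  self$children <- c(list(self$b0), self$atrous, list(self$bpool, self$proj))
  self$cout <- cout
  self$forward <- function(x, training = TRUE) {
    d <- dim(x); hw <- d[1] * d[2]
    outs <- c(list(self$b0$forward(x, training)),
              lapply(self$atrous, function(br) br$forward(x, training)))
    # global average pool -> 1x1 conv block -> broadcast back to (H, W)
    gp <- array(colMeans(matrix(x, hw, d[3] * d[4])), c(1L, 1L, d[3], d[4]))
    pb <- self$bpool$forward(gp, training)
    pbu <- pb[rep(1L, d[1]), rep(1L, d[2]), , , drop = FALSE]
    outs <- c(outs, list(pbu))
    co <- self$cout
    y <- array(0, c(d[1], d[2], length(outs) * co, d[4]))
    for (i in seq_along(outs)) y[, , (i - 1L) * co + seq_len(co), ] <- outs[[i]]
    self$in_dim <- d
    self$proj$forward(y, training)
  }
  self$backward <- function(dy) {
    d <- self$in_dim; hw <- d[1] * d[2]; co <- self$cout
    dcat <- self$proj$backward(dy)
    dx <- self$b0$backward(dcat[, , seq_len(co), , drop = FALSE])
    for (i in seq_along(self$atrous))
      dx <- dx + self$atrous[[i]]$backward(
        dcat[, , i * co + seq_len(co), , drop = FALSE])
    dpbu <- dcat[, , (length(self$atrous) + 1L) * co + seq_len(co), ,
                 drop = FALSE]
    # broadcast backward: sum over pixels, then mean-pool backward
    dpb <- array(colSums(matrix(dpbu, hw, co * d[4])), c(1L, 1L, co, d[4]))
    dgp <- self$bpool$backward(dpb) / hw
    dx + dgp[rep(1L, d[1]), rep(1L, d[2]), , , drop = FALSE]
  }
  self
}
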