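# Convolutional block attention (CBAM): a channel-attention gate followed in
# series by a spatial-attention gate, each sigmoid-bounded and applied
# multiplicatively, so attention can only re-weight features, never amplify
# them beyond their input magnitude.

# Channel attention map: sigmoid(MLP(AvgPool(F)) + MLP(MaxPool(F))) where the
# global average- and max-pooled channel vectors pass through the SAME shared
# two-layer MLP (C -> C/r -> C, ReLU in between, no biases).
# F: (H,W,C,N); w1: (C x C/r); w2: (C/r x C). Returns an N x C matrix in (0,1).
cam_map <- function(f, w1, w2) {
  f <- as_hwcn(f)
  d <- dim(f); hw <- d[1] * d[2]; C <- d[3]; N <- d[4]
  m <- matrix(f, hw, C * N)
  av <- t(matrix(colMeans(m), C, N))
  mi <- max.col(t(m), ties.method = "first")
  mx <- t(matrix(m[cbind(mi, seq_len(C * N))], C, N))
  o_a <- pmax(av %*% w1, 0) %*% w2
  o_m <- pmax(mx %*% w1, 0) %*% w2
  1 / (1 + exp(-(o_a + o_m)))
}

# Spatial attention map: sigmoid(conv7x7([AvgPool_c(F); MaxPool_c(F)])) where
# pooling is across channels, producing a 2-channel map convolved to 1
# channel (padding 3). Returns an (H,W,1,N) array in (0,1).
sam_map <- function(f, w, b = 0) {
  f <- as_hwcn(f)
  d <- dim(f); hw <- d[1] * d[2]; C <- d[3]; N <- d[4]
  mt <- matrix(aperm(f, c(1L, 2L, 4L, 3L)), hw * N, C)
  cat2 <- array(0, c(d[1], d[2], 2L, N))
  cat2[, , 1L, ] <- array(rowMeans(mt), c(d[1], d[2], N))
  mi <- max.col(mt, ties.method = "first")
  cat2[, , 2L, ] <- array(mt[cbind(seq_len(hw * N), mi)], c(d[1], d[2], N))
  s <- conv_fw(cat2, w, b, stride = 1L, pad = (dim(w)[1] - 1L) %/% 2L,
               keep_cache = FALSE)$y
  1 / (1 + exp(-s))
}

nn_cam <- function(C, reduction = 16L) {
  if (reduction >= C)
    stop("channel-attention reduction (", reduction,
         ") must be smaller than the channel count (", C, ")")
  self <- nn_module("cam")
  r <- max(1L, C %/% reduction)
  self$w1 <- matrix(stats::rnorm(C * r, sd = sqrt(2 / C)), C, r)
  self$w2 <- matrix(stats::rnorm(r * C, sd = sqrt(2 / r)), r, C)
  self$param_names <- c("w1", "w2")
  self$forward <- function(x, training = TRUE) {
    d <- dim(x); hw <- d[1] * d[2]; C <- d[3]; N <- d[4]
    m <- matrix(x, hw, C * N)
    av <- t(matrix(colMeans(m), C, N))            # N x C
    mi <- max.col(t(m), ties.method = "first")    # argmax pixel per (c,n)
    mx <- t(matrix(m[cbind(mi, seq_len(C * N))], C, N))
    ha <- pmax(av %*% self$w1, 0)
    hm <- pmax(mx %*% self$w1, 0)
    s <- ha %*% self$w2 + hm %*% self$w2
    gmap <- 1 / (1 + exp(-s))                     # N x C in (0,1)
    ga <- array(rep(as.vector(t(gmap)), each = hw), d)
    y <- x * ga
    self$last_map <- gmap
    if (training)
      self$cache <- list(x = x, ga = ga, gmap = gmap, mi = mi,
                         av = av, mx = mx, ha = ha, hm = hm, d = d)
    y
  }
  self$backward <- function(dy) {
    ca <- self$cache; self$cache <- NULL
    d <- ca$d; hw <- d[1] * d[2]; C <- d[3]; N <- d[4]
    dx <- dy * ca$ga
    dgv <- t(matrix(colSums(matrix(dy * ca$x, hw, C * N)), C, N)) # N x C
    ds <- dgv * ca$gmap * (1 - ca$gmap)
    self$g$w2 <- crossprod(ca$ha, ds) + crossprod(ca$hm, ds)
    dha <- tcrossprod(ds, self$w2) * (ca$ha > 0)
    dhm <- tcrossprod(ds, self$w2) * (ca$hm > 0)
    self$g$w1 <- crossprod(ca$av, dha) + crossprod(ca$mx, dhm)
    dav <- tcrossprod(dha, self$w1)  # N x C
    dmx <- tcrossprod(dhm, self$w1)
    dx <- dx + array(rep(as.vector(t(dav)) / hw, each = hw), d)
    dm <- matrix(0, hw, C * N)
    dm[cbind(ca$mi, seq_len(C * N))] <- as.vector(t(dmx))
    dx + array(dm, d)
  }
  self
}

nn_sam <- function(kernel = 7L) {
  self <- nn_module("sam")
  self$conv <- nn_conv(2L, 1L, kernel, pad = (kernel - 1L) %/% 2L, bias = TRUE)
  self$children <- list(self$conv)
  self$forward <- function(x, training = TRUE) {
    d <- dim(x); hw <- d[1] * d[2]; C <- d[3]; N <- d[4]
    mt <- matrix(aperm(x, c(1L, 2L, 4L, 3L)), hw * N, C)
    cat2 <- array(0, c(d[1], d[2], 2L, N))
    cat2[, , 1L, ] <- array(rowMeans(mt), c(d[1], d[2], N))
    mi <- max.col(mt, ties.method = "first")
    cat2[, , 2L, ] <- array(mt[cbind(seq_len(hw * N), mi)], c(d[1], d[2], N))
    s <- self$conv$forward(cat2, training)
    gmap <- 1 / (1 + exp(-s))                     # (H,W,1,N)
    y <- x * gmap[, , rep(1L, C), , drop = FALSE]
    self$last_map <- gmap
    if (training) self$cache <- list(x = x, gmap = gmap, mi = mi, d = d)
    y
  }
  self$backward <- function(dy) {
    ca <- self$cache; self$cache <- NULL
    d <- ca$d; hw <- d[1] * d[2]; C <- d[3]; N <- d[4]
    dx <- dy * ca$gmap[, , rep(1L, C), , drop = FALSE]
    dg <- rowSums(matrix(aperm(dy * ca$x, c(1L, 2L, 4L, 3L)), hw * N, C))
    g <- ca$gmap
    ds <- array(dg, dim(g)) * g * (1 - g)
    dcat <- self$conv$backward(ds)
    dmu <- dcat[, , 1L, , drop = FALSE] / C
    dx <- dx + dmu[, , rep(1L, C), , drop = FALSE]
    dmx <- as.vector(dcat[, , 2L, ])
    dm <- matrix(0, hw * N, C)
    dm[cbind(seq_len(hw * N), ca$mi)] <- dmx
    dx + aperm(array(dm, c(d[1], d[2], N, C)), c(1L, 2L, 4L, 3L))
  }
  self
}

# CBAM: channel attention then spatial attention in series; the CAM output is
# the SAM input. Shape-preserving.
nn_cbam <- function(C, reduction = 16L, spatial_kernel = 7L) {
  self <- nn_module("cbam")
  self$cam <- nn_cam(C, reduction)
  self$sam <- nn_sam(spatial_kernel)
  self$children <- list(self$cam, self$sam)
  self$forward <- function(x, training = TRUE)
    self$sam$forward(self$cam$forward(x, training), training)
  self$backward <- function(dy) self$cam$backward(self$sam$backward(dy))
  self
}
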