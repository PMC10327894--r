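# Neural-network primitives on (H, W, C, N) arrays.
#
# All heavy arithmetic is expressed as BLAS matrix products: a K x K
# convolution is computed as K^2 shifted (Hout*Wout*N, Cin) x (Cin, Cout)
# products ("shift-and-matmul"), which keeps peak memory at the size of one
# shifted activation rather than a full im2col buffer. Depthwise convolutions
# take an elementwise broadcast path. Every primitive has an exact analytic
# backward used by the training engine; forwards run cache-free in inference
# mode.

conv_out_len <- function(n, k, stride, pad, dilation) {
  keff <- (k - 1L) * dilation + 1L
  out <- (n + 2L * pad - keff) %/% stride + 1L
  if (out < 1L) stop("convolution output would be empty (input ", n,
                     ", kernel ", k, ", stride ", stride, ")")
  out
}

# Functional convolution forward.
# x: (H,W,C,N); w: (k,k,Cin/groups,Cout). groups must be 1 or Cin (depthwise).
conv_fw <- function(x, w, b = NULL, stride = 1L, pad = 0L, dilation = 1L,
                    groups = 1L, keep_cache = TRUE) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  k <- dim(w)[1]; cing <- dim(w)[3]; cout <- dim(w)[4]
  if (!(groups == 1L || groups == C))
    stop("only groups = 1 or depthwise (groups = Cin) convolutions supported")
  if (C != cing * groups)
    stop("input has ", C, " channels but weights expect ", cing * groups)
  Ho <- conv_out_len(H, k, stride, pad, dilation)
  Wo <- conv_out_len(W, k, stride, pad, dilation)
  xp <- pad_hw(x, pad)
  depthwise <- groups == C && C > 1L
  if (depthwise) {
    y <- array(0, c(Ho, Wo, cout, N))
    hw <- Ho * Wo
    for (i in seq_len(k)) for (j in seq_len(k)) {
      ri <- (i - 1L) * dilation + 1L + (seq_len(Ho) - 1L) * stride
      ci <- (j - 1L) * dilation + 1L + (seq_len(Wo) - 1L) * stride
      xs <- xp[ri, ci, , , drop = FALSE]
      y <- y + xs * rep(w[i, j, 1L, ], each = hw)
    }
  } else {
    acc <- matrix(0, Ho * Wo * N, cout)
    for (i in seq_len(k)) for (j in seq_len(k)) {
      ri <- (i - 1L) * dilation + 1L + (seq_len(Ho) - 1L) * stride
      ci <- (j - 1L) * dilation + 1L + (seq_len(Wo) - 1L) * stride
      xs <- xp[ri, ci, , , drop = FALSE]
      # for N = 1 the (H,W,C,1) layout is already (Hout*Wout, C) column-major
      xf <- if (N == 1L) matrix(xs, Ho * Wo, C)
      else matrix(aperm(xs, c(1L, 2L, 4L, 3L)), Ho * Wo * N, C)
      acc <- acc + xf %*% matrix(w[i, j, , ], nrow = C)
    }
    y <- if (N == 1L) array(acc, c(Ho, Wo, cout, 1L))
    else aperm(array(acc, c(Ho, Wo, N, cout)), c(1L, 2L, 4L, 3L))
  }
  if (!is.null(b)) y <- y + rep(b, each = Ho * Wo)
  cache <- if (keep_cache) {
    list(xp = xp, in_dim = d, stride = stride, pad = pad, dilation = dilation,
         groups = groups, depthwise = depthwise, k = k, out_hw = c(Ho, Wo),
         has_bias = !is.null(b))
  }
  list(y = y, cache = cache)
}

conv_bw <- function(cache, dy, w) {
  xp <- cache$xp; d <- cache$in_dim
  k <- cache$k; stride <- cache$stride; dilation <- cache$dilation
  Ho <- cache$out_hw[1]; Wo <- cache$out_hw[2]
  C <- d[3]; N <- d[4]; cout <- dim(w)[4]
  hw <- Ho * Wo
  dxp <- array(0, dim(xp))
  gw <- array(0, dim(w))
  if (cache$depthwise) {
    for (i in seq_len(k)) for (j in seq_len(k)) {
      ri <- (i - 1L) * dilation + 1L + (seq_len(Ho) - 1L) * stride
      ci <- (j - 1L) * dilation + 1L + (seq_len(Wo) - 1L) * stride
      xs <- xp[ri, ci, , , drop = FALSE]
      prod <- xs * dy
      gw[i, j, 1L, ] <- rowSums(matrix(colSums(matrix(prod, hw, C * N)), C, N))
      dxs <- dy * rep(w[i, j, 1L, ], each = hw)
      dxp[ri, ci, , ] <- dxp[ri, ci, , , drop = FALSE] + dxs
    }
  } else {
    dyf <- if (N == 1L) matrix(dy, hw, cout)
    else matrix(aperm(dy, c(1L, 2L, 4L, 3L)), hw * N, cout)
    for (i in seq_len(k)) for (j in seq_len(k)) {
      ri <- (i - 1L) * dilation + 1L + (seq_len(Ho) - 1L) * stride
      ci <- (j - 1L) * dilation + 1L + (seq_len(Wo) - 1L) * stride
      xs <- xp[ri, ci, , , drop = FALSE]
      xf <- if (N == 1L) matrix(xs, hw, C)
      else matrix(aperm(xs, c(1L, 2L, 4L, 3L)), hw * N, C)
      gw[i, j, , ] <- crossprod(xf, dyf)
      dxf <- tcrossprod(dyf, matrix(w[i, j, , ], nrow = C))
      dxs <- if (N == 1L) array(dxf, c(Ho, Wo, C, 1L))
      else aperm(array(dxf, c(Ho, Wo, N, C)), c(1L, 2L, 4L, 3L))
      dxp[ri, ci, , ] <- dxp[ri, ci, , , drop = FALSE] + dxs
    }
  }
  p <- cache$pad
  dx <- if (p > 0L) {
    dxp[(p + 1L):(p + d[1]), (p + 1L):(p + d[2]), , , drop = FALSE]
  } else dxp
  gb <- if (cache$has_bias) colSums(matrix(aperm(dy, c(1L, 2L, 4L, 3L)),
                                           hw * N, cout)) else NULL
  list(dx = dx, gw = gw, gb = gb)
}

# ---- module objects ---------------------------------------------------------

nn_module <- function(type) {
  self <- new.env(parent = emptyenv())
  self$type <- type
  self$param_names <- character()
  self$children <- list()
  self$g <- list()
  class(self) <- "nn_module"
  self
}

#' @export
print.nn_module <- function(x, ...) {
  cat("<nn_module:", x$type, "> parameters:",
      format(n_module_params(x), big.mark = ","), "\n")
  invisible(x)
}

# Flat list of parameter slots (environment + name) over the module tree.
module_param_slots <- function(mod) {
  out <- lapply(mod$param_names, function(nm) list(env = mod, name = nm))
  for (ch in mod$children) out <- c(out, module_param_slots(ch))
  out
}

n_module_params <- function(mod) {
  sum(vapply(module_param_slots(mod),
             function(s) length(get(s$name, envir = s$env)), numeric(1)))
}

# Extract / restore all weights as a plain named list (checkpointing).
module_state <- function(mod, prefix = "") {
  nm <- paste0(prefix, mod$type)
  out <- list()
  for (p in mod$param_names)
    out[[paste0(nm, ".", p, ".", length(out))]] <- get(p, envir = mod)
  for (b in c("rmean", "rvar")) if (!is.null(mod[[b]]))
    out[[paste0(nm, ".", b, ".", length(out))]] <- mod[[b]]
  for (i in seq_along(mod$children))
    out <- c(out, module_state(mod$children[[i]], paste0(nm, ".", i, "/")))
  out
}

module_load_state <- function(mod, state, pos = 1L) {
  take <- function() { v <- state[[pos]]; pos <<- pos + 1L; v }
  for (p in mod$param_names) assign(p, take(), envir = mod)
  for (b in c("rmean", "rvar")) if (!is.null(mod[[b]])) mod[[b]] <- take()
  for (ch in mod$children) pos <- module_load_state(ch, state, pos)
  pos
}

nn_conv <- function(cin, cout, k, stride = 1L, pad = 0L, dilation = 1L,
                    groups = 1L, bias = FALSE) {
  self <- nn_module(sprintf("conv%dx%d", k, k))
  cing <- cin / groups
  stopifnot(cing == as.integer(cing))
  sd <- sqrt(2 / (k * k * cing))
  self$w <- array(stats::rnorm(k * k * cing * cout, sd = sd),
                  c(k, k, cing, cout))
  if (bias) self$b <- numeric(cout)
  self$param_names <- c("w", if (bias) "b")
  self$meta <- list(cin = cin, cout = cout, k = k, stride = stride, pad = pad,
                    dilation = dilation, groups = groups, bias = bias)
  self$forward <- function(x, training = TRUE) {
    m <- self$meta
    if (dim(x)[3] != m$cin)
      stop("expected ", m$cin, " input channels, got ", dim(x)[3])
    res <- conv_fw(x, self$w, if (m$bias) self$b, m$stride, m$pad, m$dilation,
                   m$groups, keep_cache = training)
    self$cache <- res$cache
    res$y
  }
  self$backward <- function(dy) {
    cb <- conv_bw(self$cache, dy, self$w)
    self$g$w <- cb$gw
    if (self$meta$bias) self$g$b <- cb$gb
    self$cache <- NULL
    cb$dx
  }
  self
}

nn_bn <- function(c, momentum = 0.1, eps = 1e-5) {
  self <- nn_module("bn")
  self$gamma <- rep(1, c); self$beta <- numeric(c)
  self$rmean <- numeric(c); self$rvar <- rep(1, c)
  self$param_names <- c("gamma", "beta")
  self$momentum <- momentum; self$eps <- eps; self$c <- c
  self$forward <- function(x, training = TRUE) {
    d <- dim(x); hw <- d[1] * d[2]; C <- d[3]; N <- d[4]
    m <- matrix(aperm(x, c(1L, 2L, 4L, 3L)), hw * N, C)
    if (training) {
      mu <- colMeans(m)
      v <- colMeans(m * m) - mu * mu
      v <- pmax(v, 0)
      istd <- 1 / sqrt(v + self$eps)
      xhat <- (m - rep(mu, each = hw * N)) * rep(istd, each = hw * N)
      self$rmean <- (1 - self$momentum) * self$rmean + self$momentum * mu
      self$rvar <- (1 - self$momentum) * self$rvar + self$momentum * v
      self$cache <- list(xhat = xhat, istd = istd, d = d)
    } else {
      istd <- 1 / sqrt(self$rvar + self$eps)
      xhat <- (m - rep(self$rmean, each = hw * N)) * rep(istd, each = hw * N)
    }
    ym <- xhat * rep(self$gamma, each = hw * N) + rep(self$beta, each = hw * N)
    aperm(array(ym, c(d[1], d[2], N, C)), c(1L, 2L, 4L, 3L))
  }
  self$backward <- function(dy) {
    ca <- self$cache; d <- ca$d; hw <- d[1] * d[2]; C <- d[3]; N <- d[4]
    M <- hw * N
    dyf <- matrix(aperm(dy, c(1L, 2L, 4L, 3L)), M, C)
    xhat <- ca$xhat
    self$g$gamma <- colSums(dyf * xhat)
    self$g$beta <- colSums(dyf)
    dxh <- dyf * rep(self$gamma, each = M)
    s1 <- colSums(dxh); s2 <- colSums(dxh * xhat)
    dxm <- (dxh - rep(s1 / M, each = M) - xhat * rep(s2 / M, each = M)) *
      rep(ca$istd, each = M)
    self$cache <- NULL
    aperm(array(dxm, c(d[1], d[2], N, C)), c(1L, 2L, 4L, 3L))
  }
  self
}

nn_relu <- function() {
  self <- nn_module("relu")
  self$forward <- function(x, training = TRUE) {
    y <- pmax(x, 0)
    if (training) self$cache <- x > 0
    y
  }
  self$backward <- function(dy) {
    dx <- dy * self$cache
    self$cache <- NULL
    dx
  }
  self
}

nn_sigmoid <- function() {
  self <- nn_module("sigmoid")
  self$forward <- function(x, training = TRUE) {
    y <- 1 / (1 + exp(-x))
    if (training) self$cache <- y
    y
  }
  self$backward <- function(dy) {
    y <- self$cache; self$cache <- NULL
    dy * y * (1 - y)
  }
  self
}

nn_maxpool <- function(k = 3L, stride = 2L, pad = 1L) {
  self <- nn_module("maxpool")
  self$meta <- list(k = k, stride = stride, pad = pad)
  self$forward <- function(x, training = TRUE) {
    m <- self$meta; d <- dim(x)
    Ho <- conv_out_len(d[1], m$k, m$stride, m$pad, 1L)
    Wo <- conv_out_len(d[2], m$k, m$stride, m$pad, 1L)
    xp <- pad_hw(x, m$pad, value = -Inf)
    best <- array(-Inf, c(Ho, Wo, d[3], d[4]))
    arg <- array(0L, c(Ho, Wo, d[3], d[4]))
    t <- 0L
    for (i in seq_len(m$k)) for (j in seq_len(m$k)) {
      t <- t + 1L
      ri <- i + (seq_len(Ho) - 1L) * m$stride
      ci <- j + (seq_len(Wo) - 1L) * m$stride
      xs <- xp[ri, ci, , , drop = FALSE]
      upd <- xs > best
      best[upd] <- xs[upd]
      arg[upd] <- t
    }
    if (training) self$cache <- list(arg = arg, d = d, out = c(Ho, Wo))
    best
  }
  self$backward <- function(dy) {
    ca <- self$cache; self$cache <- NULL
    m <- self$meta; d <- ca$d
    Ho <- ca$out[1]; Wo <- ca$out[2]
    dxp <- array(0, c(d[1] + 2L * m$pad, d[2] + 2L * m$pad, d[3], d[4]))
    t <- 0L
    for (i in seq_len(m$k)) for (j in seq_len(m$k)) {
      t <- t + 1L
      ri <- i + (seq_len(Ho) - 1L) * m$stride
      ci <- j + (seq_len(Wo) - 1L) * m$stride
      dxp[ri, ci, , ] <- dxp[ri, ci, , , drop = FALSE] + dy * (ca$arg == t)
    }
    p <- m$pad
    if (p > 0L)
      dxp[(p + 1L):(p + d[1]), (p + 1L):(p + d[2]), , , drop = FALSE]
    else dxp
  }
  self
}

# Row-interpolation matrix for bilinear resizing with half-pixel-center
# alignment: output sample i (0-based) reads source coordinate
# (i + 0.5) * n_in / n_out - 0.5, clamped to the valid range.
interp_matrix <- function(n_out, n_in) {
  R <- matrix(0, n_out, n_in)
  src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  i0 <- pmin(pmax(floor(src), 0), n_in - 1)
  f <- pmin(pmax(src - i0, 0), 1)
  i1 <- pmin(i0 + 1, n_in - 1)
  R[cbind(seq_len(n_out), i0 + 1)] <- R[cbind(seq_len(n_out), i0 + 1)] + 1 - f
  R[cbind(seq_len(n_out), i1 + 1)] <- R[cbind(seq_len(n_out), i1 + 1)] + f
  R
}

# Separable bilinear resize of (H,W,C,N) to (nrow(Ry), nrow(Rx)).
resize_apply <- function(x, Ry, Rx) {
  d <- dim(x); Hi <- d[1]; Wi <- d[2]; C <- d[3]; N <- d[4]
  Ho <- nrow(Ry); Wo <- nrow(Rx)
  t1 <- Ry %*% matrix(x, Hi, Wi * C * N)
  a1 <- aperm(array(t1, c(Ho, Wi, C, N)), c(2L, 1L, 3L, 4L))
  t2 <- Rx %*% matrix(a1, Wi, Ho * C * N)
  aperm(array(t2, c(Wo, Ho, C, N)), c(2L, 1L, 3L, 4L))
}

bilinear_resize <- function(x, out_hw) {
  x <- as_hwcn(x)
  resize_apply(x, interp_matrix(out_hw[1], dim(x)[1]),
               interp_matrix(out_hw[2], dim(x)[2]))
}

nn_upsample <- function(scale) {
  self <- nn_module(sprintf("upsample%dx", scale))
  self$scale <- scale
  self$forward <- function(x, training = TRUE) {
    d <- dim(x)
    self$Ry <- interp_matrix(d[1] * self$scale, d[1])
    self$Rx <- interp_matrix(d[2] * self$scale, d[2])
    resize_apply(x, self$Ry, self$Rx)
  }
  self$backward <- function(dy) resize_apply(dy, t(self$Ry), t(self$Rx))
  self
}

# Transpose convolution implemented as zero-insertion followed by a stride-1
# convolution with the spatially flipped kernel (pad' = k - 1 - pad), so the
# forward/backward share the conv core. Output size (H-1)*stride - 2*pad + k.
nn_tconv <- function(cin, cout, k = 4L, stride = 2L, pad = 1L, bias = TRUE) {
  self <- nn_module("tconv")
  sd <- sqrt(2 / (k * k * cin))
  self$w <- array(stats::rnorm(k * k * cin * cout, sd = sd),
                  c(k, k, cin, cout))
  if (bias) self$b <- numeric(cout)
  self$param_names <- c("w", if (bias) "b")
  self$meta <- list(cin = cin, cout = cout, k = k, stride = stride, pad = pad,
                    bias = bias)
  zero_insert <- function(x, s) {
    d <- dim(x)
    z <- array(0, c(s * (d[1] - 1L) + 1L, s * (d[2] - 1L) + 1L, d[3], d[4]))
    z[seq(1L, by = s, length.out = d[1]),
      seq(1L, by = s, length.out = d[2]), , ] <- x
    z
  }
  flip_w <- function(w) w[rev(seq_len(dim(w)[1])), rev(seq_len(dim(w)[2])), , ,
                          drop = FALSE]
  self$forward <- function(x, training = TRUE) {
    m <- self$meta
    if (dim(x)[3] != m$cin)
      stop("expected ", m$cin, " input channels, got ", dim(x)[3])
    self$in_dim <- dim(x)
    z <- zero_insert(x, m$stride)
    res <- conv_fw(z, flip_w(self$w), if (m$bias) self$b,
                   stride = 1L, pad = m$k - 1L - m$pad, keep_cache = training)
    self$cache <- res$cache
    res$y
  }
  self$backward <- function(dy) {
    m <- self$meta
    cb <- conv_bw(self$cache, dy, flip_w(self$w))
    self$cache <- NULL
    self$g$w <- flip_w(cb$gw)
    if (m$bias) self$g$b <- cb$gb
    d <- self$in_dim
    cb$dx[seq(1L, by = m$stride, length.out = d[1]),
          seq(1L, by = m$stride, length.out = d[2]), , , drop = FALSE]
  }
  self
}

nn_linear <- function(cin, cout, bias = FALSE) {
  self <- nn_module("linear")
  self$w <- matrix(stats::rnorm(cin * cout, sd = sqrt(2 / cin)), cin, cout)
  if (bias) self$b <- numeric(cout)
  self$param_names <- c("w", if (bias) "b")
  self$bias <- bias
  self$forward <- function(x, training = TRUE) {
    if (training) self$cache <- x
    y <- x %*% self$w
    if (self$bias) y <- sweep(y, 2L, self$b, "+")
    y
  }
  self$backward <- function(dy) {
    self$g$w <- crossprod(self$cache, dy)
    if (self$bias) self$g$b <- colSums(dy)
    dx <- tcrossprod(dy, self$w)
    self$cache <- NULL
    dx
  }
  self
}

nn_sequential <- function(...) {
  self <- nn_module("sequential")
  self$children <- list(...)
  self$forward <- function(x, training = TRUE) {
    for (ch in self$children) x <- ch$forward(x, training)
    x
  }
  self$backward <- function(dy) {
    for (ch in rev(self$children)) dy <- ch$backward(dy)
    dy
  }
  self
}

# conv -> batch norm -> ReLU, the standard block in both the encoder and the
# decoder refinement path.
nn_cbr <- function(cin, cout, k, stride = 1L, pad = 0L, dilation = 1L,
                   groups = 1L) {
  nn_sequential(nn_conv(cin, cout, k, stride, pad, dilation, groups),
                nn_bn(cout), nn_relu())
}

# conv -> batch norm (no activation; used for depthwise stages of shuffle
# units, which ShuffleNet v2 leaves linear).
nn_cb <- function(cin, cout, k, stride = 1L, pad = 0L, dilation = 1L,
                  groups = 1L) {
  nn_sequential(nn_conv(cin, cout, k, stride, pad, dilation, groups),
                nn_bn(cout))
}
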