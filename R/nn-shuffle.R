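# ShuffleNet v2 building blocks: channel shuffle, the basic (channel-split)
# unit and the spatial down-sampling unit. Both units concatenate their two
# branches (never add) and end with a channel shuffle so information crosses
# between branches.

#' Channel shuffle permutation
#'
#' Reorders the channels of a feature map by reshaping them to
#' `(groups, C/groups)` and transposing, the mixing operation that closes
#' every ShuffleNet v2 unit. A pure permutation: values are untouched.
#'
#' @param x Array of shape `(H, W, C)` or `(H, W, C, N)`.
#' @param groups Number of shuffle groups; must divide the channel count.
#' @return Array of the same shape with channels permuted.
#' @examples
#' x <- array(1:16, c(2, 2, 4))
#' y <- channel_shuffle(x, 2) # channel order becomes 1,3,2,4
#' @export
channel_shuffle <- function(x, groups = 2L) {
  x <- as_hwcn(x)
  C <- dim(x)[3]
  x[, , shuffle_permutation(C, groups), , drop = FALSE]
}

# 1-based permutation: output channel t reads input channel perm[t].
shuffle_permutation <- function(C, groups) {
  if (C %% groups != 0L)
    stop("channel count ", C, " not divisible by groups = ", groups)
  t <- seq_len(C) - 1L
  (t %% groups) * (C %/% groups) + (t %/% groups) + 1L
}

nn_channel_shuffle <- function(groups = 2L) {
  self <- nn_module("channel_shuffle")
  self$groups <- groups
  self$forward <- function(x, training = TRUE) {
    self$perm <- shuffle_permutation(dim(x)[3], self$groups)
    x[, , self$perm, , drop = FALSE]
  }
  self$backward <- function(dy) {
    inv <- integer(length(self$perm))
    inv[self$perm] <- seq_along(self$perm)
    dy[, , inv, , drop = FALSE]
  }
  self
}

# Basic shuffle unit: split channels in half; the identity half bypasses all
# computation, the other half runs 1x1 conv -> 3x3 depthwise -> 1x1 conv with
# its channel count preserved; halves are concatenated and shuffled.
# Shape-preserving; requires an even channel count.
nn_shuffle_basic <- function(C) {
  if (C %% 2L != 0L)
    stop("basic shuffle unit needs an even channel count, got ", C)
  self <- nn_module("shuffle_basic")
  h <- C %/% 2L
  self$branch <- nn_sequential(
    nn_cbr(h, h, 1L),
    nn_cb(h, h, 3L, pad = 1L, groups = h),
    nn_cbr(h, h, 1L))
  self$shuffle <- nn_channel_shuffle(2L)
  self$children <- list(self$branch, self$shuffle)
  self$half <- h
  self$forward <- function(x, training = TRUE) {
    if (dim(x)[3] != 2L * self$half)
      stop("expected ", 2L * self$half, " channels, got ", dim(x)[3])
    h <- self$half
    x1 <- x[, , seq_len(h), , drop = FALSE]
    y2 <- self$branch$forward(x[, , h + seq_len(h), , drop = FALSE], training)
    d <- dim(x)
    y <- array(0, d)
    y[, , seq_len(h), ] <- x1
    y[, , h + seq_len(h), ] <- y2
    self$shuffle$forward(y, training)
  }
  self$backward <- function(dy) {
    h <- self$half
    dz <- self$shuffle$backward(dy)
    d1 <- dz[, , seq_len(h), , drop = FALSE]
    d2 <- self$branch$backward(dz[, , h + seq_len(h), , drop = FALSE])
    dx <- array(0, dim(dz))
    dx[, , seq_len(h), ] <- d1
    dx[, , h + seq_len(h), ] <- d2
    dx
  }
  self
}

# Down-sampling shuffle unit: no channel split; both branches consume the full
# input and halve the spatial size with a stride-2 depthwise convolution;
# concatenation doubles the channels: (Cin, H, W) -> (cout, H/2, W/2).
nn_shuffle_down <- function(cin, cout = 2L * cin) {
  if (cout %% 2L != 0L) stop("output channels must be even")
  self <- nn_module("shuffle_down")
  h <- cout %/% 2L
  self$b1 <- nn_sequential(
    nn_cb(cin, cin, 3L, stride = 2L, pad = 1L, groups = cin),
    nn_cbr(cin, h, 1L))
  self$b2 <- nn_sequential(
    nn_cbr(cin, h, 1L),
    nn_cb(h, h, 3L, stride = 2L, pad = 1L, groups = h),
    nn_cbr(h, h, 1L))
  self$shuffle <- nn_channel_shuffle(2L)
  self$children <- list(self$b1, self$b2, self$shuffle)
  self$half <- h
  self$forward <- function(x, training = TRUE) {
    d <- dim(x)
    if (d[1] < 2L || d[2] < 2L)
      stop("cannot halve a ", d[1], "x", d[2], " feature map")
    h <- self$half
    y1 <- self$b1$forward(x, training)
    y2 <- self$b2$forward(x, training)
    y <- array(0, c(dim(y1)[1], dim(y1)[2], 2L * h, d[4]))
    y[, , seq_len(h), ] <- y1
    y[, , h + seq_len(h), ] <- y2
    self$shuffle$forward(y, training)
  }
  self$backward <- function(dy) {
    h <- self$half
    dz <- self$shuffle$backward(dy)
    self$b1$backward(dz[, , seq_len(h), , drop = FALSE]) +
      self$b2$backward(dz[, , h + seq_len(h), , drop = FALSE])
  }
  self
}

# A full encoder stage: one down-sampling unit followed by `repeats - 1` basic
# units.
nn_shuffle_stage <- function(cin, cout, repeats) {
  units <- c(list(nn_shuffle_down(cin, cout)),
             lapply(seq_len(repeats - 1L), function(i) nn_shuffle_basic(cout)))
  do.call(nn_sequential, units)
}
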