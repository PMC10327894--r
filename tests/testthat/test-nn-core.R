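# Numerical primitives: convolution vs a literal-loop oracle, analytic
# gradients vs finite differences, pooling, bilinear resizing, transpose
# convolution.

test_that("convolution matches the naive-loop oracle", {
  withr::local_seed(1)
  x <- array(rnorm(7 * 9 * 3), c(7, 9, 3, 1))
  w <- array(rnorm(3 * 3 * 3 * 4), c(3, 3, 3, 4))
  cases <- list(c(1, 0, 1), c(2, 1, 1), c(1, 2, 2), c(2, 2, 2))
  for (cs in cases) {
    got <- agrinet:::conv_fw(x, w, NULL, cs[1], cs[2], cs[3])$y
    want <- naive_conv(x[, , , 1], w, cs[1], cs[2], cs[3])
    expect_equal(got[, , , 1], want, tolerance = 1e-12,
                 label = paste("conv s/p/d", paste(cs, collapse = "/")))
  }
  # depthwise
  wd <- array(rnorm(3 * 3 * 1 * 3), c(3, 3, 1, 3))
  got <- agrinet:::conv_fw(x, wd, NULL, 1, 1, 1, groups = 3)$y
  expect_equal(got[, , , 1], naive_conv(x[, , , 1], wd, 1, 1, 1),
               tolerance = 1e-12)
  # bias broadcast
  b <- c(1, 2, 3, 4)
  got <- agrinet:::conv_fw(x, w, b, 1, 1, 1)$y
  want <- naive_conv(x[, , , 1], w, 1, 1, 1)
  for (oc in 1:4) expect_equal(got[, , oc, 1], want[, , oc] + b[oc])
  # batch path agrees with per-sample computation
  x2 <- array(rnorm(7 * 9 * 3 * 2), c(7, 9, 3, 2))
  got2 <- agrinet:::conv_fw(x2, w, NULL, 1, 1, 1)$y
  for (n in 1:2)
    expect_equal(got2[, , , n], naive_conv(x2[, , , n], w, 1, 1, 1),
                 tolerance = 1e-12)
})

test_that("layer backward passes agree with finite differences", {
  withr::local_seed(2)
  x <- array(rnorm(8 * 8 * 4 * 2), c(8, 8, 4, 2))
  layers <- list(
    conv = agrinet:::nn_conv(4, 5, 3, pad = 1, bias = TRUE),
    conv_s2 = agrinet:::nn_conv(4, 5, 3, stride = 2, pad = 1),
    conv_dil = agrinet:::nn_conv(4, 3, 3, pad = 2, dilation = 2),
    depthwise = agrinet:::nn_conv(4, 4, 3, pad = 1, groups = 4),
    bn = agrinet:::nn_bn(4),
    tconv = agrinet:::nn_tconv(4, 3),
    cam = agrinet:::nn_cam(4, 2),
    sam = agrinet:::nn_sam(7),
    aspp = agrinet:::nn_aspp(4, c(2, 3), 6))
  for (nm in names(layers))
    expect_lt(dir_gradcheck(layers[[nm]], x), 1e-3, label = nm)
})

test_that("max pooling selects the 3x3 stride-2 maxima", {
  x <- array(0, c(4, 4, 1, 1))
  x[, , 1, 1] <- matrix(1:16, 4, 4)
  mp <- agrinet:::nn_maxpool(3, 2, 1)
  y <- mp$forward(x, training = FALSE)
  # padded 3x3 windows centred on the stride-2 grid of a 1..16 grid
  expect_equal(y[, , 1, 1], rbind(c(6, 14), c(8, 16)))
  # gradient routes to the argmax only
  y <- mp$forward(x, training = TRUE)
  dy <- array(1, dim(y))
  dx <- mp$backward(dy)
  expect_equal(sum(dx), 4)
  expect_equal(dx[2, 2, 1, 1], 1) # position of value 6
  expect_equal(dx[4, 4, 1, 1], 1) # position of value 16
})

test_that("bilinear resizing is exact on affine ramps and invertible-sized", {
  # a linear ramp is reproduced exactly away from the clamped border
  r <- matrix(seq(0, 30, length.out = 16), 16, 12)
  up <- agrinet:::bilinear_resize(r, c(32, 24))
  expect_equal(dim(up)[1:2], c(32L, 24L))
  expect_lt(max(abs(diff(up[8:24, 1, 1, 1]) - 1)), 1e-9)
  # upsample backward is the transpose operator (adjoint identity)
  withr::local_seed(3)
  u <- agrinet:::nn_upsample(2)
  xx <- array(rnorm(6 * 6), c(6, 6, 1, 1))
  y <- u$forward(xx, training = TRUE)
  dy <- array(rnorm(length(y)), dim(y))
  dx <- u$backward(dy)
  expect_equal(sum(y * dy), sum(xx * dx), tolerance = 1e-10)
})

test_that("transpose convolution restores 2x spatial size", {
  withr::local_seed(4)
  tc <- agrinet:::nn_tconv(3, 2, k = 4, stride = 2, pad = 1)
  x <- array(rnorm(5 * 7 * 3), c(5, 7, 3, 1))
  y <- tc$forward(x, training = FALSE)
  expect_identical(dim(y), c(10L, 14L, 2L, 1L))
  # a constant input with a constant kernel gives interior outputs equal to
  # sum over the 4 contributing taps per output pixel
  tc$w <- array(1, dim(tc$w))
  tc$b <- c(0, 0)
  xc <- array(1, c(4, 4, 3, 1))
  yc <- tc$forward(xc, training = FALSE)
  expect_equal(yc[4, 4, 1, 1], 3 * 4) # interior: 4 taps x 3 channels
})

test_that("batch norm normalizes per channel and respects modes", {
  withr::local_seed(5)
  bn <- agrinet:::nn_bn(3)
  x <- array(rnorm(10 * 10 * 3 * 2, mean = 4, sd = 3), c(10, 10, 3, 2))
  y <- bn$forward(x, training = TRUE)
  m <- matrix(aperm(y, c(1, 2, 4, 3)), 200, 3)
  expect_lt(max(abs(colMeans(m))), 1e-10)
  expect_lt(max(abs(apply(m, 2, sd) - 1)), 1e-2)
  # inference mode uses running statistics: output differs from train mode
  y2 <- bn$forward(x, training = FALSE)
  expect_false(identical(y, y2))
})
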