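# Parameter and FLOP accounting.

test_that("single-layer parameter counts follow the kernel formula", {
  # ordinary 3x3 conv, 10 -> 64 channels, no bias
  expect_equal(3 * 3 * 10 * 64, 5760)
  specs <- complexity_profile(tiny_config(), 64)$layers
  stem <- specs[specs$name == "stem", ]
  expect_equal(stem$params, 3 * 3 * 10 * 8)
  # depthwise convolutions divide the input channels by the group count
  full <- complexity_profile(network_config(), 512)$layers
  dw <- full[full$name == "stage3.basic1.dw", ]
  expect_equal(dw$params, 3 * 3 * 116) # 1044
  expect_equal(dw$groups, 116)
})

test_that("single-layer FLOPs follow the kernel x output-size formula", {
  full <- complexity_profile(network_config(), 512)$layers
  stem <- full[full$name == "stem", ]
  # 3x3, 10 in, stride 2 on 512^2 -> 256^2 out, 24 channels
  expect_equal(stem$flops, 3 * 3 * 10 * 256 * 256 * 24)
  # 1x1 conv example: Cin = Cout = 8 on a 4x4 map -> 1024 multiplications
  expect_equal(1 * 1 * 8 * 4 * 4 * 8, 1024)
  # transpose convolution counted at its own output size (input resolution)
  head_row <- full[full$name == "head.tconv", ]
  expect_equal(head_row$hout, 512)
  expect_equal(head_row$flops, 4 * 4 * 86 * 512 * 512 * 3)
})

test_that("per-layer FLOPs equal a literal multiplication count", {
  withr::local_seed(1)
  for (case in list(list(k = 3, cin = 3, cout = 4, h = 6, s = 1, p = 1),
                    list(k = 3, cin = 4, cout = 2, h = 8, s = 2, p = 1),
                    list(k = 1, cin = 4, cout = 4, h = 5, s = 1, p = 0))) {
    x <- array(rnorm(case$h^2 * case$cin), c(case$h, case$h, case$cin))
    w <- array(rnorm(case$k^2 * case$cin * case$cout),
               c(case$k, case$k, case$cin, case$cout))
    res <- naive_conv(x, w, case$s, case$p, count_mults = TRUE)
    ho <- dim(res$y)[1]
    expect_equal(res$mults,
                 case$k^2 * case$cin * ho^2 * case$cout,
                 label = sprintf("k%d", case$k))
  }
  # depthwise: one input channel per output channel
  x <- array(rnorm(64 * 4), c(8, 8, 4))
  wd <- array(rnorm(9 * 4), c(3, 3, 1, 4))
  res <- naive_conv(x, wd, 1, 1, count_mults = TRUE)
  expect_equal(res$mults, 3 * 3 * (4 / 4) * 8 * 8 * 4)
})

test_that("FLOPs scale linearly in area and quadratically in width", {
  cfg <- tiny_config()
  a <- complexity_profile(cfg, 64)$layers
  b <- complexity_profile(cfg, 128)$layers
  # spatial layers: x4 FLOPs for x4 pixels (global-pool and attention-MLP
  # rows work on pooled vectors and are area-independent)
  spatial <- a$kind %in% c("conv", "tconv") & a$hout > 1
  expect_equal(b$flops[spatial], 4 * a$flops[spatial])
  # doubling every channel width quadruples FLOPs in layers whose input and
  # output widths both scale
  cfg2 <- network_config(stage_out_channels = c(16L, 32L, 64L),
                         stage_repeats = c(2L, 2L),
                         aspp_dilations = c(1L, 2L), aspp_out_channels = 32L,
                         cbam_reduction = 4L,
                         skip_reduce_channels_low = 16L,
                         skip_reduce_channels_mid = 16L,
                         decoder_refine_channels = c(32L, 16L))
  d <- complexity_profile(cfg2, 64)$layers
  dense <- !(a$name %in% c("stem", "head.tconv", "cbam.sam.conv")) &
    a$kind %in% c("conv", "tconv", "linear") & a$groups == 1
  expect_equal(d$flops[dense], 4 * a$flops[dense])
  # depthwise rows carry one input channel per output channel, so they are
  # linear in width, as are the fixed-boundary stem (Cin pinned by the data)
  # and classification head (Cout pinned by the classes)
  dw <- a$groups > 1
  expect_equal(d$flops[dw], 2 * a$flops[dw])
  expect_equal(d$flops[a$name == "stem"], 2 * a$flops[a$name == "stem"])
})

test_that("the kernel-formula total reconciles with the built model", {
  cfg <- tiny_config(seed = 1)
  m <- agrinet_model(cfg)
  r <- complexity_profile(m, 64)
  # Eq-style headline + itemized bias/BN terms = every stored weight
  expect_equal(r$params + r$extra_params, agrinet:::n_module_params(m))
  cfg_off <- tiny_config(seed = 1, use_cbam = FALSE)
  m2 <- agrinet_model(cfg_off)
  r2 <- complexity_profile(m2, 64)
  expect_equal(r2$params + r2$extra_params, agrinet:::n_module_params(m2))
})

test_that("comparison tables include the ablation and reject empty input", {
  on <- complexity_profile(network_config(), 512, name = "full")
  off <- complexity_profile(network_config(use_cbam = FALSE), 512,
                            name = "no-cbam")
  tab <- compare_configs(list(on, off))
  expect_equal(nrow(tab), 2)
  expect_lt(tab$params_m[2], tab$params_m[1])
  expect_equal(nrow(compare_configs(list(on))), 1)
  expect_error(compare_configs(list()), "no reports")
})
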