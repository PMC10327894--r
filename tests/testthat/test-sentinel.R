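# Band screening, bilinear resampling, fusion and linear stretching.

make_raw13 <- function(H = 32, W = 32, seed = 1) {
  withr::local_seed(seed)
  ids <- names(agrinet:::SENTINEL2_BANDS)
  res <- unname(agrinet:::SENTINEL2_BANDS)
  bands <- lapply(seq_along(ids), function(i) {
    f <- res[i] / 10
    h <- floor(H / f); w <- floor(W / f)
    matrix(runif(h * w, 0, 4000), h, w)
  })
  band_stack(bands, ids, res)
}

test_that("band screening drops B1/B9/B10 and fixes the canonical order", {
  raw <- make_raw13()
  sel <- select_bands(raw)
  expect_identical(sel$band_ids,
                   c("B2", "B3", "B4", "B5", "B6", "B7", "B8", "B8A",
                     "B11", "B12"))
  expect_length(sel$bands, 10)
  expect_false(any(c("B1", "B9", "B10") %in% sel$band_ids))
  # already-screened stack passes through unchanged
  sel2 <- select_bands(sel)
  expect_identical(sel2$bands, sel$bands)
  # missing required band is reported by name
  broken <- raw
  keep <- broken$band_ids != "B11"
  broken$bands <- broken$bands[keep]
  broken$band_ids <- broken$band_ids[keep]
  broken$resolution_m <- broken$resolution_m[keep]
  expect_error(select_bands(broken), "B11")
})

test_that("bilinear resampling doubles 20 m bands and matches the oracle", {
  # constant band stays constant at 2x size
  cb <- matrix(5, 4, 6)
  up <- resample_to_10m(cb, 20)
  expect_identical(dim(up), c(8L, 12L))
  expect_true(all(abs(up - 5) < 1e-12))
  # 10 m input untouched
  b10 <- matrix(runif(12), 3, 4)
  expect_identical(resample_to_10m(b10, 10), b10)
  # frozen hand-computed 2x2 -> 4x4 grid under half-pixel-center alignment
  b <- rbind(c(0, 10), c(20, 30))
  expected <- rbind(c(0, 2.5, 7.5, 10),
                    c(5, 7.5, 12.5, 15),
                    c(15, 17.5, 22.5, 25),
                    c(20, 22.5, 27.5, 30))
  expect_equal(resample_to_10m(b, 20), expected)
  # interpolants stay within the input envelope
  withr::local_seed(3)
  bb <- matrix(runif(30, 100, 900), 5, 6)
  ub <- resample_to_10m(bb, 20)
  expect_true(min(ub) >= min(bb) - 1e-9 && max(ub) <= max(bb) + 1e-9)
  expect_error(resample_to_10m(bb, 60), "unsupported")
})

test_that("fusion demands ten equal-shape bands", {
  bands <- lapply(1:10, function(i) matrix(i, 4, 4))
  st <- fuse(bands)
  expect_length(st$bands, 10)
  expect_true(all(st$resolution_m == 10))
  expect_error(fuse(bands[1:9]), "10 bands")
  bad <- bands
  bad[[3]] <- matrix(0, 5, 4)
  expect_error(fuse(bad), "B4")
})

test_that("linear stretch follows the affine formula with clipping", {
  p <- stretch_params(0, 200, 0, 100)
  expect_equal(linear_stretch(matrix(0), p)[1], 0)     # min_in -> min_out
  expect_equal(linear_stretch(matrix(200), p)[1], 100) # max_in -> max_out
  expect_equal(linear_stretch(matrix(50), p)[1], 25)
  # out-of-range inputs clip to the output bounds
  expect_equal(linear_stretch(matrix(c(-50, 400), 1), p)[1, ], c(0, 100))
  # stretching a band onto its own range is the identity
  withr::local_seed(5)
  b <- matrix(runif(64, 10, 90), 8, 8)
  own <- stretch_params(min(b), max(b), min(b), max(b))
  expect_equal(linear_stretch(b, own), b)
  expect_error(stretch_params(5, 5, 0, 1), "degenerate")
  expect_error(stretch_params(0, 1, 0, 1, clip_percent = 0.7), "clip_percent")
})

test_that("harmonization maps the target onto the reference DN range", {
  withr::local_seed(7)
  mk <- function(lo, hi) {
    bands <- lapply(1:10, function(i) {
      m <- matrix(runif(64, lo, hi), 8, 8)
      m[1] <- lo; m[64] <- hi # pin the exact range
      m
    })
    fuse(bands)
  }
  ref <- mk(0, 200)
  tgt <- mk(100, 300)
  out <- harmonize(ref, tgt)
  for (i in 1:10) expect_equal(range(out$bands[[i]]), c(0, 200))
  expect_s3_class(out$stretch[["B2"]], "stretch_params")
  # identical stacks: stretch is the identity
  same <- harmonize(ref, ref)
  for (i in 1:10) expect_equal(same$bands[[i]], ref$bands[[i]])
  # constant reference band is degenerate
  cref <- ref
  cref$bands[[4]] <- matrix(42, 8, 8)
  expect_error(harmonize(cref, tgt), "B5")
})

test_that("preprocessing a 13-band scene yields a 10-band 10 m stack", {
  H <- 32L
  raw <- make_raw13(H, H)
  out <- preprocess_scene(raw)
  expect_length(out$bands, 10)
  for (b in out$bands) expect_identical(dim(b), c(H, H))
  expect_true(all(out$resolution_m == 10))
  # with only 10 m inputs, screening + fusion is lossless
  sc <- generate_scene(fixture_spec(scene_hw = 32, seed = 2))
  raw10 <- raw13_from_scene(sc$stack)
  rt <- preprocess_scene(raw10)
  for (b in agrinet:::RETAINED_BANDS)
    expect_equal(rt$bands[[b]], sc$stack$bands[[b]])
})

test_that("raster files round-trip DN values and metadata", {
  sc <- generate_scene(fixture_spec(scene_hw = 16, seed = 4))
  path <- withr::local_tempfile(fileext = ".tif")
  write_raster(sc$stack, path)
  back <- read_raster(path)
  expect_identical(back$band_ids, sc$stack$band_ids)
  for (i in 1:10)
    expect_equal(back$bands[[i]], sc$stack$bands[[i]], tolerance = 1e-6)
  expect_equal(back$geotransform, sc$stack$geotransform)
  # masks round-trip exactly
  mpath <- withr::local_tempfile(fileext = ".tif")
  write_mask(sc$mask, mpath)
  expect_identical(read_mask(mpath), sc$mask)
})
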