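# Tiling, coverage filtering, splitting and augmentation.

mk_scene <- function(H, W, mask_val = 1L) {
  img <- array(runif(H * W * 10), c(H, W, 10))
  msk <- matrix(mask_val, H, W)
  list(img = img, msk = msk)
}

test_that("tiling cuts a row-major grid and drops partial tiles", {
  withr::local_seed(1)
  s <- mk_scene(128, 128)
  tiles <- tile_scene(s$img, s$msk, 64, "sc")
  expect_length(tiles, 4)
  expect_identical(vapply(tiles, function(t) t$tile_id, character(1)),
                   c("sc_r01_c01", "sc_r01_c02", "sc_r02_c01", "sc_r02_c02"))
  # trailing strip dropped, no padding
  s2 <- mk_scene(129, 128)
  expect_length(tile_scene(s2$img, s2$msk, 64), 4)
  # tile areas account for the full cropped grid
  expect_equal(sum(vapply(tiles, function(t) prod(dim(t$mask)), numeric(1))),
               (128 %/% 64)^2 * 64^2)
  # tile content matches direct slicing
  expect_equal(tiles[[2]]$image, s$img[1:64, 65:128, , drop = FALSE])
  expect_error(tile_scene(s$img, matrix(0L, 64, 128), 64), "differ")
})

test_that("crop fraction counts pixels of either crop class", {
  withr::local_seed(2)
  msk <- matrix(0L, 64, 64)
  msk[1:25, 1:41] <- 1L # 1025 pixels of 4096
  pair <- tile_pair(array(0, c(64, 64, 10)), msk)
  expect_equal(pair$crop_fraction, 1025 / 4096)
  msk[, ] <- 0L; msk[1:32, 1:52] <- 2L # exact 40 %: 1664 / 4096
  expect_equal(tile_pair(array(0, c(64, 64, 10)), msk)$crop_fraction,
               1664 / 4096)
})

test_that("coverage filter keeps tiles at or above the threshold", {
  fracs <- seq(0, 0.9, by = 0.1)
  tiles <- lapply(seq_along(fracs), function(i) {
    msk <- matrix(0L, 20, 20)
    n <- round(fracs[i] * 400)
    if (n > 0) msk[seq_len(n)] <- 1L
    tile_pair(array(0, c(20, 20, 10)), msk, sprintf("t%02d", i))
  })
  kept <- filter_coverage(tiles, 0.30)
  expect_length(kept, 7) # 0.3..0.9 inclusive
  expect_identical(kept[[1]]$tile_id, "t04")
  # boundary: exactly 0.30 is retained; all-background removed
  expect_equal(min(vapply(kept, function(t) t$crop_fraction, numeric(1))),
               0.30)
  # idempotent
  expect_identical(filter_coverage(kept, 0.30), kept)
})

test_that("random split is 7:3, disjoint and seed-deterministic", {
  withr::local_seed(3)
  tiles <- lapply(1:100, function(i)
    tile_pair(array(0, c(4, 4, 10)), matrix(1L, 4, 4), sprintf("t%03d", i)))
  m <- split_tiles(tiles, 0.7, seed = 42)
  expect_length(m$train_ids, 70)
  expect_length(m$val_ids, 30)
  expect_length(intersect(m$train_ids, m$val_ids), 0)
  expect_identical(split_tiles(tiles, 0.7, seed = 42), m)
  expect_false(identical(split_tiles(tiles, 0.7, seed = 43)$train_ids,
                         m$train_ids))
  m10 <- split_tiles(tiles[1:10], 0.7, seed = 1)
  expect_length(m10$train_ids, 7)
  expect_length(m10$val_ids, 3)
  expect_error(split_tiles(tiles[1], 0.7, 1), "at least 2")
})

test_that("geometric augmentation acts identically on image and mask", {
  withr::local_seed(4)
  sc <- generate_scene(fixture_spec(scene_hw = 32, seed = 9))
  pair <- tile_pair(agrinet:::stack_to_array(sc$stack), sc$mask, "p")
  # group identities
  expect_equal(augment_tile(pair, rotate_k = 4), pair)
  expect_equal(augment_tile(augment_tile(pair, hmirror = TRUE),
                            hmirror = TRUE), pair)
  expect_equal(augment_tile(augment_tile(pair, vmirror = TRUE),
                            vmirror = TRUE), pair)
  expect_equal(augment_tile(pair, noise_sd = 0), pair)
  # one quarter turn moves image and mask together
  r1 <- augment_tile(pair, rotate_k = 1)
  expect_equal(r1$mask[1, 1], pair$mask[1, ncol(pair$mask)])
  expect_equal(r1$image[1, 1, ], pair$image[1, ncol(pair$mask), ])
  # per-class pixel counts conserved by every geometric op
  counts <- tabulate(pair$mask + 1L, 3)
  for (k in 0:3) for (hm in c(FALSE, TRUE)) for (vm in c(FALSE, TRUE)) {
    a <- augment_tile(pair, k, hm, vm)
    expect_identical(tabulate(a$mask + 1L, 3), counts)
  }
  # noise perturbs the image only and leaves labels alone
  nz <- augment_tile(pair, noise_sd = 0.01, seed = 5)
  expect_identical(nz$mask, pair$mask)
  expect_false(identical(nz$image, pair$image))
  expect_lt(max(abs(nz$image - pair$image)),
            0.1 * max(pair$image))
  # same seed, same noise
  expect_equal(augment_tile(pair, noise_sd = 0.01, seed = 5), nz)
})

test_that("random augmentation is deterministic under a seed", {
  sc <- generate_scene(fixture_spec(scene_hw = 32, seed = 10))
  pair <- tile_pair(agrinet:::stack_to_array(sc$stack), sc$mask, "p")
  a1 <- random_augment(pair, seed = 11)
  expect_equal(random_augment(pair, seed = 11), a1)
  expect_identical(tabulate(a1$mask + 1L, 3), tabulate(pair$mask + 1L, 3))
})

test_that("datasets round-trip through disk", {
  withr::local_seed(6)
  dir <- withr::local_tempdir()
  ds <- generate_ds_like(fixture_spec(scene_hw = 32, seed = 12), 4, 0.30)
  write_dataset(ds$tiles, ds$manifest, dir)
  back <- read_dataset(dir)
  expect_length(back$tiles, 4)
  for (i in 1:4) {
    expect_identical(back$tiles[[i]]$tile_id, ds$tiles[[i]]$tile_id)
    expect_identical(back$tiles[[i]]$mask, ds$tiles[[i]]$mask)
    expect_equal(back$tiles[[i]]$image, ds$tiles[[i]]$image,
                 tolerance = 1e-6)
  }
  expect_identical(back$manifest$train_ids, ds$manifest$train_ids)
})
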