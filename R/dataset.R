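# Dataset construction: cut preprocessed scenes into fixed-size tiles paired
# with label masks, discard tiles with little crop cover, and split the rest
# into training and validation sets.

#' Image/label tile pair
#'
#' @param image `(H, W, C)` array of stretched DN.
#' @param mask `(H, W)` integer matrix with values in `{0 background,
#'   1 winter canola, 2 winter wheat}`.
#' @param tile_id Identifier encoding scene and grid position.
#' @return An object of class `tile_pair` carrying `crop_fraction`, the
#'   fraction of mask pixels belonging to either crop class.
#' @export
tile_pair <- function(image, mask, tile_id = "tile") {
  stopifnot(length(dim(image)) == 3L, is.matrix(mask))
  if (!identical(dim(image)[1:2], dim(mask)))
    stop("image and mask sizes differ")
  if (!all(mask %in% 0:2))
    stop("mask values must lie in {0, 1, 2}")
  storage.mode(mask) <- "integer"
  structure(list(image = image, mask = mask, tile_id = tile_id,
                 crop_fraction = mean(mask != 0L)),
            class = "tile_pair")
}

#' @export
print.tile_pair <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("tile_pair %s: %dx%d px, %d bands, crop fraction %.3f\n",
              x$tile_id, d[1], d[2], d[3], x$crop_fraction))
  invisible(x)
}

#' Cut a scene into tiles
#'
#' Non-overlapping `tile_size` x `tile_size` tiles read in row-major order;
#' trailing partial tiles are dropped (never padded, so no label artifacts
#' are introduced at scene edges).
#'
#' @param scene A [band_stack()] or `(H, W, C)` array.
#' @param mask_raster `(H, W)` label matrix co-registered with the scene.
#' @param tile_size Tile edge length in pixels (512 for training scenes).
#' @param scene_id Prefix for tile ids.
#' @return List of [tile_pair()] objects.
#' @export
tile_scene <- function(scene, mask_raster, tile_size = 512L,
                       scene_id = "scene") {
  arr <- if (inherits(scene, "band_stack")) stack_to_array(scene) else scene
  stopifnot(length(dim(arr)) == 3L)
  if (!identical(dim(arr)[1:2], dim(mask_raster)))
    stop("scene and mask sizes differ: ",
         paste(dim(arr)[1:2], collapse = "x"), " vs ",
         paste(dim(mask_raster), collapse = "x"))
  nr <- nrow(mask_raster) %/% tile_size
  nc <- ncol(mask_raster) %/% tile_size
  tiles <- list()
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    ri <- (r - 1L) * tile_size + seq_len(tile_size)
    ci <- (cc - 1L) * tile_size + seq_len(tile_size)
    tiles[[length(tiles) + 1L]] <- tile_pair(
      arr[ri, ci, , drop = FALSE], mask_raster[ri, ci],
      sprintf("%s_r%02d_c%02d", scene_id, r, cc))
  }
  tiles
}

#' Filter tiles by crop coverage
#'
#' Retains exactly the tiles whose crop fraction (pixels of either crop
#' class) is at least `threshold`; tiles with less coverage are removed.
#' Input order is preserved; the operation is idempotent.
#'
#' @param tiles List of [tile_pair()] objects.
#' @param threshold Minimum retained crop fraction (0.30 by default).
#' @return Filtered list.
#' @export
filter_coverage <- function(tiles, threshold = 0.30) {
  keep <- vapply(tiles, function(t) t$crop_fraction >= threshold, logical(1))
  tiles[keep]
}

#' Randomly split tiles into training and validation sets
#'
#' Uniformly random permutation under `seed`; the first `floor(ratio * n)`
#' tiles become the training set. Deterministic for a fixed seed.
#'
#' @param tiles List of [tile_pair()] objects (at least 2).
#' @param ratio Training fraction (0.7 for the 7:3 split).
#' @param seed Integer seed.
#' @param coverage_threshold Recorded in the manifest for provenance.
#' @return A `dataset_manifest`: `train_ids`, `val_ids`, `split_ratio`,
#'   `seed`, `coverage_threshold`.
#' @export
split_tiles <- function(tiles, ratio = 0.7, seed = 1L,
                        coverage_threshold = NA_real_) {
  n <- length(tiles)
  if (n < 2L) stop("need at least 2 tiles to split")
  ids <- vapply(tiles, function(t) t$tile_id, character(1))
  perm <- with_seed(seed, sample(n))
  ntr <- floor(ratio * n)
  structure(list(train_ids = ids[perm[seq_len(ntr)]],
                 val_ids = ids[perm[(ntr + 1L):n]],
                 split_ratio = ratio, seed = as.integer(seed),
                 coverage_threshold = coverage_threshold),
            class = "dataset_manifest")
}

#' @export
print.dataset_manifest <- function(x, ...) {
  cat(sprintf("dataset_manifest: %d train / %d val (ratio %.2f, seed %d)\n",
              length(x$train_ids), length(x$val_ids), x$split_ratio, x$seed))
  invisible(x)
}

rot90_hwc <- function(a, k) {
  k <- ((k %% 4L) + 4L) %% 4L
  if (k == 0L) return(a)
  for (i in seq_len(k)) {
    # one counter-clockwise quarter turn: transpose then reverse rows
    a <- aperm(a, c(2L, 1L, 3L))
    a <- a[rev(seq_len(dim(a)[1])), , , drop = FALSE]
  }
  a
}

#' Augment a tile pair
#'
#' Deterministic geometric/noise augmentation: rotations by multiples of 90
#' degrees and mirrorings are applied identically to image and mask (so
#' per-class pixel counts are conserved); additive zero-mean Gaussian noise
#' is applied to the image only, with the standard deviation expressed as a
#' fraction of each band's value range. The mask is never interpolated.
#'
#' @param pair A [tile_pair()].
#' @param rotate_k Number of 90-degree counter-clockwise rotations (0-3).
#' @param hmirror,vmirror Mirror along the horizontal/vertical axis.
#' @param noise_sd Noise standard deviation as a fraction of each band's
#'   (max - min) range; 0 disables noise.
#' @param seed Seed for the noise draw (required when `noise_sd > 0`).
#' @return The augmented [tile_pair()].
#' @export
augment_tile <- function(pair, rotate_k = 0L, hmirror = FALSE,
                         vmirror = FALSE, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(pair, "tile_pair"))
  img <- pair$image
  msk <- pair$mask
  dim(msk) <- c(dim(msk), 1L)
  if (rotate_k %% 4L != 0L) {
    img <- rot90_hwc(img, rotate_k)
    msk <- rot90_hwc(msk, rotate_k)
  }
  if (hmirror) { # flip left-right
    img <- img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
    msk <- msk[, rev(seq_len(dim(msk)[2])), , drop = FALSE]
  }
  if (vmirror) { # flip up-down
    img <- img[rev(seq_len(dim(img)[1])), , , drop = FALSE]
    msk <- msk[rev(seq_len(dim(msk)[1])), , , drop = FALSE]
  }
  if (noise_sd > 0) {
    d <- dim(img)
    rng <- apply(img, 3L, function(b) diff(range(b)))
    sds <- rep(noise_sd * pmax(rng, .Machine$double.eps), each = d[1] * d[2])
    noise <- with_seed(seed %||% stop("seed required for noise"),
                       stats::rnorm(length(img), sd = sds))
    img <- img + array(noise, d)
  }
  tile_pair(img, matrix(msk, dim(msk)[1], dim(msk)[2]), pair$tile_id)
}

#' Randomly augment a tile pair
#'
#' Draws a rotation (0-3 quarter turns), mirror flags and a noise
#' realization under `seed` and applies them via [augment_tile()].
#'
#' @param pair A [tile_pair()].
#' @param seed Integer seed.
#' @param noise_sd Fractional noise level passed to [augment_tile()].
#' @return The augmented [tile_pair()].
#' @export
random_augment <- function(pair, seed, noise_sd = 0.01) {
  draw <- with_seed(seed, list(k = sample(0:3, 1), hm = stats::runif(1) < 0.5,
                               vm = stats::runif(1) < 0.5))
  augment_tile(pair, draw$k, draw$hm, draw$vm, noise_sd,
               seed = derive_seed(seed, 7L))
}

#' Write a tiled dataset to disk
#'
#' Each tile becomes a paired multiband image TIFF and 8-bit mask TIFF, with
#' a JSON manifest recording ids, crop fractions, the split and its seed.
#'
#' @param tiles List of [tile_pair()] objects.
#' @param manifest A [split_tiles()] manifest (or `NULL`).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(tiles, manifest, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (t in tiles) {
    st <- band_stack(lapply(seq_len(dim(t$image)[3]),
                            function(i) t$image[, , i]),
                     band_ids = RETAINED_BANDS[seq_len(dim(t$image)[3])])
    write_raster(st, file.path(dir, paste0(t$tile_id, "_img.tif")))
    write_mask(t$mask, file.path(dir, paste0(t$tile_id, "_mask.tif")))
  }
  meta <- list(tiles = data.frame(
    tile_id = vapply(tiles, function(t) t$tile_id, character(1)),
    crop_fraction = vapply(tiles, function(t) t$crop_fraction, numeric(1))))
  if (!is.null(manifest)) meta$manifest <- unclass(manifest)
  jsonlite::write_json(meta, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Dataset directory.
#' @return List with `tiles` and `manifest` (or `NULL`).
#' @export
read_dataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "manifest.json"),
                              simplifyVector = TRUE)
  tiles <- lapply(meta$tiles$tile_id, function(id) {
    st <- read_raster(file.path(dir, paste0(id, "_img.tif")))
    msk <- read_mask(file.path(dir, paste0(id, "_mask.tif")))
    tile_pair(stack_to_array(st), msk, id)
  })
  manifest <- NULL
  if (!is.null(meta$manifest)) {
    manifest <- meta$manifest
    class(manifest) <- "dataset_manifest"
  }
  list(tiles = tiles, manifest = manifest)
}
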