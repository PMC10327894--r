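# Synthetic multispectral scenes with the structure of winter-crop imagery:
# contiguous rectangular fields of two crop classes separated by thin
# background roads, with class-specific 10-band spectral signatures plus
# additive Gaussian noise. The generator exists so the full pipeline is
# testable end to end without any satellite downloads; it makes no claim of
# radiometric realism.

# Default per-class mean DN signatures (10 retained bands, surface
# reflectance x 1e4 convention). Winter canola and winter wheat differ most
# strongly in the red / red-edge / SWIR bands; background emulates bare
# roads/soil with a flat spectrum.
FIXTURE_SIGNATURES <- rbind(
  background = c(1200, 1400, 1600, 1800, 2000, 2100, 2200, 2250, 2500, 2300),
  canola     = c(500, 1200, 1300, 1900, 3200, 3800, 4200, 4300, 2600, 1400),
  wheat      = c(400, 800, 600, 1200, 2800, 3600, 4000, 4100, 1800, 900))

#' Synthetic-scene specification
#'
#' @param scene_hw Scene height/width in pixels.
#' @param n_fields Approximate number of fields (rectangular cells of an
#'   irregular grid partition).
#' @param road_width_px Width of the background roads separating fields.
#' @param class_priors Probabilities of assigning a field to (canola, wheat).
#' @param signatures 3 x 10 matrix of per-class per-band mean DN
#'   (background, canola, wheat rows).
#' @param noise_sd Additive Gaussian DN noise standard deviation.
#' @param seed Integer seed; scenes are deterministic given the spec.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(scene_hw = c(512L, 512L), n_fields = 16L,
                         road_width_px = 2L, class_priors = c(0.5, 0.5),
                         signatures = FIXTURE_SIGNATURES, noise_sd = 100,
                         seed = 1L) {
  if (length(scene_hw) == 1L) scene_hw <- c(scene_hw, scene_hw)
  stopifnot(all(scene_hw >= 8L), n_fields >= 1L, road_width_px >= 1L,
            length(class_priors) == 2L, all(class_priors >= 0),
            sum(class_priors) > 0, noise_sd >= 0,
            nrow(signatures) == 3L, ncol(signatures) == 10L)
  if (max(abs(signatures[2, ] - signatures[3, ])) == 0)
    stop("crop class signatures must differ in at least one band")
  structure(list(scene_hw = as.integer(scene_hw),
                 n_fields = as.integer(n_fields),
                 road_width_px = as.integer(road_width_px),
                 class_priors = class_priors / sum(class_priors),
                 signatures = signatures, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a synthetic scene and label raster
#'
#' Partitions the scene into rectangular fields by irregular grid cuts,
#' assigns each field to winter canola (1) or winter wheat (2) by the class
#' priors, separates fields by background roads (0), and renders each band
#' as the per-class mean signature plus i.i.d. Gaussian noise clipped at 0.
#'
#' @param spec A [fixture_spec()].
#' @return List with `stack` (a 10-band [band_stack()]) and `mask` (integer
#'   label matrix).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  H <- spec$scene_hw[1]; W <- spec$scene_hw[2]
  with_seed(spec$seed, {
    # irregular grid: cut rows and columns into roughly sqrt(n_fields) strips
    ncut <- max(1L, round(sqrt(spec$n_fields)))
    cuts <- function(n) {
      if (ncut == 1L || n < 24L) return(c(0L, n))
      cand <- seq(8L, n - 8L)
      k <- min(ncut - 1L, length(cand))
      c(0L, sort(cand[sample.int(length(cand), k)]), n)
    }
    rcut <- cuts(H); ccut <- cuts(W)
    mask <- matrix(0L, H, W)
    rw <- spec$road_width_px
    for (i in seq_len(length(rcut) - 1L)) for (j in seq_len(length(ccut) - 1L)) {
      r0 <- rcut[i] + 1L + (if (i > 1L) rw else 0L)
      r1 <- rcut[i + 1L] - (if (i < length(rcut) - 1L) rw else 0L)
      c0 <- ccut[j] + 1L + (if (j > 1L) rw else 0L)
      c1 <- ccut[j + 1L] - (if (j < length(ccut) - 1L) rw else 0L)
      if (r1 < r0 || c1 < c0) next
      cls <- sample(1:2, 1L, prob = spec$class_priors)
      mask[r0:r1, c0:c1] <- cls
    }
    # border roads so every scene has background pixels even with one field
    mask[c(seq_len(rw), H - seq_len(rw) + 1L), ] <- 0L
    mask[, c(seq_len(rw), W - seq_len(rw) + 1L)] <- 0L
    bands <- lapply(seq_len(10L), function(b) {
      m <- matrix(spec$signatures[mask + 1L, b], H, W)
      if (spec$noise_sd > 0)
        m <- m + matrix(stats::rnorm(H * W, sd = spec$noise_sd), H, W)
      pmax(m, 0)
    })
    list(stack = band_stack(bands, RETAINED_BANDS, 10), mask = mask)
  })
}

#' Generate a ready-made tile dataset
#'
#' Emits `n_tiles` tile pairs that already pass the crop-coverage filter at
#' the stated threshold (tiles are drawn scene by scene and re-drawn until
#' they pass), plus a 7:3 split manifest. Round-trips unchanged through the
#' dataset builder.
#'
#' @param spec A [fixture_spec()]; `scene_hw` is the tile size.
#' @param n_tiles Number of tiles to emit.
#' @param coverage_threshold Minimum crop fraction each tile must reach.
#' @param ratio Train fraction of the split manifest.
#' @param dir Optional directory; if given the dataset is written there.
#' @return List with `tiles` and `manifest`.
#' @export
generate_ds_like <- function(spec, n_tiles, coverage_threshold = 0.30,
                             ratio = 0.7, dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"), n_tiles >= 2L)
  if (coverage_threshold >= 1)
    stop("coverage threshold ", coverage_threshold, " is unsatisfiable: ",
         "roads guarantee background pixels in every tile")
  tiles <- list()
  attempt <- 0L
  while (length(tiles) < n_tiles) {
    attempt <- attempt + 1L
    if (attempt > 50L * n_tiles)
      stop("could not generate enough tiles passing the coverage filter")
    s <- spec
    s$seed <- derive_seed(spec$seed, attempt)
    sc <- generate_scene(s)
    pair <- tile_pair(stack_to_array(sc$stack), sc$mask,
                      sprintf("fix%04d", attempt))
    if (pair$crop_fraction >= coverage_threshold)
      tiles[[length(tiles) + 1L]] <- pair
  }
  manifest <- split_tiles(tiles, ratio, spec$seed, coverage_threshold)
  if (!is.null(dir)) write_dataset(tiles, manifest, dir)
  list(tiles = tiles, manifest = manifest)
}
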