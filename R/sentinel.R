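# Sentinel-2 preprocessing: band screening, bilinear resampling of the 20 m
# bands to 10 m, fusion into a canonical 10-channel stack, and percentage
# linear DN stretching so scenes from different acquisitions share a common
# radiometric range.

# The 13 Sentinel-2 bands with their native ground sampling distances (m).
SENTINEL2_BANDS <- c(B1 = 60, B2 = 10, B3 = 10, B4 = 10, B5 = 20, B6 = 20,
                     B7 = 20, B8 = 10, B8A = 20, B9 = 60, B10 = 60,
                     B11 = 20, B12 = 20)

# Canonical retained-band order: ascending band number; B1 (coastal aerosol),
# B9 (water vapour) and B10 (SWIR-cirrus), the 60 m bands, are excluded.
RETAINED_BANDS <- c("B2", "B3", "B4", "B5", "B6", "B7", "B8", "B8A",
                    "B11", "B12")

#' Multiband raster stack
#'
#' A georeferenced multiband raster: an ordered list of 2-D digital-number
#' (DN) matrices with per-band identifiers and resolutions plus an affine
#' geotransform and CRS string.
#'
#' @param bands Named or unnamed list of numeric matrices (DN >= 0).
#' @param band_ids Band identifiers (e.g. `"B2"`); defaults to names of
#'   `bands`.
#' @param resolution_m Per-band ground sampling distance in metres (recycled).
#' @param geotransform Length-6 affine transform
#'   `(x0, dx, rx, y0, ry, dy)` mapping pixel to map coordinates.
#' @param crs Coordinate reference system identifier.
#' @return An object of class `band_stack`.
#' @export
band_stack <- function(bands, band_ids = names(bands), resolution_m = 10,
                       geotransform = c(0, 10, 0, 0, 0, -10),
                       crs = "EPSG:32649") {
  stopifnot(is.list(bands), length(bands) >= 1L)
  if (is.null(band_ids)) stop("band_ids required")
  stopifnot(length(band_ids) == length(bands))
  if (any(vapply(bands, function(b) any(b < 0), logical(1))))
    stop("digital numbers must be non-negative")
  structure(list(bands = stats::setNames(bands, band_ids),
                 band_ids = band_ids,
                 resolution_m = rep_len(resolution_m, length(bands)),
                 geotransform = geotransform, crs = crs,
                 stretch = NULL),
            class = "band_stack")
}

#' @export
print.band_stack <- function(x, ...) {
  d <- dim(x$bands[[1]])
  cat(sprintf("band_stack: %d bands (%s), %dx%d px, %s\n",
              length(x$bands), paste(x$band_ids, collapse = ","),
              d[1], d[2], x$crs))
  invisible(x)
}

#' Screen Sentinel-2 bands
#'
#' Drops the 60 m atmospheric bands (B1 coastal aerosol, B9 water vapour,
#' B10 SWIR-cirrus) and returns the 10 retained bands in canonical ascending
#' order B2,B3,B4,B5,B6,B7,B8,B8A,B11,B12.
#'
#' @param raw A [band_stack()] containing at least the 10 retained bands.
#' @return A [band_stack()] with exactly the retained bands.
#' @export
select_bands <- function(raw) {
  stopifnot(inherits(raw, "band_stack"))
  missing <- setdiff(RETAINED_BANDS, raw$band_ids)
  if (length(missing) > 0L)
    stop("required band ", paste(missing, collapse = ", "), " absent")
  idx <- match(RETAINED_BANDS, raw$band_ids)
  band_stack(raw$bands[idx], RETAINED_BANDS, raw$resolution_m[idx],
             raw$geotransform, raw$crs)
}

#' Resample a band to 10 m resolution
#'
#' 20 m bands are upsampled 2x per axis by bilinear interpolation
#' (half-pixel-center alignment); 10 m bands are returned unchanged.
#'
#' @param band Numeric DN matrix.
#' @param src_res_m Source resolution, 10 or 20 metres.
#' @return DN matrix at 10 m grid spacing.
#' @export
resample_to_10m <- function(band, src_res_m) {
  stopifnot(is.matrix(band), length(band) > 0L)
  if (src_res_m == 10) return(band)
  if (src_res_m != 20)
    stop("unsupported source resolution: ", src_res_m, " m")
  f <- src_res_m / 10
  ry <- interp_matrix(nrow(band) * f, nrow(band))
  rx <- interp_matrix(ncol(band) * f, ncol(band))
  ry %*% band %*% t(rx)
}

#' Fuse resampled bands into a 10-channel stack
#'
#' @param bands List of exactly 10 equal-shape DN matrices in canonical band
#'   order.
#' @param geotransform,crs Georeferencing propagated from the 10 m reference
#'   band.
#' @return A [band_stack()] with 10 bands at 10 m.
#' @export
fuse <- function(bands, geotransform = c(0, 10, 0, 0, 0, -10),
                 crs = "EPSG:32649") {
  if (length(bands) != 10L)
    stop("expected 10 bands to fuse, got ", length(bands))
  dims <- vapply(bands, function(b) dim(b), integer(2))
  ref <- dims[, 1]
  bad <- which(dims[1, ] != ref[1] | dims[2, ] != ref[2])
  if (length(bad) > 0L)
    stop("bands with mismatched shapes: ",
         paste(RETAINED_BANDS[bad], collapse = ", "))
  band_stack(bands, RETAINED_BANDS, 10, geotransform, crs)
}

#' Stretch parameters
#'
#' Bounds of the percentage linear stretch
#' `result = (DN - min_in) / (max_in - min_in) * (max_out - min_out) +
#' min_out`. With `clip_percent = 0` the input bounds are the band's true
#' min/max; a positive value clips that fraction of the DN histogram at each
#' tail first (e.g. 0.02 for a classic 2 % stretch).
#'
#' @param min_in,max_in Input DN bounds.
#' @param min_out,max_out Target DN bounds.
#' @param clip_percent Tail fraction clipped when deriving input bounds.
#' @return An object of class `stretch_params`.
#' @export
stretch_params <- function(min_in, max_in, min_out, max_out,
                           clip_percent = 0) {
  if (max_in <= min_in)
    stop("degenerate input range: max_in must exceed min_in")
  if (max_out <= min_out) stop("max_out must exceed min_out")
  if (clip_percent < 0 || clip_percent >= 0.5)
    stop("clip_percent must lie in [0, 0.5)")
  structure(list(min_in = min_in, max_in = max_in, min_out = min_out,
                 max_out = max_out, clip_percent = clip_percent),
            class = "stretch_params")
}

# Input bounds of a band under a tail-clip fraction.
stretch_bounds <- function(band, clip_percent = 0) {
  if (clip_percent == 0) range(band)
  else stats::quantile(band, c(clip_percent, 1 - clip_percent), names = FALSE)
}

#' Percentage linear stretch of a band
#'
#' Affine remap of `[min_in, max_in]` onto `[min_out, max_out]`; values
#' outside the input bounds are clipped to the output bounds.
#'
#' @param band Numeric DN matrix (or array).
#' @param p A [stretch_params()].
#' @return Stretched band of the same shape.
#' @export
linear_stretch <- function(band, p) {
  stopifnot(inherits(p, "stretch_params"))
  out <- (band - p$min_in) / (p$max_in - p$min_in) *
    (p$max_out - p$min_out) + p$min_out
  pmin(pmax(out, min(p$min_out, p$max_out)), max(p$min_out, p$max_out))
}

#' Harmonize a scene's DN range to a reference scene
#'
#' Stretches each band of `target` so its DN range matches the per-band
#' [min, max] of `reference` (optionally after tail clipping), bringing both
#' scenes onto a common radiometric range. The per-band stretch parameters
#' are recorded in the result's `stretch` field.
#'
#' @param reference,target [band_stack()] objects with the same 10 bands.
#' @param clip_percent Tail fraction clipped when deriving input bounds.
#' @return The stretched target [band_stack()].
#' @export
harmonize <- function(reference, target, clip_percent = 0) {
  stopifnot(inherits(reference, "band_stack"), inherits(target, "band_stack"))
  if (!identical(reference$band_ids, target$band_ids))
    stop("reference and target band lists differ")
  out <- target
  out$stretch <- vector("list", length(target$bands))
  names(out$stretch) <- target$band_ids
  for (i in seq_along(target$bands)) {
    rb <- stretch_bounds(reference$bands[[i]], clip_percent)
    tb <- stretch_bounds(target$bands[[i]], clip_percent)
    if (rb[2] <= rb[1])
      stop("reference band ", reference$band_ids[i], " has a constant range")
    if (tb[2] <= tb[1])
      stop("target band ", target$band_ids[i], " has a constant range")
    p <- stretch_params(tb[1], tb[2], rb[1], rb[2], clip_percent)
    out$bands[[i]] <- linear_stretch(target$bands[[i]], p)
    out$stretch[[i]] <- p
  }
  out
}

#' Preprocess a raw Sentinel-2 scene
#'
#' Band screening, bilinear resampling of 20 m bands to 10 m, fusion to the
#' canonical 10-channel stack, and (when a reference is given) per-band
#' linear stretching onto the reference's DN range.
#'
#' @param raw Raw [band_stack()] with at least the 10 retained bands at
#'   native resolutions.
#' @param reference Optional preprocessed reference [band_stack()] whose DN
#'   range defines the stretch target.
#' @param clip_percent Tail fraction for stretch-bound estimation.
#' @return A 10-band, 10 m [band_stack()].
#' @export
preprocess_scene <- function(raw, reference = NULL, clip_percent = 0) {
  sel <- select_bands(raw)
  res <- lapply(seq_along(sel$bands), function(i)
    resample_to_10m(sel$bands[[i]], sel$resolution_m[i]))
  fused <- fuse(res, sel$geotransform, sel$crs)
  if (!is.null(reference)) fused <- harmonize(reference, fused, clip_percent)
  fused
}

# ---- raster IO --------------------------------------------------------------
# Multiband rasters are stored as multi-page 32-bit-float TIFFs with DN
# scaled into [0, 1] by a recorded dn_scale; georeferencing, band metadata
# and stretch parameters live in a JSON sidecar (<file>.json). Label masks
# are single-page 8-bit TIFFs.

#' Write a band stack to a TIFF file (+ JSON sidecar metadata)
#'
#' @param stack A [band_stack()].
#' @param path Output TIFF path; metadata goes to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_raster <- function(stack, path) {
  stopifnot(inherits(stack, "band_stack"))
  dn_scale <- max(1, vapply(stack$bands, max, numeric(1)))
  pages <- lapply(stack$bands, function(b) b / dn_scale)
  suppressWarnings(tiff::writeTIFF(pages, path, bits.per.sample = 32L))
  meta <- list(band_ids = stack$band_ids, resolution_m = stack$resolution_m,
               geotransform = stack$geotransform, crs = stack$crs,
               dn_scale = dn_scale,
               stretch = lapply(stack$stretch, unclass))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a band stack written by [write_raster()]
#'
#' @param path TIFF path with a JSON sidecar.
#' @return A [band_stack()].
#' @export
read_raster <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  mpath <- paste0(path, ".json")
  meta <- if (file.exists(mpath)) jsonlite::read_json(mpath,
                                                      simplifyVector = TRUE)
  else list()
  dn_scale <- meta$dn_scale %||% 1
  bands <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]
    p * dn_scale
  })
  st <- band_stack(bands,
                   band_ids = meta$band_ids %||%
                     paste0("band", seq_along(bands)),
                   resolution_m = meta$resolution_m %||% 10,
                   geotransform = meta$geotransform %||%
                     c(0, 10, 0, 0, 0, -10),
                   crs = meta$crs %||% "EPSG:32649")
  if (!is.null(meta$stretch) && length(meta$stretch) > 0L)
    st$stretch <- meta$stretch
  st
}

#' Write a label mask as an 8-bit TIFF
#'
#' @param mask Integer matrix with values in 0..255.
#' @param path Output path.
#' @export
write_mask <- function(mask, path) {
  tiff::writeTIFF(mask / 255, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read a label mask written by [write_mask()]
#'
#' @param path TIFF path.
#' @return Integer matrix.
#' @export
read_mask <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  storage.mode(m) <- "integer"
  m
}

# (H,W,C) array view of a band_stack.
stack_to_array <- function(stack) {
  d <- dim(stack$bands[[1]])
  arr <- array(0, c(d[1], d[2], length(stack$bands)))
  for (i in seq_along(stack$bands)) arr[, , i] <- stack$bands[[i]]
  arr
}
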