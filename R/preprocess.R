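#' Tumour ROI volume
#'
#' A light container for a 3D intensity array (CT attenuation or normalized
#' units) with per-axis voxel spacing in millimetres.
#'
#' @param intensities 3D numeric array.
#' @param voxel_spacing numeric length-3, mm per axis; all positive.
#' @return object of class `tumor_volume`.
#' @export
tumor_volume <- function(intensities, voxel_spacing = c(1, 1, 1)) {
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    stop("intensities must be a 3D array")
  if (any(dim(intensities) < 1L)) stop("all three dimensions must be positive")
  if (length(voxel_spacing) != 3L || any(voxel_spacing <= 0))
    stop("voxel_spacing must be three positive numbers")
  structure(list(intensities = intensities,
                 voxel_spacing = as.numeric(voxel_spacing)),
            class = "tumor_volume")
}

#' @export
print.tumor_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("Tumour volume %dx%dx%d, spacing %s mm, range [%.3g, %.3g]\n",
              d[1], d[2], d[3],
              paste(signif(x$voxel_spacing, 3), collapse = "x"),
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' Read / write a tumour volume as NIfTI
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return `read_volume()` returns a [tumor_volume()];
#'   `write_volume()` returns `path` invisibly.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- attr(img, "pixdim")
  if (is.null(sp)) sp <- RNifti::pixdim(img)
  tumor_volume(array(as.numeric(img), dim = dim(img)),
               voxel_spacing = sp[1:3])
}

#' @param vol a [tumor_volume()].
#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "tumor_volume"))
  img <- RNifti::asNifti(vol$intensities)
  RNifti::pixdim(img) <- vol$voxel_spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Normalize a CT volume by windowing and bone removal
#'
#' Voxels at or above `bone_threshold` (bright bone/calcification) are set to
#' the window floor, then intensities are clipped to
#' `[window_low, window_high]` and rescaled linearly to `[0, 1]`.
#'
#' @param vol a [tumor_volume()] in HU.
#' @param window_low,window_high CT window in HU; `window_low < window_high`.
#'   The default (-1000, 400) spans air to soft tissue.
#' @param bone_threshold HU value at or above which voxels are zeroed out.
#' @return a [tumor_volume()] with intensities in `[0, 1]`.
#' @export
normalize_volume <- function(vol, window_low = -1000, window_high = 400,
                             bone_threshold = 400) {
  stopifnot(inherits(vol, "tumor_volume"))
  if (length(vol$intensities) == 0L) stop("empty volume")
  if (window_low >= window_high) stop("window_low must be below window_high")
  x <- vol$intensities
  x[x >= bone_threshold] <- window_low
  x <- pmin(pmax(x, window_low), window_high)
  x <- (x - window_low) / (window_high - window_low)
  tumor_volume(array(x, dim = dim(vol$intensities)), vol$voxel_spacing)
}

# Centre-crop or zero-pad one axis of an array index set.
crop_pad_index <- function(n_in, n_out) {
  if (n_in >= n_out) {
    start <- (n_in - n_out) %/% 2L + 1L
    list(src = start:(start + n_out - 1L), dst = seq_len(n_out))
  } else {
    start <- (n_out - n_in) %/% 2L + 1L
    list(src = seq_len(n_in), dst = start:(start + n_in - 1L))
  }
}

#' Standardize a tumour volume to 128 x 128 x 64
#'
#' Small volumes are centred inside a zero background; oversized volumes are
#' centre-cropped. Both operations may apply per axis.
#'
#' @param vol a [tumor_volume()] (typically normalized to `[0, 1]`).
#' @param target integer length-3 target shape.
#' @return a [tumor_volume()] of exactly the target shape.
#' @export
standardize_crop <- function(vol, target = c(128L, 128L, 64L)) {
  stopifnot(inherits(vol, "tumor_volume"))
  target <- as.integer(target)
  d <- dim(vol$intensities)
  if (all(d == target)) return(vol)
  ix <- crop_pad_index(d[1], target[1])
  iy <- crop_pad_index(d[2], target[2])
  iz <- crop_pad_index(d[3], target[3])
  out <- array(0, dim = target)
  out[ix$dst, iy$dst, iz$dst] <-
    vol$intensities[ix$src, iy$src, iz$src, drop = FALSE]
  tumor_volume(out, vol$voxel_spacing)
}

# Linear resampling of an array along one axis to n_out samples, aligning
# the first and last sample with the input extremes.
resample_axis <- function(x, axis, n_out) {
  d <- dim(x)
  n_in <- d[axis]
  if (n_in == n_out) return(x)
  pos <- if (n_in == 1L) rep(1, n_out) else
    seq(1, n_in, length.out = n_out)
  lo <- pmax(floor(pos), 1)
  hi <- pmin(lo + 1, n_in)
  w <- pos - lo
  idx_lo <- lapply(seq_along(d), function(a) if (a == axis) lo else seq_len(d[a]))
  idx_hi <- lapply(seq_along(d), function(a) if (a == axis) hi else seq_len(d[a]))
  xlo <- do.call(`[`, c(list(x), idx_lo, list(drop = FALSE)))
  xhi <- do.call(`[`, c(list(x), idx_hi, list(drop = FALSE)))
  # broadcast w along the resampled axis
  d_out <- replace(d, axis, n_out)
  perm <- c(axis, setdiff(seq_along(d), axis))
  wa <- aperm(array(w, dim = d_out[perm]), order(perm))
  (1 - wa) * xlo + wa * xhi
}

#' Trilinear resampling to 64 x 64 x 36
#'
#' Separable linear interpolation along each axis; constants are preserved
#' exactly and monotone profiles stay monotone.
#'
#' @param vol a [tumor_volume()] of shape 128 x 128 x 64.
#' @param target integer length-3 output shape.
#' @param expect_shape shape the input must have (`NULL` to skip the check).
#' @return a [tumor_volume()] of the target shape, spacing scaled accordingly.
#' @export
resize_volume <- function(vol, target = c(64L, 64L, 36L),
                          expect_shape = c(128L, 128L, 64L)) {
  stopifnot(inherits(vol, "tumor_volume"))
  d <- dim(vol$intensities)
  if (!is.null(expect_shape) && !all(d == expect_shape))
    stop(sprintf("expected a %s volume, got %s",
                 paste(expect_shape, collapse = "x"),
                 paste(d, collapse = "x")))
  target <- as.integer(target)
  x <- vol$intensities
  for (axis in 1:3) x <- resample_axis(x, axis, target[axis])
  tumor_volume(x, vol$voxel_spacing * d / target)
}

#' Assemble a 6 x 6 slice montage
#'
#' Lays out the 36 axial slices of a 64 x 64 x 36 volume on a 6 x 6 grid in
#' ascending slice order, row-major (slice k goes to row `k %/% 6`, column
#' `k %% 6`, zero-based), producing a single 384 x 384 image.
#'
#' @param vol a [tumor_volume()] of shape 64 x 64 x 36 with values in
#'   `[0, 1]`.
#' @return an object of class `montage2d`: list with `pixels`
#'   (384 x 384 matrix) and `tile_size`.
#' @export
make_montage <- function(vol) {
  stopifnot(inherits(vol, "tumor_volume"))
  d <- dim(vol$intensities)
  if (!all(d == c(64L, 64L, 36L)))
    stop(sprintf("expected a 64x64x36 volume, got %s",
                 paste(d, collapse = "x")))
  px <- matrix(0, 384, 384)
  for (k in 0:35) {
    r <- k %/% 6L; cc <- k %% 6L
    px[r * 64 + 1:64, cc * 64 + 1:64] <- vol$intensities[, , k + 1L]
  }
  structure(list(pixels = px, tile_size = 64L), class = "montage2d")
}

#' Split a montage back into its 36 ordered tiles
#'
#' Inverse of [make_montage()]: returns the tiles in ascending slice order.
#'
#' @param m a `montage2d`.
#' @return list of 36 matrices of size 64 x 64.
#' @export
split_montage <- function(m) {
  stopifnot(inherits(m, "montage2d"))
  lapply(0:35, function(k) {
    r <- k %/% 6L; cc <- k %% 6L
    m$pixels[r * 64 + 1:64, cc * 64 + 1:64]
  })
}

#' @export
print.montage2d <- function(x, ...) {
  cat(sprintf("Montage %dx%d (36 tiles of %d), range [%.3f, %.3f]\n",
              nrow(x$pixels), ncol(x$pixels), x$tile_size,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Write a montage to PNG
#'
#' @param m a `montage2d`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_montage_png <- function(m, path) {
  stopifnot(inherits(m, "montage2d"))
  png::writePNG(pmin(pmax(m$pixels, 0), 1), target = path)
  invisible(path)
}

#' Featurizer configuration
#'
#' Selects and parameterizes the montage-to-vector featurizer. The built-in
#' `"tile_stats"` featurizer computes, for each of the 36 tiles, its mean,
#' standard deviation and the configured quantiles, concatenates them in
#' tile order, and zero-pads or truncates the result to `dim` values. It is
#' deterministic and cheap; richer featurizers (e.g. a pretrained image
#' encoder) can be registered by passing a function `f(montage) -> numeric`
#' as `fun` with `name = "custom"`.
#'
#' @param name `"tile_stats"` or `"custom"`.
#' @param dim output feature length.
#' @param quantiles quantile levels per tile (tile_stats only).
#' @param fun custom featurizer function (custom only).
#' @return object of class `featurizer_config`.
#' @export
featurizer_config <- function(name = "tile_stats", dim = 768L,
                              quantiles = c(0.25, 0.5, 0.75), fun = NULL) {
  if (!name %in% c("tile_stats", "custom"))
    stop(sprintf("unknown featurizer '%s'", name))
  if (name == "custom" && !is.function(fun))
    stop("custom featurizer requires a function in 'fun'")
  structure(list(name = name, dim = as.integer(dim),
                 quantiles = quantiles, fun = fun),
            class = "featurizer_config")
}

#' Turn a montage into a fixed-length node feature vector
#'
#' @param m a `montage2d`.
#' @param featurizer a [featurizer_config()].
#' @return numeric vector of length `featurizer$dim`.
#' @export
featurize <- function(m, featurizer = featurizer_config()) {
  stopifnot(inherits(m, "montage2d"), inherits(featurizer, "featurizer_config"))
  raw <- if (featurizer$name == "tile_stats") {
    unlist(lapply(split_montage(m), function(tile) {
      c(mean(tile), stats::sd(as.vector(tile)),
        stats::quantile(tile, featurizer$quantiles, names = FALSE))
    }), use.names = FALSE)
  } else {
    as.numeric(featurizer$fun(m))
  }
  if (any(!is.finite(raw))) stop("featurizer produced non-finite values")
  d <- featurizer$dim
  if (length(raw) >= d) raw[seq_len(d)] else c(raw, rep(0, d - length(raw)))
}

#' Full image preprocessing path
#'
#' normalize -> standardize crop -> resample -> montage -> featurize, the
#' standard route from a raw tumour ROI volume to a node feature vector.
#'
#' @param vol a raw [tumor_volume()] in HU.
#' @param featurizer a [featurizer_config()].
#' @param window_low,window_high,bone_threshold see [normalize_volume()].
#' @return list with `montage` and `features`.
#' @export
preprocess_volume <- function(vol, featurizer = featurizer_config(),
                              window_low = -1000, window_high = 400,
                              bone_threshold = 400) {
  m <- make_montage(resize_volume(standardize_crop(
    normalize_volume(vol, window_low, window_high, bone_threshold))))
  list(montage = m, features = featurize(m, featurizer))
}
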