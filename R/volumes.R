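#' Create an image volume
#'
#' A volume is a 3D (single-channel) or 4D (multi-channel) intensity grid with
#' voxel dimensions in mm. Channels occupy the 4th array dimension, matching
#' the NIfTI convention used for multi-contrast and diffusion data.
#'
#' @param data numeric 3D or 4D array; all values must be finite.
#' @param voxel_size numeric length-3, mm per axis; strictly positive.
#' @param channel_names optional character vector naming the channels
#'   (e.g. `"b0"`, `"dwi_03"`); length must equal the channel count.
#' @return An object of class `n2a_volume`.
#' @export
as_volume <- function(data, voxel_size = c(1, 1, 1), channel_names = NULL) {
  if (inherits(data, "n2a_volume")) return(data)
  data <- as.array(data)
  nd <- length(dim(data))
  if (nd != 3L && nd != 4L)
    stop("volume data must be a 3D or 4D array, got ", nd, " dimensions")
  if (!all(is.finite(data)))
    stop("volume contains non-finite values")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("voxel_size must be three strictly positive numbers")
  nc <- if (nd == 4L) dim(data)[4] else 1L
  if (!is.null(channel_names) && length(channel_names) != nc)
    stop("channel_names length (", length(channel_names),
         ") does not match channel count (", nc, ")")
  structure(list(data = data, voxel_size = voxel_size,
                 channel_names = channel_names),
            class = "n2a_volume")
}

#' @export
print.n2a_volume <- function(x, ...) {
  d <- dim(x$data)
  cat("<n2a_volume> ", paste(spatial_shape(x), collapse = " x "),
      " voxels, ", n_channels(x), " channel(s), voxel size ",
      paste(signif(x$voxel_size, 3), collapse = " x "), " mm\n", sep = "")
  invisible(x)
}

#' Spatial shape of a volume, mask, or array
#' @param x a volume, mask, or array.
#' @return integer vector of length 3.
#' @export
spatial_shape <- function(x) {
  d <- if (inherits(x, c("n2a_volume", "n2a_mask"))) dim(x$data) else dim(x)
  as.integer(d[1:3])
}

#' Number of channels of a volume
#' @param x a volume or array.
#' @return integer channel count (1 for 3D data).
#' @export
n_channels <- function(x) {
  d <- if (inherits(x, "n2a_volume")) dim(x$data) else dim(x)
  if (length(d) == 4L) as.integer(d[4]) else 1L
}

# Always-4D view of the intensity array (X, Y, Z, C).
vol_data4 <- function(x) {
  a <- if (inherits(x, "n2a_volume")) x$data else x
  if (length(dim(a)) == 3L) dim(a) <- c(dim(a), 1L)
  a
}

# Rebuild a volume like `template` from a (possibly 4D) array, dropping the
# channel dimension again if the template was 3D.
vol_like <- function(data, template) {
  if (length(dim(template$data)) == 3L && length(dim(data)) == 4L &&
      dim(data)[4] == 1L)
    dim(data) <- dim(data)[1:3]
  as_volume(data, template$voxel_size, template$channel_names)
}

#' Create a brain mask
#'
#' @param data logical (or coercible) 3D array; must contain at least one
#'   `TRUE` voxel.
#' @return An object of class `n2a_mask`.
#' @export
as_mask <- function(data) {
  if (inherits(data, "n2a_mask")) return(data)
  data <- as.array(data)
  if (length(dim(data)) == 4L && dim(data)[4] == 1L) dim(data) <- dim(data)[1:3]
  if (length(dim(data)) != 3L)
    stop("mask must be a 3D array")
  storage.mode(data) <- "logical"
  if (!any(data)) stop("mask has no TRUE voxels")
  structure(list(data = data), class = "n2a_mask")
}

#' @export
print.n2a_mask <- function(x, ...) {
  cat("<n2a_mask> ", paste(dim(x$data), collapse = " x "), " voxels, ",
      sum(x$data), " in mask\n", sep = "")
  invisible(x)
}

#' Bundle co-registered noisy repetitions with their brain mask
#'
#' The repetition set is the unit of denoising: n volumes of the same anatomy
#' and contrast that ideally differ only in their noise realisation.
#'
#' @param repetitions list of volumes sharing spatial shape and channel count.
#' @param mask a brain mask matching the shared spatial shape.
#' @param require_pair if `TRUE` (default) demand n >= 2, the minimum for any
#'   self-supervised denoising entry point.
#' @return An object of class `n2a_repetition_set` with elements
#'   `repetitions`, `mask`, `n`.
#' @export
repetition_set <- function(repetitions, mask, require_pair = TRUE) {
  repetitions <- lapply(repetitions, as_volume)
  n <- length(repetitions)
  if (require_pair && n < 2L)
    stop("at least 2 repetitions are required (got ", n, ")")
  if (n < 1L) stop("empty repetition list")
  mask <- as_mask(mask)
  ss <- spatial_shape(repetitions[[1]])
  nc <- n_channels(repetitions[[1]])
  for (r in repetitions) {
    if (!identical(spatial_shape(r), ss) || n_channels(r) != nc)
      stop("all repetitions must share spatial shape and channel count")
  }
  if (!identical(spatial_shape(mask), ss))
    stop("mask shape does not match repetitions")
  structure(list(repetitions = repetitions, mask = mask, n = n),
            class = "n2a_repetition_set")
}

#' @export
print.n2a_repetition_set <- function(x, ...) {
  cat("<n2a_repetition_set> n = ", x$n, ", ",
      paste(spatial_shape(x$mask), collapse = " x "), " voxels\n", sep = "")
  invisible(x)
}

#' Per-channel standardization parameters from masked voxels
#'
#' Computes the population mean and population standard deviation of the
#' intensities inside the brain mask, independently for every channel. These
#' parameters drive the affine standardization applied before network
#' training and inverted afterwards.
#'
#' @param volume a volume.
#' @param mask a brain mask for the volume.
#' @return An object of class `n2a_standardization` with numeric vectors
#'   `mean` and `std` (one entry per channel).
#' @export
compute_standardization <- function(volume, mask) {
  volume <- as_volume(volume); mask <- as_mask(mask)
  a <- vol_data4(volume)
  if (!identical(spatial_shape(volume), spatial_shape(mask)))
    stop("mask shape does not match volume")
  nc <- dim(a)[4]
  m <- s <- numeric(nc)
  idx <- which(mask$data)
  nvox <- prod(spatial_shape(volume))
  for (c in seq_len(nc)) {
    v <- a[idx + (c - 1) * nvox]
    m[c] <- mean(v)
    s[c] <- sqrt(mean((v - m[c])^2))  # population SD
    if (s[c] == 0)
      stop("channel ", c, " is constant inside the mask (zero variance)")
  }
  structure(list(mean = m, std = s), class = "n2a_standardization")
}

#' Standardize (or de-standardize) a volume
#'
#' Forward: `(v - mean) / std` per channel. Inverse: `v * std + mean`.
#' The same affine map is applied to every voxel, inside and outside the
#' mask, so the two directions compose to the identity.
#'
#' @param volume a volume.
#' @param params standardization parameters from [compute_standardization()].
#' @param inverse if `TRUE`, apply the inverse map.
#' @return A volume of the same shape.
#' @export
standardize <- function(volume, params, inverse = FALSE) {
  volume <- as_volume(volume)
  a <- vol_data4(volume)
  nc <- dim(a)[4]
  if (length(params$mean) != nc || length(params$std) != nc)
    stop("standardization has ", length(params$mean),
         " channel(s) but volume has ", nc)
  for (c in seq_len(nc)) {
    if (inverse) {
      a[, , , c] <- a[, , , c] * params$std[c] + params$mean[c]
    } else {
      a[, , , c] <- (a[, , , c] - params$mean[c]) / params$std[c]
    }
  }
  vol_like(a, volume)
}

#' Read a NIfTI volume
#'
#' The 4th NIfTI dimension, when present, is interpreted as the channel
#' dimension; voxel sizes come from the header.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param channel_names optional channel labels.
#' @return A volume.
#' @export
read_volume <- function(path, channel_names = NULL) {
  img <- RNifti::readNifti(path)
  vox <- RNifti::pixdim(img)[1:3]
  arr <- as.array(img)
  arr <- structure(as.vector(arr), dim = dim(arr))  # drop NIfTI attributes
  as_volume(arr, voxel_size = vox, channel_names = channel_names)
}

#' Write a volume to NIfTI
#' @param volume a volume.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  volume <- as_volume(volume)
  img <- RNifti::asNifti(volume$data)
  nd <- length(dim(volume$data))
  RNifti::pixdim(img) <- c(volume$voxel_size, rep(1, nd - 3L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI brain mask
#' @param path path to a NIfTI file; nonzero voxels become mask voxels.
#' @return A mask.
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img) != 0
  as_mask(structure(as.vector(arr), dim = dim(arr)))
}

#' Write a brain mask to NIfTI
#' @param mask a mask.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  mask <- as_mask(mask)
  img <- RNifti::asNifti(array(as.integer(mask$data), dim = dim(mask$data)))
  RNifti::writeNifti(img, path)
  invisible(path)
}

# Masked values of one channel as a plain vector.
masked_values <- function(volume, mask, channel = 1L) {
  a <- vol_data4(volume)
  idx <- which(as_mask(mask)$data)
  a[idx + (channel - 1L) * prod(dim(a)[1:3])]
}

# Voxelwise mean of a list of volumes.
average_volumes <- function(volumes) {
  stopifnot(length(volumes) >= 1L)
  acc <- vol_data4(volumes[[1]])
  if (length(volumes) > 1L)
    for (k in 2:length(volumes)) acc <- acc + vol_data4(volumes[[k]])
  vol_like(acc / length(volumes), as_volume(volumes[[1]]))
}
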