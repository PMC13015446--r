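#' Plan a covering block grid
#'
#' Chooses, per axis, the smallest number of blocks `k = ceiling(extent /
#' block_extent)` that covers the volume, with origins spread as evenly as
#' possible from 0 to `extent - block_extent` (0-based, half-open intervals).
#' Neighbouring blocks overlap whenever `k * block_extent > extent`; the
#' overlapped voxels are averaged on reassembly. A block extent larger than
#' the volume extent is clamped to the volume extent.
#'
#' @param spatial_shape integer length-3 volume extents in voxels.
#' @param block_shape integer length 1 or 3, block extents in voxels.
#' @param channel_count channels the blocks will carry (metadata only).
#' @return An object of class `n2a_block_grid` with `block_shape`, a matrix
#'   `origins` (one 0-based corner per row), and `channel_count`.
#' @export
plan_blocks <- function(spatial_shape, block_shape, channel_count = 1L) {
  spatial_shape <- as.integer(spatial_shape)
  if (length(block_shape) == 1L) block_shape <- rep(block_shape, 3L)
  block_shape <- as.integer(block_shape)
  if (length(spatial_shape) != 3L || length(block_shape) != 3L)
    stop("spatial_shape and block_shape must have length 3")
  if (any(spatial_shape <= 0L) || any(block_shape <= 0L))
    stop("shapes must be strictly positive")
  block_shape <- pmin(block_shape, spatial_shape)  # clamp, never pad
  per_axis <- lapply(1:3, function(ax) {
    extent <- spatial_shape[ax]; b <- block_shape[ax]
    k <- as.integer(ceiling(extent / b))
    if (k == 1L) 0L
    else as.integer(round(seq(0, extent - b, length.out = k)))
  })
  origins <- as.matrix(expand.grid(per_axis[[1]], per_axis[[2]], per_axis[[3]]))
  dimnames(origins) <- NULL
  structure(list(block_shape = block_shape, origins = origins,
                 channel_count = as.integer(channel_count),
                 spatial_shape = spatial_shape),
            class = "n2a_block_grid")
}

#' @export
print.n2a_block_grid <- function(x, ...) {
  cat("<n2a_block_grid> ", nrow(x$origins), " block(s) of ",
      paste(x$block_shape, collapse = " x "), " voxels over ",
      paste(x$spatial_shape, collapse = " x "), "\n", sep = "")
  invisible(x)
}

check_grid <- function(grid, spatial_shape) {
  if (!inherits(grid, "n2a_block_grid")) stop("not a block grid")
  if (!identical(as.integer(spatial_shape), grid$spatial_shape))
    stop("grid was planned for shape ",
         paste(grid$spatial_shape, collapse = "x"), ", volume is ",
         paste(spatial_shape, collapse = "x"))
  hi <- sweep(grid$origins, 2, grid$block_shape, "+")
  if (any(grid$origins < 0) || any(t(hi) > spatial_shape))
    stop("grid contains blocks outside the volume bounds")
  invisible(TRUE)
}

#' Extract blocks from a volume
#'
#' Each block is a copy of the half-open region
#' `[origin, origin + block_shape)` across all channels.
#'
#' @param volume a volume (or 3D/4D array).
#' @param grid a block grid from [plan_blocks()].
#' @return List of 4D arrays `(bx, by, bz, channels)`, one per grid origin.
#' @export
extract_blocks <- function(volume, grid) {
  volume <- as_volume(volume)
  check_grid(grid, spatial_shape(volume))
  a <- vol_data4(volume)
  bs <- grid$block_shape
  lapply(seq_len(nrow(grid$origins)), function(i) {
    o <- grid$origins[i, ]
    a[o[1] + seq_len(bs[1]), o[2] + seq_len(bs[2]), o[3] + seq_len(bs[3]), ,
      drop = FALSE]
  })
}

#' Reassemble blocks into a volume, averaging overlaps
#'
#' Every output voxel is the arithmetic mean of its value over all blocks
#' that contain it, so `assemble_blocks(extract_blocks(v, g), g)` recovers
#' `v` exactly for any grid.
#'
#' @param blocks list of 4D block arrays, one per grid origin.
#' @param grid the block grid the blocks came from.
#' @param voxel_size voxel size for the output volume.
#' @return A volume.
#' @export
assemble_blocks <- function(blocks, grid, voxel_size = c(1, 1, 1)) {
  if (length(blocks) != nrow(grid$origins))
    stop("got ", length(blocks), " blocks for ", nrow(grid$origins),
         " grid origins")
  ss <- grid$spatial_shape
  nc <- dim(vol_data4(blocks[[1]]))[4]
  acc <- array(0, c(ss, nc))
  cnt <- array(0L, ss)
  bs <- grid$block_shape
  for (i in seq_along(blocks)) {
    b <- vol_data4(blocks[[i]])
    if (!identical(dim(b)[1:3], bs))
      stop("block ", i, " has shape ", paste(dim(b)[1:3], collapse = "x"),
           ", expected ", paste(bs, collapse = "x"))
    xi <- grid$origins[i, 1] + seq_len(bs[1])
    yi <- grid$origins[i, 2] + seq_len(bs[2])
    zi <- grid$origins[i, 3] + seq_len(bs[3])
    acc[xi, yi, zi, ] <- acc[xi, yi, zi, , drop = FALSE] + b
    cnt[xi, yi, zi] <- cnt[xi, yi, zi] + 1L
  }
  if (any(cnt == 0L)) stop("grid does not cover the volume")
  for (c in seq_len(nc)) acc[, , , c] <- acc[, , , c] / cnt
  if (nc == 1L) dim(acc) <- ss
  as_volume(acc, voxel_size = voxel_size)
}

#' Serialize a block grid to JSON
#' @param grid a block grid.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
grid_to_json <- function(grid, path = NULL) {
  obj <- list(block_shape = grid$block_shape,
              spatial_shape = grid$spatial_shape,
              channel_count = grid$channel_count,
              origins = grid$origins)
  js <- jsonlite::toJSON(obj, auto_unbox = FALSE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Deserialize a block grid from JSON
#' @param json a JSON string or path to a JSON file.
#' @return A block grid.
#' @export
grid_from_json <- function(json) {
  if (length(json) == 1L && file.exists(json)) json <- readLines(json)
  obj <- jsonlite::fromJSON(paste(json, collapse = ""))
  g <- plan_blocks(obj$spatial_shape, obj$block_shape, obj$channel_count)
  g$origins <- matrix(as.integer(obj$origins), ncol = 3)
  g
}
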