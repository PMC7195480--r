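#' Multi-channel 3D image stack
#'
#' Container for a multiphoton z-stack: one 3D array per channel, indexed
#' `[z, y, x]`, plus the physical voxel size `(dz, dy, dx)` in um. Channel
#' roles are carried in the channel names; `CFP` and `YFP` must both be
#' present for ratiometric use and `RED` typically holds the angiogram or
#' amyloid-plaque label.
#'
#' Voxel `(z, y, x)` (1-based) is centred at `((z-0.5) dz, (y-0.5) dy,
#' (x-0.5) dx)` um; all physical measurements in the package use this
#' convention.
#'
#' @param channels Named list of 3D numeric arrays of identical dimension,
#'   e.g. `list(CFP = ..., YFP = ..., RED = ...)`. Intensities must be
#'   non-negative.
#' @param voxel_size Numeric length-3 vector `(dz, dy, dx)` in um, all > 0.
#' @param metadata Optional list of acquisition notes.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(channels, voxel_size, metadata = list()) {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels))))
    abort("`channels` must be a named list of 3D arrays.")
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    abort("Every channel must be a 3D array (z, y, x).")
  if (length(unique(lapply(dims, as.integer))) != 1L)
    abort("All channels must share identical dimensions.")
  if (!is.numeric(voxel_size) || length(voxel_size) != 3L ||
      any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    abort("`voxel_size` must be three positive numbers (dz, dy, dx) in um.")
  structure(
    list(channels = channels, voxel_size = as.numeric(voxel_size),
         metadata = metadata, qc = list()),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<image_stack> %d x %d x %d (z,y,x), channels: %s\n",
              d[1], d[2], d[3], paste(names(x$channels), collapse = ", ")))
  cat(sprintf("  voxel size %.3g x %.3g x %.3g um\n",
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

#' @rdname image_stack
#' @param x An `image_stack`.
#' @export
stack_dim <- function(x) {
  stopifnot(inherits(x, "image_stack"))
  dim(x$channels[[1]])
}

# Return a channel array, erroring with the role name if absent.
get_channel <- function(stack, role) {
  stopifnot(inherits(stack, "image_stack"))
  if (!role %in% names(stack$channels))
    abort(sprintf("Stack has no '%s' channel.", role),
          class = "mitofret_missing_channel")
  stack$channels[[role]]
}

#' Labeled mitochondrion objects in a 3D volume
#'
#' @param labels 3D integer array; 0 is background, `k > 0` marks object `k`.
#'   Labels must be consecutive `1..object_count`.
#' @param voxel_size `(dz, dy, dx)` in um.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, voxel_size) {
  stopifnot(length(dim(labels)) == 3L)
  n <- max(0L, max(labels))
  structure(
    list(labels = labels, object_count = as.integer(n),
         voxel_size = as.numeric(voxel_size)),
    class = "label_volume"
  )
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_volume> %d object(s) in %d x %d x %d (z,y,x)\n",
              x$object_count, d[1], d[2], d[3]))
  invisible(x)
}

#' Read / write a multi-page TIFF as an image stack
#'
#' Thin I/O layer over the `tiff` package. Pages are read in acquisition
#' order and deinterleaved into channels: page `i` belongs to channel
#' `((i-1) mod n_channels) + 1`. Channel roles and voxel size are supplied by
#' the caller (TIFF files rarely carry trustworthy physical metadata).
#'
#' @param path TIFF file path.
#' @param channel_roles Character vector of channel names in page order,
#'   e.g. `c("CFP", "YFP", "RED")`.
#' @param voxel_size `(dz, dy, dx)` in um.
#' @return An [image_stack()].
#' @export
read_stack_tiff <- function(path, channel_roles, voxel_size) {
  if (!requireNamespace("tiff", quietly = TRUE))
    abort("Package 'tiff' is required to read TIFF stacks.")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  nc <- length(channel_roles)
  if (length(pages) %% nc != 0)
    abort("Page count is not a multiple of the number of channels.")
  nz <- length(pages) / nc
  chans <- lapply(seq_len(nc), function(ci) {
    slices <- pages[seq(ci, length(pages), by = nc)]
    arr <- array(0, dim = c(nz, nrow(slices[[1]]), ncol(slices[[1]])))
    for (z in seq_len(nz)) arr[z, , ] <- slices[[z]]
    arr
  })
  names(chans) <- channel_roles
  image_stack(chans, voxel_size)
}

#' @rdname read_stack_tiff
#' @param x An [image_stack()] or [label_volume()] to write; channels/labels
#'   are interleaved per slice. Intensities are scaled to the 16-bit range.
#' @export
write_stack_tiff <- function(x, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    abort("Package 'tiff' is required to write TIFF stacks.")
  arrs <- if (inherits(x, "image_stack")) x$channels else list(x$labels)
  nz <- dim(arrs[[1]])[1]
  top <- max(1, max(vapply(arrs, max, 1)))
  pages <- list()
  for (z in seq_len(nz))
    for (a in arrs)
      pages[[length(pages) + 1L]] <- a[z, , ] / top
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}
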