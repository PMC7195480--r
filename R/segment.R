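# Neighbor offsets for 6- or 26-connectivity in (z, y, x).
connectivity_offsets <- function(connectivity) {
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  else if (connectivity != 26) abort("`connectivity` must be 6 or 26.")
  offs
}

#' Label connected components of a 3D mask
#'
#' Vectorised flood fill over the foreground voxels of a 3D logical array
#' under 6- or 26-connectivity. No installed package labels 3D arrays, so the
#' labeling is done here; it is oracle-checked against an independent
#' per-voxel flood fill in the test-suite.
#'
#' @param mask 3D logical array `(z, y, x)`.
#' @param connectivity 6 (faces) or 26 (faces, edges, corners; default).
#' @return 3D integer array of labels (0 = background, objects numbered
#'   `1..n` in first-encounter order).
#' @export
label_components_3d <- function(mask, connectivity = 26) {
  dims <- dim(mask)
  stopifnot(length(dims) == 3L)
  offs <- connectivity_offsets(connectivity)
  labels <- array(0L, dims)
  fg <- which(mask)
  if (length(fg) == 0) return(labels)
  cur <- 0L
  nzy <- dims[1] * dims[2]
  for (i in fg) {
    if (labels[i] > 0L) next
    cur <- cur + 1L
    labels[i] <- cur
    frontier <- arrayInd(i, dims)
    while (nrow(frontier) > 0) {
      nb <- do.call(rbind, lapply(seq_len(nrow(offs)), function(k)
        sweep(frontier, 2, offs[k, ], "+")))
      keep <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
              nb[, 2] >= 1 & nb[, 2] <= dims[2] &
              nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nb <- nb[keep, , drop = FALSE]
      lin <- nb[, 1] + (nb[, 2] - 1L) * dims[1] + (nb[, 3] - 1L) * nzy
      lin <- unique(lin[mask[lin] & labels[lin] == 0L])
      if (length(lin) == 0) break
      labels[lin] <- cur
      frontier <- arrayInd(lin, dims)
    }
  }
  labels
}

# Keep only components whose voxel count falls in [min_vox, max_vox];
# renumber survivors 1..N preserving order.
filter_by_size <- function(labels, min_vox, max_vox) {
  if (max(labels) == 0L) return(labels)
  counts <- tabulate(labels[labels > 0L])
  keep <- which(counts >= min_vox & counts <= max_vox)
  map <- integer(length(counts))
  map[keep] <- seq_along(keep)
  out <- labels
  out[out > 0L] <- map[out[out > 0L]]
  out
}

#' Segment mitochondria by slice-wise adaptive thresholding
#'
#' Works on the total indicator signal (CFP + YFP by default, so detection is
#' not biased towards low- or high-calcium objects). Each z-slice is
#' binarised by a local-mean adaptive threshold: a pixel is in the detection
#' support when its value exceeds both the mean of its
#' `block_size x block_size` neighborhood plus `offset`, and a per-slice
#' noise floor (`median + noise_floor_k * MAD`, which suppresses the speckle
#' that a bare local-mean rule passes on background regions).
#'
#' The mean filter applied upstream dilates every object's support by its
#' radius, so the support is refined before labeling. When the unsmoothed
#' (background-subtracted) stack is supplied via `intensity_stack`, support
#' pixels are kept only where the raw intensity also clears its own per-slice
#' noise floor -- a two-scale rule that reproduces object boundaries exactly
#' on clean data. Without `intensity_stack`, the support is instead eroded by
#' `erode_px` pixels per slice. Components are then labeled in 3D, those
#' outside the physical size window removed, and survivors renumbered
#' `1..N`.
#'
#' All threshold ingredients (local mean, median, MAD) scale linearly with
#' intensity, so at `offset = 0` the segmentation is invariant to multiplying
#' both channels by a common positive factor.
#'
#' @param stack A background-subtracted, smoothed [image_stack()].
#' @param block_size Odd integer >= 3; side of the local-mean window (px).
#' @param offset Additive threshold offset (intensity units; default 0).
#' @param min_size,max_size Object volume window in um^3 (defaults 0.2 and
#'   500); converted to voxel counts via the stack's voxel size.
#' @param connectivity 3D connectivity for labeling, 6 or 26 (default).
#' @param noise_floor_k Multiplier of the per-slice MAD for the noise floors
#'   (default 4). Set to 0 to disable them.
#' @param intensity_stack Optional background-subtracted, unsmoothed
#'   [image_stack()] used to refine the smoothed detection support.
#' @param erode_px Per-slice erosion radius used only when `intensity_stack`
#'   is absent (default 2, matching the default smoothing radius).
#' @param channel `"CFP+YFP"` (default), or a single channel name.
#' @return A [label_volume()].
#' @export
segment_mitochondria <- function(stack, block_size = 51, offset = 0,
                                 min_size = 0.2, max_size = 500,
                                 connectivity = 26, noise_floor_k = 4,
                                 intensity_stack = NULL, erode_px = 2,
                                 channel = "CFP+YFP") {
  stopifnot(inherits(stack, "image_stack"))
  if (block_size < 3 || block_size %% 2 == 0)
    abort("`block_size` must be an odd integer >= 3.",
          class = "mitofret_config_error")
  seg_channel <- function(stk) {
    if (identical(channel, "CFP+YFP"))
      get_channel(stk, "CFP") + get_channel(stk, "YFP")
    else get_channel(stk, channel)
  }
  img <- seg_channel(stack)
  raw <- if (!is.null(intensity_stack)) seg_channel(intensity_stack)
  dims <- dim(img)
  mask <- array(FALSE, dims)
  r <- (block_size - 1L) / 2L
  brush <- if (erode_px > 0)
    EBImage::makeBrush(2L * erode_px + 1L, shape = "box") else NULL
  for (z in seq_len(dims[1])) {
    s <- img[z, , ]
    lm <- mean_filter_2d(s, r)
    floor_z <- if (noise_floor_k > 0)
      median(s) + noise_floor_k * mad(s) else -Inf
    m <- (s > lm + offset) & (s > floor_z)
    if (!is.null(raw)) {
      rs <- raw[z, , ]
      raw_floor <- if (noise_floor_k > 0)
        median(rs) + noise_floor_k * mad(rs) else 0
      m <- m & (rs > raw_floor)
    } else if (!is.null(brush) && any(m)) {
      m <- as.matrix(EBImage::erode(m * 1, brush)) > 0
    }
    mask[z, , ] <- m
  }
  labels <- label_components_3d(mask, connectivity)
  vox_vol <- prod(stack$voxel_size)
  labels <- filter_by_size(labels, min_vox = min_size / vox_vol,
                           max_vox = max_size / vox_vol)
  label_volume(labels, stack$voxel_size)
}

# Edge voxels: mask voxels 6-adjacent to background (array borders count as
# background). Returns a matrix of (z, y, x) indices.
mask_edge_voxels <- function(mask) {
  dims <- dim(mask)
  pad <- array(FALSE, dims + 2L)
  pad[2:(dims[1] + 1), 2:(dims[2] + 1), 2:(dims[3] + 1)] <- mask
  core <- pad[2:(dims[1] + 1), 2:(dims[2] + 1), 2:(dims[3] + 1)]
  nb_bg <- !pad[1:dims[1], 2:(dims[2] + 1), 2:(dims[3] + 1)] |
           !pad[3:(dims[1] + 2), 2:(dims[2] + 1), 2:(dims[3] + 1)] |
           !pad[2:(dims[1] + 1), 1:dims[2], 2:(dims[3] + 1)] |
           !pad[2:(dims[1] + 1), 3:(dims[2] + 2), 2:(dims[3] + 1)] |
           !pad[2:(dims[1] + 1), 2:(dims[2] + 1), 1:dims[3]] |
           !pad[2:(dims[1] + 1), 2:(dims[2] + 1), 3:(dims[3] + 2)]
  arrayInd(which(core & nb_bg), dims)
}

#' Extract amyloid-plaque masks from a stack
#'
#' Plaques are either supplied as a manual mask (mirroring manual extraction
#' from the z-stacks) or segmented from the plaque-label (`RED`) channel by a
#' global threshold. Each plaque's edge voxels (mask voxels 6-adjacent to
#' background) are precomputed for centroid-to-edge distance measurements.
#'
#' @param stack An [image_stack()]; required for `mode = "threshold"`.
#' @param mode `"threshold"` (segment the RED channel) or `"mask"` (use the
#'   supplied array).
#' @param mask For `mode = "mask"`: 3D logical or integer label array.
#' @param threshold Intensity cutoff for `mode = "threshold"`; defaults to
#'   the midpoint between the channel median and maximum.
#' @param min_size Minimum plaque volume in um^3 (default 10).
#' @return A `plaque_set`: labels array, number of plaques, per-plaque edge
#'   voxel table (`plaque_id`, voxel indices and um coordinates), voxel size.
#' @export
extract_plaques <- function(stack = NULL, mode = c("threshold", "mask"),
                            mask = NULL, threshold = NULL, min_size = 10) {
  mode <- match.arg(mode)
  if (mode == "mask") {
    if (is.null(mask)) abort("`mask` is required for mode = 'mask'.")
    if (is.null(stack)) abort("`stack` is required to supply the voxel size.")
    voxel_size <- stack$voxel_size
    labels <- if (is.logical(mask)) label_components_3d(mask, 26)
              else { storage.mode(mask) <- "integer"; mask }
  } else {
    if (is.null(stack)) abort("`stack` is required for mode = 'threshold'.")
    red <- get_channel(stack, "RED")
    voxel_size <- stack$voxel_size
    if (is.null(threshold)) threshold <- (median(red) + max(red)) / 2
    fg <- red > threshold
    labels <- label_components_3d(fg, 26)
    labels <- filter_by_size(labels, min_vox = min_size / prod(voxel_size),
                             max_vox = Inf)
  }
  n <- max(0L, max(labels))
  edges <- if (n > 0) {
    purrr::map_dfr(seq_len(n), function(k) {
      e <- mask_edge_voxels(labels == k)
      tibble(plaque_id = k, z = e[, 1], y = e[, 2], x = e[, 3],
             z_um = (e[, 1] - 0.5) * voxel_size[1],
             y_um = (e[, 2] - 0.5) * voxel_size[2],
             x_um = (e[, 3] - 0.5) * voxel_size[3])
    })
  } else {
    tibble(plaque_id = integer(), z = integer(), y = integer(),
           x = integer(), z_um = numeric(), y_um = numeric(),
           x_um = numeric())
  }
  structure(
    list(labels = labels, n_plaques = as.integer(n), edges = edges,
         voxel_size = as.numeric(voxel_size)),
    class = "plaque_set"
  )
}

#' @export
print.plaque_set <- function(x, ...) {
  cat(sprintf("<plaque_set> %d plaque(s)\n", x$n_plaques))
  invisible(x)
}

#' Per-plaque volumes and centroids
#'
#' @param plaques A `plaque_set` from [extract_plaques()].
#' @return Tibble with one row per plaque: voxel count, volume (um^3) and
#'   centroid in um.
#' @export
plaque_table <- function(plaques) {
  stopifnot(inherits(plaques, "plaque_set"))
  if (plaques$n_plaques == 0)
    return(tibble(plaque_id = integer(), voxel_count = integer(),
                  volume_um3 = numeric(), centroid_z_um = numeric(),
                  centroid_y_um = numeric(), centroid_x_um = numeric()))
  vs <- plaques$voxel_size
  purrr::map_dfr(seq_len(plaques$n_plaques), function(k) {
    idx <- arrayInd(which(plaques$labels == k), dim(plaques$labels))
    tibble(
      plaque_id = k, voxel_count = nrow(idx),
      volume_um3 = nrow(idx) * prod(vs),
      centroid_z_um = mean((idx[, 1] - 0.5) * vs[1]),
      centroid_y_um = mean((idx[, 2] - 0.5) * vs[2]),
      centroid_x_um = mean((idx[, 3] - 0.5) * vs[3])
    )
  })
}
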