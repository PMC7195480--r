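#' Circularity from perimeter and area
#'
#' `perimeter^2 / (4 * pi * area)`: equals 1 for a perfect circle, larger for
#' less circular shapes (no inversion to the reciprocal convention).
#'
#' @param perimeter,area Positive numbers in consistent units.
#' @return Dimensionless circularity.
#' @export
circularity <- function(perimeter, area) {
  if (any(area <= 0) || any(perimeter <= 0))
    abort("`perimeter` and `area` must be > 0.")
  perimeter^2 / (4 * pi * area)
}

# Boundary pixels: object pixels 4-adjacent to background (image border
# counts as background).
boundary_pixels_2d <- function(mask) {
  d <- dim(mask)
  pad <- matrix(FALSE, d[1] + 2L, d[2] + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1)] <- mask
  core <- pad[2:(d[1] + 1), 2:(d[2] + 1)]
  core & (!pad[1:d[1], 2:(d[2] + 1)] | !pad[3:(d[1] + 2), 2:(d[2] + 1)] |
          !pad[2:(d[1] + 1), 1:d[2]] | !pad[2:(d[1] + 1), 3:(d[2] + 2)])
}

# Exposed pixel edges ("cracks") between object and background.
crack_count_2d <- function(mask) {
  d <- dim(mask)
  pad <- matrix(FALSE, d[1] + 2L, d[2] + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1)] <- mask
  core <- pad[2:(d[1] + 1), 2:(d[2] + 1)]
  sum(core & !pad[1:d[1], 2:(d[2] + 1)]) +
    sum(core & !pad[3:(d[1] + 2), 2:(d[2] + 1)]) +
    sum(core & !pad[2:(d[1] + 1), 1:d[2]]) +
    sum(core & !pad[2:(d[1] + 1), 3:(d[2] + 2)])
}

#' Area, perimeter and circularity of a 2D object mask
#'
#' Implements the pixel-count conventions used for hand-drawn mitochondrion
#' ROIs: area is the number of pixels in the ROI times the pixel area;
#' perimeter is, by default, the number of pixels outlining the ROI (object
#' pixels 4-adjacent to background) times the pixel side. Pixel counting is
#' biased on oblique boundaries (a diagonal staircase step contributes one
#' pixel for sqrt(2) of true length), so a crack-length estimator (exposed
#' pixel edges scaled by pi/4, a two-direction Cauchy-Crofton formula that
#' is asymptotically unbiased for smooth convex shapes) is offered as
#' `perimeter = "crofton"`. Circularity is
#' `perimeter^2 / (4 pi area)` under either convention.
#'
#' Objects so small that every pixel is a boundary pixel are flagged
#' below-resolution: the pixel-count convention biases their circularity
#' (a single pixel gives `1/(4 pi)`).
#'
#' @param mask 2D logical matrix; non-empty, assumed connected.
#' @param pixel_size Pixel side length in um (isotropic; default 1).
#' @param perimeter `"pixel_count"` (default, the literal outlining-pixel
#'   convention) or `"crofton"`.
#' @return One-row tibble: `n_pixels`, `area_um2`, `perimeter_um`,
#'   `circularity`, `below_resolution`, `perimeter_method`.
#' @export
measure_morphology <- function(mask, pixel_size = 1,
                               perimeter = c("pixel_count", "crofton")) {
  perimeter <- match.arg(perimeter)
  stopifnot(is.matrix(mask))
  mask <- mask > 0
  n_px <- sum(mask)
  if (n_px == 0)
    abort("Mask is empty.", class = "mitofret_empty_mask")
  bnd <- boundary_pixels_2d(mask)
  per_px <- if (perimeter == "pixel_count") sum(bnd)
            else crack_count_2d(mask) * pi / 4
  area <- n_px * pixel_size^2
  per <- per_px * pixel_size
  tibble(
    n_pixels = n_px,
    area_um2 = area,
    perimeter_um = per,
    circularity = circularity(per, area),
    below_resolution = sum(bnd) == n_px,
    perimeter_method = perimeter
  )
}

#' Morphology of labeled objects on selected slices
#'
#' Measures every requested (object, slice) ROI: the 2D cross-section of the
#' labeled object in that z-slice.
#'
#' @param labels A [label_volume()].
#' @param rois Tibble with `object_id` and `slice_z` (e.g. from
#'   [select_analysis_slices()]); `NULL` measures every object in every slice
#'   it appears in.
#' @param pixel_size Lateral pixel side in um; defaults to the label volume's
#'   dy (isotropic in-plane pixels assumed).
#' @inheritParams measure_morphology
#' @return Tibble with one row per ROI (object_id, slice_z + morphology).
#' @export
morphology_table <- function(labels, rois = NULL, pixel_size = NULL,
                             perimeter = c("pixel_count", "crofton")) {
  stopifnot(inherits(labels, "label_volume"))
  perimeter <- match.arg(perimeter)
  if (is.null(pixel_size)) pixel_size <- labels$voxel_size[2]
  if (is.null(rois)) {
    idx <- which(labels$labels > 0L)
    co <- arrayInd(idx, dim(labels$labels))
    rois <- dplyr::distinct(tibble(object_id = labels$labels[idx],
                                   slice_z = co[, 1]))
  }
  check_columns(rois, c("object_id", "slice_z"), "`rois`")
  purrr::pmap_dfr(rois[c("object_id", "slice_z")], function(object_id,
                                                            slice_z) {
    m <- labels$labels[slice_z, , ] == object_id
    if (!any(m)) return(NULL)
    dplyr::bind_cols(
      tibble(object_id = object_id, slice_z = slice_z),
      measure_morphology(m, pixel_size, perimeter)
    )
  })
}

#' Sample mitochondrion ROIs from slices in a depth window
#'
#' Restricts to z-slices whose depth `(z - 1) * dz` lies inside
#' `depth_range` (inclusive), enumerates the (object, slice) ROIs present
#' there, and draws a reproducible random sample.
#'
#' @param labels A [label_volume()].
#' @param depth_range `c(min, max)` depth window in um (default 30-60).
#' @param n Number of ROIs to sample (default 125). If fewer are available,
#'   all are returned with a warning.
#' @param seed Optional integer seed for a reproducible sample.
#' @return Tibble: `object_id`, `slice_z`, `depth_um`, `n_pixels`.
#' @export
select_analysis_slices <- function(labels, depth_range = c(30, 60), n = 125,
                                   seed = NULL) {
  stopifnot(inherits(labels, "label_volume"))
  dz <- labels$voxel_size[1]
  nz <- dim(labels$labels)[1]
  depth <- (seq_len(nz) - 1) * dz
  zs <- which(depth >= depth_range[1] & depth <= depth_range[2])
  if (length(zs) == 0)
    abort("No slices fall inside the requested depth range.",
          class = "mitofret_depth_error")
  cand <- purrr::map_dfr(zs, function(z) {
    lab <- labels$labels[z, , ]
    ids <- sort(unique(lab[lab > 0L]))
    if (length(ids) == 0) return(NULL)
    tibble(object_id = ids, slice_z = z, depth_um = depth[z],
           n_pixels = as.integer(tabulate(lab[lab > 0L])[ids]))
  })
  if (nrow(cand) == 0)
    return(cand)
  if (nrow(cand) <= n) {
    if (nrow(cand) < n)
      warn(sprintf("Only %d ROIs available (requested %d); returning all.",
                   nrow(cand), n))
    return(cand)
  }
  local_seed(seed, cand[sort(sample.int(nrow(cand), n)), ])
}
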