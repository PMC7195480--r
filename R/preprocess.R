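#' Per-slice background subtraction
#'
#' For each requested channel and each z-slice independently, estimates the
#' background as the mean of the lowest `fraction` of that slice's intensity
#' values and subtracts it; negative results are clamped to 0. The estimated
#' per-slice offsets are stored in the returned stack's QC slot and can be
#' retrieved with [background_offsets()].
#'
#' @param stack An [image_stack()].
#' @param fraction Proportion of lowest-intensity pixels per slice used to
#'   estimate the background (default 0.05, i.e. the bottom 5%);
#'   `0 < fraction < 0.5`.
#' @param channels Channels to correct; defaults to the ratiometric pair.
#' @return The corrected `image_stack`, with a
#'   `qc$background_offsets` tibble (`channel`, `z`, `offset`).
#' @export
subtract_background <- function(stack, fraction = 0.05,
                                channels = c("CFP", "YFP")) {
  stopifnot(inherits(stack, "image_stack"))
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction >= 0.5)
    abort("`fraction` must be in (0, 0.5).")
  channels <- intersect(channels, names(stack$channels))
  if (length(channels) == 0) abort("No matching channels to correct.")
  nz <- stack_dim(stack)[1]
  qc <- list()
  for (ch in channels) {
    arr <- stack$channels[[ch]]
    offsets <- numeric(nz)
    for (z in seq_len(nz)) {
      v <- as.numeric(arr[z, , ])
      if (length(v) == 0 || all(!is.finite(v)))
        abort(sprintf("Slice z=%d of channel %s is empty.", z, ch),
              class = "mitofret_empty_slice")
      k <- max(1L, floor(fraction * length(v)))
      off <- mean(sort(v, partial = k)[seq_len(k)])
      arr[z, , ] <- pmax(arr[z, , ] - off, 0)
      offsets[z] <- off
    }
    stack$channels[[ch]] <- arr
    qc[[ch]] <- tibble(channel = ch, z = seq_len(nz), offset = offsets)
  }
  stack$qc$background_offsets <- dplyr::bind_rows(qc)
  stack$metadata$background_subtracted <- TRUE
  stack
}

#' @rdname subtract_background
#' @export
background_offsets <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  stack$qc$background_offsets
}

# 2D mean filter of one slice; square (2r+1)^2 or disc kernel, replicated
# borders so constant images are exactly preserved.
mean_filter_2d <- function(mat, radius, kernel = "square") {
  if (radius == 0) return(mat)
  # window cannot exceed the image
  radius <- min(radius, floor((min(dim(mat)) - 1) / 2))
  if (radius == 0) return(mat)
  n <- 2L * radius + 1L
  k <- if (kernel == "disc") {
    b <- EBImage::makeBrush(n, shape = "disc")
    b / sum(b)
  } else {
    matrix(1 / n^2, n, n)
  }
  as.matrix(EBImage::filter2(mat, k, boundary = "replicate"))
}

#' Mean-filter smoothing of a stack
#'
#' Applies a 2D mean filter to every z-slice of the requested channels
#' (slice-wise: the axial dimension is not smoothed). The default kernel is
#' the square `(2r+1) x (2r+1)` neighborhood; a disc kernel is available.
#' `radius = 0` is the identity.
#'
#' @inheritParams subtract_background
#' @param radius Non-negative integer kernel radius in pixels (default 2).
#' @param kernel `"square"` (default) or `"disc"`.
#' @return The smoothed `image_stack`.
#' @export
smooth_stack <- function(stack, radius = 2, channels = c("CFP", "YFP"),
                         kernel = c("square", "disc")) {
  stopifnot(inherits(stack, "image_stack"))
  kernel <- match.arg(kernel)
  if (!is.numeric(radius) || length(radius) != 1 || radius < 0 ||
      radius != round(radius))
    abort("`radius` must be a non-negative integer.")
  channels <- intersect(channels, names(stack$channels))
  nz <- stack_dim(stack)[1]
  for (ch in channels) {
    arr <- stack$channels[[ch]]
    for (z in seq_len(nz))
      arr[z, , ] <- mean_filter_2d(arr[z, , ], radius, kernel)
    stack$channels[[ch]] <- arr
  }
  stack$metadata$smoothed_radius <- radius
  stack$metadata$smoothed_kernel <- kernel
  stack
}
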