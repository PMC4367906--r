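#' Segmentation parameters
#'
#' @param block_size Side of the local window (pixels, odd, >= 3) used for
#'   the median-filter background estimate in [correct_illumination()].
#' @param min_area,max_area Retained object area bounds in pixels^2.
#' @param min_mean_intensity Minimum mean (corrected) intensity of a
#'   retained object, on the image's intensity scale.
#' @param threshold `"otsu"` (default) or a fixed numeric threshold applied
#'   to the corrected image.
#' @return A list of class `"seg_params"`.
#' @export
seg_params <- function(block_size = 31, min_area = 20, max_area = 5000,
                       min_mean_intensity = 0, threshold = "otsu") {
  if (!is.numeric(block_size) || length(block_size) != 1 ||
      block_size < 3 || block_size %% 2 != 1) {
    rlang::abort("`block_size` must be a single odd integer >= 3",
                 class = "mitoscreen_parameter_error")
  }
  stopifnot_scalar_number(min_area, "min_area", min = 1)
  stopifnot_scalar_number(max_area, "max_area", min = 1)
  if (min_area >= max_area) {
    rlang::abort("need 0 < min_area < max_area", class = "mitoscreen_parameter_error")
  }
  stopifnot_scalar_number(min_mean_intensity, "min_mean_intensity", min = 0)
  if (!(identical(threshold, "otsu") || (is.numeric(threshold) && length(threshold) == 1))) {
    rlang::abort('`threshold` must be "otsu" or a single number',
                 class = "mitoscreen_parameter_error")
  }
  structure(
    list(block_size = as.integer(block_size), min_area = min_area,
         max_area = max_area, min_mean_intensity = min_mean_intensity,
         threshold = threshold),
    class = "seg_params"
  )
}

#' Correct uneven illumination
#'
#' Estimates the background as a local median over a `block_size` window
#' and subtracts it, clipping at zero. Removes smooth illumination fields
#' (vignetting, lamp gradients) while leaving compact bright objects
#' standing, since the median of a window dominated by background ignores
#' small bright structures.
#'
#' @param image 2-D nonnegative numeric matrix.
#' @param block_size Odd window size in pixels, >= 3 and at most the
#'   smaller image dimension.
#' @return A matrix of the same shape: `pmax(image - background, 0)`.
#' @export
correct_illumination <- function(image, block_size = 31) {
  image <- as.matrix(image)
  if (any(!is.finite(image)) || any(image < 0)) {
    rlang::abort("`image` must be finite and nonnegative",
                 class = "mitoscreen_validation_error")
  }
  if (block_size %% 2 != 1 || block_size < 3) {
    rlang::abort("`block_size` must be odd and >= 3",
                 class = "mitoscreen_parameter_error")
  }
  if (block_size > min(dim(image))) {
    rlang::abort("`block_size` exceeds the image dimensions",
                 class = "mitoscreen_parameter_error")
  }
  hi <- max(image)
  if (hi == 0) return(image)
  ## EBImage's constant-time median filter works on [0, 1] grayscale
  scaled <- image / hi
  bg <- EBImage::medianFilter(EBImage::Image(scaled), size = (block_size - 1L) / 2L)
  out <- (scaled - as.matrix(bg)) * hi
  out[out < 0] <- 0
  out
}

#' Threshold an image and count objects by size and intensity
#'
#' Binarizes the (illumination-corrected) image — Otsu threshold by
#' default — labels connected components, and retains components with
#' `min_area <= area <= max_area` and mean intensity at or above
#' `min_mean_intensity`. Touching objects are not split (no watershed);
#' at screen scale the merge error is tolerated and declared.
#'
#' @param image 2-D nonnegative numeric matrix, ideally from
#'   [correct_illumination()].
#' @param params A [seg_params()] object.
#' @return A list: `count` (retained objects) and `objects`, a tibble with
#'   `label`, `area`, `mean_intensity`, `x`, `y` (centroid). A blank
#'   (zero-variance) image yields `count = 0` without error.
#' @export
segment_and_count <- function(image, params = seg_params()) {
  image <- as.matrix(image)
  empty <- tibble::tibble(label = integer(), area = double(),
                          mean_intensity = double(), x = double(), y = double())
  if (max(image) == 0 || stats::sd(image) == 0) {
    return(list(count = 0L, objects = empty))
  }
  hi <- max(image)
  scaled <- image / hi
  thr <- if (identical(params$threshold, "otsu")) {
    EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
  } else {
    params$threshold / hi
  }
  mask <- scaled > thr
  if (!any(mask)) {
    return(list(count = 0L, objects = empty))
  }
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  labm <- as.matrix(lab)
  ids <- seq_len(max(labm))
  area <- tabulate(labm[labm > 0], nbins = max(labm))
  idx <- labm > 0
  mean_int <- tapply(image[idx], labm[idx], mean)
  rows <- row(labm)[idx]
  cols <- col(labm)[idx]
  cx <- tapply(rows, labm[idx], mean)
  cy <- tapply(cols, labm[idx], mean)
  objects <- tibble::tibble(
    label = ids,
    area = area[ids],
    mean_intensity = as.numeric(mean_int[as.character(ids)]),
    x = as.numeric(cx[as.character(ids)]),
    y = as.numeric(cy[as.character(ids)])
  )
  keep <- objects$area >= params$min_area & objects$area <= params$max_area &
    objects$mean_intensity >= params$min_mean_intensity
  objects <- objects[keep, , drop = FALSE]
  list(count = nrow(objects), objects = objects)
}

#' Count nuclei and mitotic cells in a two-channel image pair
#'
#' The DAPI channel yields the total nucleus count, the pH3 channel the
#' mitotic-cell count; both run through [correct_illumination()] and
#' [segment_and_count()].
#'
#' @param dapi,ph3 2-D nonnegative matrices of identical shape.
#' @param dapi_params,ph3_params Per-channel [seg_params()].
#' @return A one-row tibble: `n_total`, `n_mitotic`.
#' @export
quantify_pair <- function(dapi, ph3,
                          dapi_params = seg_params(),
                          ph3_params = dapi_params) {
  dapi <- as.matrix(dapi)
  ph3 <- as.matrix(ph3)
  if (!identical(dim(dapi), dim(ph3))) {
    rlang::abort("DAPI and pH3 images must have identical dimensions",
                 class = "mitoscreen_validation_error")
  }
  dc <- correct_illumination(dapi, dapi_params$block_size)
  pc <- correct_illumination(ph3, ph3_params$block_size)
  tibble::tibble(
    n_total = segment_and_count(dc, dapi_params)$count,
    n_mitotic = segment_and_count(pc, ph3_params)$count
  )
}
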