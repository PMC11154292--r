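#' Rectangular region of interest
#'
#' Pixel coordinates are 0-based with half-open extents, matching the image
#' conventions used throughout the package.
#'
#' @param rows,cols Length-2 vectors `c(first, one-past-last)`.
#' @param label Optional region label (e.g. `"im_complex"`, `"plaque"`).
#' @return An `roi_rect` object.
#' @export
#' @examples
#' roi_rect(c(50, 64), c(0, 128), label = "im_complex")
roi_rect <- function(rows, cols, label = NULL) {
  stopifnot(length(rows) == 2L, length(cols) == 2L,
            rows[1] >= 0, cols[1] >= 0, rows[1] < rows[2], cols[1] < cols[2])
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 label = label), class = "roi_rect")
}

# Resolve an ROI argument against an image into a vector of pixel values.
roi_pixels <- function(image, roi) {
  mat <- if (inherits(image, "wall_image")) image$image else image
  stopifnot(is.matrix(mat))
  if (is.character(roi)) {
    if (!inherits(image, "wall_image") || is.null(image$masks[[roi]])) {
      stop("no mask named '", roi, "' in this image", call. = FALSE)
    }
    roi <- image$masks[[roi]]
  }
  if (inherits(roi, "roi_rect")) {
    if (roi$rows[2] > nrow(mat) || roi$cols[2] > ncol(mat)) {
      stop("ROI exceeds image bounds", call. = FALSE)
    }
    px <- mat[(roi$rows[1] + 1):roi$rows[2], (roi$cols[1] + 1):roi$cols[2]]
  } else if (is.logical(roi)) {
    stopifnot(identical(dim(roi), dim(mat)))
    px <- mat[roi]
  } else {
    stop("roi must be an roi_rect, a logical mask, or a mask name", call. = FALSE)
  }
  as.vector(px)
}

#' Gray-scale median of a region of interest
#'
#' The GSM of an ROI is the 50th percentile of the gray levels (0-255) of
#' its pixels. For an even pixel count the convention is the midpoint of the
#' two central order statistics.
#'
#' @param image A `wall_image` or a numeric gray-level matrix.
#' @param roi An [roi_rect()], a logical mask matrix, or (for a
#'   `wall_image`) the name of one of its ground-truth masks.
#' @return The median gray level (scalar).
#' @export
#' @examples
#' m <- matrix(c(10, 20, 30, 200), 2, 2)
#' pixel_median(m, roi_rect(c(0, 2), c(0, 2)))
pixel_median <- function(image, roi) {
  px <- roi_pixels(image, roi)
  if (length(px) == 0) stop("empty ROI", call. = FALSE)
  median(px)
}

#' Per-image black/white calibration pair
#'
#' The darkest section of the vessel lumen is the reference black (gray
#' 0-37) and the brightest part of the adventitia the reference white
#' (gray 104-255).
#'
#' @param black,white Reference gray levels.
#' @return A `calibration_pair` object.
#' @export
calibration_pair <- function(black, white) {
  stopifnot(is.numeric(black), is.numeric(white))
  if (black < 0 || black > 37) stop("reference black must lie in [0, 37]", call. = FALSE)
  if (white < 104 || white > 255) stop("reference white must lie in [104, 255]", call. = FALSE)
  if (black >= white) stop("reference black must be below reference white", call. = FALSE)
  structure(list(black = black, white = white), class = "calibration_pair")
}

#' Calibrate a raw GSM against the image's reference black and white
#'
#' Affine rescaling that anchors the reference black at 0 and the reference
#' white at `w_target` (the conventional blood-0 / adventitia-190
#' normalization), clipped below at 0.
#'
#' @param raw Raw gray level(s).
#' @param cal A [calibration_pair()].
#' @param w_target Gray level the reference white maps to (default 190).
#' @return Calibrated gray level(s).
#' @export
#' @examples
#' calibrate_gsm(70, calibration_pair(20, 120))
calibrate_gsm <- function(raw, cal, w_target = 190) {
  stopifnot(inherits(cal, "calibration_pair"), w_target > 0)
  pmax(0, w_target * (raw - cal$black) / (cal$white - cal$black))
}

#' Select the subject-level plaque GSM
#'
#' Implements the darkest-of-the-two-thickest rule: per side, the lesion
#' with the largest maximum intima-media thickness (any of CC, bifurcation,
#' ICA) wins; across the up-to-two side winners the lower calibrated GSM is
#' taken. A thickness tie within a side resolves to the lower GSM; a GSM tie
#' across sides resolves left before right. Only lesions with thickness at
#' or above the plaque threshold (1.5 mm) are eligible.
#'
#' @param candidates Tibble of per-lesion measurements with columns `side`
#'   (`"left"`/`"right"`), `gsm` (calibrated), `imt_of_lesion` (mm) and
#'   optionally `segment`.
#' @param min_imt Plaque eligibility threshold in mm (default 1.5).
#' @return One-row tibble (the selected measurement), or a zero-row tibble
#'   when no eligible lesion exists (the subject is excluded from
#'   plaque-GSM analyses).
#' @export
#' @examples
#' x <- tibble::tibble(
#'   side = c("left", "left", "right"),
#'   imt_of_lesion = c(2.1, 2.4, 1.6),
#'   gsm = c(33, 45, 29)
#' )
#' select_plaque_gsm(x)
select_plaque_gsm <- function(candidates, min_imt = 1.5) {
  stopifnot(all(c("side", "gsm", "imt_of_lesion") %in% names(candidates)))
  stopifnot(all(candidates$side %in% c("left", "right")))
  elig <- dplyr::filter(candidates, .data$imt_of_lesion >= min_imt)
  if (nrow(elig) == 0) return(elig)
  side_winners <- elig |>
    dplyr::group_by(.data$side) |>
    dplyr::filter(.data$imt_of_lesion == max(.data$imt_of_lesion)) |>
    dplyr::filter(.data$gsm == min(.data$gsm)) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  side_winners |>
    dplyr::arrange(.data$gsm, factor(.data$side, levels = c("left", "right"))) |>
    dplyr::slice(1)
}

#' Intima-media GSM as the left/right average
#'
#' The IM-GSM is the arithmetic mean of the calibrated GSM of the left and
#' right plaque-free common-carotid far walls (2nd cm, lateral projection).
#' If one side is missing the other is returned with a single-side flag.
#'
#' @param left,right Calibrated GSM values (scalar, `NA` if missing).
#' @return One-row tibble with `im_gsm` and `single_side`.
#' @export
#' @examples
#' compute_im_gsm(40, 48)
compute_im_gsm <- function(left, right) {
  if (is.na(left) && is.na(right)) {
    stop("both sides missing: IM-GSM undefined", call. = FALSE)
  }
  single <- is.na(left) || is.na(right)
  tibble::tibble(
    im_gsm = mean(c(left, right), na.rm = TRUE),
    single_side = single
  )
}
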