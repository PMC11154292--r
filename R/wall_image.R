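#' Specification of a synthetic carotid wall image
#'
#' Describes an 8-bit far-wall B-mode image as three horizontal bands along
#' the depth axis (lumen, intima-media complex, adventitia), an optional
#' elliptical plaque region, per-region target median gray levels and a
#' multiplicative speckle model. Row/column coordinates are 0-based with
#' half-open extents.
#'
#' @param width,height Image size in pixels.
#' @param lumen_rows,im_rows,adventitia_rows Half-open row ranges
#'   `c(first, one-past-last)` of the three bands; they must be disjoint and
#'   ordered lumen -> IM -> adventitia with increasing depth.
#' @param medians Named target median gray levels (`lumen`, `im`,
#'   `adventitia`), ordered lumen < im < adventitia.
#' @param plaque Optional list `list(center = c(row, col), axes = c(a, b),
#'   median = g, imt_mm = t)` describing an elliptical lesion.
#' @param dispersion Speckle dispersion exponent (0 = no speckle, 1 = full
#'   Rayleigh multiplicative speckle).
#' @param seed Integer seed.
#' @return A `wall_image_spec` list.
#' @export
wall_image_spec <- function(width = 128L, height = 128L,
                            lumen_rows = c(0L, 50L),
                            im_rows = c(50L, 64L),
                            adventitia_rows = c(64L, 128L),
                            medians = c(lumen = 10, im = 44, adventitia = 180),
                            plaque = NULL,
                            dispersion = 0.6,
                            seed = 1L) {
  bands <- list(lumen = lumen_rows, im = im_rows, adventitia = adventitia_rows)
  for (b in bands) {
    stopifnot(length(b) == 2L, b[1] >= 0, b[2] <= height, b[1] < b[2])
  }
  if (lumen_rows[2] > im_rows[1] || im_rows[2] > adventitia_rows[1]) {
    stop("bands must be disjoint and ordered lumen -> IM -> adventitia",
         call. = FALSE)
  }
  stopifnot(
    all(c("lumen", "im", "adventitia") %in% names(medians)),
    medians[["lumen"]] < medians[["im"]],
    medians[["im"]] < medians[["adventitia"]],
    all(medians >= 0), all(medians <= 255),
    dispersion >= 0
  )
  structure(
    list(width = as.integer(width), height = as.integer(height),
         lumen_rows = lumen_rows, im_rows = im_rows,
         adventitia_rows = adventitia_rows,
         medians = medians, plaque = plaque,
         dispersion = dispersion, seed = as.integer(seed)),
    class = "wall_image_spec"
  )
}

# Multiplicative speckle factors with unit median: Rayleigh draws divided by
# the Rayleigh median, raised to the dispersion exponent. The median of the
# factor is exactly 1, so the per-region median gray is preserved.
speckle_factor <- function(n, dispersion) {
  if (dispersion == 0) return(rep(1, n))
  r <- sqrt(-2 * log(runif(n)))
  (r / sqrt(2 * log(2)))^dispersion
}

#' Generate a speckled wall image with ground-truth masks
#'
#' Renders the banded geometry of a far-wall image: each region's pixels are
#' its target median gray multiplied by unit-median Rayleigh speckle, rounded
#' and clipped to the 8-bit range, so the per-region pixel median stays at
#' the target (within rounding and sampling noise). Region masks are
#' returned alongside as the measurement oracle.
#'
#' @param spec A [wall_image_spec()].
#' @return A `wall_image` list with `image` (integer matrix, gray 0-255),
#'   `masks` (named list of logical matrices: lumen, im, adventitia and
#'   optionally plaque; band masks exclude plaque pixels) and `spec`.
#' @export
#' @examples
#' img <- generate_wall_image(wall_image_spec(seed = 1))
#' pixel_median(img, "im")
generate_wall_image <- function(spec) {
  stopifnot(inherits(spec, "wall_image_spec"))
  set.seed(spec$seed)
  h <- spec$height; w <- spec$width
  img <- matrix(0, h, w)
  band_rows <- list(lumen = spec$lumen_rows, im = spec$im_rows,
                    adventitia = spec$adventitia_rows)
  masks <- list()
  for (nm in names(band_rows)) {
    m <- matrix(FALSE, h, w)
    rr <- band_rows[[nm]]
    m[(rr[1] + 1):rr[2], ] <- TRUE
    masks[[nm]] <- m
  }
  if (!is.null(spec$plaque)) {
    pq <- spec$plaque
    rowg <- matrix(0:(h - 1), h, w)
    colg <- matrix(0:(w - 1), h, w, byrow = TRUE)
    inside <- ((rowg - pq$center[1]) / pq$axes[1])^2 +
      ((colg - pq$center[2]) / pq$axes[2])^2 <= 1
    if (!any(inside)) stop("plaque ellipse contains no pixels", call. = FALSE)
    masks <- lapply(masks, function(m) m & !inside)
    masks$plaque <- inside
  }
  targets <- c(spec$medians,
               if (!is.null(spec$plaque)) c(plaque = spec$plaque$median))
  for (nm in names(masks)) {
    npx <- sum(masks[[nm]])
    img[masks[[nm]]] <- targets[[nm]] * speckle_factor(npx, spec$dispersion)
  }
  img <- matrix(as.integer(pmin(pmax(round(img), 0), 255)), h, w)
  structure(list(image = img, masks = masks, spec = spec),
            class = "wall_image")
}

#' @export
print.wall_image <- function(x, ...) {
  cat("<wall_image> ", x$spec$height, "x", x$spec$width, " px; regions: ",
      paste(names(x$masks), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write a wall image (and its masks) as PNG files
#'
#' @param img A `wall_image`.
#' @param path Output PNG path for the image; masks are written alongside as
#'   `<path-sans-ext>_mask_<region>.png`.
#' @return Invisibly, the paths written.
#' @export
write_wall_image <- function(img, path) {
  stopifnot(inherits(img, "wall_image"))
  png::writePNG(img$image / 255, path)
  base <- sub("\\.png$", "", path)
  mask_paths <- vapply(names(img$masks), function(nm) {
    mp <- paste0(base, "_mask_", nm, ".png")
    png::writePNG(img$masks[[nm]] * 1, mp)
    mp
  }, character(1))
  invisible(c(path, mask_paths))
}

#' Read an 8-bit grayscale PNG as an integer gray-level matrix
#'
#' @param path PNG path; color images are converted by channel averaging.
#' @return Integer matrix with values in 0-255.
#' @export
read_gray_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- apply(a[, , 1:3, drop = FALSE], c(1, 2), mean)
  matrix(as.integer(round(a * 255)), nrow(a), ncol(a))
}
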