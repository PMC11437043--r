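#' Load a raster wing image
#'
#' Reads a PNG/TIFF/JPEG/BMP raster and returns a grayscale intensity image
#' normalized to \[0, 1\]. RGB images are collapsed to luminance with the
#' ITU-R 601 weights (0.299, 0.587, 0.114) before normalization; an alpha
#' channel, if present, is ignored.
#'
#' @param path Path to the image file.
#' @return A `wa_raw` object: a list with `pixels` (numeric matrix, rows =
#'   image rows, values in \[0, 1\]), `height`, `width`, and `source_path`.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image file: ", path)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop("cannot read image file: ", path,
                                           " (", conditionMessage(e), ")"))
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) == 3) {
    nch <- dim(dat)[3]
    dat <- if (nch >= 3) {
      0.299 * dat[, , 1] + 0.587 * dat[, , 2] + 0.114 * dat[, , 3]
    } else dat[, , 1]
  }
  # EBImage stores x (columns) as the first dimension
  pixels <- t(dat)
  pixels[pixels < 0] <- 0
  pixels[pixels > 1] <- 1
  wa_raw(pixels, source_path = path)
}

#' Construct a raw intensity image
#'
#' @param pixels Numeric matrix of intensities in \[0, 1\]; rows are image
#'   rows (origin top-left).
#' @param source_path Optional provenance string.
#' @return A `wa_raw` object.
#' @export
wa_raw <- function(pixels, source_path = NA_character_) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("pixels must be a numeric matrix")
  if (nrow(pixels) < 8 || ncol(pixels) < 8)
    stop("image too small: need at least 8 x 8 pixels")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1)
    stop("intensities must lie in [0, 1]")
  structure(list(pixels = pixels, height = nrow(pixels), width = ncol(pixels),
                 source_path = source_path),
            class = "wa_raw")
}

#' Binarize an intensity image
#'
#' Thresholds a grayscale image into membrane (light, foreground) and vein
#' (dark, background) phases. A pixel is foreground iff its intensity is
#' strictly greater than the threshold, so a pixel exactly at the threshold
#' counts as vein, erring toward connectivity of the vein network. The
#' default threshold of 0.54 applies to intensities normalized to \[0, 1\].
#'
#' @param image A `wa_raw` object.
#' @param threshold Threshold in (0, 1); default 0.54.
#' @return A `wa_binary` object: list with logical `mask` (`TRUE` =
#'   membrane), `threshold`, `mirrored` flag and optional `scale`
#'   (length units per pixel, `NULL` = pixel units).
#' @export
binarize <- function(image, threshold = 0.54) {
  stopifnot(inherits(image, "wa_raw"))
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly inside (0, 1)")
  structure(list(mask = image$pixels > threshold, threshold = threshold,
                 mirrored = FALSE, scale = NULL),
            class = "wa_binary")
}

#' Mirror a binarized wing horizontally
#'
#' Left wings are mirrored so that both wings of a pair share the same
#' orientation before comparison. Mirroring reverses the column order,
#' toggles the `mirrored` flag, and conserves the foreground pixel count;
#' applying it twice restores the input.
#'
#' @param image A `wa_binary` object.
#' @return The mirrored `wa_binary` object.
#' @export
mirror_horizontal <- function(image) {
  stopifnot(inherits(image, "wa_binary"))
  image$mask <- image$mask[, rev(seq_len(ncol(image$mask))), drop = FALSE]
  image$mirrored <- !image$mirrored
  image
}

#' Remove salt-and-pepper speckle from a binarized wing
#'
#' One pass of a 3 x 3 binary majority (median) filter: a pixel keeps its
#' phase iff a strict majority of the in-image pixels in its neighborhood
#' (itself included; ties keep the pixel) share it. This removes
#' isolated bright pixels inside veins and dark pixels inside membranes --
#' the classic salt-and-pepper artifacts -- while leaving cell interiors
#' and veins at least 2 px wide untouched.
#'
#' @param image A `wa_binary` object.
#' @return The filtered `wa_binary` object.
#' @export
despeckle <- function(image) {
  stopifnot(inherits(image, "wa_binary"))
  m <- image$mask * 1L
  ones <- matrix(1L, nrow(m), ncol(m))
  votes <- m
  valid <- ones
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    votes <- votes + shift_mat(m, dr, dc, 0L)
    valid <- valid + shift_mat(ones, dr, dc, 0L)
  }
  # strict majority of the in-image neighborhood; ties keep the pixel
  out <- 2L * votes > valid
  tie <- 2L * votes == valid
  out[tie] <- image$mask[tie]
  image$mask <- out
  image
}

#' Attach a physical scale to a binarized wing
#'
#' All downstream lengths are multiplied by `units_per_pixel` and areas by
#' its square. Dimensionless quantities (circularity, counts, regression,
#' NRMSE) are unaffected.
#'
#' @param image A `wa_binary` object.
#' @param units_per_pixel Positive length units per pixel.
#' @return The `wa_binary` object with `scale` set.
#' @export
set_scale <- function(image, units_per_pixel) {
  stopifnot(inherits(image, "wa_binary"))
  if (!is.numeric(units_per_pixel) || length(units_per_pixel) != 1 ||
      !is.finite(units_per_pixel) || units_per_pixel <= 0)
    stop("units_per_pixel must be a positive number")
  image$scale <- units_per_pixel
  image
}

#' @export
print.wa_raw <- function(x, ...) {
  cat("<wa_raw> ", x$height, "x", x$width, " intensity image",
      if (!is.na(x$source_path)) paste0(" from ", x$source_path), "\n", sep = "")
  invisible(x)
}

#' @export
print.wa_binary <- function(x, ...) {
  cat("<wa_binary> ", nrow(x$mask), "x", ncol(x$mask),
      " (threshold ", x$threshold,
      ", mirrored ", x$mirrored,
      ", scale ", if (is.null(x$scale)) "px" else x$scale, ")\n", sep = "")
  invisible(x)
}
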