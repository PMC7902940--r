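# 8-bit image IO (PNG/TIFF), lossless for the integer gray values the
# quantification operates on.

image_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("png")) return("png")
  if (ext %in% c("tif", "tiff")) return("tiff")
  stop(sprintf("unsupported image format '.%s' (use PNG or TIFF)", ext),
       call. = FALSE)
}

#' Read an 8-bit grayscale or RGB image
#'
#' Returns an integer matrix (grayscale) or a height x width x 3 array (RGB)
#' of values in \[0, 255\]. Only 8-bit inputs are supported: deeper TIFFs are
#' rejected from the file header, deeper PNGs by the non-integrality of
#' their rescaled values. Use [rgb_to_gray8()] to collapse RGB input.
#'
#' @param path PNG or TIFF file.
#' @return Integer matrix or 3-channel array.
#' @export
read_image <- function(path) {
  fmt <- image_format(path)
  if (fmt == "tiff") {
    meta <- tiff::readTIFF(path, payload = FALSE)
    if (meta$bits.per.sample != 8) {
      stop(sprintf("%s is %d-bit; only 8-bit images are supported (rescale it first)",
                   path, meta$bits.per.sample), call. = FALSE)
    }
    img <- round(tiff::readTIFF(path) * 255)
  } else {
    raw <- png::readPNG(path)
    img <- raw * 255
    if (max(abs(img - round(img))) > 1e-6) {
      stop(sprintf("%s does not contain 8-bit samples; only 8-bit images are supported",
                   path), call. = FALSE)
    }
    img <- round(img)
  }
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] == 4L) img <- img[, , 1:3]  # drop alpha
    if (dim(img)[3] == 1L) img <- img[, , 1]
  }
  if (is.matrix(img)) storage.mode(img) <- "integer"
  img
}

#' Write an 8-bit image
#'
#' Losslessly writes an integer gray matrix (or height x width x 3 RGB
#' array) of values in \[0, 255\] as 8-bit PNG or TIFF; a [section_image()]
#' may be passed directly.
#'
#' @param image Matrix, 3-channel array, or `section_image`.
#' @param path Output PNG or TIFF file.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  px <- if (inherits(image, "section_image")) image$pixels else image
  if (anyNA(px) || any(px < 0 | px > 255)) {
    stop("pixel values must be in [0, 255]", call. = FALSE)
  }
  fmt <- image_format(path)
  norm <- px / 255
  if (fmt == "tiff") {
    tiff::writeTIFF(norm, path, bits.per.sample = 8)
  } else {
    png::writePNG(norm, path)
  }
  invisible(path)
}

#' Read an integer label mask with its name map
#'
#' The mask is an 8-bit label image; `name_map_path` is a JSON object mapping
#' region names to label values.
#'
#' @param path Label image (PNG/TIFF).
#' @param name_map_path JSON file, e.g. `{"Cg1": 1, "Cg2": 2}`.
#' @return A [roi_mask()].
#' @export
read_roi_mask <- function(path, name_map_path) {
  labels <- read_image(path)
  if (!is.matrix(labels)) {
    stop("ROI mask must be a single-channel label image", call. = FALSE)
  }
  nm <- jsonlite::read_json(name_map_path, simplifyVector = TRUE)
  roi_mask(labels, unlist(nm))
}

#' @rdname read_roi_mask
#' @param mask A [roi_mask()] to write.
#' @export
write_roi_mask <- function(mask, path, name_map_path) {
  stopifnot(inherits(mask, "roi_mask"))
  if (max(mask$labels) > 255) {
    stop("label values above 255 cannot be stored in an 8-bit mask image",
         call. = FALSE)
  }
  write_image(mask$labels, path)
  jsonlite::write_json(as.list(mask$name_map), name_map_path,
                       auto_unbox = TRUE)
  invisible(path)
}
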