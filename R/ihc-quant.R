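# Brightfield IHC signal quantification.
#
# The method: convert to 8-bit gray, take the whole-image histogram mode as
# the background estimate, set the signal threshold at mode - k * SD (k fixed
# per antibody across a series), call every pixel at or below the threshold
# positive (the chromogen is darker than the background), report the positive
# area as a percentage of each ROI, and for cell-body markers count connected
# positive objects larger than a size filter.

# Per-antibody SD multipliers used throughout a staining series.
DEFAULT_K <- c(MBP = 2.0, GFAP = 2.5, Iba1 = 3.0)

# Cell-body markers for which objects are counted (MBP stains myelin, not
# discrete somata, so no count there).
COUNTED_ANTIBODIES <- c("GFAP", "Iba1")

#' Default object-count size filter, in pixels
#'
#' Connected positive components must exceed this many pixels (strictly) to
#' be counted as cell bodies; at the native acquisition scale this
#' corresponds to roughly 20 um^2.
#' @export
DEFAULT_MIN_OBJECT_AREA <- 250L

#' Convert an RGB image to 8-bit grayscale
#'
#' Per-pixel unweighted mean of the three channels, rounded half up and
#' clamped to \[0, 255\].
#'
#' @param rgb Numeric array `height x width x 3` with channel values in
#'   \[0, 255\].
#' @return Integer matrix of gray values.
#' @examples
#' rgb <- array(c(255, 0, 0), c(1, 1, 3))  # pure red pixel
#' rgb_to_gray8(rgb)                       # 85
#' @export
rgb_to_gray8 <- function(rgb) {
  if (!(is.array(rgb) && length(dim(rgb)) == 3L && dim(rgb)[3] == 3L)) {
    stop("`rgb` must be a height x width x 3 array", call. = FALSE)
  }
  if (anyNA(rgb) || any(rgb < 0 | rgb > 255)) {
    stop("channel values must be in [0, 255]", call. = FALSE)
  }
  gray <- (rgb[, , 1] + rgb[, , 2] + rgb[, , 3]) / 3
  gray <- matrix(clamp(round_half_up(gray), 0, 255),
                 dim(rgb)[1], dim(rgb)[2])
  storage.mode(gray) <- "integer"
  gray
}

#' Whole-image gray-value statistics
#'
#' Mean, median, mode and population standard deviation of all pixels in the
#' picture (not restricted to any ROI). The mode is the most frequent gray
#' level; among ties the highest (brightest) level is taken, since the mode
#' estimates the bright background.
#'
#' @param image A [section_image()] or an integer matrix of gray values.
#' @return A list of class `histogram_stats` with `mean`, `median`, `mode`,
#'   `sd`.
#' @export
image_stats <- function(image) {
  px <- if (inherits(image, "section_image")) image$pixels else image
  if (length(px) == 0) stop("empty image", call. = FALSE)
  v <- as.vector(px)
  counts <- tabulate(v + 1L, nbins = 256L)
  mode_level <- max(which(counts == max(counts))) - 1L
  m <- mean(v)
  structure(
    list(mean = m,
         median = stats::median(v),
         mode = mode_level,
         sd = sqrt(mean((v - m)^2))),
    class = "histogram_stats"
  )
}

#' @export
print.histogram_stats <- function(x, ...) {
  cat(sprintf("<histogram_stats> mean=%.2f median=%g mode=%d sd=%.2f\n",
              x$mean, x$median, x$mode, x$sd))
  invisible(x)
}

#' Per-picture signal threshold: mode minus k standard deviations
#'
#' The whole-image mode estimates the background staining level; subtracting
#' `k` whole-image SDs gives the signal cutoff for that picture. `k` is held
#' constant across a series for each antibody (MBP 2, GFAP 2.5, Iba1 3).
#'
#' @param stats A `histogram_stats` object from [image_stats()].
#' @param k SD multiplier (> 0), or an antibody name to use its standard
#'   multiplier.
#' @return A list of class `threshold_spec` with `k` and `threshold` (clamped
#'   to \[0, 255\]).
#' @examples
#' st <- structure(list(mean = 195, median = 200, mode = 200, sd = 10),
#'                 class = "histogram_stats")
#' compute_threshold(st, 2)$threshold       # 180
#' compute_threshold(st, "Iba1")$threshold  # 170
#' @export
compute_threshold <- function(stats, k) {
  if (is.character(k)) {
    if (!k %in% names(DEFAULT_K)) {
      stop(sprintf("no standard SD multiplier for antibody '%s'", k),
           call. = FALSE)
    }
    k <- DEFAULT_K[[k]]
  }
  stopifnot_scalar(k, "k")
  if (k <= 0) stop("`k` must be > 0", call. = FALSE)
  thr <- clamp(stats$mode - k * stats$sd, 0, 255)
  structure(list(k = k, threshold = thr), class = "threshold_spec")
}

#' Percent positive area within a region of interest
#'
#' A pixel is positive when its gray value is at or below the threshold
#' (stain darker than background). Returns 100 x (positive ROI pixels) /
#' (ROI pixels).
#'
#' @param image A [section_image()] or gray matrix.
#' @param roi Logical matrix selecting the ROI (same shape as the image).
#' @param threshold Gray-value cutoff.
#' @return Percent of ROI area positive, in \[0, 100\].
#' @export
positive_area_fraction <- function(image, roi, threshold) {
  px <- if (inherits(image, "section_image")) image$pixels else image
  if (!identical(dim(px), dim(roi))) {
    stop("ROI shape does not match image shape", call. = FALSE)
  }
  n <- sum(roi)
  if (n == 0) stop("empty ROI", call. = FALSE)
  100 * sum(px[roi] <= threshold) / n
}

# Connected-component labels of a binary mask (8- or 4-connectivity),
# via the pixel-adjacency graph. Returns the component areas in pixels.
component_areas <- function(mask, connectivity = 8) {
  if (!connectivity %in% c(4, 8)) {
    stop("`connectivity` must be 4 or 8", call. = FALSE)
  }
  idx <- which(mask)
  if (!length(idx)) return(integer(0))
  h <- nrow(mask)
  w <- ncol(mask)
  pos <- integer(h * w)
  pos[idx] <- seq_along(idx)
  rows <- ((idx - 1L) %% h) + 1L
  cols <- ((idx - 1L) %/% h) + 1L
  edge_list <- list()
  add_edges <- function(valid, off) {
    i <- idx[valid]
    j <- i + off
    keep <- mask[j]
    cbind(pos[i[keep]], pos[j[keep]])
  }
  edge_list[[1]] <- add_edges(rows < h, 1L)                      # down
  edge_list[[2]] <- add_edges(cols < w, h)                       # right
  if (connectivity == 8) {
    edge_list[[3]] <- add_edges(rows < h & cols < w, h + 1L)     # down-right
    edge_list[[4]] <- add_edges(rows > 1L & cols < w, h - 1L)    # up-right
  }
  edges <- do.call(rbind, edge_list)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)
  tabulate(comp$membership, nbins = comp$no)
}

#' Count stained objects above a size filter
#'
#' Number of connected components of the positive mask whose area strictly
#' exceeds `min_area` pixels. Used to estimate cell-body counts for GFAP and
#' Iba1.
#'
#' @param positive_mask Logical matrix of positive pixels (already restricted
#'   to the ROI of interest).
#' @param min_area Size filter in pixels; components must be larger than this
#'   to count (default [DEFAULT_MIN_OBJECT_AREA]).
#' @param connectivity Pixel adjacency, 8 (default, includes diagonals) or 4.
#' @return Nonnegative integer count.
#' @export
count_objects <- function(positive_mask, min_area = DEFAULT_MIN_OBJECT_AREA,
                          connectivity = 8) {
  if (!is.matrix(positive_mask)) {
    stop("`positive_mask` must be a matrix", call. = FALSE)
  }
  areas <- component_areas(positive_mask != 0, connectivity)
  sum(areas > min_area)
}

#' Quantify one section over all its ROIs
#'
#' Computes the whole-image statistics and the mode - k*SD threshold once per
#' picture, then measures the percent-positive area in every named ROI.
#' Object counts are reported for cell-body markers (GFAP, Iba1) only.
#'
#' @param image A [section_image()].
#' @param rois A [roi_mask()] with the same shape as the image.
#' @param k SD multiplier; defaults to the image's antibody standard value.
#' @param min_object_area Size filter for object counting, in pixels.
#' @param connectivity Component connectivity for object counting.
#' @return A data.frame with one row per named ROI: subject metadata, region,
#'   `threshold_used`, `percent_positive_area` and `object_count` (NA for
#'   antibodies without counting).
#' @export
quantify_section <- function(image, rois, k = NULL,
                             min_object_area = DEFAULT_MIN_OBJECT_AREA,
                             connectivity = 8) {
  stopifnot(inherits(image, "section_image"), inherits(rois, "roi_mask"))
  if (!identical(dim(image$pixels), dim(rois$labels))) {
    stop("ROI mask shape does not match image shape", call. = FALSE)
  }
  antibody <- image$metadata$antibody
  if (is.null(k)) k <- antibody
  spec <- compute_threshold(image_stats(image), k)
  positive <- image$pixels <= spec$threshold
  count_cells <- antibody %in% COUNTED_ANTIBODIES
  out <- lapply(names(rois$name_map), function(region) {
    roi <- rois$labels == rois$name_map[[region]]
    cnt <- NA_integer_
    if (count_cells) {
      cnt <- count_objects(positive & roi, min_object_area, connectivity)
    }
    data.frame(
      subject_id = image$metadata$subject_id, sex = image$metadata$sex,
      genotype = image$metadata$genotype, antibody = antibody,
      level = image$metadata$level, region = region,
      threshold_used = spec$threshold,
      percent_positive_area = positive_area_fraction(image, roi, spec$threshold),
      object_count = cnt,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Quantify a batch of sections into one tidy table
#'
#' @param sections List of [section_image()]s (or of `simulate_ihc_cohort()`
#'   entries carrying an `image` element).
#' @param rois A shared [roi_mask()], or a list of masks parallel to
#'   `sections`.
#' @param ... Passed to [quantify_section()].
#' @return Row-bound data.frame of per-ROI measurements.
#' @export
quantify_batch <- function(sections, rois, ...) {
  rows <- lapply(seq_along(sections), function(i) {
    s <- sections[[i]]
    img <- if (inherits(s, "section_image")) s else s$image
    r <- if (inherits(rois, "roi_mask")) rois else rois[[i]]
    quantify_section(img, r, ...)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Evenly tiled synthetic ROI parcellation
#'
#' Splits an image into an `nr` x `nc` grid of rectangular named ROIs — a
#' stand-in parcellation for synthetic sections, where anatomical ROIs do
#' not exist.
#'
#' @param shape Integer (height, width) of the image.
#' @param nr,nc Grid rows and columns.
#' @param names Optional region names (length `nr * nc`).
#' @return A [roi_mask()].
#' @export
synthetic_roi_grid <- function(shape, nr = 2, nc = 2, names = NULL) {
  h <- shape[1]; w <- shape[2]
  labels <- matrix(0L, h, w)
  row_cut <- ceiling(seq_len(h) / (h / nr))
  col_cut <- ceiling(seq_len(w) / (w / nc))
  labels <- matrix((pmin(row_cut, nr) - 1L), h, w) * nc +
    matrix(pmin(col_cut, nc), h, w, byrow = TRUE)
  if (is.null(names)) names <- sprintf("roi_%02d", seq_len(nr * nc))
  stopifnot(length(names) == nr * nc)
  roi_mask(labels, stats::setNames(seq_len(nr * nc), names))
}
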