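# Lightweight S3 containers for the pipeline's domain objects.

#' Create a section image
#'
#' An 8-bit grayscale brightfield section with acquisition/animal metadata.
#' Pixel values are integers in \[0, 255\]; stained signal is darker than the
#' bright background.
#'
#' @param pixels Integer matrix of gray values in \[0, 255\] (rows = image
#'   rows, origin top-left).
#' @param antibody Stain marker, one of `"MBP"`, `"GFAP"`, `"Iba1"` (or any
#'   label for non-cohort use).
#' @param subject_id,sex,genotype,level Animal metadata. `level` is the
#'   frontocaudal sectioning level (e.g. `"anterior"`, `"hippocampus"`).
#' @param extra Named list of additional metadata (e.g. generator flags).
#' @return An object of class `section_image` with elements `pixels` and
#'   `metadata`.
#' @export
section_image <- function(pixels, antibody = NA_character_,
                          subject_id = NA_character_, sex = NA_character_,
                          genotype = NA_character_, level = NA_character_,
                          extra = list()) {
  if (!is.matrix(pixels) || length(pixels) == 0L) {
    stop("`pixels` must be a nonempty matrix", call. = FALSE)
  }
  px <- as.vector(pixels)
  if (anyNA(px) || any(px < 0 | px > 255) || any(px != trunc(px))) {
    stop("pixel values must be integers in [0, 255]", call. = FALSE)
  }
  storage.mode(pixels) <- "integer"
  structure(
    list(
      pixels = pixels,
      metadata = c(
        list(antibody = antibody, subject_id = subject_id, sex = sex,
             genotype = genotype, level = level),
        extra
      )
    ),
    class = "section_image"
  )
}

#' @export
print.section_image <- function(x, ...) {
  cat(sprintf(
    "<section_image> %d x %d px, antibody=%s subject=%s sex=%s genotype=%s level=%s\n",
    nrow(x$pixels), ncol(x$pixels), x$metadata$antibody, x$metadata$subject_id,
    x$metadata$sex, x$metadata$genotype, x$metadata$level
  ))
  invisible(x)
}

#' Create a region-of-interest mask
#'
#' Named anatomical parcellation of a section: an integer label image plus a
#' name map. Label 0 means unassigned.
#'
#' @param labels Integer matrix, same shape as the image it parcellates.
#' @param name_map Named integer vector mapping region name -> label value.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(labels, name_map) {
  if (!is.matrix(labels)) stop("`labels` must be a matrix", call. = FALSE)
  if (is.null(names(name_map)) || any(!nzchar(names(name_map)))) {
    stop("`name_map` must be a named vector (region name -> label)", call. = FALSE)
  }
  name_map <- vapply(name_map, as.integer, integer(1))
  present <- unique(as.vector(labels))
  missing <- setdiff(name_map, present)
  if (length(missing)) {
    stop(sprintf("labels absent from the mask: %s",
                 paste(names(name_map)[name_map %in% missing], collapse = ", ")),
         call. = FALSE)
  }
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, name_map = name_map), class = "roi_mask")
}

#' Create a 3D label atlas
#'
#' Integer parcellation of the imaging grid into named brain structures.
#' Label 0 is outside the brain; labels > 0 partition the brain.
#'
#' @param labels 3D integer array.
#' @param name_map Named integer vector, structure name -> label.
#' @param voxel_size Isotropic voxel edge length in mm (> 0).
#' @return An object of class `label_atlas`.
#' @export
label_atlas <- function(labels, name_map, voxel_size) {
  if (!(is.array(labels) && length(dim(labels)) == 3L)) {
    stop("`labels` must be a 3D array", call. = FALSE)
  }
  stopifnot_scalar(voxel_size, "voxel_size")
  if (voxel_size <= 0) stop("`voxel_size` must be > 0", call. = FALSE)
  name_map <- vapply(name_map, as.integer, integer(1))
  present <- unique(as.vector(labels))
  missing <- setdiff(name_map, present)
  if (length(missing)) {
    stop(sprintf("atlas labels absent from the volume: %s",
                 paste(names(name_map)[name_map %in% missing], collapse = ", ")),
         call. = FALSE)
  }
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, name_map = name_map, voxel_size = voxel_size),
            class = "label_atlas")
}

#' Create a Jacobian-determinant map
#'
#' Per-subject voxel-wise local volume-change field on the atlas grid. Values
#' must be strictly positive: the Jacobian determinant of an orientation-
#' preserving deformation is > 0.
#'
#' @param values 3D numeric array of Jacobian determinants.
#' @param subject_id Subject identifier.
#' @return An object of class `jacobian_map`.
#' @export
jacobian_map <- function(values, subject_id) {
  if (!(is.array(values) && length(dim(values)) == 3L)) {
    stop("`values` must be a 3D array", call. = FALSE)
  }
  if (anyNA(values) || any(values <= 0)) {
    stop("Jacobian determinants must be strictly positive", call. = FALSE)
  }
  structure(list(values = values, subject_id = as.character(subject_id)),
            class = "jacobian_map")
}

#' Build a balanced two-factor cohort design
#'
#' Subjects crossed over sex (M/F) and genotype (WT/KO), `n_per_cell` in each
#' of the four cells, with optional exclusions (e.g. a scan dropped for
#' imaging artifacts).
#'
#' @param n_per_cell Animals per sex-by-genotype cell (default 6).
#' @param exclude Character vector of subject ids to drop after construction.
#' @return A data.frame with columns `subject_id`, `sex`, `genotype`.
#' @examples
#' design <- cohort_design(6)
#' table(design$sex, design$genotype)
#' # drop one WT male, as after a quality-control exclusion
#' nrow(cohort_design(6, exclude = "M_WT_1"))
#' @export
cohort_design <- function(n_per_cell = 6, exclude = NULL) {
  if (n_per_cell < 1) stop("`n_per_cell` must be >= 1", call. = FALSE)
  grid <- expand.grid(sex = c("M", "F"), genotype = c("WT", "KO"),
                      rep = seq_len(n_per_cell), stringsAsFactors = FALSE)
  design <- data.frame(
    subject_id = sprintf("%s_%s_%d", grid$sex, grid$genotype, grid$rep),
    sex = grid$sex,
    genotype = grid$genotype,
    stringsAsFactors = FALSE
  )
  design <- design[order(design$sex, design$genotype, design$subject_id), ]
  if (!is.null(exclude)) {
    unknown <- setdiff(exclude, design$subject_id)
    if (length(unknown)) {
      stop(sprintf("unknown subject id(s) in `exclude`: %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    design <- design[!design$subject_id %in% exclude, ]
  }
  if (anyDuplicated(design$subject_id)) {
    stop("subject ids must be unique", call. = FALSE)
  }
  rownames(design) <- NULL
  design
}
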