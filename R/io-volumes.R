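# NIfTI-1 IO for label atlases and Jacobian maps. Volumes are treated in
# voxel space only; the isotropic voxel size travels in the NIfTI pixdim.

write_nifti_array <- function(values, path, voxel_size = 1) {
  img <- RNifti::asNifti(values)
  img$pixdim <- c(1, rep(voxel_size, 3), 0, 0, 0, 0)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read / write a label atlas as NIfTI
#'
#' Labels are stored as a NIfTI volume (values rounded to integers on read);
#' the structure name map travels as a JSON sidecar; the voxel size is taken
#' from the NIfTI pixdim (must be isotropic).
#'
#' @param path NIfTI file (`.nii` / `.nii.gz`).
#' @param name_map_path JSON object mapping structure names to labels.
#' @return A [label_atlas()].
#' @export
read_atlas <- function(path, name_map_path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  if (max(pd) - min(pd) > 1e-9) {
    stop("atlas voxels must be isotropic", call. = FALSE)
  }
  nm <- unlist(jsonlite::read_json(name_map_path, simplifyVector = TRUE))
  labels <- array(as.integer(round(img)), dim(img))
  label_atlas(labels, nm, voxel_size = pd[1])
}

#' @rdname read_atlas
#' @param atlas A [label_atlas()] to write.
#' @export
write_atlas <- function(atlas, path, name_map_path) {
  stopifnot(inherits(atlas, "label_atlas"))
  write_nifti_array(atlas$labels, path, atlas$voxel_size)
  jsonlite::write_json(as.list(atlas$name_map), name_map_path,
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read / write a Jacobian-determinant map as NIfTI
#'
#' @param path NIfTI file.
#' @param subject_id Subject the map belongs to (defaults to the file stem).
#' @param atlas Optional [label_atlas()]; if given, the map's grid must match
#'   the atlas grid.
#' @return A [jacobian_map()].
#' @export
read_jacobian <- function(path, subject_id = NULL, atlas = NULL) {
  img <- RNifti::readNifti(path)
  if (is.null(subject_id)) {
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  }
  values <- array(as.numeric(img), dim(img))
  if (!is.null(atlas) && !identical(dim(values), dim(atlas$labels))) {
    stop(sprintf("grid mismatch: atlas %s vs map %s (%s)",
                 paste(dim(atlas$labels), collapse = "x"),
                 paste(dim(values), collapse = "x"), path), call. = FALSE)
  }
  jacobian_map(values, subject_id)
}

#' @rdname read_jacobian
#' @param jac A [jacobian_map()] to write.
#' @param voxel_size Voxel edge recorded in the header, mm.
#' @export
write_jacobian <- function(jac, path, voxel_size = 1) {
  stopifnot(inherits(jac, "jacobian_map"))
  write_nifti_array(jac$values, path, voxel_size)
  invisible(path)
}

#' Read a cohort design table
#'
#' CSV with columns `subject_id`, `sex` (M/F), `genotype` (WT/KO).
#'
#' @param path CSV file.
#' @return Data.frame.
#' @export
read_design <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("subject_id", "sex", "genotype")
  miss <- setdiff(needed, names(d))
  if (length(miss)) {
    stop(sprintf("design table missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(d$subject_id)) {
    stop("design table has duplicated subject ids", call. = FALSE)
  }
  d
}
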