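# NIfTI IO goes through RNifti; volumes are reoriented to RAS+ on load so the
# geometric ROI operators ("anterior", "axial", "lateral") act in a fixed
# anatomical frame.

#' Read a labelled parcellation volume from NIfTI
#'
#' @param path Path to a 3D integer-valued NIfTI file.
#' @param label_table Named integer vector (or path to a YAML/JSON file holding
#'   one) mapping structure names to label values.
#' @return A [label_volume]. Labels named in the table but absent from the
#'   grid are flagged in the `absent` field with a warning.
#' @export
read_label_volume <- function(path, label_table) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("expected a 3D label volume, got ", length(dim(img)), "D", call. = FALSE)
  RNifti::orientation(img) <- "RAS"
  arr <- array(as.numeric(img), dim = dim(img))
  if (max(abs(arr - round(arr))) > 0)
    stop("label volume must be integer-valued", call. = FALSE)
  if (is.character(label_table) && length(label_table) == 1L)
    label_table <- read_label_table(label_table)
  label_volume(array(as.integer(round(arr)), dim = dim(arr)),
               nifti_affine(img), label_table)
}

read_label_table <- function(path) {
  tab <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  stats::setNames(as.integer(unlist(tab)), names(unlist(tab)))
}

#' Read a scalar map from NIfTI
#' @param path NIfTI file path.
#' @param role Value semantics; see [scalar_map()].
#' @return A [scalar_map].
#' @export
read_scalar_map <- function(path, role = "binary") {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("expected a 3D volume", call. = FALSE)
  RNifti::orientation(img) <- "RAS"
  scalar_map(array(as.numeric(img), dim = dim(img)), nifti_affine(img), role)
}

#' Write a scalar map or label volume to NIfTI
#'
#' Files are written uncompressed (`.nii`) by default so that byte-identical
#' reproduction under a fixed seed is checkable with a plain checksum.
#'
#' @param x A [scalar_map] or [label_volume].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(x, path) {
  grid <- x$grid
  datatype <- if (inherits(x, "label_volume") || x$role %in% c("binary", "density"))
    "int32" else "double"
  # pixdim must be attached before conversion or the on-disk header reverts
  # to unit voxels
  img <- RNifti::asNifti(structure(grid, pixdim = voxel_dims_mm(x$affine)),
                         datatype = datatype)
  img <- RNifti::`sform<-`(img, structure(x$affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(x$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 4D spherical-harmonic coefficient volume as an fODF field
#' @param path NIfTI path; 4th dimension holds real even-order SH coefficients.
#' @return A [fodf_field].
#' @export
read_fodf_field <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 4L)
    stop("expected a 4D SH coefficient volume", call. = FALSE)
  arr <- array(as.numeric(img), dim = dim(img))
  ncoef <- dim(arr)[4]
  fodf_field(arr, sh_order_from_ncoef(ncoef), nifti_affine(img))
}

#' Write an fODF field to a 4D NIfTI
#' @param field A [fodf_field].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fodf_field <- function(field, path) {
  img <- RNifti::asNifti(structure(field$coef,
                                   pixdim = c(voxel_dims_mm(field$affine), 1)),
                         datatype = "double")
  img <- RNifti::`sform<-`(img, structure(field$affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(field$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

nifti_affine <- function(img) {
  m <- RNifti::xform(img)
  attributes(m) <- list(dim = dim(m))
  m
}
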