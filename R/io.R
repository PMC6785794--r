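#' Read and write planar images and SPECT volumes as NIfTI
#'
#' Thin NIfTI wrappers around RNifti.  Planar count images are stored as
#' 2-D volumes; masks as unsigned 8-bit; SPECT volumes carry their voxel
#' spacing in the NIfTI pixdim.
#'
#' @param img Matrix (planar image), logical matrix/array (mask) or
#'   [spect_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `write_*` return the path invisibly; `read_*` return the
#'   corresponding in-memory object.
#' @name nifti_io
NULL

#' @rdname nifti_io
#' @export
write_planar_image <- function(img, path) {
  stopifnot(is.matrix(img))
  RNifti::writeNifti(RNifti::asNifti(img), path)
  invisible(path)
}

#' @rdname nifti_io
#' @export
read_planar_image <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) > 2L) arr <- arr[, , 1L]
  matrix(as.numeric(arr), nrow = dim(arr)[1L])
}

#' @rdname nifti_io
#' @export
write_mask <- function(img, path) {
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(img), dim(img))),
                     path, datatype = "uint8")
  invisible(path)
}

#' @rdname nifti_io
#' @export
read_mask <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  array(arr != 0, dim(arr))
}

#' @rdname nifti_io
#' @export
write_spect_volume <- function(img, path) {
  stopifnot(inherits(img, "spect_volume"))
  nim <- RNifti::asNifti(img$data)
  RNifti::pixdim(nim) <- img$spacing_mm
  RNifti::writeNifti(nim, path)
  invisible(path)
}

#' @rdname nifti_io
#' @export
read_spect_volume <- function(path) {
  nim <- RNifti::readNifti(path)
  spect_volume(array(as.numeric(nim), dim(nim)), RNifti::pixdim(nim))
}

#' Read a pipeline configuration from YAML
#'
#' Reads a YAML file into the nested list [run_pipeline()] consumes, and
#' checks that any referenced file paths exist.
#'
#' @param path Path to a YAML configuration file.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  cfg <- yaml::read_yaml(path)
  for (key in c("calibration_csv", "patient_csv")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]]))
      stop("configured file not found: ", cfg[[key]], call. = FALSE)
  }
  cfg
}
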