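#' Read a volume from NIfTI
#'
#' Reads a NIfTI-1 file and reconstructs the grid from its affine header.
#' The affine must be orthonormal up to voxel scaling (no shear); otherwise
#' an error is raised. If a JSON legend sidecar is present (same path with
#' \code{.json} extension, or given explicitly) the file is read as a
#' \linkS4class{LabelVolume}, otherwise as a \linkS4class{ScalarVolume}.
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @param kind scalar value kind for ScalarVolumes (default "SUL").
#' @param legend optional path to a JSON legend ({"1": "liver", ...});
#'   forces a LabelVolume.
#' @return A \linkS4class{ScalarVolume} or \linkS4class{LabelVolume}.
#' @export
readVolume <- function(path, kind = "SUL", legend = NULL) {
  img <- RNifti::readNifti(path)
  A <- unclass(RNifti::xform(img))
  grid <- gridFromAffine(A, dim(img)[1:3])
  if (is.null(legend)) {
    side <- legendSidecar(path)
    if (file.exists(side)) legend <- side
  }
  arr <- array(as.numeric(img), dim = dim(img)[1:3])
  if (!is.null(legend)) {
    leg <- jsonlite::read_json(legend, simplifyVector = TRUE)
    leg <- stats::setNames(as.character(unlist(leg)), names(leg))
    LabelVolume(array(as.integer(round(arr)), dim = dim(arr)), grid, leg)
  } else {
    ScalarVolume(arr, grid, kind)
  }
}

#' Write a volume to NIfTI
#'
#' Scalar volumes are stored as float64 so that a write/read round trip is
#' bit-exact; label volumes as int32 with their legend in a JSON sidecar.
#'
#' @param volume a \linkS4class{ScalarVolume} or \linkS4class{LabelVolume}.
#' @param path output NIfTI path.
#' @param legend legend sidecar path for LabelVolumes (default: \code{path}
#'   with a .json extension).
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(volume, path, legend = legendSidecar(path)) {
  grid <- volume@grid
  isLabel <- is(volume, "LabelVolume")
  arr <- if (isLabel) volume@labels else volume@values
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- grid@spacing
  A <- rbind(cbind(grid@direction %*% diag(grid@spacing), grid@origin),
             c(0, 0, 0, 1))
  img <- RNifti::`sform<-`(img, structure(A, code = 2L))
  img <- RNifti::`qform<-`(img, structure(A, code = 2L))
  RNifti::writeNifti(img, path, datatype = if (isLabel) "int32" else "double")
  if (isLabel)
    jsonlite::write_json(as.list(volume@legend), legend, auto_unbox = TRUE,
                         pretty = TRUE)
  invisible(path)
}

legendSidecar <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

gridFromAffine <- function(A, shape) {
  if (any(!is.finite(A))) stop("missing or invalid NIfTI affine")
  M <- A[1:3, 1:3]
  sp <- sqrt(colSums(M^2))
  if (any(sp <= 0)) stop("degenerate NIfTI affine (zero spacing)")
  D <- sweep(M, 2L, sp, "/")
  if (max(abs(crossprod(D) - diag(3))) > 1e-4)
    stop("non-orthonormal NIfTI affine (sheared grids are not supported)")
  # snap to exact orthonormality so round trips are clean
  sv <- svd(D)
  D <- sv$u %*% t(sv$v)
  ImageGrid(shape, sp, A[1:3, 4], D)
}

#' Patient metadata for SUL conversion
#'
#' @slot sex "male" or "female" (the two categories of the James
#'   lean-body-mass equations).
#' @slot weightKg body weight, kg.
#' @slot heightCm height, cm.
#' @slot doseMBq injected activity, MBq (decay-corrected by the caller).
#' @export
setClass("PatientMeta", representation(sex = "character", weightKg = "numeric",
                                       heightCm = "numeric", doseMBq = "numeric"))

setValidity("PatientMeta", function(object) {
  msg <- character()
  if (!object@sex %in% c("male", "female"))
    msg <- c(msg, "sex must be 'male' or 'female'")
  if (object@weightKg <= 0) msg <- c(msg, "weight must be positive")
  if (object@heightCm <= 0) msg <- c(msg, "height must be positive")
  if (object@doseMBq <= 0) msg <- c(msg, "injected dose must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct patient metadata
#' @param sex "male" or "female".
#' @param weightKg weight in kg.
#' @param heightCm height in cm.
#' @param doseMBq injected dose in MBq.
#' @return A \linkS4class{PatientMeta}.
#' @examples
#' patientMeta("male", 70, 170, 400)
#' @export
patientMeta <- function(sex, weightKg, heightCm, doseMBq) {
  new("PatientMeta", sex = sex, weightKg = weightKg, heightCm = heightCm,
      doseMBq = doseMBq)
}

#' Read patient metadata from JSON
#'
#' Expects keys sex, weight_kg, height_cm, dose_MBq.
#' @param path JSON file.
#' @return A \linkS4class{PatientMeta}.
#' @export
readPatientMeta <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  patientMeta(j$sex, j$weight_kg, j$height_cm, j$dose_MBq)
}

#' @rdname readPatientMeta
#' @param meta a \linkS4class{PatientMeta}.
#' @export
writePatientMeta <- function(meta, path) {
  jsonlite::write_json(list(sex = meta@sex, weight_kg = meta@weightKg,
                            height_cm = meta@heightCm, dose_MBq = meta@doseMBq),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

setMethod("show", "PatientMeta", function(object) {
  cat("PatientMeta:", object@sex, object@weightKg, "kg,", object@heightCm,
      "cm, dose", object@doseMBq, "MBq\n")
})
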