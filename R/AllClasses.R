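#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib petrack, .registration = TRUE
#' @include AllGenerics.R
NULL

.SCALAR_KINDS <- c("activity_kBq_per_mL", "SUL", "HU", "distance_mm",
                   "uncertainty_mm")

#' Voxel grid geometry
#'
#' An \code{ImageGrid} fixes the geometry shared by all voxel volumes: the
#' array shape, the voxel spacing in mm, the world position (mm) of the
#' centre of voxel (0,0,0), and an orthonormal direction matrix whose columns
#' are the world directions of the three voxel axes. World coordinates follow
#' the NIfTI affine convention; voxel indices are 0-based and values sit at
#' voxel centres.
#'
#' @slot shape integer(3), voxels per axis.
#' @slot spacing numeric(3), mm per voxel along each axis.
#' @slot origin numeric(3), world mm of voxel (0,0,0) centre.
#' @slot direction 3x3 orthonormal matrix, det +/-1.
#' @export
setClass("ImageGrid", representation(shape = "integer", spacing = "numeric",
                                     origin = "numeric", direction = "matrix"))

setValidity("ImageGrid", function(object) {
  msg <- character()
  if (length(object@shape) != 3L || any(object@shape <= 0L))
    msg <- c(msg, "shape must be 3 positive integers")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be positive on all axes")
  if (length(object@origin) != 3L)
    msg <- c(msg, "origin must have length 3")
  D <- object@direction
  if (!all(dim(D) == c(3L, 3L)) ||
      max(abs(crossprod(D) - diag(3))) > 1e-6 ||
      abs(abs(det(D)) - 1) > 1e-6)
    msg <- c(msg, "direction must be orthonormal with determinant +/-1")
  if (length(msg)) msg else TRUE
})

#' Construct an ImageGrid
#'
#' @param shape integer(3) voxel counts.
#' @param spacing numeric(3) mm per voxel (scalar recycled).
#' @param origin numeric(3) world mm of the first voxel centre.
#' @param direction 3x3 orthonormal axis matrix.
#' @return An \linkS4class{ImageGrid}.
#' @examples
#' g <- ImageGrid(c(16, 16, 16), spacing = 2)
#' @export
ImageGrid <- function(shape, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      direction = diag(3)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("ImageGrid", shape = as.integer(shape), spacing = as.numeric(spacing),
      origin = as.numeric(origin), direction = direction)
}

#' Scalar voxel volume
#'
#' A 3-D voxel grid carrying real values of a stated kind: PET activity
#' concentration (kBq/mL), lean-body-mass corrected standardized uptake
#' values (SUL), CT numbers (HU), distances, or alignment uncertainty (mm).
#'
#' @slot grid the \linkS4class{ImageGrid}.
#' @slot values 3-D numeric array matching the grid shape.
#' @slot kind one of activity_kBq_per_mL, SUL, HU, distance_mm,
#'   uncertainty_mm.
#' @export
setClass("ScalarVolume", representation(grid = "ImageGrid", values = "array",
                                        kind = "character"))

setValidity("ScalarVolume", function(object) {
  msg <- character()
  if (!identical(dim(object@values), as.integer(object@grid@shape)))
    msg <- c(msg, "values dimensions must match grid shape")
  if (!object@kind %in% .SCALAR_KINDS)
    msg <- c(msg, paste("kind must be one of:", paste(.SCALAR_KINDS, collapse = ", ")))
  if (anyNA(object@values) || any(!is.finite(object@values)))
    msg <- c(msg, "values must be finite")
  else if (identical(object@kind, "SUL") && any(object@values < 0))
    msg <- c(msg, "SUL values must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a ScalarVolume
#' @param values 3-D numeric array.
#' @param grid an \linkS4class{ImageGrid} (defaults to unit spacing).
#' @param kind value kind, see \linkS4class{ScalarVolume}.
#' @return A \linkS4class{ScalarVolume}.
#' @export
ScalarVolume <- function(values, grid = NULL, kind = "SUL") {
  if (is.null(grid)) grid <- ImageGrid(dim(values))
  storage.mode(values) <- "double"
  new("ScalarVolume", grid = grid, values = values, kind = kind)
}

#' Integer label volume
#'
#' Organ/region/normal-activity labels on a voxel grid, with a legend mapping
#' label values to names. Label 0 is background and carries no legend entry.
#'
#' @slot grid the \linkS4class{ImageGrid}.
#' @slot labels 3-D integer array.
#' @slot legend named character vector; names are label integers as strings.
#' @export
setClass("LabelVolume", representation(grid = "ImageGrid", labels = "array",
                                       legend = "character"))

setValidity("LabelVolume", function(object) {
  msg <- character()
  if (!identical(dim(object@labels), as.integer(object@grid@shape)))
    msg <- c(msg, "labels dimensions must match grid shape")
  if (any(object@labels < 0L))
    msg <- c(msg, "labels must be non-negative")
  used <- setdiff(unique(as.integer(object@labels)), 0L)
  if (!all(as.character(used) %in% names(object@legend)))
    msg <- c(msg, "every non-zero label must be present in the legend")
  if (length(msg)) msg else TRUE
})

#' Construct a LabelVolume
#' @param labels 3-D integer array (0 = background).
#' @param grid an \linkS4class{ImageGrid}.
#' @param legend named character vector mapping label values to names.
#' @return A \linkS4class{LabelVolume}.
#' @export
LabelVolume <- function(labels, grid = NULL, legend = character()) {
  if (is.null(grid)) grid <- ImageGrid(dim(labels))
  storage.mode(labels) <- "integer"
  new("LabelVolume", grid = grid, labels = labels, legend = legend)
}

#' Dense displacement field
#'
#' Per-voxel displacement vectors u(x), in mm, mapping source (follow-up)
#' world coordinates to target (baseline) world coordinates: a point x on the
#' source grid corresponds to x + u(x) in the target scan. Inside segmented
#' organs u(x) equals the organ transform's displacement exactly (Dirichlet
#' condition of the harmonic interpolation).
#'
#' @slot grid the source \linkS4class{ImageGrid}.
#' @slot u 4-D numeric array [nx, ny, nz, 3], mm.
#' @slot region 3-D integer array of body-region ids (may be empty).
#' @export
setClass("DisplacementField", representation(grid = "ImageGrid", u = "array",
                                             region = "array"))

setValidity("DisplacementField", function(object) {
  msg <- character()
  if (!identical(dim(object@u)[1:3], as.integer(object@grid@shape)) ||
      dim(object@u)[4] != 3L)
    msg <- c(msg, "u must be [nx, ny, nz, 3]")
  if (any(!is.finite(object@u)))
    msg <- c(msg, "u must be finite everywhere")
  if (length(msg)) msg else TRUE
})

#' Triangulated organ surface
#'
#' Iso-surface of a binary organ mask: vertex coordinates in world mm and
#' triangle index triples.
#'
#' @slot vertices Nx3 numeric matrix, mm.
#' @slot faces Mx3 integer matrix of 1-based vertex indices.
#' @export
setClass("Surface", representation(vertices = "matrix", faces = "matrix"))

setValidity("Surface", function(object) {
  msg <- character()
  if (ncol(object@vertices) != 3L) msg <- c(msg, "vertices must be Nx3")
  if (nrow(object@vertices) < 4L) msg <- c(msg, "a surface needs >= 4 vertices")
  if (nrow(object@faces) > 0L &&
      (min(object@faces) < 1L || max(object@faces) > nrow(object@vertices)))
    msg <- c(msg, "face indices out of range")
  if (length(msg)) msg else TRUE
})

#' Per-organ spatial transform
#'
#' Rigid (rotation + translation) or affine map estimated for one organ,
#' stored as a 3x4 matrix [A | b] acting on world mm coordinates:
#' y = A x + b. For rigid transforms A is a rotation with det +1.
#'
#' @slot organ organ name.
#' @slot model "rigid" or "affine".
#' @slot matrix 3x4 transform matrix.
#' @slot iterations ICP iterations run.
#' @slot meanDist final mean correspondence distance (mm).
#' @slot converged logical convergence flag.
#' @export
setClass("OrganTransform", representation(organ = "character", model = "character",
                                          matrix = "matrix", iterations = "integer",
                                          meanDist = "numeric", converged = "logical"))

setValidity("OrganTransform", function(object) {
  msg <- character()
  if (!object@model %in% c("rigid", "affine"))
    msg <- c(msg, "model must be rigid or affine")
  if (!all(dim(object@matrix) == c(3L, 4L)))
    msg <- c(msg, "matrix must be 3x4")
  else if (any(!is.finite(object@matrix)))
    msg <- c(msg, "matrix must be finite")
  else if (identical(object@model, "rigid")) {
    R <- object@matrix[, 1:3]
    if (max(abs(crossprod(R) - diag(3))) > 1e-8 || abs(det(R) - 1) > 1e-8)
      msg <- c(msg, "rigid rotation must be orthonormal with det(R) = +1")
  }
  if (length(msg)) msg else TRUE
})

OrganTransform <- function(organ, model, matrix, iterations = 0L,
                           meanDist = NA_real_, converged = TRUE) {
  new("OrganTransform", organ = organ, model = model, matrix = matrix,
      iterations = as.integer(iterations), meanDist = meanDist,
      converged = converged)
}

#' Background volume of interest
#'
#' The PERCIST reference VOI: a 30 mm diameter sphere in the liver or a
#' 10 mm x 20 mm cylinder in the descending aorta, placed automatically to
#' avoid focal lesions and noise.
#'
#' @slot shape "sphere" or "cylinder".
#' @slot centre world mm centre.
#' @slot organ "liver" or "aorta".
#' @slot axis cylinder axis direction (unit vector; NA for spheres).
#' @slot members linear voxel indices (1-based) of member voxels.
#' @slot grid the grid the members refer to.
#' @export
setClass("BackgroundVOI", representation(shape = "character", centre = "numeric",
                                         organ = "character", axis = "numeric",
                                         members = "integer", grid = "ImageGrid"))

setValidity("BackgroundVOI", function(object) {
  msg <- character()
  if (!object@shape %in% c("sphere", "cylinder"))
    msg <- c(msg, "shape must be sphere or cylinder")
  if (!object@organ %in% c("liver", "aorta"))
    msg <- c(msg, "organ must be liver or aorta")
  if (length(object@members) < 1L)
    msg <- c(msg, "VOI must contain at least one voxel")
  if (length(msg)) msg else TRUE
})

#' Background activity statistics
#'
#' SULmean, SD and the lesion-measurability threshold of a background VOI.
#' Liver threshold: 1.5 SULmean + 2 SD; aorta: 2.0 SULmean + 2 SD
#' (PERCIST 1.0).
#'
#' @slot organ "liver" or "aorta".
#' @slot SULmean mean SUL over member voxels.
#' @slot SD sample standard deviation (0 for a single voxel).
#' @slot threshold measurability threshold.
#' @slot n member voxel count.
#' @export
setClass("BackgroundStats", representation(organ = "character", SULmean = "numeric",
                                           SD = "numeric", threshold = "numeric",
                                           n = "integer"))

setValidity("BackgroundStats", function(object) {
  msg <- character()
  if (object@SD < 0) msg <- c(msg, "SD must be >= 0")
  if (object@threshold < object@SULmean)
    msg <- c(msg, "threshold must be >= SULmean")
  if (length(msg)) msg else TRUE
})

#' Alignment uncertainty table
#'
#' Per-organ Hausdorff distances from calibration pairs and the derived
#' within-organ uncertainty: the 75th percentile (linear interpolation
#' between order statistics).
#'
#' @slot distances named list of numeric vectors (mm) per organ.
#' @slot q75 named numeric vector of 75th percentiles (mm).
#' @export
setClass("UncertaintyTable", representation(distances = "list", q75 = "numeric"))

setValidity("UncertaintyTable", function(object) {
  msg <- character()
  if (any(unlist(object@distances, use.names = FALSE) < 0))
    msg <- c(msg, "distances must be >= 0")
  if (!identical(sort(names(object@distances)), sort(names(object@q75))))
    msg <- c(msg, "distances and q75 must cover the same organs")
  if (length(msg)) msg else TRUE
})

# ---- accessors ----

#' @describeIn ImageGrid voxel counts per axis
#' @param x an object with a grid
#' @export
setMethod("gridShape", "ImageGrid", function(x) x@shape)
#' @export
setMethod("spacing", "ImageGrid", function(x) x@spacing)
#' @export
setMethod("origin", "ImageGrid", function(x) x@origin)
#' @export
setMethod("direction", "ImageGrid", function(x) x@direction)

#' @export
setMethod("imageGrid", "ScalarVolume", function(x) x@grid)
#' @export
setMethod("imageGrid", "LabelVolume", function(x) x@grid)
#' @export
setMethod("imageGrid", "DisplacementField", function(x) x@grid)
#' @export
setMethod("gridShape", "ScalarVolume", function(x) x@grid@shape)
#' @export
setMethod("gridShape", "LabelVolume", function(x) x@grid@shape)
#' @export
setMethod("spacing", "ScalarVolume", function(x) x@grid@spacing)
#' @export
setMethod("spacing", "LabelVolume", function(x) x@grid@spacing)
#' @export
setMethod("voxelValues", "ScalarVolume", function(x) x@values)
#' @export
setMethod("voxelKind", "ScalarVolume", function(x) x@kind)
#' @export
setMethod("voxelLabels", "LabelVolume", function(x) x@labels)
#' @export
setMethod("labelLegend", "LabelVolume", function(x) x@legend)
#' @export
setMethod("displacement", "DisplacementField", function(x) x@u)
#' @export
setMethod("vertices", "Surface", function(x) x@vertices)
#' @export
setMethod("faces", "Surface", function(x) x@faces)
#' @export
setMethod("transformMatrix", "OrganTransform", function(x) x@matrix)
#' @export
setMethod("voiMembers", "BackgroundVOI", function(x) x@members)

# ---- show methods ----

setMethod("show", "ImageGrid", function(object) {
  cat("ImageGrid:", paste(object@shape, collapse = " x "), "voxels,",
      paste(signif(object@spacing, 4), collapse = " x "), "mm\n")
})

setMethod("show", "ScalarVolume", function(object) {
  cat("ScalarVolume [", object@kind, "]: ",
      paste(object@grid@shape, collapse = " x "), " voxels, ",
      paste(signif(object@grid@spacing, 4), collapse = " x "), " mm, range [",
      signif(min(object@values), 4), ", ", signif(max(object@values), 4), "]\n",
      sep = "")
})

setMethod("show", "LabelVolume", function(object) {
  used <- setdiff(unique(as.integer(object@labels)), 0L)
  cat("LabelVolume: ", paste(object@grid@shape, collapse = " x "),
      " voxels, ", length(used), " labels",
      if (length(object@legend)) paste0(" (", paste(utils::head(object@legend, 5),
                                                    collapse = ", "),
                                        if (length(object@legend) > 5) ", ..." else "", ")"),
      "\n", sep = "")
})

setMethod("show", "DisplacementField", function(object) {
  mag <- sqrt(object@u[, , , 1]^2 + object@u[, , , 2]^2 + object@u[, , , 3]^2)
  cat("DisplacementField: ", paste(object@grid@shape, collapse = " x "),
      " voxels, |u| mean ", signif(mean(mag), 4), " mm, max ",
      signif(max(mag), 4), " mm\n", sep = "")
})

setMethod("show", "Surface", function(object) {
  cat("Surface:", nrow(object@vertices), "vertices,", nrow(object@faces),
      "triangles\n")
})

setMethod("show", "OrganTransform", function(object) {
  cat("OrganTransform [", object@organ, ", ", object@model, "]: ",
      object@iterations, " ICP iterations, mean distance ",
      signif(object@meanDist, 4), " mm",
      if (!object@converged) " (not converged)", "\n", sep = "")
})

setMethod("show", "BackgroundVOI", function(object) {
  cat("BackgroundVOI [", object@organ, ", ", object@shape, "]: centre (",
      paste(signif(object@centre, 4), collapse = ", "), ") mm, ",
      length(object@members), " voxels\n", sep = "")
})

setMethod("show", "BackgroundStats", function(object) {
  cat("BackgroundStats [", object@organ, "]: SULmean ",
      signif(object@SULmean, 4), ", SD ", signif(object@SD, 4),
      ", threshold ", signif(object@threshold, 4), " (", object@n,
      " voxels)\n", sep = "")
})

setMethod("show", "UncertaintyTable", function(object) {
  cat("UncertaintyTable:", length(object@q75), "organs; 75th percentile range [",
      signif(min(object@q75), 4), ",", signif(max(object@q75), 4), "] mm\n")
})
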