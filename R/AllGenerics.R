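NULL

#' @export
setGeneric("imageGrid", function(x) standardGeneric("imageGrid"))

#' @export
setGeneric("gridShape", function(x) standardGeneric("gridShape"))

#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @export
setGeneric("origin", function(x) standardGeneric("origin"))

#' @export
setGeneric("direction", function(x) standardGeneric("direction"))

#' @export
setGeneric("voxelValues", function(x) standardGeneric("voxelValues"))

#' @export
setGeneric("voxelKind", function(x) standardGeneric("voxelKind"))

#' @export
setGeneric("voxelLabels", function(x) standardGeneric("voxelLabels"))

#' @export
setGeneric("labelLegend", function(x) standardGeneric("labelLegend"))

#' @export
setGeneric("displacement", function(x) standardGeneric("displacement"))

#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))

#' @export
setGeneric("faces", function(x) standardGeneric("faces"))

#' @export
setGeneric("transformMatrix", function(x) standardGeneric("transformMatrix"))

#' @export
setGeneric("voiMembers", function(x) standardGeneric("voiMembers"))
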