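#' Organ-to-model and organ-to-region tables
#'
#' \code{organModelTable} says which transformation model each organ gets
#' during organ-wise alignment: bones and vertebrae are rigid, soft-tissue
#' organs affine. \code{organRegionTable} assigns each organ to one of the
#' six interpolation regions (head, torso, left/right arm, left/right leg)
#' used for the regional harmonic interpolation. Both can be overridden by
#' passing a modified named vector to the alignment functions. Unknown organ
#' names fall back to "affine" / raise an error respectively.
#'
#' @return A named character vector (organ name -> model or region).
#' @examples
#' organModelTable()[["liver"]]
#' organRegionTable()[["femur_left"]]
#' @export
organModelTable <- function() {
  c(liver = "affine", spleen = "affine", lung_left = "affine",
    lung_right = "affine", kidney_left = "affine", kidney_right = "affine",
    heart = "affine", bladder = "affine", aorta = "affine", brain = "affine",
    spine = "rigid", skull = "rigid",
    femur_left = "rigid", femur_right = "rigid",
    humerus_left = "rigid", humerus_right = "rigid",
    vertebra = "rigid", pelvis = "rigid", rib = "rigid")
}

#' @rdname organModelTable
#' @export
organRegionTable <- function() {
  c(liver = "torso", spleen = "torso", lung_left = "torso",
    lung_right = "torso", kidney_left = "torso", kidney_right = "torso",
    heart = "torso", bladder = "torso", aorta = "torso", spine = "torso",
    brain = "head", skull = "head",
    femur_left = "leg_left", femur_right = "leg_right",
    humerus_left = "arm_left", humerus_right = "arm_right")
}

#' The six interpolation regions
#'
#' Fixed id/name mapping of the anatomical regions in which displacement
#' interpolation is carried out independently.
#' @return Named integer vector of region ids.
#' @export
bodyRegions <- function() {
  c(head = 1L, torso = 2L, arm_left = 3L, arm_right = 4L,
    leg_left = 5L, leg_right = 6L)
}
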