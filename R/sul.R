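#' Lean body mass (James equations)
#'
#' Computes lean body mass from sex, weight and height using the James
#' predictive equations, the LBM definition PERCIST prescribes for SUL:
#' males \eqn{1.10 W - 128 (W/H)^2}, females \eqn{1.07 W - 148 (W/H)^2},
#' with W in kg and H in cm.
#'
#' @param sex "male" or "female".
#' @param weightKg weight, kg (> 0).
#' @param heightCm height, cm (> 0).
#' @return Lean body mass in kg.
#' @examples
#' computeLeanBodyMass("male", 70, 170)    # 55.298
#' computeLeanBodyMass("female", 60, 165)  # 44.630
#' @export
computeLeanBodyMass <- function(sex, weightKg, heightCm) {
  if (!is.character(sex) || length(sex) != 1L || !sex %in% c("male", "female"))
    stop("sex must be 'male' or 'female'")
  if (weightKg <= 0 || heightCm <= 0)
    stop("weight and height must be positive")
  r2 <- (weightKg / heightCm)^2
  lbm <- if (sex == "male") 1.10 * weightKg - 128 * r2
         else 1.07 * weightKg - 148 * r2
  if (lbm <= 0)
    stop("non-physiological input: computed lean body mass is not positive (",
         signif(lbm, 4), " kg)")
  lbm
}

#' Convert PET activity to SUL
#'
#' Converts an activity-concentration volume (kBq/mL, decay-corrected to the
#' injection reference time by the caller) into lean-body-mass corrected
#' standardized uptake values:
#' \deqn{SUL(x) = C(x)[Bq/mL] \cdot LBM[g] / dose[Bq]}
#' assuming 1 g/mL tissue density, which reduces to
#' \code{C_kBq_per_mL * LBM_kg / dose_MBq}. A volume already of kind
#' \code{"SUL"} is returned unchanged (pre-computed SUL inputs are accepted).
#'
#' @param volume a \linkS4class{ScalarVolume} of kind
#'   \code{"activity_kBq_per_mL"} or \code{"SUL"}.
#' @param meta a \linkS4class{PatientMeta}.
#' @return A \linkS4class{ScalarVolume} of kind "SUL".
#' @examples
#' g <- ImageGrid(c(4, 4, 4), 2)
#' act <- ScalarVolume(array(5, c(4, 4, 4)), g, kind = "activity_kBq_per_mL")
#' sul <- toSUL(act, patientMeta("male", 70, 170, 400))
#' voxelValues(sul)[1]  # ~0.691
#' @export
toSUL <- function(volume, meta) {
  if (identical(volume@kind, "SUL")) return(volume)
  if (!identical(volume@kind, "activity_kBq_per_mL"))
    stop("toSUL expects an activity_kBq_per_mL or SUL volume, got ", volume@kind)
  if (meta@doseMBq <= 0) stop("injected dose must be positive")
  lbm <- computeLeanBodyMass(meta@sex, meta@weightKg, meta@heightCm)
  vals <- volume@values * lbm / meta@doseMBq
  vals[vals < 0] <- 0
  ScalarVolume(vals, volume@grid, kind = "SUL")
}
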