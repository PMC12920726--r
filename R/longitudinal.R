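#' Map a point through a displacement field
#'
#' Returns \code{x + u(x)} with the displacement trilinearly interpolated at
#' the (possibly off-lattice) source point, i.e. the baseline position
#' corresponding to a follow-up position.
#'
#' @param field a \linkS4class{DisplacementField}.
#' @param point world mm point (length-3 vector or Nx3 matrix).
#' @return Mapped point(s), same shape as the input.
#' @export
mapPoint <- function(field, point) {
  grid <- field@grid
  pts <- rbindMat(point)
  vox <- worldToVoxel(grid, pts)
  if (any(vox < -0.5) || any(sweep(vox, 2L, grid@shape - 0.5, ">=")))
    stop("point outside the displacement-field grid")
  u <- vapply(1:3, function(k)
    trilinearInterp(array(field@u[, , , k], dim = grid@shape), vox),
    numeric(nrow(pts)))
  out <- pts + matrix(u, nrow = nrow(pts))
  if (is.null(dim(point))) out[1L, ] else out
}

#' Baseline SULpeak within an uncertainty search sphere
#'
#' Extracts the highest non-physiological SULpeak in the baseline scan,
#' searched over sphere centres (voxel centres) within \code{radius} mm of
#' the mapped point. Candidate centres whose 1 cm3 peak sphere
#' majority-overlaps the normal-activity mask are excluded as physiological
#' (same >50 percent vote as hotspot classification). Returns an absent
#' value when no admissible centre exists.
#'
#' @param sul baseline SUL \linkS4class{ScalarVolume}.
#' @param normalMask baseline normal-activity mask
#'   (\linkS4class{LabelVolume} or logical array).
#' @param centre mapped point, world mm.
#' @param radius search radius, mm (>= 0; at 0 only the nearest voxel
#'   centre is used).
#' @return List: \code{value} (SULpeak or NA), \code{centre} (peak centre mm
#'   or NULL).
#' @export
pairedSULpeak <- function(sul, normalMask, centre, radius) {
  if (radius < 0) stop("search radius must be >= 0")
  grid <- sul@grid
  if (is(normalMask, "LabelVolume")) {
    stopIfGridMismatch(grid, normalMask@grid, "SUL and normal-activity mask")
    normalMask <- normalMask@labels != 0L
  }
  cvox <- worldToVoxel(grid, centre)[1L, ]
  off <- sphereOffsets(grid@spacing, radius)
  cand <- sweep(off, 2L, round(cvox), "+")
  W <- voxelToWorld(grid, cand)
  d <- sqrt(rowSums(sweep(W, 2L, rbindMat(centre)[1L, ], "-")^2))
  cand <- cand[d <= radius + 1e-9, , drop = FALSE]
  if (nrow(cand) == 0L)   # radius smaller than a voxel: nearest centre only
    cand <- matrix(round(cvox), ncol = 3L)
  ok <- cand[, 1L] >= 0 & cand[, 1L] < grid@shape[1L] &
        cand[, 2L] >= 0 & cand[, 2L] < grid@shape[2L] &
        cand[, 3L] >= 0 & cand[, 3L] < grid@shape[3L]
  cand <- cand[ok, , drop = FALSE]
  if (nrow(cand) == 0L) return(list(value = NA_real_, centre = NULL))
  ord <- order(cand[, 1L], cand[, 2L], cand[, 3L])
  cand <- cand[ord, , drop = FALSE]
  peakOff <- sphereOffsets(grid@spacing, 6.2035)
  st <- .sphere_scan(as.numeric(sul@values), as.integer(grid@shape),
                     matrix(as.integer(cand), ncol = 3L),
                     matrix(as.integer(peakOff), ncol = 3L),
                     as.logical(normalMask))
  admissible <- st$maskfrac <= 0.5
  if (!any(admissible)) return(list(value = NA_real_, centre = NULL))
  vals <- st$mean
  vals[!admissible] <- -Inf
  best <- which.max(vals)
  list(value = st$mean[best],
       centre = voxelToWorld(grid, cand[best, , drop = FALSE])[1L, ])
}

#' Percent change in SULpeak
#'
#' \code{100 (followup - baseline) / baseline}; undefined (NA) when the
#' baseline value is absent or non-positive, in which case the pair is a
#' candidate new lesion.
#'
#' @param baseline,followup SULpeak values.
#' @return Percent change, or NA when undefined.
#' @examples
#' percentChange(10, 5)    # -50
#' percentChange(2, 2.8)   # +40
#' @export
percentChange <- function(baseline, followup) {
  if (is.na(baseline) || baseline <= 0) return(NA_real_)
  100 * (followup - baseline) / baseline
}

#' Pair follow-up lesions with baseline SULpeaks
#'
#' For every follow-up lesion hotspot: reads the search radius from the
#' uncertainty map at the lesion's SULpeak voxel, maps that point to the
#' baseline scan through the displacement field, extracts the highest
#' non-physiological baseline SULpeak within the search sphere, and computes
#' the percent change. Pairs are sorted by follow-up SULpeak, descending.
#' Lesions with no admissible baseline value get NA change and a
#' new-lesion-candidate flag.
#'
#' @param followupHotspots classified hotspot table (lesions only are used).
#' @param field \linkS4class{DisplacementField} (follow-up to baseline).
#' @param uncMap uncertainty \linkS4class{ScalarVolume} on the follow-up
#'   grid.
#' @param baselineSUL baseline SUL \linkS4class{ScalarVolume}.
#' @param baselineNormal baseline normal-activity mask.
#' @return data.frame: followupId, followupSULpeak, search radius, mapped
#'   centre, baselineSULpeak, percentChange, newLesionCandidate plus
#'   user-settable flags (newLesion, unequivocalProgression) initialised to
#'   FALSE.
#' @export
buildLesionPairs <- function(followupHotspots, field, uncMap, baselineSUL,
                             baselineNormal) {
  hs <- followupHotspots[!is.na(followupHotspots$class) &
                         followupHotspots$class == "lesion", , drop = FALSE]
  out <- data.frame(followupId = integer(), followupSULpeak = numeric(),
                    radius = numeric(), mappedX = numeric(),
                    mappedY = numeric(), mappedZ = numeric(),
                    baselineSULpeak = numeric(), percentChange = numeric(),
                    absoluteChange = numeric(),
                    newLesionCandidate = logical(), newLesion = logical(),
                    unequivocalProgression = logical())
  if (nrow(hs) == 0L) return(out)
  hs <- hs[order(-hs$SULpeak), , drop = FALSE]
  grid <- uncMap@grid
  for (i in seq_len(nrow(hs))) {
    ctr <- c(hs$cx[i], hs$cy[i], hs$cz[i])
    vox <- voxelToLinear(grid, round(worldToVoxel(grid, ctr)))
    radius <- uncMap@values[vox]
    mapped <- mapPoint(field, ctr)
    pk <- pairedSULpeak(baselineSUL, baselineNormal, mapped, radius)
    pc <- percentChange(pk$value, hs$SULpeak[i])
    out <- rbind(out, data.frame(
      followupId = hs$id[i], followupSULpeak = hs$SULpeak[i],
      radius = radius, mappedX = mapped[1L], mappedY = mapped[2L],
      mappedZ = mapped[3L],
      baselineSULpeak = if (is.null(pk$value)) NA_real_ else pk$value,
      percentChange = pc,
      absoluteChange = if (is.na(pk$value)) NA_real_ else
        hs$SULpeak[i] - pk$value,
      newLesionCandidate = is.na(pc), newLesion = FALSE,
      unequivocalProgression = FALSE))
  }
  rownames(out) <- NULL
  out
}
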