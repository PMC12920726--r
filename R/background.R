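#' Place the spherical liver background VOI
#'
#' Places the PERCIST 30 mm diameter sphere inside the liver so that focal
#' lesions and noisy areas are avoided: candidate centres are the in-mask
#' voxels at which the whole sphere fits inside the liver (inner Euclidean
#' distance to the mask boundary greater than the 15 mm radius), subsampled
#' on a voxel stride for speed; the centre minimising
#' \code{|VOI mean - robust liver mean| + VOI SD} is selected, where the
#' robust liver mean is the trimmed mean of in-mask SUL between the 25th and
#' 75th percentiles. Ties break by lexicographic centre order, making the
#' placement deterministic.
#'
#' @param sul a SUL \linkS4class{ScalarVolume}.
#' @param mask liver mask: logical array or \linkS4class{LabelVolume}
#'   (non-zero = liver).
#' @param stride candidate subsampling stride in voxels.
#' @param exhaustive if TRUE, score every feasible centre.
#' @param maxCandidates cap on scored candidates (effective stride grows
#'   deterministically beyond it).
#' @return A \linkS4class{BackgroundVOI}.
#' @export
placeLiverVOI <- function(sul, mask, stride = 2L, exhaustive = FALSE,
                          maxCandidates = 600L) {
  placeVOI(sul, mask, organ = "liver", stride = stride,
           exhaustive = exhaustive, maxCandidates = maxCandidates)
}

#' Place the cylindrical aorta background VOI
#'
#' Places the PERCIST 10 mm diameter, 20 mm high cylinder in the descending
#' aorta. The cylinder axis is aligned with the principal axis of the mask
#' (first eigenvector of the voxel-coordinate covariance); candidates are
#' scored with the same lesion/noise-avoidance rule as the liver sphere.
#'
#' @inheritParams placeLiverVOI
#' @param mask aorta mask.
#' @return A \linkS4class{BackgroundVOI}.
#' @export
placeAortaVOI <- function(sul, mask, stride = 2L, exhaustive = FALSE,
                          maxCandidates = 600L) {
  placeVOI(sul, mask, organ = "aorta", stride = stride,
           exhaustive = exhaustive, maxCandidates = maxCandidates)
}

maskArray <- function(mask) {
  if (is(mask, "LabelVolume")) mask@labels != 0L
  else if (is.array(mask)) mask != 0
  else stop("mask must be an array or LabelVolume")
}

placeVOI <- function(sul, mask, organ, stride = 2L, exhaustive = FALSE,
                     maxCandidates = 600L) {
  grid <- sul@grid
  m <- maskArray(mask)
  if (!identical(dim(m), as.integer(grid@shape)))
    stop("grid mismatch between SUL volume and ", organ, " mask")
  if (!any(m)) stop(organ, " mask is empty")
  sp <- grid@spacing
  vals <- sul@values
  inIdx <- which(m)

  if (organ == "liver") {
    r <- 15
    # inner distance: distance from each in-mask voxel to the nearest
    # outside voxel centre (counting off-grid voxels as outside); the sphere
    # fits where it exceeds the radius
    iv <- linearToVoxel(grid, inIdx)
    edge <- pmin((iv[, 1L] + 1L) * sp[1L], (grid@shape[1L] - iv[, 1L]) * sp[1L],
                 (iv[, 2L] + 1L) * sp[2L], (grid@shape[2L] - iv[, 2L]) * sp[2L],
                 (iv[, 3L] + 1L) * sp[3L], (grid@shape[3L] - iv[, 3L]) * sp[3L])
    inner <- edge
    if (any(!m)) {
      ed <- .edt_feature(as.logical(!m), as.integer(dim(m)), as.numeric(sp))
      inner <- pmin(ed$dist[inIdx], edge)
    }
    feasible <- inIdx[inner > r]
    if (!length(feasible))
      stop("liver mask cannot contain the 30 mm background sphere; ",
           "fall back to the aorta VOI")
    offsets <- sphereOffsets(sp, r)
    axis <- c(NA_real_, NA_real_, NA_real_)
    memberFun <- NULL
  } else {
    idx <- linearToVoxel(grid, inIdx)
    Wm <- voxelToWorld(grid, idx)
    ctr <- colMeans(Wm)
    pc <- eigen(stats::cov(Wm), symmetric = TRUE)
    axis <- pc$vectors[, 1L]
    proj <- as.numeric(sweep(Wm, 2L, ctr, "-") %*% axis)
    if (diff(range(proj)) < 20)
      stop("aorta mask too short along its principal axis ",
           "(a 20 mm cylinder does not fit)")
    # all grid voxels of the ideal cylinder around a candidate centre;
    # feasible only when every one of them lies inside the mask
    cylOff <- sphereOffsets(sp, sqrt(10^2 + 5^2) + max(sp))
    memberFun <- function(centreIdx, centreW) {
      nb <- sweep(cylOff, 2L, centreIdx, "+")
      rel <- sweep(voxelToWorld(grid, nb), 2L, centreW, "-")
      ax <- as.numeric(rel %*% axis)
      rad2 <- rowSums(rel^2) - ax^2
      # boundary-exclusive membership so the realised height/diameter do not
      # overshoot the nominal 20 mm / 10 mm
      nb <- nb[abs(ax) < 10 - 1e-9 & rad2 < 25 - 1e-9, , drop = FALSE]
      inGrid <- nb[, 1L] >= 0 & nb[, 1L] < grid@shape[1L] &
                nb[, 2L] >= 0 & nb[, 2L] < grid@shape[2L] &
                nb[, 3L] >= 0 & nb[, 3L] < grid@shape[3L]
      if (!all(inGrid)) return(NULL)
      mem <- voxelToLinear(grid, nb)
      if (!all(m[mem])) return(NULL)   # cylinder clipped by the mask
      mem
    }
    # necessary condition, pruning candidates before the full cylinder
    # check: the 5 mm radius must fit around the centre locally
    iv <- linearToVoxel(grid, inIdx)
    edge <- pmin((iv[, 1L] + 1L) * sp[1L], (grid@shape[1L] - iv[, 1L]) * sp[1L],
                 (iv[, 2L] + 1L) * sp[2L], (grid@shape[2L] - iv[, 2L]) * sp[2L],
                 (iv[, 3L] + 1L) * sp[3L], (grid@shape[3L] - iv[, 3L]) * sp[3L])
    inner <- edge
    if (any(!m)) {
      ed <- .edt_feature(as.logical(!m), as.integer(dim(m)), as.numeric(sp))
      inner <- pmin(ed$dist[inIdx], edge)
    }
    feasible <- inIdx[inner > 5 - max(sp)]
    if (!length(feasible))
      stop("no feasible placement for the aorta cylinder VOI")
    offsets <- NULL
  }

  robust <- trimmedMean(vals[inIdx])

  # deterministic stride subsampling on voxel coordinates
  pickStride <- function(cand, s) {
    iv <- linearToVoxel(grid, cand)
    cand[iv[, 1L] %% s == 0L & iv[, 2L] %% s == 0L & iv[, 3L] %% s == 0L]
  }
  cand <- feasible
  if (!exhaustive) {
    s <- as.integer(stride)
    cand <- pickStride(feasible, s)
    while (length(cand) > maxCandidates) {
      s <- s + 1L
      cand <- pickStride(feasible, s)
    }
    if (!length(cand)) cand <- feasible
  }
  # lexicographic candidate order for deterministic ties
  civ <- linearToVoxel(grid, cand)
  ord <- order(civ[, 1L], civ[, 2L], civ[, 3L])
  cand <- cand[ord]
  civ <- civ[ord, , drop = FALSE]

  if (organ == "liver") {
    st <- .sphere_scan(as.numeric(vals), as.integer(grid@shape),
                       matrix(as.integer(civ), ncol = 3L),
                       matrix(as.integer(offsets), ncol = 3L),
                       as.logical(m))
    ok <- st$maskfrac >= 1 - 1e-12   # whole sphere inside the liver
    if (!any(ok))
      stop("liver mask cannot contain the 30 mm background sphere; ",
           "fall back to the aorta VOI")
    score <- abs(st$mean - robust) + st$sd
    score[!ok] <- Inf
    best <- which.min(score)
    centreW <- voxelToWorld(grid, civ[best, , drop = FALSE])[1L, ]
    members <- inSphere(grid, centreW, 15)
  } else {
    scoreCands <- function(civ, candW) {
      score <- rep(Inf, nrow(candW))
      membersList <- vector("list", nrow(candW))
      for (i in seq_len(nrow(candW))) {
        mem <- memberFun(civ[i, ], candW[i, ])
        if (is.null(mem) || length(mem) < 2L) next
        v <- vals[mem]
        score[i] <- abs(mean(v) - robust) + stats::sd(v)
        membersList[[i]] <- mem
      }
      list(score = score, members = membersList)
    }
    candW <- voxelToWorld(grid, civ)
    sc <- scoreCands(civ, candW)
    if (!any(is.finite(sc$score)) && length(cand) < length(feasible)) {
      # the stride lattice can miss the narrow feasible core entirely
      civ <- linearToVoxel(grid, feasible)
      ord <- order(civ[, 1L], civ[, 2L], civ[, 3L])
      civ <- civ[ord, , drop = FALSE]
      candW <- voxelToWorld(grid, civ)
      sc <- scoreCands(civ, candW)
    }
    score <- sc$score
    membersList <- sc$members
    if (!any(is.finite(score)))
      stop("no feasible placement for the aorta cylinder VOI")
    best <- which.min(score)
    centreW <- candW[best, ]
    members <- membersList[[best]]
  }

  new("BackgroundVOI", shape = if (organ == "liver") "sphere" else "cylinder",
      centre = as.numeric(centreW), organ = organ, axis = as.numeric(axis),
      members = as.integer(members), grid = grid)
}

trimmedMean <- function(v) {
  q <- stats::quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
  mean(v[v >= q[1L] & v <= q[2L]])
}

inSphere <- function(grid, centreW, radius) {
  cIdx <- round(worldToVoxel(grid, centreW))[1L, ]
  off <- sphereOffsets(grid@spacing, radius + max(grid@spacing))
  idx <- sweep(off, 2L, cIdx, "+")
  ok <- idx[, 1L] >= 0 & idx[, 1L] < grid@shape[1L] &
        idx[, 2L] >= 0 & idx[, 2L] < grid@shape[2L] &
        idx[, 3L] >= 0 & idx[, 3L] < grid@shape[3L]
  idx <- idx[ok, , drop = FALSE]
  W <- voxelToWorld(grid, idx)
  d2 <- rowSums(sweep(W, 2L, centreW, "-")^2)
  # boundary-exclusive so the realised diameter does not overshoot 2*radius
  voxelToLinear(grid, idx[d2 < radius^2 - 1e-9, , drop = FALSE])
}

#' Background activity statistics
#'
#' SULmean and SD over the VOI member voxels and the lesion-measurability
#' threshold: \code{1.5 SULmean + 2 SD} for the liver VOI,
#' \code{2.0 SULmean + 2 SD} for the aorta VOI (PERCIST 1.0).
#'
#' @param sul a SUL \linkS4class{ScalarVolume}.
#' @param voi a \linkS4class{BackgroundVOI}.
#' @return A \linkS4class{BackgroundStats}.
#' @export
backgroundStats <- function(sul, voi) {
  if (length(voi@members) == 0L) stop("empty background VOI")
  stopIfGridMismatch(sul@grid, voi@grid, "SUL volume and VOI")
  v <- sul@values[voi@members]
  m <- mean(v)
  s <- if (length(v) > 1L) stats::sd(v) else 0
  thr <- if (voi@organ == "liver") 1.5 * m + 2 * s else 2.0 * m + 2 * s
  new("BackgroundStats", organ = voi@organ, SULmean = m, SD = s,
      threshold = thr, n = length(v))
}

#' Check longitudinal comparability of background activity
#'
#' Two scans are comparable per PERCIST when the background SULmean changed
#' by less than 0.3 SUL units and by less than 20 percent of the baseline
#' value (strict inequalities at both bounds).
#'
#' @param baseline,followup \linkS4class{BackgroundStats} from the same
#'   organ.
#' @return List with \code{comparable} (logical) and \code{reasons}
#'   (character vector, empty when comparable).
#' @examples
#' a <- new("BackgroundStats", organ = "liver", SULmean = 2, SD = 0.1,
#'          threshold = 3.2, n = 100L)
#' b <- new("BackgroundStats", organ = "liver", SULmean = 2.29, SD = 0.1,
#'          threshold = 3.635, n = 100L)
#' checkComparability(a, b)$comparable   # TRUE
#' @export
checkComparability <- function(baseline, followup) {
  if (!identical(baseline@organ, followup@organ))
    stop("comparability requires background stats from the same organ (got ",
         baseline@organ, " vs ", followup@organ, ")")
  delta <- abs(followup@SULmean - baseline@SULmean)
  rel <- delta / baseline@SULmean
  reasons <- character()
  if (delta >= 0.3 - 1e-12)
    reasons <- c(reasons, sprintf(
      "background SULmean changed by %.3f SUL units (limit 0.3)", delta))
  if (rel >= 0.2 - 1e-12)
    reasons <- c(reasons, sprintf(
      "background SULmean changed by %.1f%% (limit 20%%)", 100 * rel))
  list(comparable = length(reasons) == 0L, reasons = reasons,
       deltaSUL = delta, relative = rel)
}

#' Export a background VOI as a binary mask volume
#' @param voi a \linkS4class{BackgroundVOI}.
#' @return A \linkS4class{LabelVolume} with the VOI voxels labelled 1.
#' @export
voiMask <- function(voi) {
  v <- integer(prod(voi@grid@shape))
  v[voi@members] <- 1L
  LabelVolume(array(v, dim = voi@grid@shape), voi@grid,
              c("1" = paste0(voi@organ, "_voi")))
}
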