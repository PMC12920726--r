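#' SULpeak of a candidate region
#'
#' The PERCIST lesion metric: a sphere of volume 1 cm3 (radius 6.2035 mm) is
#' swept over candidate centre voxels and SULpeak is the largest mean SUL
#' over the voxels whose centres fall inside the sphere. The sphere mean is
#' computed over all voxels regardless of component membership (the fixed
#' PERCIST sphere); at the grid edge the mean runs over the in-grid part.
#' Ties break by lexicographic centre order.
#'
#' @param sul a SUL \linkS4class{ScalarVolume}.
#' @param region candidate centres: logical array, linear indices, or an
#'   Nx3 matrix of 0-based voxel indices.
#' @return List: \code{value}, \code{centre} (world mm), \code{centreIndex}
#'   (1-based linear index).
#' @export
sulPeak <- function(sul, region) {
  grid <- sul@grid
  centers <- regionCentres(grid, region)
  if (nrow(centers) == 0L) stop("empty candidate region for SULpeak")
  ord <- order(centers[, 1L], centers[, 2L], centers[, 3L])
  centers <- centers[ord, , drop = FALSE]
  off <- sphereOffsets(grid@spacing, 6.2035)
  st <- .sphere_scan(as.numeric(sul@values), as.integer(grid@shape),
                     matrix(as.integer(centers), ncol = 3L),
                     matrix(as.integer(off), ncol = 3L), logical(0))
  best <- which.max(st$mean)   # first max = lexicographic tie-break
  list(value = st$mean[best],
       centre = voxelToWorld(grid, centers[best, , drop = FALSE])[1L, ],
       centreIndex = voxelToLinear(grid, centers[best, , drop = FALSE]))
}

regionCentres <- function(grid, region) {
  if (is.logical(region) || (is.array(region) && !is.matrix(region)))
    linearToVoxel(grid, which(region != 0))
  else if (is.matrix(region)) rbindMat(region)
  else linearToVoxel(grid, as.integer(region))
}

#' Detect supra-threshold hotspots
#'
#' Finds connected components (26-connectivity) of voxels with SUL strictly
#' above the background threshold, computes each component's SULpeak (sphere
#' centres restricted to the component's 1-voxel-dilated envelope) and keeps
#' components whose SULpeak is at or above the threshold.
#'
#' @param sul a SUL \linkS4class{ScalarVolume}.
#' @param threshold measurability threshold (> 0), usually
#'   \code{backgroundStats(...)@threshold}.
#' @param bodyMask optional logical array restricting the search.
#' @return A data.frame with one row per hotspot: id, nVoxels, SULpeak,
#'   centre (mm), class (NA until classified), and a \code{voxels}
#'   list-column of member linear indices. An empty frame when nothing
#'   exceeds the threshold.
#' @export
detectHotspots <- function(sul, threshold, bodyMask = NULL) {
  if (threshold <= 0) stop("threshold must be positive")
  grid <- sul@grid
  above <- sul@values > threshold
  if (!is.null(bodyMask)) {
    if (!identical(dim(bodyMask), as.integer(grid@shape)))
      stop("grid mismatch between SUL volume and body mask")
    above <- above & bodyMask
  }
  empty <- data.frame(id = integer(), nVoxels = integer(), SULpeak = numeric(),
                      cx = numeric(), cy = numeric(), cz = numeric(),
                      class = character(), rank = integer())
  empty$voxels <- list()
  if (!any(above)) return(empty)
  cc <- .cc_label26(as.logical(above), as.integer(grid@shape))
  ncomp <- max(cc)
  rows <- vector("list", ncomp)
  vox <- split(which(cc > 0L), cc[cc > 0L])
  for (k in seq_len(ncomp)) {
    mem <- vox[[as.character(k)]]
    env <- dilateIndices(grid, mem)
    pk <- sulPeak(sul, env)
    if (pk$value < threshold) next
    rows[[k]] <- data.frame(id = k, nVoxels = length(mem), SULpeak = pk$value,
                            cx = pk$centre[1L], cy = pk$centre[2L],
                            cz = pk$centre[3L], class = NA_character_,
                            rank = NA_integer_)
    rows[[k]]$voxels <- list(mem)
  }
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out$id <- seq_len(nrow(out))
  out
}

# 26-neighbourhood dilation of a set of linear indices, returned as 0-based
# voxel index matrix
dilateIndices <- function(grid, members) {
  idx <- linearToVoxel(grid, members)
  off <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  all <- do.call(rbind, lapply(seq_len(nrow(off)), function(i)
    sweep(idx, 2L, off[i, ], "+")))
  all <- all[all[, 1L] >= 0 & all[, 1L] < grid@shape[1L] &
             all[, 2L] >= 0 & all[, 2L] < grid@shape[2L] &
             all[, 3L] >= 0 & all[, 3L] < grid@shape[3L], , drop = FALSE]
  unique(all)
}

#' Classify hotspots as lesion or physiological
#'
#' A hotspot is called physiological when more than half of its component
#' voxels lie inside the normal-activity mask, otherwise lesion. The
#' \code{class} column is overwritten unless a \code{userClass} column is
#' present and non-NA (manual override mirroring visual review).
#'
#' @param hotspots data.frame from \code{\link{detectHotspots}}.
#' @param normalMask \linkS4class{LabelVolume} (non-zero = physiological) or
#'   logical array on the same grid.
#' @param grid the \linkS4class{ImageGrid} of the hotspot volume (used for
#'   the mismatch check when \code{normalMask} is a LabelVolume).
#' @return The data.frame with \code{class} filled in, plus an
#'   \code{overlapFraction} column.
#' @export
classifyHotspots <- function(hotspots, normalMask, grid = NULL) {
  if (is(normalMask, "LabelVolume")) {
    if (!is.null(grid)) stopIfGridMismatch(grid, normalMask@grid,
                                           "SUL volume and normal-activity mask")
    normalMask <- normalMask@labels != 0L
  }
  if (nrow(hotspots) == 0L) return(hotspots)
  frac <- vapply(hotspots$voxels, function(v) mean(normalMask[v]), numeric(1L))
  cls <- ifelse(frac > 0.5, "physiological", "lesion")
  if (!is.null(hotspots$userClass)) {
    ov <- !is.na(hotspots$userClass)
    cls[ov] <- hotspots$userClass[ov]
  }
  hotspots$class <- cls
  hotspots$overlapFraction <- frac
  hotspots
}

#' Rank hotspots by SULpeak
#'
#' Orders hotspots by descending SULpeak; ties break by component size
#' (larger first), then by lexicographic peak-centre order.
#'
#' @param hotspots data.frame from \code{\link{detectHotspots}}.
#' @return The data.frame reordered with \code{rank} 1..n filled in.
#' @export
rankHotspots <- function(hotspots) {
  if (nrow(hotspots) == 0L) return(hotspots)
  ord <- order(-hotspots$SULpeak, -hotspots$nVoxels, hotspots$cx,
               hotspots$cy, hotspots$cz)
  out <- hotspots[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Export a hotspot table
#'
#' Writes the hotspot list (id, SULpeak, centre mm, class, rank) as CSV and,
#' optionally, JSON.
#' @param hotspots data.frame from the detect/classify/rank steps.
#' @param csv,json output paths (NULL to skip).
#' @return The exported table (without the voxel list-column), invisibly.
#' @export
exportHotspots <- function(hotspots, csv = NULL, json = NULL) {
  tab <- hotspots[, setdiff(names(hotspots), "voxels"), drop = FALSE]
  if (!is.null(csv)) utils::write.csv(tab, csv, row.names = FALSE)
  if (!is.null(json)) jsonlite::write_json(tab, json, dataframe = "rows",
                                           auto_unbox = TRUE, pretty = TRUE)
  invisible(tab)
}
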