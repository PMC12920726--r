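#' Hausdorff distance between two masks
#'
#' Symmetric Hausdorff distance between the boundary voxel-centre sets of
#' two masks on the same grid: the larger of the two directed maxima of the
#' nearest-boundary distance.
#'
#' @param maskA,maskB logical/integer arrays or \linkS4class{LabelVolume}s
#'   (non-zero = organ), both non-empty.
#' @param grid the \linkS4class{ImageGrid} (taken from a LabelVolume if
#'   given).
#' @return Distance in mm.
#' @examples
#' a <- array(FALSE, c(8, 8, 8)); a[2:4, 2:4, 2:4] <- TRUE
#' hausdorffDistance(a, a, ImageGrid(c(8, 8, 8)))   # 0
#' @export
hausdorffDistance <- function(maskA, maskB, grid = NULL) {
  if (is(maskA, "LabelVolume")) { grid <- maskA@grid; maskA <- maskA@labels != 0L }
  if (is(maskB, "LabelVolume")) {
    if (is.null(grid)) grid <- maskB@grid
    maskB <- maskB@labels != 0L
  }
  if (is.null(grid)) grid <- ImageGrid(dim(maskA))
  if (!any(maskA) || !any(maskB))
    stop("Hausdorff distance requires two non-empty masks")
  pa <- boundaryPoints(grid, maskA)
  pb <- boundaryPoints(grid, maskB)
  max(max(.nn_brute(pa, pb)$dist), max(.nn_brute(pb, pa)$dist))
}

boundaryPoints <- function(grid, mask) {
  b <- .boundary6(as.logical(mask), as.integer(grid@shape))
  voxelToWorld(grid, linearToVoxel(grid, which(b)))
}

#' Build an uncertainty table from distances
#'
#' The within-organ alignment uncertainty is the 75th percentile of the
#' organ's Hausdorff-distance distribution, computed with linear
#' interpolation between order statistics (so distances 1,2,3,4 give 3.25).
#'
#' @param distances named list: organ name -> numeric vector of Hausdorff
#'   distances (mm).
#' @param groups optional named list mapping a group name to the organ names
#'   it pools; grouped organs share the pooled distance list and percentile.
#' @return An \linkS4class{UncertaintyTable}.
#' @examples
#' uncertaintyTable(list(liver = c(1, 2, 3, 4)))@q75   # 3.25
#' @export
uncertaintyTable <- function(distances, groups = NULL) {
  if (!is.null(groups)) {
    for (g in names(groups)) {
      members <- intersect(groups[[g]], names(distances))
      if (!length(members)) next
      pooled <- unlist(distances[members], use.names = FALSE)
      for (m in members) distances[[m]] <- pooled
    }
  }
  q75 <- vapply(distances, function(d)
    stats::quantile(d, 0.75, names = FALSE, type = 7), numeric(1L))
  new("UncertaintyTable", distances = distances, q75 = q75)
}

#' Calibrate alignment uncertainty from mask pairs
#'
#' For every calibration pair and organ present in both the propagated and
#' the actual segmentation, computes the Hausdorff distance, then derives
#' the per-organ 75th percentile. Organs absent from every pair are omitted
#' with a warning.
#'
#' @param pairs list of pairs, each with \code{propagated} and \code{actual}
#'   \linkS4class{LabelVolume}s (e.g. from
#'   \code{\link{makeCalibrationSet}}).
#' @param groups optional organ grouping, see
#'   \code{\link{uncertaintyTable}}.
#' @return An \linkS4class{UncertaintyTable}.
#' @export
calibrateUncertainty <- function(pairs, groups = NULL) {
  if (!length(pairs)) stop("no calibration pairs given")
  distances <- list()
  allOrgans <- character()
  for (p in pairs) {
    prop <- p$propagated; act <- p$actual
    legend <- prop@legend
    pl <- setdiff(unique(as.integer(prop@labels)), 0L)
    al <- setdiff(unique(as.integer(act@labels)), 0L)
    allOrgans <- union(allOrgans, unname(legend[as.character(union(pl, al))]))
    for (lv in intersect(pl, al)) {
      nm <- legend[[as.character(lv)]]
      d <- hausdorffDistance(prop@labels == lv, act@labels == lv, prop@grid)
      distances[[nm]] <- c(distances[[nm]], d)
    }
  }
  dropped <- setdiff(allOrgans, names(distances))
  if (length(dropped))
    warning("organs absent from all calibration pairs omitted: ",
            paste(dropped, collapse = ", "))
  uncertaintyTable(distances, groups = groups)
}

#' Per-voxel alignment uncertainty map
#'
#' Voxels inside an organ get that organ's calibrated uncertainty (its 75th
#' percentile Hausdorff distance); voxels outside all organs get the nearest
#' organ's value plus 0.2 mm per mm of Euclidean distance to the nearest
#' organ boundary. Organs missing from the table conservatively take the
#' table-wide maximum.
#'
#' @param labels organ \linkS4class{LabelVolume} (non-empty).
#' @param table an \linkS4class{UncertaintyTable}.
#' @param rate growth rate outside organs, mm per mm.
#' @return A \linkS4class{ScalarVolume} of kind "uncertainty_mm".
#' @export
uncertaintyMap <- function(labels, table, rate = 0.2) {
  grid <- labels@grid
  lab <- as.integer(labels@labels)
  used <- setdiff(unique(lab), 0L)
  if (!length(used)) stop("label volume contains no organs")
  fallback <- max(table@q75)
  organValue <- vapply(as.character(used), function(lv) {
    nm <- labels@legend[[lv]]
    if (!is.null(nm) && nm %in% names(table@q75)) table@q75[[nm]] else fallback
  }, numeric(1L))
  names(organValue) <- as.character(used)

  v <- numeric(length(lab))
  inOrgan <- lab > 0L
  v[inOrgan] <- organValue[as.character(lab[inOrgan])]
  ft <- .edt_feature(as.logical(inOrgan), as.integer(grid@shape),
                     as.numeric(grid@spacing))
  out <- !inOrgan
  v[out] <- v[ft$feature[out]] + rate * ft$dist[out]
  ScalarVolume(array(v, dim = grid@shape), grid, kind = "uncertainty_mm")
}

#' Read/write an uncertainty table as JSON
#' @param table an \linkS4class{UncertaintyTable}.
#' @param path JSON path.
#' @return \code{path} (write) or an \linkS4class{UncertaintyTable} (read).
#' @export
writeUncertaintyTable <- function(table, path) {
  jsonlite::write_json(list(distances = table@distances,
                            q75 = as.list(table@q75)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeUncertaintyTable
#' @export
readUncertaintyTable <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  uncertaintyTable(as.list(j$distances))
}
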