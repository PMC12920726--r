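#' Assign every voxel to one of six body regions
#'
#' Organ voxels take the region of their organ (head, torso, left/right arm,
#' left/right leg) from the organ-to-region table; all remaining voxels take
#' the region of the nearest organ voxel (exact Euclidean distance). The
#' regional decomposition keeps displacement interpolation from propagating
#' across anatomical boundaries (e.g. arm transforms into the torso).
#'
#' @param labels organ \linkS4class{LabelVolume}.
#' @param regionTable named vector organ name -> region name (default
#'   \code{\link{organRegionTable}}).
#' @return A \linkS4class{LabelVolume} of region ids (legend = region
#'   names).
#' @export
assignRegions <- function(labels, regionTable = organRegionTable()) {
  grid <- labels@grid
  lab <- as.integer(labels@labels)
  used <- setdiff(unique(lab), 0L)
  if (!length(used)) stop("label volume contains no organs")
  organNames <- labels@legend[as.character(used)]
  missing <- organNames[!organNames %in% names(regionTable)]
  if (length(missing))
    stop("organs missing from the region table: ",
         paste(missing, collapse = ", "))
  rid <- bodyRegions()
  labelRegion <- rid[regionTable[organNames]]
  names(labelRegion) <- as.character(used)

  region <- integer(length(lab))
  inOrgan <- lab > 0L
  region[inOrgan] <- labelRegion[as.character(lab[inOrgan])]
  ft <- .edt_feature(as.logical(inOrgan), as.integer(grid@shape),
                     as.numeric(grid@spacing))
  out <- !inOrgan
  region[out] <- region[ft$feature[out]]
  LabelVolume(array(region, dim = grid@shape), grid,
              stats::setNames(names(rid), as.character(rid)))
}

#' Harmonic interpolation of organ transforms
#'
#' Solves the discrete Laplace equation for each displacement component with
#' the organ transformations as Dirichlet boundary conditions: voxels inside
#' segmented organs are fixed to u(x) = T_organ(x) - x, all other voxels are
#' initialised to the mean organ displacement of their own region (keeping
#' each region's solution independent of the other regions' transforms at
#' any iteration count) and relaxed by
#' the Jacobi method on the 6-voxel stencil until the largest update falls
#' below \code{tol} mm (or \code{maxIter} sweeps). Each of the six body
#' regions is solved independently with mirrored (Neumann-like) region
#' borders; a region containing no organ is filled with the global mean
#' displacement and flagged in the diagnostics.
#'
#' With \code{coarsen > 1} the equation is first relaxed on a cascade of
#' subsampled grids (8x, 4x, 2x) whose solutions are trilinearly upsampled,
#' and the full-resolution relaxation is then a bounded smoothing pass
#' (\code{fineIter} sweeps) that removes the upsampling artifacts; the fixed
#' point of the iteration is unchanged, only the route to it.
#'
#' @param grid the source \linkS4class{ImageGrid}.
#' @param organs named list; each element has \code{voxels} (1-based linear
#'   indices of the organ on the grid) and \code{matrix} (3x4 transform) or
#'   an \linkS4class{OrganTransform} in \code{transform}.
#' @param regions region \linkS4class{LabelVolume} from
#'   \code{\link{assignRegions}}.
#' @param tol Jacobi stopping tolerance on the max per-sweep update, mm.
#' @param maxIter Jacobi sweep cap per region and component.
#' @param coarsen 1 for a plain full-resolution solve; > 1 enables the
#'   coarse-to-fine cascade.
#' @param midIter sweep cap at intermediate cascade levels.
#' @param fineIter sweep cap for the final full-resolution pass of the
#'   cascade.
#' @return A \linkS4class{DisplacementField}; diagnostics in
#'   \code{attr(, "diagnostics")}.
#' @export
solveLaplace <- function(grid, organs, regions, tol = 2e-4, maxIter = 5000L,
                         coarsen = 1L, midIter = 300L, fineIter = 500L) {
  n <- prod(grid@shape)
  fixed <- logical(n)
  u <- matrix(0, n, 3L)
  uDirichlet <- NULL
  organMeans <- matrix(0, length(organs), 3L)
  for (i in seq_along(organs)) {
    o <- organs[[i]]
    M <- if (!is.null(o$matrix)) o$matrix else o$transform@matrix
    vox <- o$voxels
    W <- voxelToWorld(grid, linearToVoxel(grid, vox))
    disp <- applyAffine(M, W) - W
    u[vox, ] <- disp
    fixed[vox] <- TRUE
    organMeans[i, ] <- colMeans(disp)
  }
  globalMean <- colMeans(organMeans)
  reg <- as.integer(regions@labels)
  # free voxels start from the mean organ displacement of their own region
  # (global mean where the region has no organ), so each region's solution
  # is fully independent of the other regions' transforms
  organRegion <- vapply(organs, function(o) reg[o$voxels[1L]], integer(1L))
  free <- !fixed
  u[free, ] <- matrix(globalMean, sum(free), 3L, byrow = TRUE)
  for (r in unique(organRegion)) {
    sel <- free & reg == r
    u[sel, ] <- matrix(colMeans(organMeans[organRegion == r, , drop = FALSE]),
                       sum(sel), 3L, byrow = TRUE)
  }
  uFixedVals <- u[fixed, , drop = FALSE]
  diagnostics <- list()
  organless <- integer()
  for (r in sort(unique(reg[reg > 0L]))) {
    if (!any(fixed & reg == r)) {
      organless <- c(organless, r)
      diagnostics[[as.character(r)]] <- list(region = r, organless = TRUE)
    }
  }

  relaxLevel <- function(u, s, iters, record = FALSE) {
    sh <- grid@shape
    if (s > 1L) {
      xi <- seq(1L, sh[1L], by = s); yi <- seq(1L, sh[2L], by = s)
      zi <- seq(1L, sh[3L], by = s)
      csh <- c(length(xi), length(yi), length(zi))
      pick <- as.vector(outer(outer(xi, (yi - 1L) * sh[1L], "+"),
                              (zi - 1L) * sh[1L] * sh[2L], "+"))
    } else {
      csh <- sh
      pick <- seq_len(n)
    }
    cfix <- fixed[pick]; creg <- reg[pick]
    cu <- u[pick, , drop = FALSE]
    for (r in sort(unique(creg[creg > 0L]))) {
      if (r %in% organless) next
      inreg <- creg == r
      if (!any(cfix & inreg)) next   # organs thinned away at this level
      its <- integer(3L); conv <- logical(3L)
      for (k in 1:3) {
        sol <- .jacobi_relax(cu[, k], cfix, inreg, as.integer(csh), tol,
                             as.integer(iters))
        cu[, k] <- sol$u
        its[k] <- sol$iterations; conv[k] <- sol$converged
      }
      if (record)
        diagnostics[[as.character(r)]] <<- list(region = r, organless = FALSE,
                                                iterations = its,
                                                converged = conv)
    }
    if (s > 1L) {
      for (k in 1:3)
        u[, k] <- .upsample3(cu[, k], as.integer(csh), as.integer(sh),
                             as.numeric(s))
      u[fixed, ] <- uFixedVals   # restore exact Dirichlet values
    } else {
      u <- cu
    }
    u
  }

  if (coarsen > 1L) {
    # coarse-to-fine cascade: full relaxation on heavily subsampled grids,
    # then bounded smoothing sweeps at full resolution to clean up the
    # upsampling; the fixed point is unchanged
    for (s in c(8L, 4L, 2L)) {
      iters <- if (s == 8L) maxIter else midIter
      u <- relaxLevel(u, s, iters)
    }
    u <- relaxLevel(u, 1L, fineIter, record = TRUE)
  } else {
    u <- relaxLevel(u, 1L, maxIter, record = TRUE)
  }
  for (r in organless)
    u[reg == r, ] <- matrix(globalMean, sum(reg == r), 3L, byrow = TRUE)

  field <- new("DisplacementField", grid = grid,
               u = array(u, dim = c(grid@shape, 3L)),
               region = array(reg, dim = grid@shape))
  attr(field, "diagnostics") <- diagnostics
  field
}

# vectorised trilinear interpolation of a 3-D array at continuous 0-based
# coordinates (clamped to the grid)
trilinearInterp <- function(arr, pts) {
  d <- dim(arr)
  x <- pmin(pmax(pts[, 1L], 0), d[1L] - 1L)
  y <- pmin(pmax(pts[, 2L], 0), d[2L] - 1L)
  z <- pmin(pmax(pts[, 3L], 0), d[3L] - 1L)
  x0 <- pmin(floor(x), d[1L] - 2L); x0 <- pmax(x0, 0)
  y0 <- pmin(floor(y), d[2L] - 2L); y0 <- pmax(y0, 0)
  z0 <- pmin(floor(z), d[3L] - 2L); z0 <- pmax(z0, 0)
  if (d[1L] == 1L) x0 <- rep(0, length(x))
  if (d[2L] == 1L) y0 <- rep(0, length(y))
  if (d[3L] == 1L) z0 <- rep(0, length(z))
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  g <- function(ix, iy, iz)
    arr[cbind(pmin(ix, d[1L] - 1L) + 1L, pmin(iy, d[2L] - 1L) + 1L,
              pmin(iz, d[3L] - 1L) + 1L)]
  c000 <- g(x0, y0, z0);     c100 <- g(x0 + 1, y0, z0)
  c010 <- g(x0, y0 + 1, z0); c110 <- g(x0 + 1, y0 + 1, z0)
  c001 <- g(x0, y0, z0 + 1); c101 <- g(x0 + 1, y0, z0 + 1)
  c011 <- g(x0, y0 + 1, z0 + 1); c111 <- g(x0 + 1, y0 + 1, z0 + 1)
  c00 <- c000 * (1 - fx) + c100 * fx
  c10 <- c010 * (1 - fx) + c110 * fx
  c01 <- c001 * (1 - fx) + c101 * fx
  c11 <- c011 * (1 - fx) + c111 * fx
  (c00 * (1 - fy) + c10 * fy) * (1 - fz) + (c01 * (1 - fy) + c11 * fy) * fz
}

#' Segmentation-guided image alignment
#'
#' The full alignment method: for every organ present in both label volumes,
#' extract the two surfaces, estimate the organ transform by ICP (rigid for
#' bones, affine for soft tissue, per the model table), then interpolate the
#' organ transforms into a dense displacement field by regional harmonic
#' interpolation. The field maps source (follow-up) coordinates to target
#' (baseline) coordinates. Organs present in only one scan are skipped and
#' logged.
#'
#' @param sourceLabels,targetLabels organ \linkS4class{LabelVolume}s of the
#'   follow-up (source) and baseline (target) scans, sharing a legend.
#' @param modelTable organ name -> "rigid"/"affine" (unlisted organs:
#'   affine).
#' @param regionTable organ name -> region name.
#' @param tol,maxIter,coarsen,midIter,fineIter passed to
#'   \code{\link{solveLaplace}}. The pipeline default uses a lighter
#'   full-resolution smoothing pass than standalone \code{solveLaplace}:
#'   organ voxels are Dirichlet-fixed either way, and the residual
#'   between-organ interpolation error is absorbed by the uncertainty-driven
#'   search radius of the lesion pairing.
#' @param icpMaxPoints vertex subsampling cap for ICP.
#' @return List: \code{field} (\linkS4class{DisplacementField}),
#'   \code{transforms} (named list of \linkS4class{OrganTransform}s),
#'   \code{diagnostics}.
#' @export
alignImages <- function(sourceLabels, targetLabels,
                        modelTable = organModelTable(),
                        regionTable = organRegionTable(), tol = 2e-4,
                        maxIter = 5000L, coarsen = 2L, midIter = 200L,
                        fineIter = 60L, icpMaxPoints = 1500L) {
  srcLab <- as.integer(sourceLabels@labels)
  tgtLab <- as.integer(targetLabels@labels)
  legend <- sourceLabels@legend
  srcGrid <- sourceLabels@grid
  tgtGrid <- targetLabels@grid

  srcOrgans <- setdiff(unique(srcLab), 0L)
  tgtOrgans <- setdiff(unique(tgtLab), 0L)
  shared <- intersect(srcOrgans, tgtOrgans)
  skipped <- legend[as.character(c(setdiff(srcOrgans, tgtOrgans),
                                   setdiff(tgtOrgans, srcOrgans)))]
  if (!length(shared))
    stop("no organ is present in both label volumes")

  srcCentre <- voxelToWorld(srcGrid, (srcGrid@shape - 1) / 2)[1L, ]
  tgtCentre <- voxelToWorld(tgtGrid, (tgtGrid@shape - 1) / 2)[1L, ]

  transforms <- list()
  organs <- list()
  for (lv in sort(shared)) {
    nm <- legend[[as.character(lv)]]
    model <- if (nm %in% names(modelTable)) modelTable[[nm]] else "affine"
    sm <- array(srcLab == lv, dim = srcGrid@shape)
    tm <- array(tgtLab == lv, dim = tgtGrid@shape)
    ss <- extractSurface(sm, srcGrid)
    ts <- extractSurface(tm, tgtGrid)
    tr <- icpAlign(ss, ts, model = model, sourceCentre = srcCentre,
                   targetCentre = tgtCentre, maxPoints = icpMaxPoints,
                   organ = nm)
    transforms[[nm]] <- tr
    organs[[nm]] <- list(voxels = which(srcLab == lv), transform = tr)
  }

  regions <- assignRegions(sourceLabels, regionTable)
  field <- solveLaplace(srcGrid, organs, regions, tol = tol,
                        maxIter = maxIter, coarsen = coarsen,
                        midIter = midIter, fineIter = fineIter)
  list(field = field, transforms = transforms,
       diagnostics = list(skippedOrgans = unname(skipped),
                          laplace = attr(field, "diagnostics")))
}

#' Write a displacement field as 4-D NIfTI
#' @param field a \linkS4class{DisplacementField}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeDisplacementField <- function(field, path) {
  img <- RNifti::asNifti(field@u)
  RNifti::pixdim(img) <- c(field@grid@spacing, 1)
  A <- rbind(cbind(field@grid@direction %*% diag(field@grid@spacing),
                   field@grid@origin), c(0, 0, 0, 1))
  img <- RNifti::`sform<-`(img, structure(A, code = 2L))
  img <- RNifti::`qform<-`(img, structure(A, code = 2L))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}
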