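#' Extract an organ surface
#'
#' Triangulated iso-surface of a binary organ mask at level 0.5, with
#' vertices in world mm. Extraction uses a table-free marching-tetrahedra
#' scheme (Kuhn 6-tetrahedra decomposition of each grid cube), applied to a
#' mildly Gaussian-smoothed copy of the indicator field; smoothing is clamped
#' so that every voxel keeps its in/out classification, which preserves thin
#' structures (down to a single voxel) while removing the staircase bias of a
#' raw binary surface.
#'
#' @param mask logical/integer array or \linkS4class{LabelVolume} (non-zero
#'   = organ).
#' @param grid the \linkS4class{ImageGrid} (taken from the LabelVolume if
#'   given).
#' @param sigma smoothing SD in voxels.
#' @return A \linkS4class{Surface}.
#' @export
extractSurface <- function(mask, grid = NULL, sigma = 0.8) {
  if (is(mask, "LabelVolume")) {
    grid <- mask@grid
    mask <- mask@labels != 0L
  }
  if (is.null(grid)) grid <- ImageGrid(dim(mask))
  if (!any(mask)) stop("cannot extract a surface from an empty mask")
  m <- array(as.numeric(mask != 0), dim = dim(mask))

  # crop to the mask bounding box (plus margin) for speed
  w <- which(m > 0)
  iv <- linearToVoxel(grid, w)
  pad <- 4L
  lo <- pmax(apply(iv, 2L, min) - pad, 0L)
  hi <- pmin(apply(iv, 2L, max) + pad, grid@shape - 1L)
  sub <- m[(lo[1L] + 1L):(hi[1L] + 1L), (lo[2L] + 1L):(hi[2L] + 1L),
           (lo[3L] + 1L):(hi[3L] + 1L), drop = FALSE]
  dims <- dim(sub)

  f <- .gauss3(as.numeric(sub), as.integer(dims), sigma)
  # clamp: inside voxels stay > 0.5, outside stay < 0.5
  inside <- as.numeric(sub) > 0.5
  f[inside] <- pmax(f[inside], 0.501)
  f[!inside] <- pmin(f[!inside], 0.499)

  mc <- .march_tets(f, as.integer(dims), 0.5)
  if (nrow(mc$vertices) < 4L)
    stop("degenerate mask: surface extraction produced < 4 vertices")
  vox <- sweep(mc$vertices, 2L, as.numeric(lo), "+")
  new("Surface", vertices = voxelToWorld(grid, vox),
      faces = matrix(as.integer(mc$faces), ncol = 3L))
}

#' Total mesh area of a surface
#' @param surface a \linkS4class{Surface}.
#' @return Area in mm2.
#' @export
surfaceArea <- function(surface) {
  v <- surface@vertices
  f <- surface@faces
  e1 <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  e2 <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  cr <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
              e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
              e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  sum(sqrt(rowSums(cr^2))) / 2
}

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares optimal rotation and translation mapping paired source
#' points onto target points, with the reflection excluded by sign
#' correction of the smallest singular vector, so det(R) = +1 always.
#'
#' @param source,target Nx3 matrices of paired points (N >= 3,
#'   non-collinear).
#' @return 3x4 matrix [R | t] with y = R x + t.
#' @examples
#' p <- matrix(rnorm(15), ncol = 3)
#' M <- kabsch(p, p)   # identity
#' @export
kabsch <- function(source, target) {
  source <- rbindMat(source); target <- rbindMat(target)
  if (nrow(source) != nrow(target)) stop("point sets must be paired")
  if (nrow(source) < 3L) stop("kabsch needs at least 3 point pairs")
  cs <- colMeans(source); ct <- colMeans(target)
  P <- sweep(source, 2L, cs, "-"); Q <- sweep(target, 2L, ct, "-")
  sv <- svd(crossprod(P, Q))    # H = P^T Q
  if (sv$d[2L] < 1e-9 * max(sv$d[1L], 1))
    stop("kabsch: point pairs are collinear (rotation is not determined)")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- ct - R %*% cs
  cbind(R, as.numeric(t))
}

#' Filter correspondence outliers
#'
#' Retains pairs whose correspondence distance does not exceed four times
#' the median distance ("exceeded" read strictly, so a distance of exactly
#' 4x the median is retained).
#'
#' @param distances numeric vector of correspondence distances.
#' @return Logical vector: TRUE = retained.
#' @examples
#' filterOutliers(c(1, 1, 1, 1, 10))   # last pair discarded
#' @export
filterOutliers <- function(distances) {
  if (!length(distances)) stop("no correspondence pairs to filter")
  distances <= 4 * stats::median(distances)
}

#' Least-squares affine fit
#'
#' 3x4 affine transform (rotation, translation, scaling and shearing)
#' minimising squared residuals over paired points, solved in homogeneous
#' coordinates. Exact on noiseless affine data.
#'
#' @param source,target Nx3 matrices of paired points (N >= 4,
#'   non-coplanar).
#' @return 3x4 matrix [A | b] with y = A x + b.
#' @export
fitAffine <- function(source, target) {
  source <- rbindMat(source); target <- rbindMat(target)
  if (nrow(source) != nrow(target)) stop("point sets must be paired")
  if (nrow(source) < 4L) stop("affine fit needs at least 4 point pairs")
  X <- cbind(source, 1)
  q <- qr(X)
  if (q$rank < 4L)
    stop("affine fit is rank-deficient: source points are coplanar ",
         "(or otherwise degenerate)")
  B <- qr.coef(q, target)         # 4 x 3: y = t(B[1:3, ]) x + B[4, ]
  cbind(t(B[1:3, , drop = FALSE]), as.numeric(B[4L, ]))
}

#' Iterative closest point surface alignment
#'
#' Aligns a source surface onto a target surface: the transform is
#' initialised by superposing the surface point closest to each image centre
#' (robust to differing fields of view), then alternates nearest-neighbour
#' correspondence with transform refitting until the mean correspondence
#' distance changes by less than \code{tol} mm or \code{maxIter} iterations.
#' Rigid refits filter outliers (pairs beyond 4x the median distance) and
#' use the Kabsch algorithm; affine refits solve the homogeneous
#' least-squares problem on all pairs.
#'
#' @param source,target \linkS4class{Surface}s (follow-up and baseline).
#' @param model "rigid" or "affine".
#' @param sourceCentre,targetCentre image centres (world mm) used for
#'   initialisation; default: the surface bounding-box centre.
#' @param tol convergence tolerance on the mean distance change, mm.
#' @param maxIter iteration cap (non-convergence is flagged, not an error).
#' @param maxPoints deterministic vertex subsampling cap per surface.
#' @param organ organ name recorded in the result.
#' @return An \linkS4class{OrganTransform}.
#' @export
icpAlign <- function(source, target, model = c("rigid", "affine"),
                     sourceCentre = NULL, targetCentre = NULL, tol = 1e-6,
                     maxIter = 200L, maxPoints = 1500L, organ = "organ") {
  model <- match.arg(model)
  src <- subsampleRows(source@vertices, maxPoints)
  tgt <- subsampleRows(target@vertices, maxPoints)
  if (is.null(sourceCentre) || is.null(targetCentre)) {
    # without image geometry, anchor both surfaces to one common reference
    # point so the two closest-point picks are consistent
    common <- (bboxCentre(source@vertices) + bboxCentre(target@vertices)) / 2
    if (is.null(sourceCentre)) sourceCentre <- common
    if (is.null(targetCentre)) targetCentre <- common
  }

  # init: superpose the points closest to the respective image centres
  ps <- src[.nn_brute(matrix(sourceCentre, ncol = 3L), src)$idx, ]
  pt <- tgt[.nn_brute(matrix(targetCentre, ncol = 3L), tgt)$idx, ]
  M <- cbind(diag(3), as.numeric(pt - ps))

  prev <- Inf
  iters <- 0L
  converged <- FALSE
  meanDist <- NA_real_
  for (it in seq_len(maxIter)) {
    iters <- it
    moved <- applyAffine(M, src)
    nn <- .nn_brute(moved, tgt)
    meanDist <- mean(nn$dist)
    if (is.finite(prev) && abs(prev - meanDist) < tol) { converged <- TRUE; break }
    prev <- meanDist
    pairsTgt <- tgt[nn$idx, , drop = FALSE]
    if (model == "rigid") {
      keep <- filterOutliers(nn$dist)
      M <- kabsch(src[keep, , drop = FALSE], pairsTgt[keep, , drop = FALSE])
    } else {
      M <- fitAffine(src, pairsTgt)
    }
  }
  OrganTransform(organ = organ, model = model, matrix = M,
                 iterations = iters, meanDist = meanDist,
                 converged = converged)
}

subsampleRows <- function(x, maxRows) {
  n <- nrow(x)
  if (n <= maxRows) return(x)
  x[seq(1L, n, length.out = maxRows), , drop = FALSE]
}

bboxCentre <- function(v) {
  (apply(v, 2L, min) + apply(v, 2L, max)) / 2
}
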