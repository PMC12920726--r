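#' Voxel/world coordinate transforms
#'
#' World coordinates (mm) are related to 0-based voxel indices by
#' \code{world = origin + direction \%*\% (spacing * index)}; voxel values sit
#' at voxel centres. The two functions are mutual inverses.
#'
#' @param grid an \linkS4class{ImageGrid}.
#' @param idx Nx3 matrix (or length-3 vector) of 0-based voxel indices;
#'   fractional indices are allowed.
#' @return Nx3 matrix of coordinates.
#' @export
voxelToWorld <- function(grid, idx) {
  idx <- rbindMat(idx)
  D <- grid@direction %*% diag(grid@spacing)
  sweep(idx %*% t(D), 2L, grid@origin, "+")
}

#' @rdname voxelToWorld
#' @param world Nx3 matrix (or length-3 vector) of world mm coordinates.
#' @export
worldToVoxel <- function(grid, world) {
  world <- rbindMat(world)
  D <- grid@direction %*% diag(grid@spacing)
  sweep(world, 2L, grid@origin, "-") %*% t(solve(D))
}

rbindMat <- function(x) {
  if (is.null(dim(x))) matrix(as.numeric(x), ncol = 3L) else {
    storage.mode(x) <- "double"
    x
  }
}

# 1-based linear index <-> 0-based voxel index triples
linearToVoxel <- function(grid, i) {
  nx <- grid@shape[1L]; ny <- grid@shape[2L]
  i0 <- as.integer(i) - 1L
  cbind(i0 %% nx, (i0 %/% nx) %% ny, i0 %/% (nx * ny))
}

voxelToLinear <- function(grid, idx) {
  idx <- rbindMat(idx)
  nx <- grid@shape[1L]; ny <- grid@shape[2L]
  as.integer(round(idx[, 1L])) + nx * (as.integer(round(idx[, 2L])) +
    ny * as.integer(round(idx[, 3L]))) + 1L
}

# world mm coordinates of all voxel centres (n x 3); heavy but vectorised
allVoxelCentres <- function(grid) {
  sh <- grid@shape
  idx <- cbind(
    rep.int(seq_len(sh[1L]) - 1L, sh[2L] * sh[3L]),
    rep.int(rep(seq_len(sh[2L]) - 1L, each = sh[1L]), sh[3L]),
    rep(seq_len(sh[3L]) - 1L, each = sh[1L] * sh[2L]))
  voxelToWorld(grid, idx)
}

#' Test whether two grids belong to the same family
#'
#' Grids are a family when shape matches and spacing/origin/direction agree
#' within tolerance, so their voxels are in one-to-one correspondence.
#'
#' @param a,b \linkS4class{ImageGrid}s.
#' @param tol mm tolerance.
#' @return logical.
#' @export
sameGrid <- function(a, b, tol = 1e-6) {
  identical(a@shape, b@shape) &&
    max(abs(a@spacing - b@spacing)) <= tol &&
    max(abs(a@origin - b@origin)) <= tol &&
    max(abs(a@direction - b@direction)) <= tol
}

stopIfGridMismatch <- function(a, b, what = "volumes") {
  if (!sameGrid(a, b))
    stop("grid mismatch between paired ", what,
         " (shape/spacing/origin/direction must agree)")
  invisible(TRUE)
}

# voxel-step offsets whose centre distance is <= radius mm (0-based steps)
sphereOffsets <- function(spacing, radius) {
  r <- ceiling(radius / spacing)
  g <- expand.grid(x = -r[1L]:r[1L], y = -r[2L]:r[2L], z = -r[3L]:r[3L])
  d2 <- (g$x * spacing[1L])^2 + (g$y * spacing[2L])^2 + (g$z * spacing[3L])^2
  as.matrix(g[d2 <= radius^2 + 1e-9, , drop = FALSE])
}
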