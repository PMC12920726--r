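# memoised phantom pairs shared across test files (generation ~3 s each)
phantomFixture <- local({
  cache <- new.env(parent = emptyenv())
  function(design = "PMR", seed = 3L, noiseSD = 0.05, transforms = NULL) {
    id <- paste(design, seed, noiseSD, is.null(transforms), sep = "_")
    if (is.null(cache[[id]]))
      cache[[id]] <- makePhantomPair(phantomSpec(seed = seed, design = design,
                                                 noiseSD = noiseSD,
                                                 transforms = transforms))
    cache[[id]]
  }
})

# ellipsoid mask on a grid, for surface/ICP tests
ellipsoidMask <- function(grid, centre, semi) {
  W <- petrack:::allVoxelCentres(grid)
  array(((W[, 1] - centre[1]) / semi[1])^2 + ((W[, 2] - centre[2]) / semi[2])^2 +
          ((W[, 3] - centre[3]) / semi[3])^2 <= 1, dim = gridShape(grid))
}

# world-mm coordinates of mask voxel centres
maskCentres <- function(grid, mask) {
  voxelToWorld(grid, petrack:::linearToVoxel(grid, which(mask)))
}

rotationAngleDeg <- function(R) {
  acos(pmin(pmax((sum(diag(R)) - 1) / 2, -1), 1)) * 180 / pi
}
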