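test_that("SULpeak equals the value on a uniform volume and the brute-force mean on a point source", {
  g <- ImageGrid(c(21, 21, 21), 1)
  uni <- ScalarVolume(array(3.7, c(21, 21, 21)), g, "SUL")
  expect_equal(sulPeak(uni, array(TRUE, c(21, 21, 21)))$value, 3.7)

  # single voxel of value V in zero background: peak mean = V / N where N is
  # the brute-force count of voxel centres within the 1 cm3 sphere radius
  v <- array(0, c(21, 21, 21)); v[11, 11, 11] <- 120
  ps <- ScalarVolume(v, g, "SUL")
  pk <- sulPeak(ps, which(v > 0))
  W <- petrack:::allVoxelCentres(g)
  N <- sum(rowSums(sweep(W, 2, voxelToWorld(g, c(10, 10, 10))[1, ], "-")^2) <=
             6.2035^2 + 1e-9)
  expect_equal(pk$value, 120 / N, tolerance = 1e-12)
  expect_error(sulPeak(uni, integer(0)), "empty")
})

test_that("the 1 cm3 peak sphere has the right discretised volume at 0.5 mm", {
  off <- petrack:::sphereOffsets(c(0.5, 0.5, 0.5), 6.2035)
  vol <- nrow(off) * 0.5^3 / 1000
  expect_lt(abs(vol - 1.0), 0.02)
})

test_that("hotspot detection finds designed components and respects the threshold", {
  g <- ImageGrid(c(40, 40, 40), 2)
  W <- petrack:::allVoxelCentres(g)
  v <- array(1, c(40, 40, 40))
  centres <- rbind(c(20, 20, 20), c(58, 20, 20), c(20, 58, 20), c(58, 58, 58))
  levels <- c(5, 5, 5, 2.5)
  for (i in 1:4)
    v[rowSums(sweep(W, 2, centres[i, ], "-")^2) <= 8^2] <- levels[i]
  sul <- ScalarVolume(v, g, "SUL")
  hs <- detectHotspots(sul, 3.0)
  expect_equal(nrow(hs), 3)
  # supra-threshold voxel count is conserved across components
  expect_equal(sum(hs$nVoxels), sum(v > 3.0))
  # empty result below any blob
  expect_equal(nrow(detectHotspots(sul, 10)), 0)
  expect_error(detectHotspots(sul, -1), "positive")
})

test_that("two blobs touching at a voxel corner form one 26-connected hotspot", {
  g <- ImageGrid(c(12, 12, 12), 1)
  v <- array(0, c(12, 12, 12))
  v[3:5, 3:5, 3:5] <- 9
  v[6:8, 6:8, 6:8] <- 9
  hs <- detectHotspots(ScalarVolume(v, g, "SUL"), 0.3)
  expect_equal(nrow(hs), 1)
  expect_equal(hs$nVoxels, 54)
})

test_that("raising the threshold never increases the hotspot count", {
  # isolated unimodal blobs of varying intensity: raising the threshold can
  # only drop whole blobs, never create new components
  g <- ImageGrid(c(36, 36, 36), 2)
  W <- petrack:::allVoxelCentres(g)
  v <- array(1, c(36, 36, 36))
  centres <- rbind(c(16, 16, 16), c(52, 16, 16), c(16, 52, 16),
                   c(52, 52, 16), c(16, 16, 52), c(52, 52, 52))
  amps <- seq(2.5, 7.5, length.out = 6)
  for (i in 1:6) {
    d2 <- rowSums(sweep(W, 2, centres[i, ], "-")^2)
    v <- pmax(v, array(amps[i] * exp(-d2 / (2 * 4^2)), c(36, 36, 36)))
  }
  sul <- ScalarVolume(v, g, "SUL")
  counts <- vapply(seq(1.5, 8, by = 0.5), function(th)
    nrow(detectHotspots(sul, th)), numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_gt(max(counts), 0)
})

test_that("hotspot SULpeak lies between component mean and neighbourhood max", {
  pair <- phantomFixture("PMR", 3L)
  sul <- pair$baseline$sul
  hs <- detectHotspots(sul, 3.1)
  expect_gt(nrow(hs), 0)
  for (i in seq_len(nrow(hs))) {
    mem <- hs$voxels[[i]]
    expect_gte(hs$SULpeak[i], mean(voxelValues(sul)[mem]) - 1e-9)
    env <- petrack:::dilateIndices(imageGrid(sul), mem)
    expect_lte(hs$SULpeak[i],
               max(voxelValues(sul)[petrack:::voxelToLinear(imageGrid(sul), env)]) + 1e-9)
  }
})

test_that("classification follows the majority-overlap vote", {
  g <- ImageGrid(c(10, 10, 10), 1)
  mask <- array(FALSE, c(10, 10, 10)); mask[1:5, , ] <- TRUE
  mkhs <- function(voxels) {
    h <- data.frame(id = 1L, nVoxels = length(voxels), SULpeak = 5,
                    cx = 0, cy = 0, cz = 0, class = NA_character_,
                    rank = NA_integer_)
    h$voxels <- list(voxels)
    h
  }
  idx <- function(x, y, z) petrack:::voxelToLinear(g, cbind(x, y, z))
  inside <- idx(1:3, 1, 1)               # fully inside
  expect_equal(classifyHotspots(mkhs(inside), mask)$class, "physiological")
  outside <- idx(6:8, 1, 1)              # zero overlap
  expect_equal(classifyHotspots(mkhs(outside), mask)$class, "lesion")
  sixty <- idx(c(1, 2, 3, 6, 7), 1, 1)   # 60 % overlap
  expect_equal(classifyHotspots(mkhs(sixty), mask)$class, "physiological")
  forty <- idx(c(1, 2, 6, 7, 8), 1, 1)   # 40 % overlap
  expect_equal(classifyHotspots(mkhs(forty), mask)$class, "lesion")
  # manual override wins
  h <- mkhs(inside); h$userClass <- "lesion"
  expect_equal(classifyHotspots(h, mask)$class, "lesion")
})

test_that("ranking is by SULpeak with size and centre tie-breaks", {
  mk <- function(peaks, sizes, cx = seq_along(peaks)) {
    h <- data.frame(id = seq_along(peaks), nVoxels = sizes, SULpeak = peaks,
                    cx = cx, cy = 0, cz = 0, class = "lesion",
                    rank = NA_integer_)
    h$voxels <- lapply(sizes, function(s) seq_len(s))
    h
  }
  r <- rankHotspots(mk(c(3, 5, 4), c(10, 10, 10)))
  expect_equal(r$SULpeak, c(5, 4, 3))
  expect_equal(r$rank, 1:3)
  r2 <- rankHotspots(mk(c(4, 4), c(10, 20)))
  expect_equal(r2$nVoxels, c(20, 10))
  r3 <- rankHotspots(mk(c(4, 4), c(10, 10), cx = c(7, 2)))
  expect_equal(r3$cx, c(2, 7))
  emptyHs <- detectHotspots(ScalarVolume(array(1, c(6, 6, 6)),
                                         ImageGrid(c(6, 6, 6), 2), "SUL"), 5)
  expect_equal(nrow(rankHotspots(emptyHs)), 0)
})
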