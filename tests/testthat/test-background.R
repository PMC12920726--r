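liverPhantom <- function(sul = 2.0, spacing = 3, lesion = NULL, noise = 0) {
  n <- as.integer(round(120 / spacing))
  g <- ImageGrid(c(n, n, n), spacing)
  W <- petrack:::allVoxelCentres(g)
  ctr <- (n - 1) * spacing / 2
  mask <- array(((W[, 1] - ctr) / 55)^2 + ((W[, 2] - ctr) / 45)^2 +
                  ((W[, 3] - ctr) / 40)^2 <= 1, dim = c(n, n, n))
  v <- array(0.5, c(n, n, n))
  v[mask] <- sul
  if (!is.null(lesion)) {
    d2 <- (W[, 1] - lesion[1])^2 + (W[, 2] - lesion[2])^2 + (W[, 3] - lesion[3])^2
    v[d2 <= lesion[4]^2] <- lesion[5]
  }
  if (noise > 0) {
    set.seed(1)
    v <- v + array(rnorm(n^3, sd = noise), c(n, n, n))
    v[v < 0] <- 0
  }
  list(sul = ScalarVolume(v, g, "SUL"), mask = mask, grid = g)
}

test_that("liver VOI on a uniform liver recovers the background level", {
  ph <- liverPhantom()
  voi <- placeLiverVOI(ph$sul, ph$mask)
  st <- backgroundStats(ph$sul, voi)
  expect_equal(st@SULmean, 2.0, tolerance = 1e-9)
  expect_equal(st@SD, 0)
  expect_equal(st@threshold, 3.0)
  # all member voxels inside the liver
  expect_true(all(ph$mask[voiMembers(voi)]))
  # voxel count close to the analytic sphere volume
  expected <- 4 / 3 * pi * 15^3 / prod(spacing(ph$sul))
  expect_lt(abs(length(voiMembers(voi)) / expected - 1), 0.1)
  # placement is deterministic
  voi2 <- placeLiverVOI(ph$sul, ph$mask)
  expect_identical(voi@centre, voi2@centre)
})

test_that("liver VOI avoids a focal hot lesion", {
  ph <- liverPhantom(lesion = c(25, 40, 40, 12, 8.0), noise = 0.05)
  voi <- placeLiverVOI(ph$sul, ph$mask)
  st <- backgroundStats(ph$sul, voi)
  expect_lt(abs(st@SULmean - 2.0), 0.1)
})

test_that("a liver too small for the 30 mm sphere triggers the aorta fallback error", {
  g <- ImageGrid(c(16, 16, 16), 2)
  W <- petrack:::allVoxelCentres(g)
  small <- array(rowSums(sweep(W, 2, rep(15, 3), "-")^2) <= 10^2, c(16, 16, 16))
  sul <- ScalarVolume(array(2, c(16, 16, 16)), g, "SUL")
  expect_error(placeLiverVOI(sul, small), "aorta")
})

aortaPhantom <- function(spacing = 3, radius = 6, length = 60, sul = 1.5) {
  nxy <- as.integer(round(48 / spacing))
  nz <- as.integer(round((length + 24) / spacing))
  g <- ImageGrid(c(nxy, nxy, nz), spacing)
  W <- petrack:::allVoxelCentres(g)
  # tube axis on a voxel centre, as a real aorta segmentation would dictate
  # the nearest lattice alignment anyway
  cx <- floor((nxy - 1) / 2) * spacing
  cz <- (nz - 1) * spacing / 2
  mask <- array((W[, 1] - cx)^2 + (W[, 2] - cx)^2 <= radius^2 &
                  abs(W[, 3] - cz) <= length / 2, dim = gridShape(g))
  v <- array(0.2, gridShape(g)); v[mask] <- sul
  list(sul = ScalarVolume(v, g, "SUL"), mask = mask, grid = g)
}

test_that("aorta VOI aligns with the vessel axis and recovers the blood level", {
  ph <- aortaPhantom()
  voi <- placeAortaVOI(ph$sul, ph$mask)
  st <- backgroundStats(ph$sul, voi)
  expect_equal(st@SULmean, 1.5, tolerance = 1e-9)
  expect_equal(st@threshold, 2 * 1.5, tolerance = 1e-9)
  angle <- acos(abs(voi@axis[3])) * 180 / pi
  expect_lt(angle, 5)
  # axial extent of member centres ~ 20 mm (one voxel tolerance)
  Wm <- maskCentres(ph$grid, seq_along(voxelValues(ph$sul)) %in% voiMembers(voi))
  ext <- diff(range(Wm %*% voi@axis))
  expect_lt(abs(ext + spacing(ph$sul)[1] - 20), spacing(ph$sul)[1] + 1e-9)
  expect_true(all(ph$mask[voiMembers(voi)]))
})

test_that("an aorta segment shorter than the cylinder is rejected", {
  ph <- aortaPhantom(length = 15)
  expect_error(placeAortaVOI(ph$sul, ph$mask), "20 mm")
})

test_that("background statistics follow the organ-specific threshold formulas", {
  g <- ImageGrid(c(8, 8, 8), 2)
  mkvoi <- function(organ, members) new("BackgroundVOI",
    shape = if (organ == "liver") "sphere" else "cylinder",
    centre = c(0, 0, 0), organ = organ, axis = c(0, 0, 1),
    members = as.integer(members), grid = g)
  sul <- ScalarVolume(array(2.0, c(8, 8, 8)), g, "SUL")
  expect_equal(backgroundStats(sul, mkvoi("liver", 1:50))@threshold, 3.0)
  sul15 <- ScalarVolume(array(1.5, c(8, 8, 8)), g, "SUL")
  expect_equal(backgroundStats(sul15, mkvoi("aorta", 1:50))@threshold, 3.0)
  # single-voxel VOI: SD defined as 0
  st1 <- backgroundStats(sul, mkvoi("liver", 5L))
  expect_equal(st1@SD, 0)
  expect_equal(st1@SULmean, 2.0)
})

test_that("threshold is monotone in mean and SD", {
  set.seed(3)
  g <- ImageGrid(c(4, 4, 4), 2)
  for (i in 1:20) {
    m <- runif(1, 0.5, 3); s <- runif(1, 0, 0.5)
    mkstats <- function(m, s) {
      v <- array(m, c(4, 4, 4)); v[1:32] <- m - s; v[33:64] <- m + s
      backgroundStats(ScalarVolume(v, g, "SUL"),
                      new("BackgroundVOI", shape = "sphere", centre = c(0, 0, 0),
                          organ = "liver", axis = c(0, 0, 1),
                          members = 1:64, grid = g))
    }
    expect_gte(mkstats(m + 0.1, s)@threshold, mkstats(m, s)@threshold)
    expect_gte(mkstats(m, s + 0.1)@threshold, mkstats(m, s)@threshold)
  }
})

test_that("comparability applies both PERCIST bounds strictly", {
  mk <- function(m, organ = "liver") new("BackgroundStats", organ = organ,
    SULmean = m, SD = 0.1, threshold = 1.5 * m + 0.2, n = 100L)
  expect_true(checkComparability(mk(2.0), mk(2.0))$comparable)
  expect_true(checkComparability(mk(2.0), mk(2.29))$comparable)   # 0.29, 14.5 %
  expect_false(checkComparability(mk(2.0), mk(2.5))$comparable)   # 0.5, 25 %
  # boundaries are exclusive ("within" read strictly)
  expect_false(checkComparability(mk(2.0), mk(2.3))$comparable)   # exactly 0.3
  expect_false(checkComparability(mk(1.0), mk(1.2))$comparable)   # exactly 20 %
  expect_true(checkComparability(mk(1.0), mk(1.19))$comparable)
  expect_error(checkComparability(mk(2), mk(2, "aorta")), "same organ")
})
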