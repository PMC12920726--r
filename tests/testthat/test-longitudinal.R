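constantField <- function(grid, d) {
  u <- array(0, c(gridShape(grid), 3))
  for (k in 1:3) u[, , , k] <- d[k]
  new("DisplacementField", grid = grid, u = u, region = array(0L, gridShape(grid)))
}

test_that("point mapping applies the interpolated displacement", {
  g <- ImageGrid(c(16, 16, 16), 2)
  zero <- constantField(g, c(0, 0, 0))
  p <- c(10.3, 7.7, 12.1)
  expect_equal(mapPoint(zero, p), p)
  shift <- constantField(g, c(5, 0, 0))
  expect_equal(mapPoint(shift, p), p + c(5, 0, 0))
  expect_error(mapPoint(shift, c(-20, 0, 0)), "outside")

  # linear field between slabs: midpoint displacement = mean of the two ends
  u <- array(0, c(16, 16, 16, 3))
  u[, , , 1] <- array(rep(seq(0, 10, length.out = 16), 256), c(16, 16, 16))
  lin <- new("DisplacementField", grid = g, u = u,
             region = array(0L, c(16, 16, 16)))
  mid <- voxelToWorld(g, c(7.5, 8, 8))[1, ]
  expect_equal(mapPoint(lin, mid)[1] - mid[1], 5, tolerance = 0.1)
})

test_that("paired SULpeak search respects radius and physiological exclusion", {
  g <- ImageGrid(c(30, 30, 30), 2)
  W <- petrack:::allVoxelCentres(g)
  v <- array(1, c(30, 30, 30))
  lesionCtr <- c(30, 30, 30)
  v[rowSums(sweep(W, 2, lesionCtr, "-")^2) <= 9^2] <- 6
  sul <- ScalarVolume(v, g, "SUL")
  nomask <- array(FALSE, c(30, 30, 30))

  # radius 0: only the nearest voxel centre is evaluated
  r0 <- pairedSULpeak(sul, nomask, lesionCtr, 0)
  expect_equal(r0$centre, lesionCtr)
  # at the lesion centre the 1 cm3 sphere is fully inside: mean = 6
  expect_equal(r0$value, 6, tolerance = 1e-9)
  # searching from 8 mm away with a sufficient radius recovers the peak
  far <- pairedSULpeak(sul, nomask, lesionCtr + c(8, 0, 0), 10)
  expect_equal(far$value, 6, tolerance = 1e-9)
  # sphere entirely physiological: absent
  allmask <- array(TRUE, c(30, 30, 30))
  expect_true(is.na(pairedSULpeak(sul, allmask, lesionCtr, 5)$value))
  expect_error(pairedSULpeak(sul, nomask, lesionCtr, -1), ">= 0")
})

test_that("enlarging the search radius never decreases the found SULpeak", {
  set.seed(8)
  g <- ImageGrid(c(24, 24, 24), 2)
  raw <- array(runif(24^3, 0.5, 5), c(24, 24, 24))
  sul <- ScalarVolume(array(petrack:::.gauss3(as.numeric(raw), gridShape(g), 1),
                            c(24, 24, 24)), g, "SUL")
  nomask <- array(FALSE, c(24, 24, 24))
  ctr <- voxelToWorld(g, c(12, 12, 12))[1, ]
  vals <- vapply(c(0, 2, 4, 8, 12), function(r)
    pairedSULpeak(sul, nomask, ctr, r)$value, numeric(1))
  expect_true(all(diff(vals) >= -1e-12))
})

test_that("percent change follows its definition and flags absent baselines", {
  expect_equal(percentChange(10, 5), -50)
  expect_equal(percentChange(2.0, 2.8), 40)
  expect_true(is.na(percentChange(NA, 5)))
  expect_true(is.na(percentChange(0, 5)))
  for (b in c(0.5, 1, 3.7, 12)) expect_equal(percentChange(b, b), 0)
})

test_that("a displaced phantom lesion is re-found through the true field", {
  # baseline lesion; the follow-up observation sits 6 mm away; mapping with
  # the exact displacement and searching within the uncertainty radius must
  # return the baseline SULpeak within 1 %
  g <- ImageGrid(c(30, 30, 30), 2)
  W <- petrack:::allVoxelCentres(g)
  v <- array(1, c(30, 30, 30))
  blCtr <- c(24, 30, 30)
  v[rowSums(sweep(W, 2, blCtr, "-")^2) <= 9^2] <- 5.5
  baseline <- ScalarVolume(v, g, "SUL")
  field <- constantField(g, c(-6, 0, 0))   # follow-up -> baseline
  fuPeak <- blCtr + c(6, 0, 0)
  mapped <- mapPoint(field, fuPeak)
  got <- pairedSULpeak(baseline, array(FALSE, c(30, 30, 30)), mapped, 3)
  expect_lt(abs(got$value / 5.5 - 1), 0.01)
})

test_that("two lesions inside one search sphere both point at the hotter one", {
  g <- ImageGrid(c(40, 40, 40), 2)
  W <- petrack:::allVoxelCentres(g)
  v <- array(0.5, c(40, 40, 40))
  hot <- c(30, 40, 40); cool <- c(48, 40, 40)   # 18 mm apart
  v[rowSums(sweep(W, 2, hot, "-")^2) <= 8^2] <- 7
  v[rowSums(sweep(W, 2, cool, "-")^2) <= 8^2] <- 4
  baseline <- ScalarVolume(v, g, "SUL")
  nomask <- array(FALSE, c(40, 40, 40))
  # a large search sphere centred between them contains both: the hotter wins
  between <- c(39, 40, 40)
  got <- pairedSULpeak(baseline, nomask, between, 15)
  expect_equal(got$value, 7, tolerance = 0.01)
  # both follow-up lesions therefore pair to the same (hotter) baseline value
  # once the search radius spans the separation
  gotNearCool <- pairedSULpeak(baseline, nomask, cool, 22)
  expect_equal(gotNearCool$value, 7, tolerance = 0.01)
})

test_that("lesion pairs are built per follow-up lesion, sorted by SULpeak", {
  g <- ImageGrid(c(40, 40, 40), 2)
  W <- petrack:::allVoxelCentres(g)
  v <- array(0.5, c(40, 40, 40))
  c1 <- c(30, 40, 40); c2 <- c(52, 40, 40)
  v[rowSums(sweep(W, 2, c1, "-")^2) <= 8^2] <- 6
  v[rowSums(sweep(W, 2, c2, "-")^2) <= 8^2] <- 4
  baseline <- ScalarVolume(v, g, "SUL")
  # follow-up identical to baseline; identity field, constant uncertainty
  hs <- detectHotspots(baseline, 2.0)
  hs <- classifyHotspots(hs, array(FALSE, c(40, 40, 40)))
  hs <- rankHotspots(hs)
  field <- constantField(g, c(0, 0, 0))
  unc <- ScalarVolume(array(4, c(40, 40, 40)), g, "uncertainty_mm")
  pairs <- buildLesionPairs(hs, field, unc, baseline, array(FALSE, c(40, 40, 40)))
  expect_equal(nrow(pairs), 2)
  expect_equal(pairs$followupSULpeak, sort(pairs$followupSULpeak, decreasing = TRUE))
  expect_equal(pairs$percentChange, c(0, 0), tolerance = 0.5)
  expect_false(any(pairs$newLesionCandidate))
  expect_equal(pairs$radius, c(4, 4))
})
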