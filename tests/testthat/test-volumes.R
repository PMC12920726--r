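test_that("James lean body mass matches hand-evaluated values and rejects bad input", {
  expect_equal(computeLeanBodyMass("male", 70, 170), 55.298, tolerance = 1e-4)
  expect_equal(computeLeanBodyMass("female", 60, 165), 44.630, tolerance = 1e-4)
  expect_error(computeLeanBodyMass("male", 100, 100), "not positive")
  expect_error(computeLeanBodyMass("other", 70, 170), "male")
  expect_error(computeLeanBodyMass("male", -1, 170), "positive")
})

test_that("lean body mass stays below body weight across a physiological sweep", {
  for (sex in c("male", "female"))
    for (H in seq(50, 250, by = 10))
      for (bmi in c(15, 22, 30, 45)) {
        W <- bmi * (H / 100)^2
        lbm <- computeLeanBodyMass(sex, W, H)
        expect_lt(lbm, W)
        expect_gt(lbm, 0)
      }
})

test_that("SUL conversion applies the unit-consistent scaling", {
  g <- ImageGrid(c(4, 4, 4), 2)
  meta <- patientMeta("male", 70, 170, 400)
  act <- ScalarVolume(array(5, c(4, 4, 4)), g, kind = "activity_kBq_per_mL")
  sul <- toSUL(act, meta)
  expect_equal(voxelKind(sul), "SUL")
  # 5000 Bq/mL * 55298 g / 4e8 Bq
  expect_equal(voxelValues(sul)[1], 5000 * 55297.578 / 4e8, tolerance = 1e-6)
  # zero activity -> zero SUL; definition identity C = dose/LBM -> SUL 1
  expect_true(all(voxelValues(toSUL(ScalarVolume(
    array(0, c(4, 4, 4)), g, kind = "activity_kBq_per_mL"), meta)) == 0))
  lbm <- computeLeanBodyMass("male", 70, 170)
  one <- toSUL(ScalarVolume(array(400 / lbm, c(4, 4, 4)), g,
                            kind = "activity_kBq_per_mL"), meta)
  expect_equal(unname(voxelValues(one)[1]), 1.0, tolerance = 1e-12)
  expect_error(toSUL(act, patientMeta("male", 70, 170, 1)), NA)
  expect_error(patientMeta("male", 70, 170, -400), "positive")
})

test_that("SUL is linear in activity and inversely proportional to dose", {
  g <- ImageGrid(c(3, 3, 3), 1)
  set.seed(42)
  base <- array(runif(27, 0, 10), c(3, 3, 3))
  for (k in c(0.5, 2, 7)) {
    a1 <- toSUL(ScalarVolume(base, g, "activity_kBq_per_mL"),
                patientMeta("female", 60, 165, 300))
    ak <- toSUL(ScalarVolume(k * base, g, "activity_kBq_per_mL"),
                patientMeta("female", 60, 165, 300))
    expect_equal(voxelValues(ak), k * voxelValues(a1), tolerance = 1e-12)
    ad <- toSUL(ScalarVolume(base, g, "activity_kBq_per_mL"),
                patientMeta("female", 60, 165, 300 * k))
    expect_equal(voxelValues(ad), voxelValues(a1) / k, tolerance = 1e-12)
  }
  # pre-computed SUL passes through untouched
  sul <- ScalarVolume(base, g, "SUL")
  expect_identical(toSUL(sul, patientMeta("male", 80, 180, 350)), sul)
})

test_that("world and voxel coordinates are mutually inverse", {
  set.seed(7)
  flip <- diag(c(-1, 1, 1))
  for (grid in list(ImageGrid(c(16, 16, 16), 1),
                    ImageGrid(c(10, 20, 30), c(1.5, 2, 2.5), origin = c(-40, 3, 7)),
                    ImageGrid(c(8, 8, 8), 3, origin = c(5, -5, 5), direction = flip))) {
    pts <- matrix(runif(60, -2, 12), ncol = 3)
    expect_lt(max(abs(worldToVoxel(grid, voxelToWorld(grid, pts)) - pts)), 1e-9)
    w <- matrix(runif(60, -50, 50), ncol = 3)
    expect_lt(max(abs(voxelToWorld(grid, worldToVoxel(grid, w)) - w)), 1e-9)
  }
})

test_that("grid and volume validity rules are enforced", {
  expect_error(ImageGrid(c(4, 4, 4), spacing = c(1, -1, 1)), "positive")
  expect_error(ImageGrid(c(4, 4, 4), direction = matrix(1, 3, 3)), "orthonormal")
  expect_error(ScalarVolume(array(c(NA, rep(1, 7)), c(2, 2, 2))), "finite")
  expect_error(ScalarVolume(array(-1, c(2, 2, 2)), kind = "SUL"), "SUL")
  expect_error(LabelVolume(array(2L, c(2, 2, 2)), legend = c("1" = "liver")),
               "legend")
})

test_that("NIfTI write/read round trip preserves values and grid", {
  tmp <- tempfile(fileext = ".nii.gz")
  on.exit(unlink(c(tmp, petrack:::legendSidecar(tmp))), add = TRUE)
  g <- ImageGrid(c(16, 16, 16), c(1.5, 2, 2.5), origin = c(-10, 4, 2))
  set.seed(11)
  vol <- ScalarVolume(array(rnorm(16^3)^2, c(16, 16, 16)), g, "SUL")
  writeVolume(vol, tmp)
  back <- readVolume(tmp, kind = "SUL")
  expect_identical(voxelValues(back), voxelValues(vol))
  expect_lt(max(abs(spacing(back) - spacing(vol))), 1e-6)
  expect_lt(max(abs(origin(imageGrid(back)) - origin(g))), 1e-6)

  lab <- LabelVolume(array(sample(0:2, 16^3, TRUE), c(16, 16, 16)), g,
                     c("1" = "liver", "2" = "aorta"))
  tmp2 <- tempfile(fileext = ".nii.gz")
  on.exit(unlink(c(tmp2, petrack:::legendSidecar(tmp2))), add = TRUE)
  writeVolume(lab, tmp2)
  back2 <- readVolume(tmp2)
  expect_s4_class(back2, "LabelVolume")
  expect_identical(voxelLabels(back2), voxelLabels(lab))
  expect_equal(labelLegend(back2), labelLegend(lab))
})

test_that("paired volumes with mismatched grids are rejected", {
  g1 <- ImageGrid(c(8, 8, 8), 2)
  g2 <- ImageGrid(c(8, 8, 9), 2)
  pet <- ScalarVolume(array(1, c(8, 8, 8)), g1, "SUL")
  lab <- LabelVolume(array(1L, c(8, 8, 9)), g2, c("1" = "liver"))
  expect_error(runBaseline(pet, lab, lab), "grid mismatch")
})

test_that("patient metadata survives a JSON round trip", {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  writePatientMeta(patientMeta("female", 61.5, 164, 352), tmp)
  m <- readPatientMeta(tmp)
  expect_equal(m@weightKg, 61.5)
  expect_equal(m@sex, "female")
  expect_equal(m@doseMBq, 352)
})
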