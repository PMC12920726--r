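test_that("extracted surfaces have accurate areas and are watertight", {
  g <- ImageGrid(c(40, 40, 40), 1)
  sph <- ellipsoidMask(g, rep(19.5, 3), rep(15, 3))
  s <- extractSurface(sph, g)
  expect_lt(abs(surfaceArea(s) / (4 * pi * 15^2) - 1), 0.1)

  cube <- array(FALSE, c(30, 30, 30)); cube[6:25, 6:25, 6:25] <- TRUE
  s2 <- extractSurface(cube, ImageGrid(c(30, 30, 30), 1))
  expect_lt(abs(surfaceArea(s2) / (6 * 20^2) - 1), 0.1)

  sv <- array(FALSE, c(5, 5, 5)); sv[3, 3, 3] <- TRUE
  s3 <- extractSurface(sv, ImageGrid(c(5, 5, 5), 1))
  expect_gte(nrow(vertices(s3)), 8)
  # closed: every undirected edge is shared by exactly two triangles
  f <- faces(s3)
  ed <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  ed <- t(apply(ed, 1, sort))
  expect_true(all(table(paste(ed[, 1], ed[, 2])) == 2))
  expect_error(extractSurface(array(FALSE, c(4, 4, 4)), ImageGrid(c(4, 4, 4), 1)),
               "empty")
})

test_that("Kabsch recovers hand-built rigid transforms exactly and never reflects", {
  set.seed(1)
  P <- matrix(rnorm(15), ncol = 3)
  expect_lt(max(abs(kabsch(P, P) - cbind(diag(3), c(0, 0, 0)))), 1e-12)
  th <- pi / 2
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  Q <- t(R %*% t(P)) + matrix(c(1, 2, 3), 5, 3, byrow = TRUE)
  M <- kabsch(P, Q)
  expect_lt(max(abs(M[, 1:3] - R)), 1e-9)
  expect_lt(max(abs(M[, 4] - c(1, 2, 3))), 1e-9)
  # mirror-image target: sign correction keeps det(R) = +1
  Mm <- kabsch(P, Q %*% diag(c(-1, 1, 1)))
  expect_equal(det(Mm[, 1:3]), 1, tolerance = 1e-9)
  # degenerate input
  line <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(kabsch(line, line), "collinear")
  expect_error(kabsch(P[1:2, ], Q[1:2, ]), "3 point")
})

test_that("outlier filtering discards pairs strictly beyond four times the median", {
  keep <- filterOutliers(c(1, 1, 1, 1, 10))
  expect_equal(keep, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_true(all(filterOutliers(rep(2.5, 7))))
  # exactly 4x the median is retained ("exceeded" read strictly)
  expect_true(filterOutliers(c(1, 1, 1, 4))[4])
  expect_false(filterOutliers(c(1, 1, 1, 4.001))[4])
  expect_error(filterOutliers(numeric(0)), "no correspondence")
})

test_that("affine fitting is exact on noiseless affine data and flags degeneracy", {
  P <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1))
  expect_lt(max(abs(fitAffine(P, P) - cbind(diag(3), c(0, 0, 0)))), 1e-12)
  A <- diag(c(2, 1, 1))
  Q <- P %*% t(A) + matrix(c(3, -1, 2), 5, 3, byrow = TRUE)
  M <- fitAffine(P, Q)
  expect_lt(max(abs(M[, 1:3] - A)), 1e-9)
  expect_lt(max(abs(M[, 4] - c(3, -1, 2))), 1e-9)
  flat <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  expect_error(fitAffine(flat, flat), "coplanar")
  expect_error(fitAffine(P[1:3, ], Q[1:3, ]), "4 point")
})

test_that("ICP recovers identity, translations and rotations of an ellipsoid surface", {
  g <- ImageGrid(c(40, 40, 40), 2)
  s1 <- extractSurface(ellipsoidMask(g, c(38, 40, 40), c(20, 14, 10)), g)
  idt <- icpAlign(s1, s1, "rigid")
  expect_lt(max(abs(transformMatrix(idt)[, 4])), 1e-6)
  expect_lt(max(abs(transformMatrix(idt)[, 1:3] - diag(3))), 1e-6)

  s2 <- new("Surface", vertices = sweep(vertices(s1), 2, c(5, 0, 0), "+"),
            faces = faces(s1))
  tr <- icpAlign(s1, s2, "rigid")
  expect_lt(max(abs(transformMatrix(tr)[, 4] - c(5, 0, 0))), 0.1)

  th <- 10 * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  ctr <- colMeans(vertices(s1))
  s3 <- new("Surface",
            vertices = sweep(sweep(vertices(s1), 2, ctr, "-") %*% t(R), 2, ctr, "+"),
            faces = faces(s1))
  tr2 <- icpAlign(s1, s3, "rigid")
  expect_lt(abs(rotationAngleDeg(transformMatrix(tr2)[, 1:3]) - 10), 0.5)
})

test_that("region assignment covers all six body regions and uses the organ table", {
  pair <- phantomFixture("PMR", 3L)
  reg <- assignRegions(pair$baseline$organs)
  ids <- sort(unique(as.integer(voxelLabels(reg))))
  expect_equal(ids, unname(bodyRegions()))
  # a voxel inside the liver is torso
  liverVox <- which(voxelLabels(pair$baseline$organs) == 1L)[1]
  expect_equal(as.integer(voxelLabels(reg)[liverVox]), unname(bodyRegions()[["torso"]]))
  # every voxel is assigned exactly one region
  expect_true(all(voxelLabels(reg) >= 1 & voxelLabels(reg) <= 6))
  # unknown organ name in the legend is an error that names the organ
  g <- ImageGrid(c(8, 8, 8), 2)
  lv <- LabelVolume(array(1L, c(8, 8, 8)), g, c("1" = "gizzard"))
  expect_error(assignRegions(lv), "gizzard")
})

slabProblem <- function() {
  g <- ImageGrid(c(20, 10, 10), 2)
  lab <- array(0L, c(20, 10, 10)); lab[1:3, , ] <- 1L; lab[18:20, , ] <- 2L
  organs <- list(
    liver = list(voxels = which(lab == 1L), matrix = cbind(diag(3), c(0, 0, 0))),
    spleen = list(voxels = which(lab == 2L), matrix = cbind(diag(3), c(10, 0, 0))))
  regions <- LabelVolume(array(2L, c(20, 10, 10)), g, c("2" = "torso"))
  list(g = g, lab = lab, organs = organs, regions = regions)
}

test_that("harmonic interpolation reproduces constant and linear analytic fields", {
  p <- slabProblem()
  # constant displacement everywhere
  const <- lapply(p$organs, function(o) {
    o$matrix <- cbind(diag(3), c(4, -2, 1)); o
  })
  fc <- solveLaplace(p$g, const, p$regions)
  expect_lt(max(abs(displacement(fc)[, , , 1] - 4)), 1e-6)
  expect_lt(max(abs(displacement(fc)[, , , 2] + 2)), 1e-6)
  expect_lt(max(abs(displacement(fc)[, , , 3] - 1)), 1e-6)
  # two parallel slabs: linear profile between them
  f <- solveLaplace(p$g, p$organs, p$regions)
  u1 <- displacement(f)[, , , 1]
  expected <- pmin(pmax(((1:20) - 3) / 15 * 10, 0), 10)
  expect_lt(max(abs(sweep(u1, 1, expected, "-"))), 0.1)
  # Dirichlet voxels keep their exact values
  expect_true(all(u1[1:3, , ] == 0))
  expect_true(all(u1[18:20, , ] == 10))
  # discrete maximum principle on the free voxels
  expect_true(all(u1 >= -1e-9 & u1 <= 10 + 1e-9))
})

test_that("the interior of the solved field is discretely harmonic", {
  p <- slabProblem()
  f <- solveLaplace(p$g, p$organs, p$regions)
  u <- displacement(f)[, , , 1]
  inner <- u[4:17, 2:9, 2:9]
  lap <- (u[3:16, 2:9, 2:9] + u[5:18, 2:9, 2:9] +
          u[4:17, 1:8, 2:9] + u[4:17, 3:10, 2:9] +
          u[4:17, 2:9, 1:8] + u[4:17, 2:9, 3:10]) / 6 - inner
  expect_lt(max(abs(lap)), 0.05)
})

test_that("the coarse-to-fine solve agrees with the plain solver", {
  p <- slabProblem()
  f1 <- solveLaplace(p$g, p$organs, p$regions, coarsen = 1)
  f2 <- solveLaplace(p$g, p$organs, p$regions, coarsen = 2)
  expect_lt(max(abs(displacement(f1) - displacement(f2))), 0.05)
})

test_that("arm transforms do not leak into torso displacements", {
  g <- ImageGrid(c(24, 12, 12), 2)
  lab <- array(0L, c(24, 12, 12))
  lab[2:5, 4:9, 4:9] <- 1L     # torso organ
  lab[18:22, 4:9, 4:9] <- 2L   # arm organ
  reg <- array(0L, c(24, 12, 12))
  reg[1:12, , ] <- bodyRegions()[["torso"]]
  reg[13:24, , ] <- bodyRegions()[["arm_left"]]
  regions <- LabelVolume(reg, g, stats::setNames(names(bodyRegions()),
                                                 as.character(bodyRegions())))
  run <- function(armShift) {
    organs <- list(
      spine = list(voxels = which(lab == 1L), matrix = cbind(diag(3), c(0, 0, 0))),
      humerus_left = list(voxels = which(lab == 2L),
                          matrix = cbind(diag(3), c(armShift, 0, 0))))
    solveLaplace(g, organs, regions)
  }
  f0 <- run(0); f5 <- run(5)
  torso <- as.integer(voxelLabels(regions)) == bodyRegions()[["torso"]]
  for (k in 1:3) {
    u0 <- displacement(f0)[, , , k][torso]
    u5 <- displacement(f5)[, , , k][torso]
    expect_lt(max(abs(u0 - u5)), 1e-6)
  }
})

test_that("a region without organs falls back to the global mean and is flagged", {
  g <- ImageGrid(c(16, 8, 8), 2)
  lab <- array(0L, c(16, 8, 8)); lab[2:4, 3:6, 3:6] <- 1L
  reg <- array(bodyRegions()[["torso"]], c(16, 8, 8))
  reg[9:16, , ] <- bodyRegions()[["head"]]   # no organ there
  regions <- LabelVolume(reg, g, stats::setNames(names(bodyRegions()),
                                                 as.character(bodyRegions())))
  organs <- list(liver = list(voxels = which(lab == 1L),
                              matrix = cbind(diag(3), c(3, 0, 0))))
  f <- solveLaplace(g, organs, regions)
  d <- attr(f, "diagnostics")
  expect_true(d[[as.character(bodyRegions()[["head"]])]]$organless)
  headVox <- as.integer(voxelLabels(regions)) == bodyRegions()[["head"]]
  expect_true(all(abs(displacement(f)[, , , 1][headVox] - 3) < 1e-9))
})
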