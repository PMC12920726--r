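#' Synthetic whole-body phantom specification
#'
#' A \code{PhantomSpec} describes a paired baseline/follow-up study with
#' known ground truth: a voxel grid, a set of geometric organs spanning all
#' six body regions, per-organ baseline-to-follow-up transforms, lesions with
#' designed SULpeak levels at both time points, physiological (normal
#' activity) structures, a background SUL level and additive Gaussian noise.
#' Fixing the seed makes the generated pair bit-identical.
#'
#' @slot grid the \linkS4class{ImageGrid}.
#' @slot organs data.frame of geometric primitives (name, label, shape,
#'   centre, size parameters, SUL level, normal-activity flag).
#' @slot body list of primitives forming the body envelope.
#' @slot transforms named list of 3x4 baseline-to-follow-up matrices.
#' @slot lesions data.frame (cx, cy, cz mm; radius mm; sulBaseline;
#'   sulFollowup; new).
#' @slot backgroundSUL soft-tissue background SUL.
#' @slot noiseSD additive Gaussian noise SD (SUL units).
#' @slot seed RNG seed.
#' @export
setClass("PhantomSpec", representation(grid = "ImageGrid", organs = "data.frame",
                                       body = "list", transforms = "list",
                                       lesions = "data.frame",
                                       backgroundSUL = "numeric",
                                       noiseSD = "numeric", seed = "integer"))

prim <- function(shape, c1, c2, c3, a, b = a, h = a) {
  list(shape = shape, centre = c(c1, c2, c3), a = a, b = b, h = h)
}

# Each organ is a union of primitives. Shapes are deliberately asymmetric
# (triaxial ellipsoids; bones with offset heads, the spine with vertebral
# bumps, the aorta with an arch) so that every rigid/affine ground-truth
# transform is observable from the organ surface alone.
defaultOrganSet <- function() {
  org <- function(name, sul, normal, prims) {
    list(name = name, sul = sul, normal = normal, prims = prims,
         centre = prims[[1L]]$centre)
  }
  specs <- list(
    org("liver", 2.0, FALSE, list(prim("ellipsoid", 105, 130, 300, 40, 34, 30))),
    org("spleen", 1.8, FALSE, list(prim("ellipsoid", 195, 130, 305, 20, 17, 14))),
    org("lung_left", 0.5, FALSE, list(prim("ellipsoid", 185, 140, 352, 26, 28, 18))),
    org("lung_right", 0.5, FALSE, list(prim("ellipsoid", 103, 140, 352, 26, 28, 18))),
    org("kidney_left", 1.7, FALSE, list(prim("ellipsoid", 178, 170, 260, 14, 12, 16))),
    org("kidney_right", 1.7, FALSE, list(prim("ellipsoid", 110, 170, 260, 14, 12, 16))),
    org("heart", 4.0, TRUE, list(prim("ellipsoid", 150, 110, 332, 20, 18, 16))),
    org("bladder", 6.0, TRUE, list(prim("ellipsoid", 144, 150, 195, 16, 14, 12))),
    org("aorta", 1.5, FALSE, list(prim("cylinder", 144, 170, 255, 6, 6, 55),
                                  prim("ycyl", 144, 160, 308, 6, 10, 6))),
    org("spine", 1.2, FALSE, c(list(prim("cylinder", 144, 190, 275, 10, 10, 90)),
                               lapply(c(215, 245, 275, 305, 335), function(z)
                                 prim("box", 144, 196, z, 6, 7, 6)))),
    org("brain", 5.0, TRUE, list(prim("ellipsoid", 144, 144, 430, 32, 28, 26))),
    org("skull", 1.1, FALSE, list(prim("box", 144, 144, 462, 20, 14, 5))),
    org("femur_left", 1.1, FALSE, list(prim("cylinder", 188, 144, 90, 11, 11, 75),
                                       prim("ellipsoid", 176, 144, 170, 10, 10, 9))),
    org("femur_right", 1.1, FALSE, list(prim("cylinder", 100, 144, 90, 11, 11, 75),
                                        prim("ellipsoid", 112, 144, 170, 10, 10, 9))),
    org("humerus_left", 1.1, FALSE, list(prim("cylinder", 266, 144, 280, 9, 9, 70),
                                         prim("ellipsoid", 257, 144, 345, 8, 8, 7))),
    org("humerus_right", 1.1, FALSE, list(prim("cylinder", 22, 144, 280, 9, 9, 70),
                                          prim("ellipsoid", 31, 144, 345, 8, 8, 7))))
  df <- data.frame(name = vapply(specs, `[[`, "", "name"),
                   sul = vapply(specs, `[[`, 0, "sul"),
                   normal = vapply(specs, `[[`, FALSE, "normal"),
                   cx = vapply(specs, function(s) s$centre[1L], 0),
                   cy = vapply(specs, function(s) s$centre[2L], 0),
                   cz = vapply(specs, function(s) s$centre[3L], 0))
  df$prims <- lapply(specs, `[[`, "prims")
  df$label <- seq_len(nrow(df))
  df
}

defaultBodyEnvelope <- function() {
  list(
    prim("ellcyl", 144, 144, 276, 82, 60, 96),    # torso
    prim("ellipsoid", 144, 144, 425, 45, 45, 45), # head
    prim("cylinder", 22, 144, 280, 18, 18, 80),   # right arm (patient right)
    prim("cylinder", 266, 144, 280, 18, 18, 80),  # left arm
    prim("cylinder", 100, 144, 93, 38, 38, 87),   # right leg
    prim("cylinder", 188, 144, 93, 38, 38, 87))   # left leg
}

defaultLesions <- function(design = "PMR") {
  base <- data.frame(
    id = c("liver_lesion", "node_lesion"),
    cx = c(120, 144), cy = c(140, 95), cz = c(290, 250),
    radius = c(9, 9),
    sulBaseline = c(7.0, 6.0),
    sulFollowup = c(4.2, 3.6),   # -40 %
    new = c(FALSE, FALSE))
  if (design == "PMD") {
    base$sulFollowup <- c(9.8, 8.4)  # +40 %
  } else if (design == "PMD_new") {
    base$sulFollowup <- base$sulBaseline        # unchanged targets
    base <- rbind(base, data.frame(
      id = "new_lesion", cx = 170, cy = 110, cz = 230, radius = 9,
      sulBaseline = 0, sulFollowup = 6.0, new = TRUE))
  } else if (design == "SMD") {
    base$sulFollowup <- c(6.3, 5.4)  # -10 %
  } else if (design == "CMR") {
    base$sulFollowup <- c(0, 0)
  } else if (design != "PMR") {
    stop("unknown lesion design: ", design)
  }
  base
}

#' Construct a phantom specification
#'
#' The default phantom is a 96 x 96 x 160 voxel, 3 mm isotropic whole-body
#' analogue with 16 organs across all six body regions, hot physiological
#' structures (brain, heart, bladder), a liver lesion and a soft-tissue
#' lesion. Per-organ ground-truth transforms are drawn deterministically from
#' the seed: translations of 2-8 mm for every organ, plus a small anisotropic
#' scaling (0.97-1.03) for soft-tissue (affine-model) organs.
#'
#' @param seed RNG seed fixing transforms and noise.
#' @param design lesion change design: "PMR" (-40\%), "PMD" (+40\%),
#'   "PMD_new" (stable + new lesion), "SMD" (-10\%), "CMR" (lesions vanish).
#' @param transforms optional named list of 3x4 matrices overriding the
#'   random draw ("identity" for all-identity).
#' @param lesions optional lesion data.frame overriding the design.
#' @param noiseSD Gaussian noise SD in SUL units.
#' @param translationRange magnitude range (mm) of random organ translations.
#' @param grid optional \linkS4class{ImageGrid} override.
#' @return A \linkS4class{PhantomSpec}.
#' @examples
#' spec <- phantomSpec(seed = 1, design = "PMR")
#' @export
phantomSpec <- function(seed = 1L, design = "PMR", transforms = NULL,
                        lesions = NULL, noiseSD = 0.05,
                        translationRange = c(2, 8), grid = NULL) {
  if (is.null(grid))
    grid <- ImageGrid(c(96L, 96L, 160L), spacing = 3)
  organs <- defaultOrganSet()
  if (is.null(lesions)) lesions <- defaultLesions(design)
  if (is.null(transforms)) {
    transforms <- randomOrganTransforms(organs, seed = seed,
                                        translationRange = translationRange)
  } else if (identical(transforms, "identity")) {
    transforms <- stats::setNames(
      rep(list(cbind(diag(3), c(0, 0, 0))), nrow(organs)), organs$name)
  }
  new("PhantomSpec", grid = grid, organs = organs, body = defaultBodyEnvelope(),
      transforms = transforms, lesions = lesions, backgroundSUL = 1.0,
      noiseSD = noiseSD, seed = as.integer(seed))
}

#' Random per-organ ground-truth transforms
#'
#' Deterministic under \code{seed}: each organ gets a translation with a
#' random direction and magnitude uniform in \code{translationRange}; organs
#' whose model is affine additionally get an anisotropic scaling about their
#' centre, uniform in \code{scaleRange} per axis.
#'
#' @param organs organ data.frame as in a \linkS4class{PhantomSpec}.
#' @param seed RNG seed.
#' @param translationRange mm range of translation magnitudes.
#' @param scaleRange per-axis scale factor range for soft-tissue organs.
#' @return Named list of 3x4 matrices.
#' @export
randomOrganTransforms <- function(organs, seed = 1L,
                                  translationRange = c(2, 8),
                                  scaleRange = c(0.97, 1.03)) {
  set.seed(seed)
  models <- organModelTable()
  out <- vector("list", nrow(organs))
  names(out) <- organs$name
  for (i in seq_len(nrow(organs))) {
    dirv <- stats::rnorm(3)
    dirv <- dirv / sqrt(sum(dirv^2))
    t <- dirv * stats::runif(1, translationRange[1L], translationRange[2L])
    A <- diag(3)
    model <- models[[organs$name[i]]]
    if (identical(model, "affine")) {
      A <- diag(stats::runif(3, scaleRange[1L], scaleRange[2L]))
    }
    ctr <- c(organs$cx[i], organs$cy[i], organs$cz[i])
    b <- ctr + t - A %*% ctr
    out[[i]] <- cbind(A, as.numeric(b))
  }
  out
}

primMember <- function(p, W) {
  cx <- p$centre[1L]; cy <- p$centre[2L]; cz <- p$centre[3L]
  switch(p$shape,
    ellipsoid = ((W[, 1L] - cx) / p$a)^2 + ((W[, 2L] - cy) / p$b)^2 +
                ((W[, 3L] - cz) / p$h)^2 <= 1,
    cylinder = ((W[, 1L] - cx) / p$a)^2 + ((W[, 2L] - cy) / p$b)^2 <= 1 &
               abs(W[, 3L] - cz) <= p$h,
    ycyl = ((W[, 1L] - cx) / p$a)^2 + ((W[, 3L] - cz) / p$h)^2 <= 1 &
           abs(W[, 2L] - cy) <= p$b,
    ellcyl = ((W[, 1L] - cx) / p$a)^2 + ((W[, 2L] - cy) / p$b)^2 <= 1 &
             abs(W[, 3L] - cz) <= p$h,
    box = abs(W[, 1L] - cx) <= p$a & abs(W[, 2L] - cy) <= p$b &
          abs(W[, 3L] - cz) <= p$h,
    stop("unknown primitive shape: ", p$shape))
}

organMember <- function(row, W) {
  member <- rep(FALSE, nrow(W))
  for (p in row$prims[[1L]]) member <- member | primMember(p, W)
  member
}

applyAffine <- function(M, pts) {
  pts <- rbindMat(pts)
  sweep(pts %*% t(M[, 1:3]), 2L, M[, 4L], "+")
}

invertAffine <- function(M) {
  Ai <- solve(M[, 1:3])
  cbind(Ai, -Ai %*% M[, 4L])
}

#' Generate a paired baseline/follow-up phantom study
#'
#' Builds the baseline study analytically, then moves every organ mask by its
#' ground-truth transform (nearest-neighbour resampling) to form the
#' follow-up study. Lesions move with their containing organ; their follow-up
#' SUL levels honour the spec. The returned truth record carries the
#' transforms, the lesion correspondence and the intended PERCIST class.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return List with elements \code{baseline} and \code{followup} (each a
#'   list: sul \linkS4class{ScalarVolume}, organs \linkS4class{LabelVolume},
#'   normal \linkS4class{LabelVolume}) and \code{truth}.
#' @examples
#' pair <- makePhantomPair(phantomSpec(seed = 7, noiseSD = 0))
#' @export
makePhantomPair <- function(spec) {
  grid <- spec@grid
  n <- prod(grid@shape)
  W <- allVoxelCentres(grid)
  organs <- spec@organs
  legend <- stats::setNames(organs$name, as.character(organs$label))

  bodyMask <- rep(FALSE, n)
  for (p in spec@body) bodyMask <- bodyMask | primMember(p, W)

  # baseline organ masks (member index vectors, painted in label order)
  blMembers <- vector("list", nrow(organs))
  lab <- integer(n)
  for (i in seq_len(nrow(organs))) {
    m <- which(organMember(organs[i, ], W))
    if (any(lab[m] != 0L))
      stop("phantom organs overlap: ", organs$name[i])
    lab[m] <- organs$label[i]
    blMembers[[i]] <- m
  }
  blLabels <- LabelVolume(array(lab, dim = grid@shape), grid, legend)

  lesions <- spec@lesions
  if (nrow(lesions) > 0) {
    inBody <- sapply(seq_len(nrow(lesions)), function(i) {
      j <- voxelToLinear(grid, round(worldToVoxel(
        grid, c(lesions$cx[i], lesions$cy[i], lesions$cz[i]))))
      bodyMask[j]
    })
    if (!all(inBody))
      stop("lesions outside the body envelope: ",
           paste(lesions$id[!inBody], collapse = ", "))
  }

  # containing organ per lesion (for motion); NA = body (identity)
  lesionOrgan <- rep(NA_character_, nrow(lesions))
  for (i in seq_len(nrow(lesions))) {
    j <- voxelToLinear(grid, round(worldToVoxel(
      grid, c(lesions$cx[i], lesions$cy[i], lesions$cz[i]))))
    if (lab[j] != 0L) lesionOrgan[i] <- legend[[as.character(lab[j])]]
  }

  set.seed(spec@seed)
  paintSUL <- function(members, lesionCentres, lesionLevels, lesionRadii) {
    v <- numeric(n)
    v[bodyMask] <- spec@backgroundSUL
    for (i in seq_along(members)) v[members[[i]]] <- organs$sul[i]
    for (i in seq_along(lesionLevels)) {
      if (lesionLevels[i] <= 0) next
      d2 <- (W[, 1L] - lesionCentres[i, 1L])^2 + (W[, 2L] - lesionCentres[i, 2L])^2 +
            (W[, 3L] - lesionCentres[i, 3L])^2
      v[d2 <= lesionRadii[i]^2] <- lesionLevels[i]
    }
    if (spec@noiseSD > 0) v <- v + stats::rnorm(n, sd = spec@noiseSD)
    v[v < 0] <- 0
    array(v, dim = grid@shape)
  }

  blCentres <- as.matrix(lesions[, c("cx", "cy", "cz"), drop = FALSE])
  blLevels <- ifelse(lesions$new, 0, lesions$sulBaseline)
  blSUL <- ScalarVolume(paintSUL(blMembers, blCentres, blLevels,
                                 lesions$radius), grid, "SUL")

  # follow-up organ masks: baseline masks moved by the ground-truth
  # transforms, nearest-neighbour resampled
  extLo <- voxelToWorld(grid, c(0, 0, 0))
  extHi <- voxelToWorld(grid, grid@shape - 1L)
  fuMembers <- vector("list", nrow(organs))
  fuLab <- integer(n)
  for (i in seq_len(nrow(organs))) {
    M <- spec@transforms[[organs$name[i]]]
    if (is.null(M)) M <- cbind(diag(3), c(0, 0, 0))
    blIdx <- linearToVoxel(grid, blMembers[[i]])
    blW <- voxelToWorld(grid, blIdx)
    fuW <- applyAffine(M, blW)
    if (any(sweep(fuW, 2L, pmin(extLo, extHi), "<") |
            sweep(fuW, 2L, pmax(extLo, extHi), ">")))
      stop("ground-truth transform pushes organ '", organs$name[i],
           "' outside the grid")
    # resample over the transformed bounding box
    bb <- apply(round(worldToVoxel(grid, fuW)), 2L, range)
    lo <- pmax(bb[1L, ] - 1, 0); hi <- pmin(bb[2L, ] + 1, grid@shape - 1L)
    idx <- as.matrix(expand.grid(x = lo[1L]:hi[1L], y = lo[2L]:hi[2L],
                                 z = lo[3L]:hi[3L]))
    wi <- voxelToWorld(grid, idx)
    src <- round(worldToVoxel(grid, applyAffine(invertAffine(M), wi)))
    ok <- src[, 1L] >= 0 & src[, 1L] < grid@shape[1L] &
          src[, 2L] >= 0 & src[, 2L] < grid@shape[2L] &
          src[, 3L] >= 0 & src[, 3L] < grid@shape[3L]
    hit <- rep(FALSE, nrow(idx))
    hit[ok] <- lab[voxelToLinear(grid, src[ok, , drop = FALSE])] == organs$label[i]
    m <- voxelToLinear(grid, idx[hit, , drop = FALSE])
    fuLab[m] <- organs$label[i]
    fuMembers[[i]] <- m
  }
  fuLabels <- LabelVolume(array(fuLab, dim = grid@shape), grid, legend)

  fuCentres <- blCentres
  for (i in seq_len(nrow(lesions))) {
    M <- if (!is.na(lesionOrgan[i])) spec@transforms[[lesionOrgan[i]]] else NULL
    if (!is.null(M)) fuCentres[i, ] <- applyAffine(M, blCentres[i, , drop = FALSE])
  }
  fuSUL <- ScalarVolume(paintSUL(fuMembers, fuCentres, lesions$sulFollowup,
                                 lesions$radius), grid, "SUL")

  normalVolume <- function(members) {
    v <- integer(n)
    for (i in which(organs$normal)) v[members[[i]]] <- 1L
    LabelVolume(array(v, dim = grid@shape), grid, c("1" = "normal_activity"))
  }

  truthLesions <- cbind(lesions,
                        fux = fuCentres[, 1L], fuy = fuCentres[, 2L],
                        fuz = fuCentres[, 3L], organ = lesionOrgan)
  present <- lesions$sulFollowup > 0
  anyNew <- any(lesions$new & present)
  if (!any(present)) {
    intended <- "CMR"
    pct <- NA_real_; absch <- NA_real_
  } else {
    tb <- max(lesions$sulBaseline[!lesions$new])
    tf <- max(lesions$sulFollowup[present & !lesions$new])
    if (!is.finite(tf)) tf <- 0
    pct <- 100 * (tf - tb) / tb
    absch <- tf - tb
    intended <- classifyResponse(lesionsPresent = TRUE, newLesions = anyNew,
                                 unequivocalProgression = FALSE,
                                 percentChange = pct,
                                 absoluteChange = absch)@classification
  }

  list(
    baseline = list(sul = blSUL, organs = blLabels, normal = normalVolume(blMembers)),
    followup = list(sul = fuSUL, organs = fuLabels, normal = normalVolume(fuMembers)),
    truth = list(transforms = spec@transforms, lesions = truthLesions,
                 intendedClass = intended, percentChange = pct,
                 absoluteChange = absch, newLesions = anyNew))
}

#' Generate a calibration set of mask pairs
#'
#' Produces \code{n} phantom pairs with varied per-organ transforms and
#' returns, for each pair and organ, a (propagated, actual) mask pair for
#' Hausdorff-based uncertainty calibration. With \code{method = "none"} the
#' propagated mask is the untouched baseline segmentation (the discrepancy
#' then measures the raw organ motion); \code{"truth"} propagates with the
#' ground-truth transform; \code{"estimate"} runs the full alignment and
#' propagates with the estimated organ transforms, which is the genuine
#' calibration procedure.
#'
#' @param template a \linkS4class{PhantomSpec} used as template.
#' @param n number of pairs (>= 1).
#' @param seed base seed; pair i uses seed + i - 1.
#' @param transforms optional list (length n) of named transform lists
#'   overriding the random draws.
#' @param method "none", "truth" or "estimate" (see above).
#' @return List of length n; each element has \code{propagated} and
#'   \code{actual} \linkS4class{LabelVolume}s and the pair's truth record.
#' @export
makeCalibrationSet <- function(template = phantomSpec(), n = 5L, seed = 1L,
                               transforms = NULL, method = c("none", "truth",
                                                             "estimate")) {
  method <- match.arg(method)
  if (n < 1L) stop("n must be >= 1")
  out <- vector("list", n)
  for (i in seq_len(n)) {
    tf <- if (!is.null(transforms)) transforms[[i]] else NULL
    spec <- phantomSpec(seed = seed + i - 1L, lesions = template@lesions,
                        noiseSD = template@noiseSD, grid = template@grid,
                        transforms = tf)
    pair <- makePhantomPair(spec)
    propagated <- pair$baseline$organs
    if (method == "truth") {
      propagated <- propagateLabels(pair$baseline$organs, spec@transforms)
    } else if (method == "estimate") {
      al <- alignImages(pair$followup$organs, pair$baseline$organs)
      est <- lapply(al$transforms, function(tr) invertAffine(tr@matrix))
      propagated <- propagateLabels(pair$baseline$organs, est)
    }
    out[[i]] <- list(propagated = propagated, actual = pair$followup$organs,
                     truth = pair$truth)
  }
  out
}

# propagate each organ mask of a label volume by its (baseline -> follow-up)
# affine, nearest-neighbour resampled on the same grid
propagateLabels <- function(labels, transforms) {
  grid <- labels@grid
  lab <- as.integer(labels@labels)
  out <- integer(length(lab))
  legend <- labels@legend
  for (lv in setdiff(unique(lab), 0L)) {
    nm <- legend[[as.character(lv)]]
    M <- transforms[[nm]]
    if (is.null(M)) M <- cbind(diag(3), c(0, 0, 0))
    mem <- which(lab == lv)
    idx <- linearToVoxel(grid, mem)
    fuW <- applyAffine(M, voxelToWorld(grid, idx))
    bb <- apply(round(worldToVoxel(grid, fuW)), 2L, range)
    lo <- pmax(bb[1L, ] - 1, 0); hi <- pmin(bb[2L, ] + 1, grid@shape - 1L)
    tgt <- as.matrix(expand.grid(x = lo[1L]:hi[1L], y = lo[2L]:hi[2L],
                                 z = lo[3L]:hi[3L]))
    src <- round(worldToVoxel(grid, applyAffine(invertAffine(M),
                                                voxelToWorld(grid, tgt))))
    ok <- src[, 1L] >= 0 & src[, 1L] < grid@shape[1L] &
          src[, 2L] >= 0 & src[, 2L] < grid@shape[2L] &
          src[, 3L] >= 0 & src[, 3L] < grid@shape[3L]
    hit <- rep(FALSE, nrow(tgt))
    hit[ok] <- lab[voxelToLinear(grid, src[ok, , drop = FALSE])] == lv
    out[voxelToLinear(grid, tgt[hit, , drop = FALSE])] <- lv
  }
  LabelVolume(array(out, dim = grid@shape), grid, legend)
}

setMethod("show", "PhantomSpec", function(object) {
  cat("PhantomSpec:", paste(object@grid@shape, collapse = " x "), "voxels,",
      nrow(object@organs), "organs,", nrow(object@lesions), "lesions, seed",
      object@seed, "\n")
})
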