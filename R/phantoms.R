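# NEMA NU-2 phantom scenes. All primitives in mm; activity in kBq/ml.
# Primitives are painted in list order (the last one wins inside overlaps).

.shapeCode <- c(sphere = 1, cylinder = 2, capsule = 3, box = 4, ellcyl = 5)

.newScene <- function(primitives, description) {
  rownames(primitives) <- NULL
  new("PhantomScene", primitives = primitives, description = description)
}

.prim <- function(shape, c, p, material, activity = 0) {
  data.frame(shape = shape, cx = c[1], cy = c[2], cz = c[3],
             p1 = p[1], p2 = if (length(p) > 1) p[2] else 0,
             p3 = if (length(p) > 2) p[3] else 0,
             material = material, activity = activity,
             stringsAsFactors = FALSE)
}

# internal: numeric matrix for the C++ kernels
.sceneCpp <- function(scene) {
  p <- scene@primitives
  cbind(.shapeCode[p$shape], p$cx, p$cy, p$cz, p$p1, p$p2, p$p3,
        .materialIndex(p$material), p$activity)
}

# analytic primitive volume in ml
.primVolume <- function(p) {
  v <- numeric(nrow(p))
  for (i in seq_len(nrow(p))) {
    v[i] <- switch(p$shape[i],
      sphere = 4 / 3 * pi * p$p1[i]^3,
      cylinder = ,
      capsule = pi * p$p1[i]^2 * 2 * p$p2[i],
      box = 8 * p$p1[i] * p$p2[i] * p$p3[i],
      ellcyl = pi * p$p1[i] * p$p2[i] * 2 * p$p3[i])
  }
  v / 1000
}

.primBBox <- function(p, i) {
  c <- c(p$cx[i], p$cy[i], p$cz[i])
  h <- switch(p$shape[i],
    sphere = rep(p$p1[i], 3),
    cylinder = ,
    capsule = c(p$p1[i], p$p1[i], p$p2[i]),
    box = c(p$p1[i], p$p2[i], p$p3[i]),
    ellcyl = c(p$p1[i], p$p2[i], p$p3[i]))
  rbind(c - h, c + h)
}

.pointInPrim <- function(p, i, x, y, z) {
  dx <- x - p$cx[i]; dy <- y - p$cy[i]; dz <- z - p$cz[i]
  switch(p$shape[i],
    sphere = dx^2 + dy^2 + dz^2 <= p$p1[i]^2,
    cylinder = ,
    capsule = dx^2 + dy^2 <= p$p1[i]^2 & abs(dz) <= p$p2[i],
    box = abs(dx) <= p$p1[i] & abs(dy) <= p$p2[i] & abs(dz) <= p$p3[i],
    ellcyl = (dx / p$p1[i])^2 + (dy / p$p2[i])^2 <= 1 & abs(dz) <= p$p3[i])
}

# volume of primitive i not covered by any later primitive, ml.
# Overlaps are resolved on a deterministic lattice (no RNG use).
.effectiveVolumes <- function(scene) {
  p <- scene@primitives
  n <- nrow(p)
  v <- .primVolume(p)
  if (n < 2) return(v)
  for (i in seq_len(n - 1)) {
    later <- (i + 1):n
    bb <- .primBBox(p, i)
    overl <- later[vapply(later, function(j) {
      bj <- .primBBox(p, j)
      all(bj[1, ] <= bb[2, ]) && all(bj[2, ] >= bb[1, ])
    }, logical(1))]
    if (!length(overl)) next
    g <- 24
    gx <- seq(bb[1, 1], bb[2, 1], length.out = g)
    gy <- seq(bb[1, 2], bb[2, 2], length.out = g)
    gz <- seq(bb[1, 3], bb[2, 3], length.out = g)
    pts <- expand.grid(x = gx, y = gy, z = gz)
    ins <- .pointInPrim(p, i, pts$x, pts$y, pts$z)
    if (!any(ins)) next
    cov <- rep(FALSE, sum(ins))
    for (j in overl)
      cov <- cov | .pointInPrim(p, j, pts$x[ins], pts$y[ins], pts$z[ins])
    v[i] <- v[i] * (1 - sum(cov) / sum(ins))
  }
  v
}

#' Total activity of a scene
#'
#' Sum over primitives of concentration times (overlap-corrected)
#' volume.
#'
#' @param scene a [PhantomScene-class]
#' @return total activity in Bq
#' @export
totalActivity <- function(scene) {
  sum(scene@primitives$activity * .effectiveVolumes(scene)) * 1000
}

setMethod("show", "PhantomScene", function(object) {
  cat("PhantomScene:", object@description, "\n")
  cat(sprintf("  %d primitives, total activity %.4g MBq\n",
              nrow(object@primitives), totalActivity(object) / 1e6))
})

# ---- scene constructors -----------------------------------------------------

#' Point-source resolution scene
#'
#' A 0.5 mm diameter F-18 sphere at 15.28 MBq/ml, optionally inside a
#' small warm water cylinder whose concentration is the source
#' concentration divided by `backgroundRatio`.
#'
#' @param positionCm numeric(3), source centre in cm
#' @param warmBackground add the warm background cylinder?
#' @param backgroundRatio source-to-background concentration ratio
#' @param scanner scanner used to validate that the position lies inside
#'   the detector coverage
#' @return a [PhantomScene-class]
#' @examples
#' makePointSourceScene(c(1, 0, 0))
#' @export
makePointSourceScene <- function(positionCm, warmBackground = FALSE,
                                 backgroundRatio = 1000,
                                 scanner = buildFlatPanelScanner()) {
  pos <- positionCm * 10
  if (is(scanner, "FlatPanelScanner")) {
    ok <- abs(pos[1]) < scanner@panelWidth / 2 &&
      abs(pos[2]) < scanner@panelSeparation / 2 &&
      abs(pos[3]) < scanner@panelAxial / 2
  } else {
    ok <- sqrt(pos[1]^2 + pos[2]^2) < scanner@ringDiameter / 2 &&
      abs(pos[3]) < scanner@axialExtent / 2
  }
  if (!ok) stop("point source outside the detector coverage")
  conc <- 15280 # kBq/ml = 15.28 MBq/ml
  prims <- NULL
  if (warmBackground) {
    # warm region centred on the source: the largest cylinder that fits
    # the local reconstruction grid (so all simulated activity is inside
    # the reconstructed volume), exercising the iterative algorithm's
    # background response
    prims <- .prim("cylinder", pos, c(15, 15), "water", conc / backgroundRatio)
  }
  prims <- rbind(prims, .prim("sphere", pos, 0.25, "water", conc))
  .newScene(prims, sprintf("point source at (%g, %g, %g) cm%s", positionCm[1],
                           positionCm[2], positionCm[3],
                           if (warmBackground) " in warm background" else ""))
}

# NU-2 sensitivity sleeve dimensions (aluminum tubes), mm
.SLEEVES <- data.frame(id = c(3.9, 7.0, 10.2, 13.4, 16.6),
                       od = c(6.4, 9.5, 12.7, 15.9, 19.1))

#' Sensitivity scene: sleeved line source
#'
#' A thin F-18 line source of 1 MBq total activity (modelled as a 1 mm
#' diameter water capsule) surrounded by up to five concentric aluminum
#' sleeves of the NU-2 sensitivity-phantom dimensions, all of the same
#' length as the source.
#'
#' @param lineLengthCm 70 or 106
#' @param nSleeves number of aluminum sleeves, 1..5
#' @param offsetCm numeric(2), transaxial (x, y) offset of the assembly
#'   in cm
#' @param totalActivityBq line-source activity, default 1 MBq
#' @return a [PhantomScene-class]
#' @export
makeSensitivityScene <- function(lineLengthCm = 70, nSleeves = 5,
                                 offsetCm = c(0, 0), totalActivityBq = 1e6) {
  if (!lineLengthCm %in% c(70, 106))
    stop("line length must be 70 or 106 cm")
  if (nSleeves < 1 || nSleeves > 5) stop("nSleeves must be in 1..5")
  hz <- lineLengthCm * 10 / 2
  ctr <- c(offsetCm * 10, 0)
  prims <- NULL
  for (k in rev(seq_len(nSleeves))) {
    prims <- rbind(prims,
      .prim("cylinder", ctr, c(.SLEEVES$od[k] / 2, hz), "aluminum"),
      .prim("cylinder", ctr, c(.SLEEVES$id[k] / 2, hz), "air"))
  }
  rLine <- 0.5
  volMl <- pi * rLine^2 * 2 * hz / 1000
  conc <- totalActivityBq / 1000 / volMl # kBq/ml
  prims <- rbind(prims, .prim("capsule", ctr, c(rLine, hz), "water", conc))
  .newScene(prims, sprintf("%g cm sleeved line source, offset (%g, %g) cm",
                           lineLengthCm, offsetCm[1], offsetCm[2]))
}

#' Scatter/count-rate scene
#'
#' The NU-2 scatter phantom: a 70 cm line source offset 4.5 cm from the
#' axis inside a 20.3 cm diameter, 70 cm long polyethylene cylinder.
#' The line activity is set so that the concentration averaged over the
#' polyethylene cylinder volume equals `activityKBqMl`.
#'
#' @param offsetAxis `"X"` (parallel to the panels) or `"Y"` (toward a
#'   panel); irrelevant up to rotation for the cylindrical scanner
#' @param activityKBqMl cylinder-volume-equivalent activity
#'   concentration, kBq/ml
#' @param offsetCm line offset from the axis, cm
#' @return a [PhantomScene-class]
#' @export
makeScatterScene <- function(offsetAxis = c("X", "Y"), activityKBqMl = 1,
                             offsetCm = 4.5) {
  offsetAxis <- match.arg(offsetAxis)
  rCyl <- 203 / 2
  hz <- 350
  rLine <- 0.5
  if (abs(offsetCm * 10) + rLine > rCyl)
    stop("line source offset places it outside the polyethylene cylinder")
  off <- if (offsetAxis == "X") c(offsetCm * 10, 0, 0) else c(0, offsetCm * 10, 0)
  cylVolMl <- pi * rCyl^2 * 2 * hz / 1000
  lineVolMl <- pi * rLine^2 * 2 * hz / 1000
  conc <- activityKBqMl * cylVolMl / lineVolMl
  prims <- rbind(
    .prim("cylinder", c(0, 0, 0), c(rCyl, hz), "polyethylene"),
    .prim("capsule", off, c(rLine, hz), "water", conc))
  .newScene(prims, sprintf("scatter phantom, %s offset, %g kBq/ml",
                           offsetAxis, activityKBqMl))
}

#' Image-quality scene
#'
#' NEMA image-quality phantom: a warm elliptical-cylinder body (water)
#' with six hot spheres (10-37 mm diameter) at a 4:1 concentration
#' ratio, and optionally two extra 10 mm lesions at the anterior and
#' posterior body surfaces.
#'
#' @param extraLesions add the two surface lesions?
#' @param axialPosition `"center"` or `"eighth"` (phantom centre moved
#'   to 1/8 of the axial FOV from the scanner edge, z = -39.75 cm)
#' @param backgroundKBqMl warm background concentration
#' @param ratio sphere-to-background concentration ratio
#' @return a [PhantomScene-class]
#' @export
makeIQScene <- function(extraLesions = FALSE,
                        axialPosition = c("center", "eighth"),
                        backgroundKBqMl = 5.3, ratio = 4) {
  axialPosition <- match.arg(axialPosition)
  zc <- if (axialPosition == "center") 0 else -397.5
  rx <- 150; ry <- 110; hz <- 90
  hot <- backgroundKBqMl * ratio
  prims <- .prim("ellcyl", c(0, 0, zc), c(rx, ry, hz), "water", backgroundKBqMl)
  dia <- c(10, 13, 17, 22, 28, 37)
  ang <- (seq_along(dia) - 1) * 60 * pi / 180
  rPos <- 114.4 / 2
  for (k in seq_along(dia)) {
    prims <- rbind(prims, .prim("sphere",
      c(rPos * cos(ang[k]), rPos * sin(ang[k]), zc), dia[k] / 2,
      "water", hot))
  }
  if (extraLesions) {
    for (sy in c(-1, 1)) {
      prims <- rbind(prims, .prim("sphere", c(0, sy * (ry - 5), zc), 5,
                                  "water", hot))
    }
  }
  .newScene(prims, sprintf("IQ phantom (%s)%s", axialPosition,
                           if (extraLesions) " + surface lesions" else ""))
}

# ---- decay sampling ---------------------------------------------------------

# uniform positions inside primitive i of scene p (rejecting the part
# covered by later primitives, which own that region)
.samplePrim <- function(p, i, n) {
  if (n == 0)
    return(matrix(numeric(0), ncol = 3))
  draw <- function(m) {
    switch(p$shape[i],
      sphere = {
        r <- p$p1[i] * runif(m)^(1 / 3)
        cz <- 2 * runif(m) - 1
        sz <- sqrt(pmax(0, 1 - cz^2))
        ph <- 2 * pi * runif(m)
        cbind(r * sz * cos(ph), r * sz * sin(ph), r * cz)
      },
      cylinder = ,
      capsule = {
        r <- p$p1[i] * sqrt(runif(m))
        ph <- 2 * pi * runif(m)
        cbind(r * cos(ph), r * sin(ph), (2 * runif(m) - 1) * p$p2[i])
      },
      box = cbind((2 * runif(m) - 1) * p$p1[i], (2 * runif(m) - 1) * p$p2[i],
                  (2 * runif(m) - 1) * p$p3[i]),
      ellcyl = {
        u <- matrix(2 * runif(2 * m) - 1, ncol = 2)
        while (any(bad <- rowSums(u^2) > 1))
          u[bad, ] <- matrix(2 * runif(2 * sum(bad)) - 1, ncol = 2)
        cbind(u[, 1] * p$p1[i], u[, 2] * p$p2[i], (2 * runif(m) - 1) * p$p3[i])
      })
  }
  out <- matrix(numeric(0), ncol = 3)
  later <- if (i < nrow(p)) (i + 1):nrow(p) else integer(0)
  guard <- 0
  while (nrow(out) < n && guard < 100) {
    m <- n - nrow(out)
    pts <- sweep(draw(m), 2, c(p$cx[i], p$cy[i], p$cz[i]), "+")
    keep <- rep(TRUE, m)
    for (j in later)
      keep <- keep & !.pointInPrim(p, j, pts[, 1], pts[, 2], pts[, 3])
    out <- rbind(out, pts[keep, , drop = FALSE])
    guard <- guard + 1
  }
  out[seq_len(n), , drop = FALSE]
}

#' Sample positron decays from a scene
#'
#' Decay positions are uniform within each primitive, weighted by
#' activity concentration times volume; decay times are uniform over the
#' acquisition. In duration mode the decay count is Poisson with mean
#' (total activity x duration); with `nDecays` given, the acquisition
#' duration is set to `nDecays / totalActivity(scene)` so that count
#' rates remain physical.
#'
#' @param scene a [PhantomScene-class]
#' @param nDecays number of decays to generate (exclusive with
#'   `durationS`)
#' @param durationS acquisition duration in seconds
#' @param eventIdOffset added to the sequential event ids (for batching)
#' @param importance optional per-primitive sampling probabilities
#'   (importance sampling): decays are allocated with these proportions
#'   instead of the physical activity weights, and the returned
#'   `weight` column compensates (physical / sampling fraction) so that
#'   weighted estimates stay unbiased
#' @return data.frame with `x`, `y`, `z` (mm), `time` (s), `eventId`,
#'   `prim` (origin primitive index) and `weight`; attributes `duration`
#'   (s) and `totalActivityBq`
#' @export
sampleDecays <- function(scene, nDecays = NULL, durationS = NULL,
                         eventIdOffset = 0, importance = NULL) {
  act <- totalActivity(scene)
  if (act <= 0) {
    if (is.null(durationS)) stop("scene has no activity")
    out <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      time = numeric(0), eventId = numeric(0))
    attr(out, "duration") <- durationS
    attr(out, "totalActivityBq") <- 0
    return(out)
  }
  if (is.null(nDecays) == is.null(durationS))
    stop("give exactly one of nDecays, durationS")
  if (is.null(nDecays)) {
    n <- rpois(1, act * durationS)
    dur <- durationS
  } else {
    n <- as.integer(nDecays)
    dur <- n / act
  }
  p <- scene@primitives
  w <- p$activity * .effectiveVolumes(scene)
  pPhys <- w / sum(w)
  pSamp <- if (is.null(importance)) pPhys else {
    stopifnot(length(importance) == nrow(p))
    imp <- importance * (pPhys > 0)
    imp / sum(imp)
  }
  counts <- as.vector(rmultinom(1, n, pSamp))
  pos <- do.call(rbind, lapply(seq_len(nrow(p)), function(i)
    .samplePrim(p, i, counts[i])))
  prim <- rep(seq_len(nrow(p)), counts)
  ord <- sample.int(n) # interleave primitives so event ids are unordered in space
  wDecay <- ifelse(pSamp > 0, pPhys / pSamp, 0)
  out <- data.frame(x = pos[ord, 1], y = pos[ord, 2], z = pos[ord, 3],
                    time = runif(n, 0, dur),
                    eventId = seq_len(n) + eventIdOffset,
                    prim = prim[ord], weight = wDecay[prim[ord]])
  attr(out, "duration") <- dur
  attr(out, "totalActivityBq") <- act
  out
}

# ---- voxelized scene maps ---------------------------------------------------

#' Voxelize a scene
#'
#' `sceneAttenuationMap` samples the 511 keV linear attenuation
#' coefficient (1/mm) at voxel centres; `sceneActivityMap` samples the
#' activity concentration (kBq/ml). Both return a [PetImage-class] that
#' can be exported as NIfTI via [writeNiftiImage()].
#'
#' @param scene a [PhantomScene-class]
#' @param grid a [VoxelGrid-class]
#' @return a [PetImage-class]
#' @export
sceneAttenuationMap <- function(scene, grid) {
  ctr <- voxelCenters(grid)
  m <- .materialsCpp()
  idx <- cpp_point_materials(ctr, .sceneCpp(scene), m$background)
  mu <- (m$muInc + m$muPe)[idx]
  new("PetImage", data = array(mu, grid@dims), grid = grid)
}

#' @rdname sceneAttenuationMap
#' @export
sceneActivityMap <- function(scene, grid) {
  ctr <- voxelCenters(grid)
  idx <- cpp_point_prims(ctr, .sceneCpp(scene))
  act <- c(0, scene@primitives$activity)[idx + 1]
  new("PetImage", data = array(act, grid@dims), grid = grid)
}
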