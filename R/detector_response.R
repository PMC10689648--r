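# Detector response: convert true interaction points into measured LOR
# endpoints. Monolithic blocks smear with an anisotropic Gaussian
# (in-plane vs depth-of-interaction); pixelated crystals collapse the
# depth to the pixel mid-plane and randomize uniformly over the face.

#' Smear interaction points of monolithic detectors
#'
#' Independent Gaussian perturbation per block-local axis: the two
#' in-plane axes (panel X and Z) use `smearSigmaXY`, the depth axis
#' (panel normal, Y) uses `smearSigmaDOI`. Coordinates falling outside
#' the block are clamped per axis to the block surface so that no
#' non-physical LOR endpoints are produced.
#'
#' @param points data.frame with true positions `x`, `y`, `z` (mm) and
#'   crystal address columns `det`, `ia`, `ib`
#' @param scanner a [FlatPanelScanner-class]
#' @return matrix with columns `x`, `y`, `z` of positioned points
#' @export
smearMonolithic <- function(points, scanner) {
  stopifnot(is(scanner, "FlatPanelScanner"))
  n <- nrow(points)
  hx <- scanner@panelWidth / 2
  hg <- scanner@panelSeparation / 2
  z0 <- -scanner@panelAxial / 2
  bx <- scanner@blockSize[1]; bz <- scanner@blockSize[2]
  dep <- scanner@blockSize[3]
  xlo <- -hx + points$ia * bx
  zlo <- z0 + points$ib * scanner@blockPitchZ
  ylo <- ifelse(points$det == 0, hg, -hg - dep)
  x <- points$x + rnorm(n) * scanner@smearSigmaXY
  z <- points$z + rnorm(n) * scanner@smearSigmaXY
  y <- points$y + rnorm(n) * scanner@smearSigmaDOI
  cbind(x = pmin(pmax(x, xlo), xlo + bx),
        y = pmin(pmax(y, ylo), ylo + dep),
        z = pmin(pmax(z, zlo), zlo + bz))
}

#' Discretize interaction points of pixelated detectors
#'
#' The depth coordinate is moved to the crystal's mid-depth plane and
#' the transverse coordinates are drawn uniformly over the crystal face
#' (tangential x axial).
#'
#' @param points data.frame with crystal address columns `ia`
#'   (tangential) and `ib` (ring)
#' @param scanner a [CylindricalScanner-class]
#' @return matrix with columns `x`, `y`, `z` of positioned points
#' @export
discretizePixelated <- function(points, scanner) {
  stopifnot(is(scanner, "CylindricalScanner"))
  n <- nrow(points)
  rMid <- scanner@ringDiameter / 2 + scanner@crystalSize[3] / 2
  dPhi <- 2 * pi / scanner@crystalsPerRing
  pitchZ <- scanner@axialExtent / scanner@nRings
  halfArc <- scanner@crystalSize[1] / 2 / rMid   # half tangential size, rad
  phi <- (points$ia + 0.5) * dPhi + (runif(n) - 0.5) * 2 * halfArc
  zc <- -scanner@axialExtent / 2 + (points$ib + 0.5) * pitchZ
  z <- zc + (runif(n) - 0.5) * scanner@crystalSize[2]
  cbind(x = rMid * cos(phi), y = rMid * sin(phi), z = z)
}

#' Position both endpoints of accepted coincidences
#'
#' Applies the detector-appropriate response model
#' ([smearMonolithic()] or [discretizePixelated()]) to the true
#' interaction points of both singles, after classification, so the
#' ground-truth tags stay pristine.
#'
#' @param coincidences coincidence data.frame
#' @param scanner a [ScannerGeometry-class]
#' @return the input with positioned endpoint columns `px1`..`pz2`
#' @export
positionEndpoints <- function(coincidences, scanner) {
  fun <- if (is(scanner, "FlatPanelScanner")) smearMonolithic else
    discretizePixelated
  e1 <- fun(data.frame(x = coincidences$x1, y = coincidences$y1,
                       z = coincidences$z1, det = coincidences$det1,
                       ia = coincidences$ia1, ib = coincidences$ib1), scanner)
  e2 <- fun(data.frame(x = coincidences$x2, y = coincidences$y2,
                       z = coincidences$z2, det = coincidences$det2,
                       ia = coincidences$ia2, ib = coincidences$ib2), scanner)
  coincidences$px1 <- e1[, 1]; coincidences$py1 <- e1[, 2]
  coincidences$pz1 <- e1[, 3]
  coincidences$px2 <- e2[, 1]; coincidences$py2 <- e2[, 2]
  coincidences$pz2 <- e2[, 3]
  coincidences
}
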