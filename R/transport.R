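# Photon transport: decay -> annihilation pair -> phantom -> crystal.
# The C++ kernels draw from R's RNG, so set.seed() makes runs reproducible.

#' Emit back-to-back annihilation photon pairs
#'
#' Each decay produces two 511 keV photons: the first direction is
#' isotropic, the second exactly antiparallel (an optional acollinearity
#' blur can deflect it by a half-Gaussian angle).
#'
#' @param decays data.frame from [sampleDecays()]
#' @param acollinearityFwhmMrad acollinearity FWHM in mrad (0 = exactly
#'   back-to-back, the default)
#' @return photon data.frame (two rows per decay): position (mm),
#'   direction, `energy` keV, `eventId`, `scattered`, `alive`, `path`
#'   (mm travelled), `time0` (decay time, s)
#' @export
emitAnnihilationPairs <- function(decays, acollinearityFwhmMrad = 0) {
  m <- cpp_emit_pairs(as.matrix(decays[, c("x", "y", "z", "time", "eventId")]),
                      acollinearityFwhmMrad)
  .photonFrame(m)
}

.photonFrame <- function(m) {
  data.frame(x = m[, 1], y = m[, 2], z = m[, 3], dx = m[, 4], dy = m[, 5],
             dz = m[, 6], energy = m[, 7], eventId = m[, 8],
             scattered = m[, 9] != 0, alive = m[, 10] != 0, path = m[, 11],
             time0 = m[, 12])
}

.photonMatrix <- function(ph) {
  cbind(ph$x, ph$y, ph$z, ph$dx, ph$dy, ph$dz, ph$energy, ph$eventId,
        as.numeric(ph$scattered), as.numeric(ph$alive), ph$path, ph$time0)
}

#' Transport photons through the phantom
#'
#' Free paths are sampled from the exponential attenuation law with the
#' local material's energy-dependent coefficient; at each interaction the
#' photon undergoes Compton scattering (Klein-Nishina angular sampling,
#' energy loss, `scattered` flag set) or photoelectric absorption.
#' Photons falling below `cutoffKeV` are terminated: they can no longer
#' pass any energy window.
#'
#' @param photons photon data.frame from [emitAnnihilationPairs()]
#' @param scene a [PhantomScene-class]
#' @param cutoffKeV tracking cutoff, keV
#' @return updated photon data.frame (positions advanced to the scene
#'   exit point for surviving photons)
#' @export
propagateThroughPhantom <- function(photons, scene, cutoffKeV = 300) {
  m <- .materialsCpp()
  out <- cpp_propagate_phantom(.photonMatrix(photons), .sceneCpp(scene),
                               m$muInc, m$muPe, m$muPeExp, m$background,
                               cutoffKeV)
  .photonFrame(out)
}

#' Detect photons in the scintillator crystals
#'
#' Each surviving photon is intersected with the crystal volumes along
#' its flight direction; the interaction depth is sampled from the
#' truncated exponential with the crystal material's attenuation
#' coefficient. Photoelectric interactions deposit the full remaining
#' energy; Compton interactions deposit the transfer and the scattered
#' photon is followed further through the crystal volumes, up to three
#' interactions in total (the residual escapes). All deposits of one
#' photon are merged into a single event at their energy-weighted
#' position, mirroring the centroid positioning of monolithic readout;
#' the crystal address is that of the largest deposit.
#'
#' @param photons photon data.frame (after [propagateThroughPhantom()])
#' @param scanner a [ScannerGeometry-class]
#' @return singles data.frame: `eventId`, crystal address (`det`, `ia`,
#'   `ib`), energy-weighted interaction point `x`, `y`, `z` (mm),
#'   deposited energy `edep` (keV), detection `time` (s, decay time plus
#'   time of flight to the first interaction) and the ground-truth
#'   `scatter` flag (Compton interaction in the phantom)
#' @export
detectInCrystal <- function(photons, scanner) {
  m <- .materialsCpp()
  cpp_detect_crystal(.photonMatrix(photons), .scannerCpp(scanner),
                     m$muInc, m$muPe, m$muPeExp)
}

#' Simulate detected singles for a scene
#'
#' Fused chain: decay sampling (unless `decays` is given), pair
#' emission, phantom transport and crystal detection.
#'
#' @inheritParams propagateThroughPhantom
#' @inheritParams detectInCrystal
#' @param nDecays,durationS acquisition size, see [sampleDecays()]
#' @param decays optional pre-sampled decay data.frame
#' @param acollinearityFwhmMrad see [emitAnnihilationPairs()]
#' @return list with `singles` (see [detectInCrystal()]), `nDecays`,
#'   `duration` (s)
#' @export
simulateSingles <- function(scene, scanner, nDecays = NULL, durationS = NULL,
                            decays = NULL, cutoffKeV = 300,
                            acollinearityFwhmMrad = 0) {
  if (is.null(decays))
    decays <- sampleDecays(scene, nDecays = nDecays, durationS = durationS)
  m <- .materialsCpp()
  s <- cpp_simulate_singles(
    as.matrix(decays[, c("x", "y", "z", "time", "eventId")]),
    .sceneCpp(scene), .scannerCpp(scanner), m$muInc, m$muPe, m$muPeExp,
    m$background, cutoffKeV, acollinearityFwhmMrad)
  list(singles = s, nDecays = nrow(decays),
       duration = attr(decays, "duration"))
}

#' Apply the energy model: resolution blur and window
#'
#' The deposited energy is blurred with a Gaussian whose sigma is
#' `resolution * 511 / 2.3548 * sqrt(E/511)` and the single is kept only
#' if the blurred energy falls inside the scanner's energy window.
#'
#' @param singles singles data.frame
#' @param scanner a [ScannerGeometry-class] (supplies resolution and
#'   window), or a list with elements `resolution` and `window`
#' @return filtered singles with an `eblur` column (keV)
#' @export
applyEnergyModel <- function(singles, scanner) {
  if (is(scanner, "ScannerGeometry")) {
    res <- scanner@energyResolution
    win <- scanner@energyWindow
  } else {
    res <- scanner$resolution
    win <- scanner$window
  }
  if (nrow(singles) == 0) {
    singles$eblur <- numeric(0)
    return(singles)
  }
  sigma <- res * 511 / 2.354820045 * sqrt(singles$edep / 511)
  singles$eblur <- singles$edep + rnorm(nrow(singles)) * sigma
  singles[singles$eblur >= win[1] & singles$eblur <= win[2], , drop = FALSE]
}

#' Apply per-block dead time
#'
#' Non-paralyzable by default: a single arriving within tau of the last
#' accepted single in the same detector block is discarded. For the
#' flat-panel scanner the block is the monolithic detector; for the
#' cylindrical scanner singles are grouped into emulated 5 x 5 cm
#' detector regions.
#'
#' @param singles time-sorted singles data.frame
#' @param scanner a [ScannerGeometry-class]
#' @param kind `"nonparalyzable"` or `"paralyzable"`
#' @param tauNs override the scanner's dead time, ns
#' @return filtered singles
#' @export
applyDeadTime <- function(singles, scanner,
                          kind = c("nonparalyzable", "paralyzable"),
                          tauNs = NULL) {
  kind <- match.arg(kind)
  tau <- if (is.null(tauNs)) scanner@deadTimeNs else tauNs
  if (tau == 0 || nrow(singles) == 0) return(singles)
  keep <- cpp_dead_time(singles$time, deadTimeBlock(singles, scanner),
                        tau * 1e-9, kind == "paralyzable")
  singles[keep, , drop = FALSE]
}

#' @rdname applyDeadTime
#' @return for `deadTimeBlock`, the integer block/region id of each
#'   single
#' @export
deadTimeBlock <- function(singles, scanner) {
  if (is(scanner, "FlatPanelScanner")) {
    as.integer(singles$det * scanner@blocksX * scanner@blocksZ +
               singles$ia * scanner@blocksZ + singles$ib)
  } else {
    pitchT <- pi * scanner@ringDiameter / scanner@crystalsPerRing
    pitchZ <- scanner@axialExtent / scanner@nRings
    tPer <- max(1L, as.integer(round(50 / pitchT)))
    zPer <- max(1L, as.integer(round(50 / pitchZ)))
    as.integer((singles$ia %/% tPer) * 10000L + singles$ib %/% zPer)
  }
}
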