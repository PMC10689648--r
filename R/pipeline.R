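# End-to-end study drivers reproducing the standard performance
# measurements: each one runs scene -> transport -> digitizer ->
# coincidences (-> reconstruction) -> metric.

#' Simulate classified coincidences for a scene
#'
#' Full acquisition chain: singles simulation, energy blur + window,
#' per-block dead time, timing blur, coincidence sorting, ground-truth
#' classification and (cylindrical) maximum-ring-difference cut.
#'
#' @inheritParams simulateSingles
#' @param energyBlur,deadTime,timingBlur chain stage toggles
#' @param decays optional pre-sampled decays (see [sampleDecays()])
#' @param mrd maximum ring difference override (cylindrical; `NA` for no
#'   cut)
#' @param policy optional [coincidencePolicy()]
#' @return list: `coincidences` (classified), `nDecays`, `duration` (s),
#'   `nSingles` (after windowing and dead time)
#' @export
simulateCoincidences <- function(scene, scanner, nDecays = NULL,
                                 durationS = NULL, energyBlur = TRUE,
                                 deadTime = TRUE, timingBlur = TRUE,
                                 mrd = NULL, policy = NULL,
                                 cutoffKeV = 300, decays = NULL) {
  sim <- simulateSingles(scene, scanner, nDecays = nDecays,
                         durationS = durationS, decays = decays,
                         cutoffKeV = cutoffKeV)
  s <- sim$singles
  s <- if (energyBlur) applyEnergyModel(s, scanner) else
    applyEnergyModel(s, list(resolution = 0, window = scanner@energyWindow))
  s <- s[order(s$time), , drop = FALSE]
  if (deadTime) s <- applyDeadTime(s, scanner)
  if (timingBlur) {
    s <- blurTimestamps(s, scanner)
    s <- s[order(s$time), , drop = FALSE]
  }
  pol <- if (is.null(policy)) coincidencePolicy(scanner, mrd = mrd) else policy
  co <- sortCoincidences(s, scanner, pol)
  co <- classifyCoincidences(co)
  co <- applyMRD(co, pol$mrd)
  list(coincidences = co, nDecays = sim$nDecays, duration = sim$duration,
       nSingles = nrow(s))
}

#' Measure system sensitivity with the sleeved line source
#'
#' Simulates the NU-2 sensitivity acquisition (1 MBq sleeved line
#' source) and reports total sensitivity in cps/kBq with the axial
#' profile. All accepted coincidences are counted.
#'
#' @param scanner a [ScannerGeometry-class]
#' @param lineLengthCm 70 or 106
#' @param offsetCm numeric(2) transaxial offset of the source, cm
#' @param nDecays decays to simulate
#' @param mrd maximum ring difference (cylindrical); `NA` = no cut
#' @return list from [sensitivityMetric()] plus `nDecays`
#' @export
measureSensitivity <- function(scanner, lineLengthCm = 70, offsetCm = c(0, 0),
                               nDecays = 1e6, mrd = NA) {
  scene <- makeSensitivityScene(lineLengthCm, offsetCm = offsetCm)
  co <- simulateCoincidences(scene, scanner, nDecays = nDecays, mrd = mrd)
  out <- sensitivityMetric(co$coincidences, co$nDecays,
                           afovMm = axialFOV(scanner) * 10)
  out$nDecays <- co$nDecays
  out
}

#' Measure the scatter fraction
#'
#' Simulates the scatter phantom at low activity, classifies events by
#' the ground-truth tags, applies single-slice rebinning with the
#' central axial window and transaxial mask, and reports
#' `100 * S / (S + T)`.
#'
#' @inheritParams measureSensitivity
#' @param offsetAxis `"X"` or `"Y"` line offset
#' @param activityKBqMl cylinder-volume-equivalent concentration
#' @return list: `scatterFraction` (percent), `counts` (by class after
#'   rebinning), `randomsFraction`, `nDecays`
#' @export
measureScatterFraction <- function(scanner, offsetAxis = "X",
                                   activityKBqMl = 0.045, nDecays = 2e6,
                                   mrd = NULL) {
  scene <- makeScatterScene(offsetAxis, activityKBqMl = activityKBqMl)
  co <- simulateCoincidences(scene, scanner, nDecays = nDecays, mrd = mrd)
  filt <- ssrbFilter(positionEndpoints(co$coincidences, scanner))
  counts <- table(filt$class)
  list(scatterFraction = scatterFraction(filt),
       counts = counts,
       randomsFraction = if (counts[["true"]] > 0)
         counts[["random"]] / counts[["true"]] else NA_real_,
       nDecays = co$nDecays)
}

#' Measure reconstructed spatial resolution at a point
#'
#' Simulates a point source, reconstructs true coincidences only with
#' TOF list-mode MLEM (0.5 mm voxels, 10 iterations by default) on a
#' local grid centred at the source, and measures FWHM/FWTM along each
#' axis by linear interpolation through the image maximum.
#'
#' @inheritParams measureSensitivity
#' @param positionCm numeric(3) source position, cm
#' @param warmBackground simulate the surrounding warm cylinder?
#' @param voxelMm reconstruction voxel size
#' @param gridDim voxels per axis of the local grid
#' @param iterations MLEM iterations
#' @param nDirsSens emission directions per sensitivity control point
#' @param ctrPs timing resolution override (ps)
#' @param replicates number of independent acquisitions; the
#'   reconstructions are averaged before the widths are measured, which
#'   suppresses the speckle noise of a single short acquisition without
#'   changing the expected point spread
#' @return list: `fwhm`, `fwtm` (named x/y/z, mm), `image`
#'   ([PetImage-class]), `nTrues`
#' @export
measureResolution <- function(scanner, positionCm, nDecays = 1.5e6,
                              warmBackground = FALSE, voxelMm = 0.5,
                              gridDim = 64, iterations = 10,
                              nDirsSens = 20000, ctrPs = NULL, mrd = NA,
                              replicates = 1) {
  scene <- makePointSourceScene(positionCm, warmBackground = warmBackground,
                                scanner = scanner)
  grid <- makeGrid(positionCm * 10, voxelMm, gridDim)
  sens <- computeSensitivityImage(scanner, grid,
                                  scene = if (warmBackground) scene else NULL,
                                  nDirs = nDirsSens)
  tofSig <- tofSigmaFromCtr(if (is.null(ctrPs)) scanner@ctrPs else ctrPs)
  acc <- 0
  nTrues <- 0
  for (r in seq_len(replicates)) {
    co <- simulateCoincidences(scene, scanner, nDecays = nDecays,
                               deadTime = FALSE, mrd = mrd)
    co$coincidences <- positionEndpoints(co$coincidences, scanner)
    lm <- makeListmode(co$coincidences, classes = "true")
    if (nrow(lm) < 100) stop("too few true coincidences for a reconstruction")
    img <- mlemReconstruct(lm, grid, sens, iterations = iterations,
                           tofSigmaMm = tofSig)
    acc <- acc + imageData(img) / replicates
    nTrues <- nTrues + nrow(lm)
  }
  img <- newPetImage(acc, grid)
  # peak search restricted to the neighbourhood of the nominal source
  # position (the NEMA response function is formed about the source peak)
  pk <- .localPeak(img, positionCm * 10, radiusMm = 3)
  wx <- profileWidth(img, 1, center = pk, method = "sum")
  wy <- profileWidth(img, 2, center = pk, method = "sum")
  wz <- profileWidth(img, 3, center = pk, method = "sum")
  list(fwhm = c(x = unname(wx["fwhm"]), y = unname(wy["fwhm"]),
                z = unname(wz["fwhm"])),
       fwtm = c(x = unname(wx["fwtm"]), y = unname(wy["fwtm"]),
                z = unname(wz["fwtm"])),
       image = img, nTrues = nTrues)
}

#' Measure image quality with the IQ phantom
#'
#' Simulates the image-quality phantom, reconstructs true coincidences
#' with sensitivity and ground-truth attenuation correction (2 mm
#' voxels) and evaluates the contrast recovery coefficients.
#'
#' @inheritParams measureResolution
#' @param extraLesions,axialPosition see [makeIQScene()]
#' @param marginMm grid margin around the phantom
#' @return list: `crc` (see [crc()]), `image`, `nTrues`
#' @export
measureImageQuality <- function(scanner, extraLesions = FALSE,
                                axialPosition = "center", nDecays = 2e6,
                                voxelMm = 2, iterations = 10,
                                nDirsSens = 20000, ctrPs = NULL,
                                marginMm = 20, mrd = NULL) {
  scene <- makeIQScene(extraLesions = extraLesions,
                       axialPosition = axialPosition)
  p <- scene@primitives
  body <- which(p$shape == "ellcyl")[1]
  ctr <- c(p$cx[body], p$cy[body], p$cz[body])
  half <- c(p$p1[body], p$p2[body], p$p3[body]) + marginMm
  dims <- as.integer(ceiling(2 * half / voxelMm))
  grid <- makeGrid(ctr, voxelMm, dims)
  co <- simulateCoincidences(scene, scanner, nDecays = nDecays, mrd = mrd)
  co$coincidences <- positionEndpoints(co$coincidences, scanner)
  # attenuation enters through the sensitivity image; the per-event
  # attenuation factor then cancels inside each event's update term
  lm <- makeListmode(co$coincidences, classes = "true")
  sens <- computeSensitivityImage(scanner, grid, scene = scene,
                                  nDirs = nDirsSens)
  tofSig <- tofSigmaFromCtr(if (is.null(ctrPs)) scanner@ctrPs else ctrPs)
  img <- mlemReconstruct(lm, grid, sens, iterations = iterations,
                         tofSigmaMm = tofSig)
  list(crc = crc(img, scene), image = img, nTrues = nrow(lm))
}

# image maximum within a radius of a nominal position (mm); returns the
# peak voxel centre coordinates
.localPeak <- function(image, nominalMm, radiusMm = 3) {
  g <- image@grid
  a <- image@data
  ctr <- lapply(1:3, function(ax)
    g@origin[ax] + (seq_len(g@dims[ax]) - 0.5) * g@spacing[ax])
  sel <- lapply(1:3, function(ax)
    which(abs(ctr[[ax]] - nominalMm[ax]) <= radiusMm))
  sub <- a[sel[[1]], sel[[2]], sel[[3]], drop = FALSE]
  i <- arrayInd(which.max(sub), dim(sub))[1, ]
  c(ctr[[1]][sel[[1]][i[1]]], ctr[[2]][sel[[2]][i[2]]],
    ctr[[3]][sel[[3]][i[3]]])
}
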