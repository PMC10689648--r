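#' Build the flat-panel scanner geometry
#'
#' Constructs the two-panel walk-through geometry: two mirror-image
#' vertical panels of monolithic scintillator blocks facing each other
#' across the patient gap. Blocks tile the panel contiguously along X;
#' along the scanner axis (Z) they are placed with a uniform pitch
#' chosen so that the outer block edges span the full stated axial FOV,
#' which with the defaults (20 blocks of 50 mm over 106 cm) leaves a
#' ~3.2 mm inter-block gap.
#'
#' @param config named list overriding the defaults. Keys (units in the
#'   names): `panel_separation_cm` (50), `panel_width_cm` (70),
#'   `panel_axial_cm` (106), `blocks_x` (14), `blocks_z` (20),
#'   `block_mm` (c(50, 50, 16): x, z, depth), `crystal_material`
#'   ("BGO"), `energy_resolution` (0.15), `energy_window_kev`
#'   (c(434, 645)), `ctw_ns` (5), `ctr_ps` (327), `dead_time_ns` (370),
#'   `smear_sigma_xy_mm` (0.55), `smear_sigma_doi_mm` (0.85).
#' @return a [FlatPanelScanner-class]
#' @examples
#' wt <- buildFlatPanelScanner()
#' nCrystals(wt)      # 560 monolithic blocks
#' crystalVolume(wt)  # 0.0224 m^3
#' @export
buildFlatPanelScanner <- function(config = list()) {
  def <- list(
    panel_separation_cm = 50, panel_width_cm = 70, panel_axial_cm = 106,
    blocks_x = 14L, blocks_z = 20L, block_mm = c(50, 50, 16),
    crystal_material = "BGO", energy_resolution = 0.15,
    energy_window_kev = c(434, 645), ctw_ns = 5, ctr_ps = 327,
    dead_time_ns = 370, smear_sigma_xy_mm = 0.55, smear_sigma_doi_mm = 0.85)
  unknown <- setdiff(names(config), names(def))
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg <- modifyList(def, config)
  if (any(unlist(cfg[c("panel_separation_cm", "panel_width_cm",
                       "panel_axial_cm", "block_mm")]) <= 0))
    stop("dimensions must be positive")
  nbz <- as.integer(cfg$blocks_z)
  axial <- cfg$panel_axial_cm * 10
  pitch <- if (nbz > 1L) (axial - cfg$block_mm[2]) / (nbz - 1L) else cfg$block_mm[2]
  new("FlatPanelScanner",
      panelSeparation = cfg$panel_separation_cm * 10,
      panelWidth = cfg$panel_width_cm * 10,
      panelAxial = axial,
      blocksX = as.integer(cfg$blocks_x), blocksZ = nbz,
      blockSize = as.numeric(cfg$block_mm),
      blockPitchZ = pitch,
      smearSigmaXY = cfg$smear_sigma_xy_mm,
      smearSigmaDOI = cfg$smear_sigma_doi_mm,
      crystalMaterial = cfg$crystal_material,
      energyResolution = cfg$energy_resolution,
      energyWindow = as.numeric(cfg$energy_window_kev),
      ctwNs = cfg$ctw_ns, ctrPs = cfg$ctr_ps, deadTimeNs = cfg$dead_time_ns)
}

#' Build the cylindrical scanner geometry
#'
#' Idealized gapless ring scanner with pixelated crystals. The number of
#' crystals per ring is `floor(pi * diameter / tangential pitch)` and the
#' axial pitch is `axial extent / n_rings`; by default the tangential
#' pitch equals the axial pitch.
#'
#' @param config named list overriding the defaults: `ring_diameter_cm`
#'   (82), `crystal_mm` (c(3.2, 3.2, 20): tangential, axial, depth),
#'   `n_rings` (322), `axial_cm` (106), `crystal_material` ("LSO"),
#'   `energy_resolution` (0.11), `energy_window_kev` (c(455, 645)),
#'   `ctw_ns` (4.7), `ctr_ps` (228), `dead_time_ns` (320), `mrd` (85),
#'   `tangential_pitch_mm` (defaults to the axial pitch),
#'   `min_tang_sep` (1/6 of the ring).
#' @return a [CylindricalScanner-class]
#' @examples
#' qd <- buildCylindricalScanner()
#' lorExtremes(qd)
#' @export
buildCylindricalScanner <- function(config = list()) {
  def <- list(
    ring_diameter_cm = 82, crystal_mm = c(3.2, 3.2, 20), n_rings = 322L,
    axial_cm = 106, crystal_material = "LSO", energy_resolution = 0.11,
    energy_window_kev = c(455, 645), ctw_ns = 4.7, ctr_ps = 228,
    dead_time_ns = 320, mrd = 85L, tangential_pitch_mm = NULL,
    min_tang_sep = NULL)
  unknown <- setdiff(names(config), names(def))
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg <- modifyList(def, config)
  if (cfg$ring_diameter_cm <= 0 || cfg$axial_cm <= 0 || any(cfg$crystal_mm <= 0))
    stop("dimensions must be positive")
  nRings <- as.integer(cfg$n_rings)
  axial <- cfg$axial_cm * 10
  pitchZ <- axial / nRings
  pitchT <- if (is.null(cfg$tangential_pitch_mm)) pitchZ else cfg$tangential_pitch_mm
  d <- cfg$ring_diameter_cm * 10
  if (pitchT > pi * d / 3) stop("tangential pitch larger than circumference/3")
  nTangF <- floor(pi * d / pitchT)
  if (!is.finite(nTangF) || nTangF > .Machine$integer.max)
    stop("tangential pitch implies a non-representable crystal count")
  nTang <- as.integer(nTangF)
  minSep <- if (is.null(cfg$min_tang_sep)) as.integer(round(nTang / 6)) else
    as.integer(cfg$min_tang_sep)
  new("CylindricalScanner",
      ringDiameter = d,
      crystalSize = as.numeric(cfg$crystal_mm),
      nRings = nRings, crystalsPerRing = nTang,
      axialExtent = axial,
      mrd = as.integer(cfg$mrd), minTangSep = minSep,
      crystalMaterial = cfg$crystal_material,
      energyResolution = cfg$energy_resolution,
      energyWindow = as.numeric(cfg$energy_window_kev),
      ctwNs = cfg$ctw_ns, ctrPs = cfg$ctr_ps, deadTimeNs = cfg$dead_time_ns)
}

#' Load a shipped scanner preset
#'
#' Reads a scanner configuration from YAML. Two presets ship with the
#' package: `"wt_pet"` (flat-panel walk-through geometry) and
#' `"quadra_like"` (cylindrical total-body geometry).
#'
#' @param name preset name or path to a YAML file
#' @return a [ScannerGeometry-class]
#' @export
loadScannerPreset <- function(name) {
  path <- if (file.exists(name)) name else
    system.file("extdata", paste0(name, ".yaml"), package = "wtpet")
  if (!nzchar(path) || !file.exists(path)) stop("unknown scanner preset: ", name)
  cfg <- yaml::read_yaml(path)
  type <- cfg$type
  cfg$type <- NULL
  switch(type,
         flatpanel = buildFlatPanelScanner(cfg),
         cylindrical = buildCylindricalScanner(cfg),
         stop("unknown scanner type in preset: ", type))
}

# ---- accessors --------------------------------------------------------------

#' Scanner summary quantities
#'
#' `axialFOV` returns the axial field of view (cm); `nCrystals` the
#' number of detection elements (monolithic blocks or crystal pixels);
#' `crystalVolume` the total scintillator volume (m^3); `sipmArea` the
#' total photodetector coupling-face area (m^2); `lorExtremes` the
#' shortest and longest line of response through the isocenter (cm),
#' measured between crystal front faces.
#'
#' @param scanner a [ScannerGeometry-class]
#' @return see details per function
#' @examples
#' lorExtremes(buildFlatPanelScanner())
#' @export
axialFOV <- function(scanner) {
  if (is(scanner, "FlatPanelScanner")) scanner@panelAxial / 10
  else scanner@axialExtent / 10
}

#' @rdname axialFOV
#' @export
nCrystals <- function(scanner) {
  if (is(scanner, "FlatPanelScanner")) 2L * scanner@blocksX * scanner@blocksZ
  else scanner@nRings * scanner@crystalsPerRing
}

#' @rdname axialFOV
#' @export
crystalVolume <- function(scanner) {
  if (is(scanner, "FlatPanelScanner"))
    nCrystals(scanner) * prod(scanner@blockSize) * 1e-9
  else nCrystals(scanner) * prod(scanner@crystalSize) * 1e-9
}

#' @rdname axialFOV
#' @export
sipmArea <- function(scanner) {
  if (is(scanner, "FlatPanelScanner"))
    nCrystals(scanner) * scanner@blockSize[1] * scanner@blockSize[2] * 1e-6
  else nCrystals(scanner) * scanner@crystalSize[1] * scanner@crystalSize[2] * 1e-6
}

#' @rdname axialFOV
#' @export
lorExtremes <- function(scanner) {
  if (is(scanner, "FlatPanelScanner")) {
    shortest <- scanner@panelSeparation / 10
    longest <- sqrt(scanner@panelWidth^2 + scanner@panelSeparation^2 +
                    scanner@panelAxial^2) / 10
  } else {
    shortest <- scanner@ringDiameter / 10
    longest <- sqrt(scanner@ringDiameter^2 + scanner@axialExtent^2) / 10
  }
  c(shortest = shortest, longest = longest)
}

# ---- crystal addressing -----------------------------------------------------

#' Locate the crystal containing a point
#'
#' Returns the [CrystalAddress-class] of the crystal volume containing a
#' global position (mm), or `NULL` when the point is outside every
#' crystal. Boundaries are half-open (`[low, high)` per axis), so a
#' point on a shared block face belongs to the lower-index block.
#'
#' @param scanner a [ScannerGeometry-class]
#' @param point numeric(3), global position in mm
#' @return [CrystalAddress-class] or `NULL`
#' @export
locateCrystal <- function(scanner, point) {
  x <- point[1]; y <- point[2]; z <- point[3]
  if (is(scanner, "FlatPanelScanner")) {
    hg <- scanner@panelSeparation / 2
    dep <- scanner@blockSize[3]
    det <- if (y >= hg && y < hg + dep) 0L
           else if (y >= -hg - dep && y < -hg) 1L else return(NULL)
    hx <- scanner@panelWidth / 2
    if (x < -hx || x >= hx) return(NULL)
    ia <- as.integer(floor((x + hx) / scanner@blockSize[1]))
    if (ia >= scanner@blocksX) return(NULL)
    z0 <- -scanner@panelAxial / 2
    w <- z - z0
    if (w < 0) return(NULL)
    ib <- as.integer(floor(w / scanner@blockPitchZ))
    if (ib >= scanner@blocksZ) return(NULL)
    if (w - ib * scanner@blockPitchZ >= scanner@blockSize[2]) return(NULL)
    new("CrystalAddress", det = det, ia = ia, ib = ib)
  } else {
    rIn <- scanner@ringDiameter / 2
    rOut <- rIn + scanner@crystalSize[3]
    rho <- sqrt(x^2 + y^2)
    if (rho < rIn || rho >= rOut) return(NULL)
    zh <- scanner@axialExtent / 2
    if (z < -zh || z >= zh) return(NULL)
    pitchZ <- scanner@axialExtent / scanner@nRings
    ib <- as.integer(floor((z + zh) / pitchZ))
    phi <- atan2(y, x)
    if (phi < 0) phi <- phi + 2 * pi
    ia <- as.integer(floor(phi / (2 * pi / scanner@crystalsPerRing)))
    if (ia >= scanner@crystalsPerRing) ia <- scanner@crystalsPerRing - 1L
    new("CrystalAddress", det = 0L, ia = ia, ib = ib)
  }
}

#' @rdname locateCrystal
#' @param address a [CrystalAddress-class]
#' @return for `crystalCenter`, the crystal centre, numeric(3) mm
#' @export
crystalCenter <- function(scanner, address) {
  ia <- address@ia; ib <- address@ib
  if (is(scanner, "FlatPanelScanner")) {
    hx <- scanner@panelWidth / 2
    hg <- scanner@panelSeparation / 2
    z0 <- -scanner@panelAxial / 2
    x <- -hx + (ia + 0.5) * scanner@blockSize[1]
    y <- (hg + scanner@blockSize[3] / 2) * if (address@det == 0L) 1 else -1
    z <- z0 + ib * scanner@blockPitchZ + scanner@blockSize[2] / 2
    c(x, y, z)
  } else {
    rMid <- scanner@ringDiameter / 2 + scanner@crystalSize[3] / 2
    dPhi <- 2 * pi / scanner@crystalsPerRing
    phi <- (ia + 0.5) * dPhi
    pitchZ <- scanner@axialExtent / scanner@nRings
    c(rMid * cos(phi), rMid * sin(phi),
      -scanner@axialExtent / 2 + (ib + 0.5) * pitchZ)
  }
}

# internal: scanner description for the C++ kernels
.scannerCpp <- function(scanner) {
  mat <- .materialIndex(scanner@crystalMaterial)
  if (is(scanner, "FlatPanelScanner")) {
    list(type = 1L, mat = mat,
         halfGap = scanner@panelSeparation / 2,
         depth = scanner@blockSize[3],
         blockX = scanner@blockSize[1], blockZ = scanner@blockSize[2],
         pitchZ = scanner@blockPitchZ, z0 = -scanner@panelAxial / 2,
         halfX = scanner@panelWidth / 2,
         nbx = scanner@blocksX, nbz = scanner@blocksZ)
  } else {
    list(type = 2L, mat = mat,
         rIn = scanner@ringDiameter / 2,
         rOut = scanner@ringDiameter / 2 + scanner@crystalSize[3],
         zHalf = scanner@axialExtent / 2,
         pitchZ = scanner@axialExtent / scanner@nRings,
         nRings = scanner@nRings, nTang = scanner@crystalsPerRing)
  }
}

setMethod("show", "FlatPanelScanner", function(object) {
  cat("FlatPanelScanner:", object@crystalMaterial, "monolithic blocks\n")
  cat(sprintf("  panels: %g x %g cm, separation %g cm, %d x %d blocks of %g x %g x %g mm\n",
              object@panelWidth / 10, object@panelAxial / 10,
              object@panelSeparation / 10, object@blocksX, object@blocksZ,
              object@blockSize[1], object@blockSize[2], object@blockSize[3]))
  cat(sprintf("  energy: %.0f%% FWHM, window [%g, %g] keV; CTR %g ps; CTW %g ns; dead time %g ns\n",
              100 * object@energyResolution, object@energyWindow[1],
              object@energyWindow[2], object@ctrPs, object@ctwNs,
              object@deadTimeNs))
  cat(sprintf("  positioning: sigma_xy %g mm, sigma_DOI %g mm\n",
              object@smearSigmaXY, object@smearSigmaDOI))
})

setMethod("show", "CylindricalScanner", function(object) {
  cat("CylindricalScanner:", object@crystalMaterial, "pixelated crystals\n")
  cat(sprintf("  ring diameter %g cm, axial FOV %g cm, %d rings x %d crystals of %g x %g x %g mm\n",
              object@ringDiameter / 10, object@axialExtent / 10,
              object@nRings, object@crystalsPerRing,
              object@crystalSize[1], object@crystalSize[2], object@crystalSize[3]))
  cat(sprintf("  energy: %.0f%% FWHM, window [%g, %g] keV; CTR %g ps; CTW %g ns; dead time %g ns; MRD %d\n",
              100 * object@energyResolution, object@energyWindow[1],
              object@energyWindow[2], object@ctrPs, object@ctwNs,
              object@deadTimeNs, object@mrd))
})

setMethod("show", "CrystalAddress", function(object) {
  cat(sprintf("CrystalAddress(det = %d, ia = %d, ib = %d)\n",
              object@det, object@ia, object@ib))
})
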