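#' Scanner geometry classes
#'
#' `ScannerGeometry` is the virtual parent of the two supported detector
#' layouts. `FlatPanelScanner` describes two mirror-image flat panels of
#' monolithic scintillator blocks facing each other across the patient
#' gap (panel normal along Y, scanner axis along Z, origin at the
#' isocenter). `CylindricalScanner` describes an idealized gapless ring
#' of pixelated crystals. All lengths are stored in millimetres;
#' constructor configuration uses centimetres for scanner-scale
#' dimensions (see [buildFlatPanelScanner()]).
#'
#' Digitizer parameters shared by both layouts live on the virtual
#' class: energy resolution (FWHM fraction at 511 keV), energy window
#' (keV), coincidence time window (ns), coincidence time resolution
#' (ps FWHM) and per-block dead time (ns).
#'
#' @slot crystalMaterial scintillator id, one of `"BGO"`, `"LSO"`
#' @slot energyResolution FWHM fraction at 511 keV
#' @slot energyWindow numeric(2), keV
#' @slot ctwNs coincidence time window, ns
#' @slot ctrPs coincidence time resolution FWHM, ps
#' @slot deadTimeNs per-block dead time, ns
#' @name ScannerGeometry-class
#' @aliases ScannerGeometry
#' @exportClass ScannerGeometry
setClass("ScannerGeometry", representation("VIRTUAL",
  crystalMaterial = "character",
  energyResolution = "numeric",
  energyWindow = "numeric",
  ctwNs = "numeric",
  ctrPs = "numeric",
  deadTimeNs = "numeric"))

#' @slot panelSeparation distance between panel inner faces, mm
#' @slot panelWidth panel extent along X, mm
#' @slot panelAxial panel extent along Z (axial FOV), mm
#' @slot blocksX,blocksZ monolithic blocks per panel along X and Z
#' @slot blockSize numeric(3): block x, z, depth, mm
#' @slot blockPitchZ axial block pitch, mm (>= block z size)
#' @slot smearSigmaXY in-plane positioning sigma, mm
#' @slot smearSigmaDOI depth-of-interaction positioning sigma, mm
#' @rdname ScannerGeometry-class
#' @exportClass FlatPanelScanner
setClass("FlatPanelScanner", contains = "ScannerGeometry", representation(
  panelSeparation = "numeric",
  panelWidth = "numeric",
  panelAxial = "numeric",
  blocksX = "integer",
  blocksZ = "integer",
  blockSize = "numeric",
  blockPitchZ = "numeric",
  smearSigmaXY = "numeric",
  smearSigmaDOI = "numeric"))

#' @slot ringDiameter inner ring diameter (crystal front faces), mm
#' @slot crystalSize numeric(3): tangential, axial, depth, mm
#' @slot nRings axial crystal rings
#' @slot crystalsPerRing crystals per ring (gapless idealized packing)
#' @slot axialExtent axial FOV, mm
#' @slot mrd default maximum ring difference for coincidence acceptance
#' @slot minTangSep minimum tangential index separation of a valid pair
#' @rdname ScannerGeometry-class
#' @exportClass CylindricalScanner
setClass("CylindricalScanner", contains = "ScannerGeometry", representation(
  ringDiameter = "numeric",
  crystalSize = "numeric",
  nRings = "integer",
  crystalsPerRing = "integer",
  axialExtent = "numeric",
  mrd = "integer",
  minTangSep = "integer"))

setValidity("FlatPanelScanner", function(object) {
  msg <- character()
  if (any(c(object@panelSeparation, object@panelWidth, object@panelAxial,
            object@blockSize) <= 0))
    msg <- c(msg, "all dimensions must be positive")
  if (object@blocksX < 1L || object@blocksZ < 1L)
    msg <- c(msg, "block counts must be >= 1")
  if (length(object@blockSize) != 3L)
    msg <- c(msg, "blockSize must be (x, z, depth)")
  else {
    if (object@blocksX * object@blockSize[1] > object@panelWidth + 1e-6)
      msg <- c(msg, "blocks overlap or exceed the panel width")
    if (object@blocksZ > 1L && object@blockPitchZ < object@blockSize[2] - 1e-9)
      msg <- c(msg, "axial block pitch smaller than the block: blocks overlap")
    ext <- (object@blocksZ - 1L) * object@blockPitchZ + object@blockSize[2]
    if (ext > object@panelAxial + 1e-6)
      msg <- c(msg, "axial block placement exceeds the panel extent")
  }
  if (diff(object@energyWindow) <= 0 || object@energyWindow[1] <= 0)
    msg <- c(msg, "energy window must satisfy 0 < low < high")
  if (length(msg)) msg else TRUE
})

setValidity("CylindricalScanner", function(object) {
  msg <- character()
  if (any(c(object@ringDiameter, object@crystalSize, object@axialExtent) <= 0))
    msg <- c(msg, "all dimensions must be positive")
  pitchZ <- object@axialExtent / object@nRings
  if (object@nRings * pitchZ > object@axialExtent + pitchZ + 1e-6)
    msg <- c(msg, "rings exceed the axial extent by more than one pitch")
  circ <- pi * object@ringDiameter
  if (object@crystalsPerRing * object@crystalSize[1] > circ + object@crystalSize[1])
    msg <- c(msg, "crystals per ring exceed the ring circumference")
  if (object@crystalSize[1] > circ / 3)
    msg <- c(msg, "tangential pitch larger than circumference/3")
  if (diff(object@energyWindow) <= 0 || object@energyWindow[1] <= 0)
    msg <- c(msg, "energy window must satisfy 0 < low < high")
  if (length(msg)) msg else TRUE
})

#' Crystal address
#'
#' Identifies a single detection element: for the flat-panel scanner a
#' monolithic block (`det` = panel 0/1, `ia` = block index along X,
#' `ib` = block index along Z); for the cylindrical scanner a crystal
#' pixel (`det` = 0, `ia` = tangential index, `ib` = ring index).
#' Indices are zero-based.
#'
#' @slot det panel index (flat) or 0 (cylindrical)
#' @slot ia block X index or tangential index
#' @slot ib block Z index or ring index
#' @exportClass CrystalAddress
setClass("CrystalAddress", representation(
  det = "integer", ia = "integer", ib = "integer"))

#' Phantom scene
#'
#' A paired activity and attenuation description built from geometric
#' primitives. Primitives are painted in list order: where primitives
#' overlap, the one listed last defines both the material and the
#' activity concentration (used to carve nested structures such as the
#' aluminum sensitivity sleeves or the hot spheres inside the warm
#' image-quality background).
#'
#' @slot primitives data.frame with columns `shape` (`"sphere"`,
#'   `"cylinder"`, `"capsule"`, `"box"`, `"ellcyl"`), `cx`, `cy`, `cz`
#'   (centre, mm), `p1`, `p2`, `p3` (shape parameters, mm), `material`
#'   (row name of [materialTable()]) and `activity` (kBq/ml)
#' @slot description free-text label
#' @exportClass PhantomScene
setClass("PhantomScene", representation(
  primitives = "data.frame", description = "character"))

setValidity("PhantomScene", function(object) {
  p <- object@primitives
  need <- c("shape", "cx", "cy", "cz", "p1", "p2", "p3", "material", "activity")
  if (!all(need %in% names(p))) return("primitives missing required columns")
  if (any(!p$shape %in% c("sphere", "cylinder", "capsule", "box", "ellcyl")))
    return("unknown primitive shape")
  if (any(p$activity < 0)) return("activity concentrations must be >= 0")
  if (any(!p$material %in% materialTable()$material))
    return("unknown material id")
  TRUE
})

#' Voxel grid
#'
#' Axis-aligned voxel lattice. `origin` is the physical coordinate (mm)
#' of the low corner of voxel (1,1,1); voxel `(i,j,k)` is centred at
#' `origin + (c(i,j,k) - 0.5) * spacing`.
#'
#' @slot origin numeric(3), mm
#' @slot spacing numeric(3), mm
#' @slot dims integer(3)
#' @exportClass VoxelGrid
setClass("VoxelGrid", representation(
  origin = "numeric", spacing = "numeric", dims = "integer"))

setValidity("VoxelGrid", function(object) {
  if (length(object@origin) != 3 || length(object@spacing) != 3 ||
      length(object@dims) != 3) return("origin/spacing/dims must have length 3")
  if (any(object@spacing <= 0)) return("voxel spacing must be positive")
  if (any(object@dims < 1)) return("grid dims must be >= 1")
  TRUE
})

#' Voxel image
#'
#' A 3-D voxel image on a [VoxelGrid-class]: reconstruction output,
#' sensitivity image or a voxelized scene map.
#'
#' @slot data numeric 3-D array
#' @slot grid the [VoxelGrid-class]
#' @exportClass PetImage
setClass("PetImage", representation(data = "array", grid = "VoxelGrid"))

setValidity("PetImage", function(object) {
  if (!identical(dim(object@data), as.integer(object@grid@dims)))
    return("array dimensions do not match the grid")
  TRUE
})
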