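# TOF list-mode MLEM reconstruction: exact ray tracing through the
# voxel grid, Gaussian TOF kernel, sensitivity and attenuation
# correction. No regularization, no post-filtering.

#' Create a voxel grid
#'
#' @param centerMm numeric(3), grid centre in mm
#' @param voxelMm voxel size, scalar or numeric(3), mm
#' @param dims number of voxels per axis, scalar or integer(3)
#' @return a [VoxelGrid-class]
#' @examples
#' makeGrid(c(10, 0, 0), 0.5, 64)
#' @export
makeGrid <- function(centerMm, voxelMm, dims) {
  voxelMm <- rep(voxelMm, length.out = 3)
  dims <- as.integer(rep(dims, length.out = 3))
  new("VoxelGrid", origin = centerMm - dims * voxelMm / 2,
      spacing = voxelMm, dims = dims)
}

#' @rdname makeGrid
#' @param grid a [VoxelGrid-class]
#' @return for `voxelCenters`, an (nvox x 3) matrix of voxel centre
#'   coordinates in grid-linear (x fastest) order
#' @export
voxelCenters <- function(grid) {
  cx <- grid@origin[1] + (seq_len(grid@dims[1]) - 0.5) * grid@spacing[1]
  cy <- grid@origin[2] + (seq_len(grid@dims[2]) - 0.5) * grid@spacing[2]
  cz <- grid@origin[3] + (seq_len(grid@dims[3]) - 0.5) * grid@spacing[3]
  as.matrix(expand.grid(x = cx, y = cy, z = cz))
}

#' @rdname makeGrid
#' @param values numeric vector or array of voxel values
#' @return for `newPetImage`, a [PetImage-class]
#' @export
newPetImage <- function(values, grid) {
  new("PetImage", data = array(values, grid@dims), grid = grid)
}

setMethod("show", "VoxelGrid", function(object) {
  cat(sprintf("VoxelGrid: %d x %d x %d voxels of %g x %g x %g mm\n",
              object@dims[1], object@dims[2], object@dims[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
})

setMethod("show", "PetImage", function(object) {
  cat(sprintf("PetImage: %d x %d x %d voxels of %g mm; range [%.4g, %.4g]\n",
              object@grid@dims[1], object@grid@dims[2], object@grid@dims[3],
              object@grid@spacing[1], min(object@data), max(object@data)))
})

#' @rdname makeGrid
#' @param image a [PetImage-class]
#' @return for `imageData`, the raw 3-D array; for `imageGrid` the
#'   [VoxelGrid-class]
#' @export
imageData <- function(image) image@data

#' @rdname makeGrid
#' @export
imageGrid <- function(image) image@grid

#' Export an image as NIfTI-1
#'
#' @param image a [PetImage-class]
#' @param path output file path (`.nii` or `.nii.gz`)
#' @return the path, invisibly
#' @export
writeNiftiImage <- function(image, path) {
  g <- image@grid
  # NIfTI stores mm; map voxel (1,1,1) centre to origin + spacing/2
  affine <- diag(c(g@spacing, 1))
  affine[1:3, 4] <- g@origin + g@spacing / 2
  nii <- RNifti::asNifti(image@data)
  RNifti::pixdim(nii) <- g@spacing
  nii <- RNifti::`sform<-`(nii, structure(affine, code = 2L))
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' Trace a line of response through a voxel grid
#'
#' Exact (Siddon-type) ray tracing: returns every voxel crossed by the
#' segment between the endpoints, with the intersection lengths, in
#' traversal order. Lengths sum to the in-grid chord length.
#'
#' @param p1,p2 numeric(3), endpoints in mm
#' @param grid a [VoxelGrid-class]
#' @return data.frame with 1-based voxel indices `ix`, `iy`, `iz`,
#'   linear `index` and `length` (mm); zero rows when the LOR misses the
#'   grid
#' @export
traceLor <- function(p1, p2, grid) {
  tr <- cpp_trace_lor(p1, p2, grid@origin, grid@spacing, grid@dims)
  idx <- tr$index
  nx <- grid@dims[1]; ny <- grid@dims[2]
  data.frame(ix = idx %% nx + 1L,
             iy = (idx %/% nx) %% ny + 1L,
             iz = idx %/% (nx * ny) + 1L,
             index = idx + 1L,
             length = tr$length)
}

#' Spatial TOF kernel width from the timing resolution
#'
#' The annihilation-position kernel along the LOR has FWHM
#' `c * CTR / 2`; this returns the corresponding Gaussian sigma in mm.
#'
#' @param ctrPs coincidence time resolution FWHM, ps
#' @return sigma in mm
#' @examples
#' tofSigmaFromCtr(327) * 2.3548  # kernel FWHM ~ 49 mm
#' @export
tofSigmaFromCtr <- function(ctrPs) {
  0.299792458 * ctrPs / (2 * 2.354820045)
}

#' TOF weights along a traced LOR
#'
#' Multiplies each traced voxel's intersection length by a Gaussian
#' factor centred at the annihilation-position estimate
#' `s = -c * dt / 2` from the LOR midpoint toward endpoint 1
#' (`dt = t1 - t2`), truncated at three sigma.
#'
#' @param trace data.frame from [traceLor()]
#' @param p1,p2 the LOR endpoints, mm
#' @param dtPs timestamp difference `t1 - t2`, ps
#' @param tofSigmaMm kernel sigma in mm (see [tofSigmaFromCtr()])
#' @param grid the [VoxelGrid-class] used for the trace
#' @return numeric vector of per-voxel weights
#' @export
tofWeights <- function(trace, p1, p2, dtPs, tofSigmaMm, grid) {
  if (tofSigmaMm <= 0) stop("tofSigmaMm must be positive")
  m <- (p1 + p2) / 2
  u <- (p1 - m) / sqrt(sum((p1 - m)^2))
  sTof <- -0.5 * 0.299792458 * dtPs
  ctr <- cbind(grid@origin[1] + (trace$ix - 0.5) * grid@spacing[1],
               grid@origin[2] + (trace$iy - 0.5) * grid@spacing[2],
               grid@origin[3] + (trace$iz - 0.5) * grid@spacing[3])
  sk <- (ctr[, 1] - m[1]) * u[1] + (ctr[, 2] - m[2]) * u[2] +
    (ctr[, 3] - m[3]) * u[3]
  d <- (sk - sTof) / tofSigmaMm
  ifelse(abs(d) <= 3, trace$length * exp(-0.5 * d^2), 0)
}

#' Attenuation survival factor along a LOR
#'
#' Returns `exp(-integral of mu dl)` between the endpoints, either
#' analytically through a [PhantomScene-class] or through a voxelized
#' attenuation map ([sceneAttenuationMap()]). The reconstruction weight
#' of an event is the reciprocal of this factor.
#'
#' @param p1,p2 endpoints, numeric(3) or (n x 3) matrices, mm
#' @param attenuation a [PhantomScene-class] or a [PetImage-class]
#'   holding mu at 511 keV in 1/mm
#' @param floor factors below this are clamped (with a warning)
#' @return numeric vector of survival probabilities in (0, 1]
#' @export
attenuationFactor <- function(p1, p2, attenuation, floor = 1e-6) {
  if (is.null(dim(p1))) p1 <- matrix(p1, ncol = 3)
  if (is.null(dim(p2))) p2 <- matrix(p2, ncol = 3)
  if (is(attenuation, "PhantomScene")) {
    m <- .materialsCpp()
    f <- exp(-cpp_scene_line_mu(p1, p2, .sceneCpp(attenuation), m$muInc,
                                m$muPe, m$muPeExp, m$background, 511))
  } else if (is(attenuation, "PetImage")) {
    g <- attenuation@grid
    f <- cpp_atten_map_factors(p1, p2, as.numeric(attenuation@data),
                               g@origin, g@spacing, g@dims)
  } else stop("attenuation must be a PhantomScene or PetImage")
  if (any(f < floor)) {
    warning(sum(f < floor), " attenuation factors clamped at ", floor)
    f <- pmax(f, floor)
  }
  f
}

#' Compute the sensitivity image
#'
#' The geometric coincidence-detection probability of an emission at
#' each point: at every control point of a coarse lattice spanning the
#' grid, a shared set of isotropic emission directions is tested for
#' acceptance by a valid crystal pair (both panel faces in a block /
#' both ring crossings inside the rings with the tangential-separation
#' rule), optionally multiplied by the analytic attenuation survival
#' factor through the scene. The control values are interpolated
#' trilinearly onto the voxel grid and normalized to the maximum.
#' Voxels with zero sensitivity are excluded from MLEM updates.
#'
#' @param scanner a [ScannerGeometry-class]
#' @param grid a [VoxelGrid-class]
#' @param scene optional [PhantomScene-class] for attenuation inclusion
#' @param nDirs emission directions sampled per control point
#' @param nControl control points per axis
#' @return a [PetImage-class]
#' @export
computeSensitivityImage <- function(scanner, grid, scene = NULL,
                                    nDirs = 20000, nControl = 9) {
  m <- .materialsCpp()
  minSep <- if (is(scanner, "CylindricalScanner")) scanner@minTangSep else 0L
  sens <- cpp_sensitivity_image(
    .scannerCpp(scanner), grid@origin, grid@spacing, grid@dims,
    as.integer(nDirs), as.integer(nControl),
    minSep, if (is.null(scene)) NULL else .sceneCpp(scene),
    m$muInc, m$muPe, m$muPeExp, m$background)
  newPetImage(sens, grid)
}

#' List-mode MLEM reconstruction
#'
#' Standard list-mode MLEM with a Gaussian TOF kernel:
#' `x_j <- (x_j / s_j) * sum_i w_i a_ij / sum_k a_ik x_k`, where `a` is
#' the TOF-weighted intersection-length matrix, `s` the sensitivity
#' image and `w_i` the per-event multiplicative correction weight
#' (e.g. the reciprocal attenuation factor). Runs exactly `iterations`
#' full passes with no subsets, no regularization and no post-filter.
#' Events whose LOR misses the grid are skipped and counted.
#'
#' @param listmode data.frame with positioned endpoints `x1`..`z2` (mm),
#'   `dtPs` and optionally `weight` (default 1)
#' @param grid a [VoxelGrid-class]
#' @param sensitivity a [PetImage-class] from
#'   [computeSensitivityImage()] (or any positive image on the support)
#' @param iterations number of MLEM iterations
#' @param tofSigmaMm Gaussian TOF kernel sigma in mm; `0` disables TOF
#' @param initial optional initial [PetImage-class] (default: uniform on
#'   the sensitivity support)
#' @return a [PetImage-class]; attributes `loglik` (per-iteration data
#'   log-likelihood) and `skipped` (events whose trace missed the grid)
#' @export
mlemReconstruct <- function(listmode, grid, sensitivity, iterations = 10,
                            tofSigmaMm = 0, initial = NULL) {
  if (nrow(listmode) == 0) stop("empty listmode")
  w <- if (is.null(listmode$weight)) rep(1, nrow(listmode)) else listmode$weight
  if (any(w <= 0)) stop("event weights must be positive")
  ev <- cbind(listmode$x1, listmode$y1, listmode$z1,
              listmode$x2, listmode$y2, listmode$z2,
              if (is.null(listmode$dtPs)) rep(0, nrow(listmode)) else listmode$dtPs,
              w)
  sens <- as.numeric(sensitivity@data)
  if (all(sens <= 0)) stop("sensitivity image is all zero")
  res <- cpp_mlem(ev, grid@origin, grid@spacing, grid@dims, sens,
                  tofSigmaMm, as.integer(iterations),
                  if (is.null(initial)) NULL else as.numeric(initial@data))
  img <- newPetImage(res$image, grid)
  attr(img, "loglik") <- res$loglik
  attr(img, "skipped") <- res$skipped
  img
}

#' Build a listmode table from classified coincidences
#'
#' Selects the requested classes (the reconstructions in this package
#' use true coincidences only) and renames the positioned endpoints to
#' the listmode schema.
#'
#' @param coincidences classified, positioned coincidence data.frame
#' @param classes classes to keep
#' @param attenuation optional [PhantomScene-class] or [PetImage-class];
#'   when given, per-event weights are set to the reciprocal attenuation
#'   factor
#' @return listmode data.frame: `x1`..`z2`, `dtPs`, `class`, `weight`
#' @export
makeListmode <- function(coincidences, classes = "true", attenuation = NULL) {
  co <- coincidences[coincidences$class %in% classes, , drop = FALSE]
  lm <- data.frame(x1 = co$px1, y1 = co$py1, z1 = co$pz1,
                   x2 = co$px2, y2 = co$py2, z2 = co$pz2,
                   dtPs = co$dtPs, class = as.character(co$class),
                   weight = 1)
  if (!is.null(attenuation) && nrow(lm) > 0) {
    lm$weight <- 1 / attenuationFactor(as.matrix(lm[, 1:3]),
                                       as.matrix(lm[, 4:6]), attenuation)
  }
  lm
}
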