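# NEMA NU-2 style performance metrics: profile widths, sensitivity,
# count rates / NECR, scatter fraction after single-slice rebinning,
# and contrast recovery coefficients.

#' Profile widths at half and tenth maximum
#'
#' Builds the 1-D point-spread profile along one axis and measures the
#' full widths at half and at tenth maximum by linear interpolation
#' between the bracketing samples on each side of the peak. With
#' `method = "cut"` the profile is the 1-D line through the image
#' maximum; with `method = "sum"` (the NEMA NU-2 response function) the
#' image is summed over the two orthogonal directions within a window of
#' two line-cut FWHM around the peak.
#'
#' @param image a [PetImage-class], or a numeric profile vector (then
#'   `positions` must be given)
#' @param axis 1 (x), 2 (y) or 3 (z); or `"x"`, `"y"`, `"z"`
#' @param center optional numeric(3): take the profile through this
#'   point (mm) instead of through the global maximum
#' @param positions sample positions (mm) when `image` is a vector
#' @param method `"cut"` or `"sum"` (see above)
#' @return named numeric: `fwhm`, `fwtm` (mm)
#' @export
profileWidth <- function(image, axis = 1, center = NULL, positions = NULL,
                         method = c("cut", "sum")) {
  method <- match.arg(method)
  if (is.character(axis)) axis <- match(axis, c("x", "y", "z"))
  if (!is(image, "PetImage")) {
    if (is.null(positions)) stop("positions required for a raw profile")
    return(c(fwhm = .widthAt(as.numeric(image), positions, 0.5),
             fwtm = .widthAt(as.numeric(image), positions, 0.1)))
  }
  g <- image@grid
  a <- image@data
  if (is.null(center)) {
    mx <- arrayInd(which.max(a), dim(a))[1, ]
  } else {
    mx <- pmin(pmax(as.integer(floor((center - g@origin) / g@spacing)) + 1L,
                    1L), g@dims)
  }
  pos <- g@origin[axis] + (seq_len(g@dims[axis]) - 0.5) * g@spacing[axis]
  cut1d <- function(ax) {
    switch(ax, a[, mx[2], mx[3]], a[mx[1], , mx[3]], a[mx[1], mx[2], ])
  }
  if (method == "cut")
    return(c(fwhm = .widthAt(cut1d(axis), pos, 0.5),
             fwtm = .widthAt(cut1d(axis), pos, 0.1)))
  # NEMA response function: sum over the orthogonal axes within a window
  # of two line-cut FWHM around the peak
  orth <- setdiff(1:3, axis)
  sel <- vector("list", 3)
  sel[[axis]] <- seq_len(g@dims[axis])
  for (o in orth) {
    po <- g@origin[o] + (seq_len(g@dims[o]) - 0.5) * g@spacing[o]
    wcut <- tryCatch(.widthAt(cut1d(o), po, 0.5), error = function(e) NA)
    if (!is.finite(wcut)) wcut <- 2 * g@spacing[o]
    sel[[o]] <- which(abs(po - po[mx[o]]) <= 2 * wcut)
  }
  sub <- a[sel[[1]], sel[[2]], sel[[3]], drop = FALSE]
  prof <- apply(sub, axis, sum)
  c(fwhm = .widthAt(prof, pos, 0.5), fwtm = .widthAt(prof, pos, 0.1))
}

.widthAt <- function(prof, pos, frac) {
  # baseline from the profile tails (warm-background pedestal); zero in a
  # cold acquisition
  n <- length(prof)
  ntail <- max(2L, n %/% 10L)
  base <- min(mean(prof[seq_len(ntail)]), mean(prof[seq(n - ntail + 1L, n)]))
  prof <- prof - base
  ipk <- which.max(prof)
  lev <- prof[ipk] * frac
  # walk outward from the peak to the first crossing on each side
  cross <- function(side) {
    idx <- if (side == "left") seq(ipk, 1) else seq(ipk, length(prof))
    below <- which(prof[idx] < lev)
    if (!length(below))
      stop("profile does not cross ", frac, " of maximum inside the grid")
    i2 <- idx[below[1]]           # first sample below the level
    i1 <- idx[below[1] - 1]       # bracketing sample above
    pos[i1] + (pos[i2] - pos[i1]) * (prof[i1] - lev) / (prof[i1] - prof[i2])
  }
  abs(cross("right") - cross("left"))
}

#' Sensitivity metric
#'
#' Total sensitivity in cps/kBq (`accepted coincidences / decays x
#' 1000`) plus the axial sensitivity profile, obtained by binning each
#' coincidence into the axial slice of its endpoint mid-plane
#' (single-slice rebinning).
#'
#' @param coincidences accepted coincidences (all classes; energy window
#'   already applied)
#' @param nDecays number of simulated decays
#' @param sliceWidthMm axial profile slice width (default: the
#'   cylindrical axial crystal pitch, for comparability between
#'   scanners)
#' @param afovMm axial extent covered by the profile
#' @return list: `cpsPerKBq`, `profile` (data.frame `z` mm,
#'   `cpsPerKBq`), `nCoincidences`
#' @export
sensitivityMetric <- function(coincidences, nDecays, sliceWidthMm = 1060 / 322,
                              afovMm = 1060) {
  if (nDecays <= 0) stop("nDecays must be positive")
  total <- nrow(coincidences) / nDecays * 1000
  zmid <- (coincidences$z1 + coincidences$z2) / 2
  nb <- ceiling(afovMm / sliceWidthMm)
  idx <- floor((zmid + afovMm / 2) / sliceWidthMm) + 1
  counts <- tabulate(idx[idx >= 1 & idx <= nb], nbins = nb)
  mids <- -afovMm / 2 + (seq_len(nb) - 0.5) * sliceWidthMm
  list(cpsPerKBq = total,
       profile = data.frame(z = mids, cpsPerKBq = counts / nDecays * 1000),
       nCoincidences = nrow(coincidences))
}

#' Noise equivalent count rate
#'
#' `NECR = T^2 / (T + S + R)`, the effective true count rate accounting
#' for the noise contributed by scattered and random coincidences.
#'
#' @param T,S,R true, scatter and random count rates (counts/s); `T` may
#'   also be a data.frame with columns `T`, `S`, `R`
#' @return NECR in counts/s (0 when all rates are zero)
#' @examples
#' necr(100, 60, 40) # 50
#' @export
necr <- function(T, S = NULL, R = NULL) {
  if (is.data.frame(T)) { S <- T$S; R <- T$R; T <- T$T }
  tot <- T + S + R
  ifelse(tot > 0, T^2 / tot, 0)
}

#' Single-slice rebinning filter for count-rate analysis
#'
#' Each coincidence is assigned the axial slice of its endpoint
#' mid-plane; events are dropped when that slice lies outside the
#' central axial window or when the LOR's closest transaxial approach to
#' the scanner axis exceeds the radial mask.
#'
#' @param coincidences positioned coincidence data.frame
#' @param axialWindowMm central axial window (650 mm: the central 65 cm
#'   of the axial FOV)
#' @param radialMaskMm transaxial mask radius (120 mm)
#' @param usePositioned use positioned endpoints (`px1`..) when
#'   available, else the true interaction points
#' @return the retained coincidences
#' @export
ssrbFilter <- function(coincidences, axialWindowMm = 650, radialMaskMm = 120,
                       usePositioned = TRUE) {
  hasP <- usePositioned && !is.null(coincidences$px1)
  x1 <- if (hasP) coincidences$px1 else coincidences$x1
  y1 <- if (hasP) coincidences$py1 else coincidences$y1
  z1 <- if (hasP) coincidences$pz1 else coincidences$z1
  x2 <- if (hasP) coincidences$px2 else coincidences$x2
  y2 <- if (hasP) coincidences$py2 else coincidences$y2
  z2 <- if (hasP) coincidences$pz2 else coincidences$z2
  zmid <- (z1 + z2) / 2
  # distance from the z axis to the transaxial projection of the LOR
  dx <- x2 - x1; dy <- y2 - y1
  den <- sqrt(dx^2 + dy^2)
  r <- ifelse(den > 0, abs(x1 * dy - y1 * dx) / den, sqrt(x1^2 + y1^2))
  keep <- abs(zmid) <= axialWindowMm / 2 & r <= radialMaskMm
  coincidences[keep, , drop = FALSE]
}

#' Scatter fraction
#'
#' `SF = 100 * S / (S + T)` from ground-truth classified counts, valid
#' at activities where randoms are below 1% of trues (warned otherwise).
#'
#' @param coincidences classified coincidences (typically after
#'   [ssrbFilter()]), or a named vector/list of counts `T`, `S`, `R`
#' @return scatter fraction in percent
#' @export
scatterFraction <- function(coincidences) {
  if (is.data.frame(coincidences)) {
    counts <- table(coincidences$class)
    Tc <- counts[["true"]]; Sc <- counts[["scatter"]]; Rc <- counts[["random"]]
  } else {
    Tc <- coincidences[["T"]]; Sc <- coincidences[["S"]]
    Rc <- coincidences[["R"]]
  }
  if (Tc > 0 && Rc >= 0.01 * Tc)
    warning("randoms exceed 1% of trues; scatter fraction reported anyway")
  100 * Sc / (Sc + Tc)
}

#' Count-rate performance sweep
#'
#' Runs the full chain (transport, energy window, dead time, timing
#' blur, coincidence sorting, classification, single-slice rebinning
#' with axial window and radial mask) for each activity concentration of
#' the scatter phantom and tabulates true/scatter/random rates and the
#' NECR.
#'
#' @param scanner a [ScannerGeometry-class]
#' @param activitiesKBqMl activity ladder, kBq/ml (cylinder-volume
#'   equivalent)
#' @param offsetAxis line source offset axis, see [makeScatterScene()]
#' @param decaysPerPoint decays simulated per ladder point
#' @param deadTime apply the dead-time model?
#' @param mrd maximum ring difference override (cylindrical)
#' @return data.frame: `activity`, `T`, `S`, `R` (counts/s), `prompts`,
#'   `necr` (counts/s), `duration` (s)
#' @export
countRateSweep <- function(scanner, activitiesKBqMl, offsetAxis = "X",
                           decaysPerPoint = 2e5, deadTime = TRUE,
                           mrd = NULL) {
  rows <- lapply(activitiesKBqMl, function(a) {
    scene <- makeScatterScene(offsetAxis, activityKBqMl = a)
    co <- simulateCoincidences(scene, scanner, nDecays = decaysPerPoint,
                               deadTime = deadTime, mrd = mrd)
    filt <- ssrbFilter(positionEndpoints(co$coincidences, scanner))
    counts <- table(filt$class)
    dur <- co$duration
    data.frame(activity = a, T = counts[["true"]] / dur,
               S = counts[["scatter"]] / dur, R = counts[["random"]] / dur,
               prompts = nrow(co$coincidences), duration = dur)
  })
  out <- do.call(rbind, rows)
  out$necr <- necr(out)
  out[, c("activity", "T", "S", "R", "prompts", "necr", "duration")]
}

# 12 background ROI centres (mm) in the central transverse slice of the
# IQ phantom: NU-2-inspired deterministic placement away from the sphere
# ring (57.2 mm) and at least one largest-ROI radius inside the body.
.IQ_BG_ROIS <- rbind(
  c(0, 0), c(20, 0), c(0, 20), c(-20, 0), c(0, -20),
  c(20 * cos(pi / 4), 20 * sin(pi / 4)),
  c(100, 0), c(-100, 0),
  c(105 * cos(20 * pi / 180), 105 * sin(20 * pi / 180)),
  c(105 * cos(-20 * pi / 180), 105 * sin(-20 * pi / 180)),
  c(105 * cos(160 * pi / 180), 105 * sin(160 * pi / 180)),
  c(105 * cos(200 * pi / 180), 105 * sin(200 * pi / 180)))

#' Contrast recovery coefficients of an IQ reconstruction
#'
#' For every hot sphere: `CRC = 100 * (H/B - 1) / (ratio - 1)`, with `H`
#' the mean in a sphere-sized circular ROI at the known sphere centre
#' (transverse slice through the sphere centre) and `B` the mean over 12
#' background ROIs of the same size in the central slice, placed to
#' avoid the spheres.
#'
#' @param image reconstructed [PetImage-class]
#' @param iqScene the [PhantomScene-class] used for the acquisition
#' @param trueRatio the simulated sphere-to-background ratio
#' @return list: `table` (data.frame `diameter` mm, `crc` percent,
#'   `hotMean`, `bgMean`), `backgroundMean`
#' @export
crc <- function(image, iqScene, trueRatio = 4) {
  p <- iqScene@primitives
  body <- which(p$shape == "ellcyl")[1]
  bg <- p$activity[body]
  sph <- which(p$shape == "sphere" & p$activity > bg)
  g <- image@grid
  a <- image@data
  roiMean2d <- function(cx, cy, cz, rMm) {
    k <- pmin(pmax(as.integer(floor((cz - g@origin[3]) / g@spacing[3])) + 1L,
                   1L), g@dims[3])
    xs <- g@origin[1] + (seq_len(g@dims[1]) - 0.5) * g@spacing[1]
    ys <- g@origin[2] + (seq_len(g@dims[2]) - 0.5) * g@spacing[2]
    d2 <- outer((xs - cx)^2, (ys - cy)^2, "+")
    sel <- d2 <= rMm^2
    if (!any(sel)) sel <- d2 <= min(d2) + 1e-9 # at least the nearest voxel
    mean(a[, , k][sel])
  }
  zc <- p$cz[body]
  out <- lapply(sph, function(i) {
    r <- p$p1[i]
    H <- roiMean2d(p$cx[i], p$cy[i], p$cz[i], r)
    B <- mean(apply(.IQ_BG_ROIS, 1, function(q)
      roiMean2d(q[1], q[2], zc, r)))
    data.frame(diameter = 2 * r, crc = 100 * (H / B - 1) / (trueRatio - 1),
               hotMean = H, bgMean = B)
  })
  tab <- do.call(rbind, out)
  tab <- tab[order(tab$diameter), ]
  rownames(tab) <- NULL
  bigRoi <- max(p$p1[sph])
  list(table = tab,
       backgroundMean = mean(apply(.IQ_BG_ROIS, 1, function(q)
         roiMean2d(q[1], q[2], zc, bigRoi))))
}
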