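# Coincidence processing: timing blur, window pairing, ground-truth
# classification and the maximum-ring-difference cut.

#' Coincidence acceptance policy
#'
#' Bundles the coincidence time window, the geometric validity rule and
#' the maximum ring difference. Flat-panel pairs are valid when the two
#' singles lie on different panels; cylindrical pairs when their
#' tangential index separation (circular) is at least `minTangSep`.
#'
#' @param scanner a [ScannerGeometry-class]
#' @param ctwNs override the scanner's coincidence time window, ns
#' @param mrd override the maximum ring difference (`NA` = no cut);
#'   ignored for the flat-panel scanner
#' @param minTangSep override the minimum tangential separation
#' @return a list with class `"CoincidencePolicy"`
#' @export
coincidencePolicy <- function(scanner, ctwNs = NULL, mrd = NULL,
                              minTangSep = NULL) {
  flat <- is(scanner, "FlatPanelScanner")
  pol <- list(
    ctwNs = if (is.null(ctwNs)) scanner@ctwNs else ctwNs,
    rule = if (flat) "opposite-panel" else "tangential-separation",
    minTangSep = if (flat) 0L else
      if (is.null(minTangSep)) scanner@minTangSep else as.integer(minTangSep),
    nTang = if (flat) 0L else scanner@crystalsPerRing,
    mrd = if (flat) NA_integer_ else
      if (is.null(mrd)) scanner@mrd else as.integer(mrd),
    type = if (flat) 1L else 2L)
  if (pol$ctwNs <= 0) stop("coincidence time window must be positive")
  structure(pol, class = "CoincidencePolicy")
}

#' Blur single timestamps with the timing resolution
#'
#' Each timestamp is perturbed by a zero-mean Gaussian with
#' `sigma = CTR / (2.3548 * sqrt(2))`, so that the difference of two
#' blurred stamps has an FWHM equal to the coincidence time resolution.
#'
#' @param singles singles data.frame
#' @param scanner a [ScannerGeometry-class], or a CTR value in ps
#' @return singles with blurred `time`
#' @export
blurTimestamps <- function(singles, scanner) {
  ctr <- if (is(scanner, "ScannerGeometry")) scanner@ctrPs else scanner
  if (ctr == 0 || nrow(singles) == 0) return(singles)
  sigma <- ctr / (2.354820045 * sqrt(2)) * 1e-12
  singles$time <- singles$time + rnorm(nrow(singles)) * sigma
  singles
}

#' Sort singles into coincidences
#'
#' Event-driven open-window pairing: the first single opens a window of
#' one CTW; all singles arriving inside it form a cluster, and every
#' pair in the cluster that passes the geometric validity rule is
#' emitted ("takeAllGoods" multiples handling). Pairs failing the
#' geometry are dropped silently.
#'
#' For flat-panel events, endpoint 1 is the single on panel 0 (+Y side)
#' and `dtPs = t1 - t2`.
#'
#' @param singles time-sorted singles data.frame
#' @param scanner a [ScannerGeometry-class]
#' @param policy a [coincidencePolicy()]; defaults to the scanner's
#' @return coincidence data.frame: per endpoint the event id, crystal
#'   address, true interaction point and scatter flag, plus `dtPs` and
#'   (cylindrical) `ringDiff`
#' @export
sortCoincidences <- function(singles, scanner,
                             policy = coincidencePolicy(scanner)) {
  pr <- cpp_sort_coincidences(singles$time, singles$det, singles$ia,
                              policy$ctwNs * 1e-9, policy$type,
                              policy$minTangSep, policy$nTang)
  i1 <- pr[, 1]; i2 <- pr[, 2]
  co <- data.frame(
    eventId1 = singles$eventId[i1], eventId2 = singles$eventId[i2],
    det1 = singles$det[i1], ia1 = singles$ia[i1], ib1 = singles$ib[i1],
    det2 = singles$det[i2], ia2 = singles$ia[i2], ib2 = singles$ib[i2],
    x1 = singles$x[i1], y1 = singles$y[i1], z1 = singles$z[i1],
    x2 = singles$x[i2], y2 = singles$y[i2], z2 = singles$z[i2],
    dtPs = (singles$time[i1] - singles$time[i2]) * 1e12,
    scatter1 = singles$scatter[i1], scatter2 = singles$scatter[i2])
  if (policy$type == 2L) co$ringDiff <- abs(co$ib1 - co$ib2)
  co
}

#' Classify coincidences against the ground truth
#'
#' Tags carried through the simulation decide the class: different
#' event ids give a random; the same event id with a phantom-Compton
#' flag on either single gives a scatter; otherwise a true.
#'
#' @param coincidences data.frame from [sortCoincidences()]
#' @return the input with a `class` factor (`true`, `scatter`,
#'   `random`)
#' @export
classifyCoincidences <- function(coincidences) {
  cls <- ifelse(coincidences$eventId1 != coincidences$eventId2, "random",
                ifelse(coincidences$scatter1 | coincidences$scatter2,
                       "scatter", "true"))
  coincidences$class <- factor(cls, levels = c("true", "scatter", "random"))
  coincidences
}

#' Apply the maximum ring difference cut
#'
#' Removes cylindrical coincidences whose ring index difference exceeds
#' the MRD. A no-op for flat-panel events (no `ringDiff` column) and for
#' `mrd = NA`.
#'
#' @param coincidences coincidence data.frame
#' @param mrd maximum ring difference (count) or `NA` for no cut
#' @return filtered coincidences
#' @export
applyMRD <- function(coincidences, mrd) {
  if (is.null(coincidences$ringDiff) || is.na(mrd)) return(coincidences)
  coincidences[coincidences$ringDiff <= mrd, , drop = FALSE]
}
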