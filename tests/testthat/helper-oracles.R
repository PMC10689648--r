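# Independent oracles used across the suite. These reimplement the
# quantities under test by brute force and must stay independent of the
# package's fast paths.

# all-pairs coincidence sorter with open-window cluster semantics:
# the first single opens a window of ctw seconds; all singles inside
# form a cluster; every geometrically valid pair is emitted.
oracleSortCoincidences <- function(time, det, ia, ctwS, type,
                                   minTangSep = 0, nTang = 0) {
  stopifnot(!is.unsorted(time))
  out <- NULL
  i <- 1
  n <- length(time)
  while (i <= n) {
    inWin <- which(time >= time[i] & time <= time[i] + ctwS)
    inWin <- inWin[inWin >= i]
    if (length(inWin) >= 2) {
      prs <- t(combn(inWin, 2))
      for (k in seq_len(nrow(prs))) {
        p <- prs[k, 1]; q <- prs[k, 2]
        if (type == 1) {
          if (det[p] != det[q]) {
            if (det[p] == 0) out <- rbind(out, c(p, q)) else
              out <- rbind(out, c(q, p))
          }
        } else {
          dd <- abs(ia[p] - ia[q])
          dd <- min(dd, nTang - dd)
          if (dd >= minTangSep) out <- rbind(out, c(p, q))
        }
      }
    }
    i <- max(inWin) + 1
  }
  if (is.null(out)) matrix(integer(0), ncol = 2) else out
}

# mean scattering cosine of the Klein-Nishina distribution at energy E,
# by numerical integration of the differential cross section
oracleKnMeanCos <- function(energyKeV, n = 20001) {
  a <- energyKeV / 511
  ct <- seq(-1, 1, length.out = n)
  eps <- 1 / (1 + a * (1 - ct)) # E'/E
  f <- eps^2 * (eps + 1 / eps - (1 - ct^2)) # dsigma/dcos(theta), unnorm.
  sum(f * ct) / sum(f)
}

# fine-step numerical line integral of mu through a scene (1/mm)
oracleLineMu <- function(scene, p1, p2, energyKeV = 511, nStep = 20000) {
  t <- (seq_len(nStep) - 0.5) / nStep
  pts <- cbind(p1[1] + t * (p2[1] - p1[1]),
               p1[2] + t * (p2[2] - p1[2]),
               p1[3] + t * (p2[3] - p1[3]))
  m <- wtpet:::.materialsCpp()
  idx <- wtpet:::cpp_point_materials(pts, wtpet:::.sceneCpp(scene),
                                     m$background)
  mu <- muAt(materialTable()$material[idx], energyKeV) / 10
  L <- sqrt(sum((p2 - p1)^2))
  sum(mu) * L / nStep
}

# photon data.frame with given positions/directions (bypasses decay
# sampling) for targeted transport tests
makePhotons <- function(pos, dir, energy = 511, eventId = NULL) {
  n <- nrow(pos)
  dir <- dir / sqrt(rowSums(dir^2))
  data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3],
             dx = dir[, 1], dy = dir[, 2], dz = dir[, 3],
             energy = energy,
             eventId = if (is.null(eventId)) seq_len(n) else eventId,
             scattered = FALSE, alive = TRUE, path = 0, time0 = 0)
}

# empty scene (nothing but air)
emptyScene <- function() {
  new("PhantomScene",
      primitives = data.frame(shape = "sphere", cx = 0, cy = 0, cz = 1e6,
                              p1 = 1, p2 = 0, p3 = 0, material = "air",
                              activity = 0, stringsAsFactors = FALSE),
      description = "empty")
}
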