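test_that("ray tracing is exact on axis-aligned and random LORs", {
  grid <- makeGrid(c(0, 0, 0), 0.5, 64)
  # axis-aligned LOR: every in-grid voxel crossed with length 0.5 mm
  tr <- traceLor(c(-100, 0.1, 0.1), c(100, 0.1, 0.1), grid)
  expect_equal(nrow(tr), 64L)
  expect_equal(tr$length, rep(0.5, 64))
  expect_equal(tr$iy, rep(33L, 64))
  # conservation and dense-sampling agreement on random LORs
  set.seed(40)
  for (k in 1:20) {
    p1 <- runif(3, -60, 60); p2 <- runif(3, -60, 60)
    tr <- traceLor(p1, p2, grid)
    if (nrow(tr) == 0) next
    # in-grid chord length by interval clipping
    d <- p2 - p1
    t0 <- 0; t1 <- 1
    for (a in 1:3) {
      lo <- grid@origin[a]; hi <- lo + 32
      ta <- (lo - p1[a]) / d[a]; tb <- (hi - p1[a]) / d[a]
      t0 <- max(t0, min(ta, tb)); t1 <- min(t1, max(ta, tb))
    }
    chord <- max(0, t1 - t0) * sqrt(sum(d^2))
    expect_equal(sum(tr$length), chord, tolerance = 1e-6)
    # dense point sampling reproduces per-voxel lengths to < 0.1%
    m <- 200000
    tt <- t0 + (seq_len(m) - 0.5) / m * (t1 - t0)
    pts <- floor(cbind(p1[1] + tt * d[1], p1[2] + tt * d[2],
                       p1[3] + tt * d[3]) / 0.5 - rep(grid@origin / 0.5,
                                                      each = m))
    key <- pts[, 1] + 64 * (pts[, 2] + 64 * pts[, 3])
    est <- table(key) / m * chord
    big <- tr$length > 0.05
    keyTr <- (tr$ix - 1) + 64 * ((tr$iy - 1) + 64 * (tr$iz - 1))
    got <- tr$length[big]
    want <- as.numeric(est[as.character(keyTr[big])])
    expect_equal(got, want, tolerance = 2e-3)
  }
  # LOR missing the grid entirely
  expect_equal(nrow(traceLor(c(100, 100, 0), c(100, -100, 0), grid)), 0L)
})

test_that("TOF weights centre on the annihilation estimate", {
  grid <- makeGrid(c(0, 0, 0), 1, 64)
  p1 <- c(0.5, 250, 0.5); p2 <- c(0.5, -250, 0.5)
  tr <- traceLor(p1, p2, grid)
  # dt = 0: maximum weight at the LOR midpoint
  w0 <- tofWeights(tr, p1, p2, 0, 20, grid)
  expect_equal(tr$iy[which.max(w0)], 32L)
  # kernel FWHM from the timing resolution: c * CTR / 2
  expect_equal(tofSigmaFromCtr(327) * 2.354820045, 327 * 0.299792458 / 2,
               tolerance = 1e-9)
  # annihilation at y = +8 means endpoint 1 is reached sooner: dt < 0
  dt <- -2 * 8 / 0.299792458 # t1 - t2 in ps for d = +8 mm
  w <- tofWeights(tr, p1, p2, dt, 10, grid)
  yPk <- grid@origin[2] + (tr$iy[which.max(w)] - 0.5)
  expect_lt(abs(yPk - 8), 1.5)
  # very wide kernel approaches plain lengths
  wInf <- tofWeights(tr, p1, p2, 0, 1e7, grid)
  expect_equal(wInf / max(wInf), tr$length / max(tr$length), tolerance = 1e-4)
})

test_that("attenuation factors match the transport constants and symmetries", {
  # empty scene: only the ~400 mm of background air attenuates (~0.4%)
  expect_equal(attenuationFactor(c(0, -200, 0), c(0, 200, 0), emptyScene()),
               1, tolerance = 0.005)
  sc <- makeScatterScene("X", 1)
  # 20.3 cm water-equivalent path through the cylinder centre
  f <- attenuationFactor(c(0, -300, 0), c(0, 300, 0), sc)
  fExp <- exp(-(muAt("polyethylene", 511) * 20.3 +
                  muAt("air", 511) * (60 - 20.3)))
  expect_equal(f, fExp, tolerance = 1e-3)
  # endpoint swap symmetry
  set.seed(41)
  for (k in 1:5) {
    a <- runif(3, -150, 150); b <- runif(3, -150, 150)
    expect_equal(attenuationFactor(a, b, sc), attenuationFactor(b, a, sc),
                 tolerance = 1e-9)
  }
  # voxelized map agrees with the analytic scene factor
  grid <- makeGrid(c(0, 0, 0), 2, c(120, 120, 40))
  mu <- sceneAttenuationMap(sc, grid)
  fMap <- attenuationFactor(c(0, -300, 10), c(0, 300, 10), mu)
  fScene <- attenuationFactor(c(0, -300, 10), c(0, 300, 10), sc)
  expect_equal(fMap, fScene, tolerance = 0.02)
})

test_that("sensitivity image is symmetric and vanishes outside coverage", {
  wt <- buildFlatPanelScanner()
  grid <- makeGrid(c(0, 0, 0), 10, 16)
  set.seed(42)
  sens <- imageData(computeSensitivityImage(wt, grid, nDirs = 30000,
                                            nControl = 5))
  # mirror symmetry under X -> -X and Y -> -Y within sampling error
  expect_equal(sens, sens[16:1, , ], tolerance = 0.05)
  expect_equal(sens, sens[, 16:1, ], tolerance = 0.05)
  # a grid centred beyond the panel gap has no two-panel coverage
  gridOut <- makeGrid(c(0, 280, 0), 5, 8)
  sensOut <- imageData(computeSensitivityImage(wt, gridOut, nDirs = 2000,
                                               nControl = 3))
  expect_true(all(sensOut == 0))
})

test_that("sensitivity ratios match a brute-force direction enumeration", {
  # oracle: deterministic quasi-random direction mesh; acceptance =
  # fraction of emission lines detected by both panels (block faces)
  wt <- buildFlatPanelScanner()
  acceptance <- function(p, n = 4e5) {
    czv <- 2 * ((seq_len(n) - 0.5) / n) - 1
    phv <- 2 * pi * (((seq_len(n) - 0.5) * 0.61803398875) %% 1)
    sz <- sqrt(pmax(0, 1 - czv^2))
    dx <- sz * cos(phv); dy <- sz * sin(phv); dz <- czv
    ok <- abs(dy) > 1e-12
    tA <- (250 - p[2]) / dy[ok]           # +Y panel face
    tB <- (-250 - p[2]) / dy[ok]          # -Y panel face
    x1 <- p[1] + dx[ok] * tA; z1 <- p[3] + dz[ok] * tA
    x2 <- p[1] + dx[ok] * tB; z2 <- p[3] + dz[ok] * tB
    inz <- function(z) {
      w <- z + 530
      k <- floor(w / wt@blockPitchZ)
      w >= 0 & k < 20 & (w - k * wt@blockPitchZ) <= 50
    }
    hit <- abs(x1) <= 350 & abs(x2) <= 350 & inz(z1) & inz(z2)
    sum(hit) / n
  }
  set.seed(43)
  grid <- makeGrid(c(80, 45, 25), 10, c(17L, 11L, 1L))
  sens <- computeSensitivityImage(wt, grid, nDirs = 1e5, nControl = 9)
  a <- imageData(sens)
  pA <- c(0, -5, 25); pB <- c(150, 85, 25) # centres of voxels (1,1) and (16,10)
  got <- a[1, 1, 1] / a[16, 10, 1]
  want <- acceptance(pA) / acceptance(pB)
  expect_equal(got, want, tolerance = 0.04)
})

test_that("MLEM is non-negative, likelihood-monotone and localizes a point", {
  wt <- buildFlatPanelScanner()
  set.seed(44)
  scene <- makePointSourceScene(c(1, 0, 0), scanner = wt)
  co <- simulateCoincidences(scene, wt, nDecays = 4e4, deadTime = FALSE)
  co$coincidences <- positionEndpoints(co$coincidences, wt)
  lm <- makeListmode(co$coincidences, "true")
  grid <- makeGrid(c(10, 0, 0), 0.5, 48)
  sens <- computeSensitivityImage(wt, grid, nDirs = 10000)
  img <- mlemReconstruct(lm, grid, sens, iterations = 10,
                         tofSigmaMm = tofSigmaFromCtr(327))
  a <- imageData(img)
  expect_true(all(a >= 0))
  # data log-likelihood non-decreasing over the iterations
  ll <- attr(img, "loglik")
  expect_true(all(diff(ll) > -1e-6 * abs(ll[1])))
  # events are never silently lost: the skip counter accounts for the
  # few LORs (large crystal-scatter centroid shifts) missing the grid
  expect_lt(attr(img, "skipped"), 0.01 * nrow(lm))
  # reconstructed peak within one voxel of the true position
  pk <- arrayInd(which.max(a), dim(a))[1, ]
  ctr <- grid@origin + (pk - 0.5) * grid@spacing
  expect_true(all(abs(ctr - c(10, 0, 0)) <= 0.5 + 1e-9))
  # degenerate inputs are rejected
  expect_error(mlemReconstruct(lm[0, ], grid, sens), "empty")
  zero <- newPetImage(rep(0, prod(grid@dims)), grid)
  expect_error(mlemReconstruct(lm, grid, zero), "all zero")
})

test_that("single TOF event concentrates mass inside its kernel window", {
  grid <- makeGrid(c(0, 0, 0), 1, 32)
  sens <- newPetImage(rep(1, 32^3), grid)
  dt <- -2 * 8 / 0.299792458 / 2 # annihilation estimate at y = +8 mm
  lm <- data.frame(x1 = 0.2, y1 = 250, z1 = 0.2, x2 = 0.2, y2 = -250,
                   z2 = 0.2, dtPs = dt, weight = 1)
  img <- mlemReconstruct(lm, grid, sens, iterations = 1, tofSigmaMm = 5)
  pk <- arrayInd(which.max(imageData(img)), rep(32L, 3))[1, ]
  yPk <- grid@origin[2] + (pk[2] - 0.5)
  expect_lt(abs(yPk - 8), 5) # argmax within one kernel sigma
})

test_that("uniform activity on the gapless cylinder is an MLEM fixed point", {
  # synthetic uniform data: LORs drawn uniformly in sinogram coordinates
  # (angle, transaxial offset, axial position) and thinned in proportion
  # to their in-grid chord -- the forward projection of a uniform image,
  # whose backprojection density is uniform -- so with a flat sensitivity
  # the uniform image is self-consistent
  set.seed(45)
  grid <- makeGrid(c(0, 0, 0), 20, c(8L, 8L, 8L))
  lmax <- sqrt(2) * 160
  acc <- list()
  nAcc <- 0
  while (nAcc < 25000) {
    th <- runif(1, 0, pi)
    s0 <- runif(1, -120, 120)
    zm <- runif(1, -81, 81)
    u <- c(cos(th), sin(th), 0)
    base <- c(-s0 * sin(th), s0 * cos(th), zm)
    p1 <- base + 300 * u
    p2 <- base - 300 * u
    tr <- traceLor(p1, p2, grid)
    chord <- sum(tr$length)
    if (chord > 0 && runif(1) < chord / lmax) {
      nAcc <- nAcc + 1
      acc[[nAcc]] <- c(p1, p2)
    }
  }
  ev <- do.call(rbind, acc)
  lm <- data.frame(x1 = ev[, 1], y1 = ev[, 2], z1 = ev[, 3], x2 = ev[, 4],
                   y2 = ev[, 5], z2 = ev[, 6], dtPs = 0, weight = 1)
  sens <- newPetImage(rep(1, prod(grid@dims)), grid)
  img <- mlemReconstruct(lm, grid, sens, iterations = 1, tofSigmaMm = 0)
  a <- imageData(img)
  a <- a / mean(a)
  # the uniform level is preserved: small per-voxel scatter, and the
  # central region mean equals the global mean well within the noise
  expect_lt(sd(a), 0.10)
  expect_equal(mean(a[3:6, 3:6, 3:6]), 1, tolerance = 0.02)
})
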