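test_that("annihilation pairs are back-to-back, 511 keV and isotropic", {
  set.seed(10)
  d <- data.frame(x = 0, y = 0, z = 0, time = 0, eventId = 1)[rep(1, 2e4), ]
  d$eventId <- seq_len(nrow(d))
  ph <- emitAnnihilationPairs(d)
  d1 <- as.matrix(ph[seq(1, nrow(ph), 2), c("dx", "dy", "dz")])
  d2 <- as.matrix(ph[seq(2, nrow(ph), 2), c("dx", "dy", "dz")])
  expect_equal(unname(rowSums(d1 * d2)), rep(-1, nrow(d1)),
               tolerance = 1e-9)
  expect_true(all(ph$energy == 511))
  # isotropy: mean direction vector magnitude < 3/sqrt(N)
  expect_lt(sqrt(sum(colMeans(d1)^2)), 3 / sqrt(nrow(d1)))
  # optional acollinearity toggle deflects the second photon
  ph2 <- emitAnnihilationPairs(d[1:2000, ], acollinearityFwhmMrad = 10)
  d1 <- as.matrix(ph2[seq(1, nrow(ph2), 2), c("dx", "dy", "dz")])
  d2 <- as.matrix(ph2[seq(2, nrow(ph2), 2), c("dx", "dy", "dz")])
  expect_true(all(rowSums(d1 * d2) > -1))
})

test_that("Compton kinematics and Klein-Nishina sampling are correct", {
  # closed-form scattered energies
  expect_equal(511 / (1 + (511 / 511) * (1 - cos(pi))), 511 / 3,
               tolerance = 1e-9)
  set.seed(11)
  for (E in c(511, 250)) {
    ct <- wtpet:::cpp_sample_kn(2e5, E)
    se <- sd(ct) / sqrt(length(ct))
    expect_lt(abs(mean(ct) - oracleKnMeanCos(E)), 3 * se)
  }
})

test_that("transmission through layered slabs is exponential", {
  set.seed(12)
  # 10 cm water box followed by 2 cm aluminum box along +y
  prims <- rbind(
    wtpet:::.prim("box", c(0, 50, 0), c(200, 50, 200), "water"),
    wtpet:::.prim("box", c(0, 110, 0), c(200, 10, 200), "aluminum"))
  sc <- new("PhantomScene", primitives = prims, description = "slabs")
  n <- 40000
  ph <- makePhotons(matrix(rep(c(0, -10, 0), each = n), ncol = 3),
                    matrix(rep(c(0, 1, 0), each = n), ncol = 3))
  out <- propagateThroughPhantom(ph, sc)
  surv <- mean(out$alive & !out$scattered)
  pExp <- exp(-(muAt("water", 511) * 10 + muAt("aluminum", 511) * 2))
  expect_lt(abs(surv - pExp), 4 * sqrt(pExp * (1 - pExp) / n))
  # unscattered survivors keep full energy and direction
  keep <- out$alive & !out$scattered
  expect_true(all(out$energy[keep] == 511))
  expect_true(all(out$dy[keep] == 1))
  # energy never increases; scattered flag set with reduced energy
  expect_true(all(out$energy <= 511))
  expect_true(all(out$energy[out$scattered & out$alive] < 511))
})

test_that("photons below the tracking cutoff are terminated", {
  set.seed(13)
  prims <- wtpet:::.prim("box", c(0, 100, 0), c(500, 100, 500), "water")
  sc <- new("PhantomScene", primitives = prims, description = "thick")
  n <- 20000
  ph <- makePhotons(matrix(rep(c(0, -10, 0), each = n), ncol = 3),
                    matrix(rep(c(0, 1, 0), each = n), ncol = 3))
  out <- propagateThroughPhantom(ph, sc, cutoffKeV = 300)
  expect_true(all(out$energy[out$alive] >= 300))
})

test_that("crystal detection follows the truncated-exponential law", {
  set.seed(14)
  wt <- buildFlatPanelScanner()
  n <- 60000
  # normal incidence into a block interior (x=10, z=25 inside block 10)
  ph <- makePhotons(matrix(rep(c(10, 0, 25), each = n), ncol = 3),
                    matrix(rep(c(0, 1, 0), each = n), ncol = 3))
  s <- detectInCrystal(ph, wt)
  mu <- muAt("BGO", 511) / 10 # 1/mm
  t <- 16
  pInt <- 1 - exp(-mu * t)
  expect_lt(abs(nrow(s) / n - pInt), 4 * sqrt(pInt * (1 - pInt) / n))
  # first-interaction depth: mean of the truncated exponential
  depth <- (s$time * 2.99792458e11) - 250
  mExp <- (1 / mu) * (1 - (1 + mu * t) * exp(-mu * t)) / (1 - exp(-mu * t))
  expect_lt(abs(mean(depth) - mExp), 4 * sd(depth) / sqrt(nrow(s)))
  # deposits stay in the entry block; address is the block containing x=10
  expect_true(all(s$det == 0L & s$ia == 7L & s$ib == 10L))
  expect_true(all(s$edep <= 511 + 1e-9))
  # photons missing the panels produce nothing
  ph2 <- makePhotons(matrix(c(0, 0, 0), ncol = 3),
                     matrix(c(0, 0, 1), ncol = 3))
  expect_equal(nrow(detectInCrystal(ph2, wt)), 0L)
})

test_that("energy model blurs and windows deposits", {
  wt <- buildFlatPanelScanner()
  s <- data.frame(eventId = 1:2, det = 0L, ia = 0L, ib = 0L, x = 0, y = 255,
                  z = 0, edep = c(511, 511 / 3), time = 0, scatter = FALSE)
  # zero resolution: photopeak accepted, backscatter deposit rejected
  keep <- applyEnergyModel(s, list(resolution = 0, window = c(434, 645)))
  expect_equal(nrow(keep), 1L)
  expect_equal(keep$eblur, 511)
  # 15% resolution at 511 keV: acceptance = Phi((645-511)/sig)-Phi((434-511)/sig)
  set.seed(15)
  n <- 50000
  s2 <- s[rep(1, n), ]
  kept <- applyEnergyModel(s2, wt)
  sig <- 0.15 * 511 / 2.354820045
  pExp <- pnorm((645 - 511) / sig) - pnorm((434 - 511) / sig)
  expect_lt(abs(nrow(kept) / n - pExp), 4 * sqrt(pExp * (1 - pExp) / n))
})

test_that("dead time removes singles within tau per block", {
  wt <- buildFlatPanelScanner()
  s <- data.frame(eventId = 1:3, det = 0L, ia = c(0L, 0L, 1L), ib = 0L,
                  x = 0, y = 255, z = 0, edep = 511,
                  time = c(0, 100e-9, 150e-9), scatter = FALSE)
  # tau = 0 is the identity
  expect_equal(nrow(applyDeadTime(s, wt, tauNs = 0)), 3L)
  # second single 100 ns after the first in the same block is discarded;
  # the third is in another block and survives
  out <- applyDeadTime(s, wt)
  expect_equal(out$eventId, c(1, 3))
  # unsorted input is rejected
  expect_error(applyDeadTime(s[c(2, 1, 3), ], wt), "sorted")
  # Poisson stream: non-paralyzable loss fraction ~ lambda tau / (1 + lambda tau)
  set.seed(16)
  n <- 40000
  lam <- 2e5 # per block-second
  tm <- sort(cumsum(rexp(n, lam)))
  sp <- data.frame(eventId = seq_len(n), det = 0L, ia = 0L, ib = 0L,
                   x = 0, y = 255, z = 0, edep = 511, time = tm,
                   scatter = FALSE)
  kept <- applyDeadTime(sp, wt) # tau = 370 ns
  lossExp <- 1 - 1 / (1 + lam * 370e-9)
  expect_equal(1 - nrow(kept) / n, lossExp, tolerance = 0.15)
})
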