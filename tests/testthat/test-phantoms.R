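test_that("point-source scene matches the stated source definition", {
  sc <- makePointSourceScene(c(1, 0, 0))
  p <- sc@primitives
  expect_equal(nrow(p), 1L)              # cold: exactly one active primitive
  expect_equal(p$p1, 0.25)               # 0.5 mm diameter
  expect_equal(p$activity, 15280)        # 15.28 MBq/ml
  expect_error(makePointSourceScene(c(40, 0, 0)), "outside")
  warm <- makePointSourceScene(c(0, 20, 39.75), warmBackground = TRUE)
  expect_equal(nrow(warm@primitives), 2L)
  expect_equal(warm@primitives$activity[1], 15280 / 1000)
})

test_that("sensitivity scene carries 1 MBq and the NU-2 sleeves", {
  sc <- makeSensitivityScene(70, 5)
  expect_equal(totalActivity(sc), 1e6, tolerance = 1e-3)
  p <- sc@primitives
  expect_equal(sum(p$material == "aluminum"), 5L)
  line <- p[nrow(p), ]
  expect_equal(line$p2 * 2, 700)                     # active length 70 cm
  sc2 <- makeSensitivityScene(106, 5, offsetCm = c(0, 10))
  expect_equal(sc2@primitives$p2[1] * 2, 1060)
  expect_equal(sc2@primitives$cy[1], 100)
  expect_error(makeSensitivityScene(80), "70 or 106")
})

test_that("scatter scene volume-equivalent concentration is respected", {
  sc <- makeScatterScene("X", activityKBqMl = 2)
  cylVol <- pi * (203 / 2)^2 * 700 / 1000            # ml
  expect_equal(totalActivity(sc), 2 * cylVol * 1000, tolerance = 0.01)
  expect_equal(sc@primitives$cx[2], 45)
  scY <- makeScatterScene("Y", activityKBqMl = 2)
  expect_equal(scY@primitives$cy[2], 45)
  expect_error(makeScatterScene("X", offsetCm = 11), "outside")
})

test_that("IQ scene has the six NEMA spheres at 4:1 over 5.3 kBq/cc", {
  sc <- makeIQScene()
  p <- sc@primitives
  sph <- p[p$shape == "sphere", ]
  expect_equal(sort(sph$p1 * 2), c(10, 13, 17, 22, 28, 37))
  expect_equal(unique(sph$activity), 4 * 5.3)
  expect_equal(p$activity[p$shape == "ellcyl"], 5.3)
  sc2 <- makeIQScene(extraLesions = TRUE, axialPosition = "eighth")
  expect_equal(sum(sc2@primitives$shape == "sphere"), 8L)
  expect_equal(sc2@primitives$cz[1], -397.5)
})

test_that("decay sampling conserves activity and respects geometry", {
  set.seed(1)
  sc <- makeSensitivityScene(70)
  # declared total activity equals the sum of concentration x volume
  p <- sc@primitives
  expect_equal(totalActivity(sc),
               1000 * sum(p$activity * wtpet:::.effectiveVolumes(sc)))
  d <- sampleDecays(sc, nDecays = 5000)
  expect_equal(nrow(d), 5000L)
  expect_equal(attr(d, "duration"), 5000 / 1e6, tolerance = 1e-6)
  # every decay lies inside the line capsule (the only active primitive)
  expect_true(all(d$x^2 + d$y^2 <= 0.5^2 + 1e-9))
  expect_true(all(abs(d$z) <= 350))
  # duration mode: Poisson count with the stated mean
  d2 <- sampleDecays(sc, durationS = 0.002)
  expect_gt(nrow(d2), 2000 - 4 * sqrt(2000))
  expect_lt(nrow(d2), 2000 + 4 * sqrt(2000))
  expect_error(sampleDecays(sc), "exactly one")
})

test_that("two active primitives split decays by activity x volume", {
  set.seed(2)
  prims <- rbind(
    wtpet:::.prim("sphere", c(-50, 0, 0), 10, "water", 3),
    wtpet:::.prim("sphere", c(50, 0, 0), 10, "water", 1))
  sc <- new("PhantomScene", primitives = prims, description = "3:1")
  d <- sampleDecays(sc, nDecays = 40000)
  n1 <- sum(d$x < 0)
  # binomial test bounds around p = 0.75
  expect_gt(n1 / 40000, 0.75 - 4 * sqrt(0.75 * 0.25 / 40000))
  expect_lt(n1 / 40000, 0.75 + 4 * sqrt(0.75 * 0.25 / 40000))
  # empirical mean position of a single-sphere scene is the centre
  m <- colMeans(d[d$x < 0, c("x", "y", "z")])
  se <- 10 / sqrt(3) / sqrt(n1) # sd of a coordinate uniform in a sphere
  expect_lt(abs(m[1] + 50), 5 * se)
  expect_lt(abs(m[2]), 5 * se)
})

test_that("importance sampling reweights decays without bias", {
  set.seed(3)
  prims <- rbind(
    wtpet:::.prim("sphere", c(-50, 0, 0), 10, "water", 3),
    wtpet:::.prim("sphere", c(50, 0, 0), 10, "water", 1))
  sc <- new("PhantomScene", primitives = prims, description = "3:1")
  d <- sampleDecays(sc, nDecays = 20000, importance = c(1, 1))
  expect_gt(sum(d$prim == 2), 9000) # balanced allocation
  # weighted shares recover the physical 3:1 split
  sh <- tapply(d$weight, d$prim, sum) / sum(d$weight)
  expect_equal(unname(sh[1]), 0.75, tolerance = 0.02)
})

test_that("scene attenuation lookup matches fine-step integration", {
  sc <- makeScatterScene("X", activityKBqMl = 1)
  p1 <- c(-300, 40, 10); p2 <- c(250, -60, -30)
  m <- wtpet:::.materialsCpp()
  fast <- wtpet:::cpp_scene_line_mu(matrix(p1, 1), matrix(p2, 1),
                                    wtpet:::.sceneCpp(sc), m$muInc, m$muPe,
                                    m$muPeExp, m$background, 511)
  slow <- oracleLineMu(sc, p1, p2)
  expect_equal(fast, slow, tolerance = 1e-3)
  # nested sensitivity sleeves, oblique ray
  sc2 <- makeSensitivityScene(70)
  p1 <- c(-40, 3, -100); p2 <- c(35, -4, 140)
  fast2 <- wtpet:::cpp_scene_line_mu(matrix(p1, 1), matrix(p2, 1),
                                     wtpet:::.sceneCpp(sc2), m$muInc, m$muPe,
                                     m$muPeExp, m$background, 511)
  expect_equal(fast2, oracleLineMu(sc2, p1, p2), tolerance = 1e-3)
})

test_that("scene maps voxelize attenuation and activity", {
  sc <- makeIQScene()
  grid <- makeGrid(c(0, 0, 0), 8, c(40, 30, 24))
  mu <- sceneAttenuationMap(sc, grid)
  act <- sceneActivityMap(sc, grid)
  muW <- muAt("water", 511) / 10
  expect_equal(imageData(mu)[20, 15, 12], muW, tolerance = 1e-6)
  expect_equal(imageData(mu)[1, 1, 1], muAt("air", 511) / 10, tolerance = 1e-9)
  # the 37 mm sphere is hot in the activity map
  sph <- sc@primitives[sc@primitives$p1 == 18.5, ]
  i <- as.integer(floor((c(sph$cx, sph$cy, sph$cz) - grid@origin) / 8)) + 1L
  expect_equal(imageData(act)[i[1], i[2], i[3]], 4 * 5.3)
})
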