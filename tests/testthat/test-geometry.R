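test_that("flat-panel geometry reproduces the stated system totals", {
  wt <- buildFlatPanelScanner()
  expect_equal(nCrystals(wt), 560L)
  expect_equal(crystalVolume(wt), 560 * 5 * 5 * 1.6 * 1e-6)
  expect_equal(sipmArea(wt), 560 * 25 * 1e-4)
  expect_equal(axialFOV(wt), 106)
  ext <- lorExtremes(wt)
  expect_equal(unname(ext["shortest"]), 50)
  expect_equal(unname(ext["longest"]),
               sqrt(70^2 + 50^2 + 106^2), tolerance = 1e-6)
  # axial block tiling spans the full AFOV with a ~3.2 mm gap
  gap <- wt@blockPitchZ - wt@blockSize[2]
  expect_equal(gap, (1060 - 20 * 50) / 19, tolerance = 1e-9)
})

test_that("cylindrical geometry derives rings and crystals per ring", {
  qd <- buildCylindricalScanner()
  expect_equal(qd@nRings, 322L)
  expect_equal(axialFOV(qd), 106)
  ext <- lorExtremes(qd)
  expect_equal(unname(ext["shortest"]), 82)
  expect_equal(unname(ext["longest"]), sqrt(82^2 + 106^2), tolerance = 1e-4)
  # crystals per ring from circumference and pitch
  qd2 <- buildCylindricalScanner(list(tangential_pitch_mm = 3.29))
  expect_equal(qd2@crystalsPerRing, as.integer(floor(pi * 820 / 3.29)))
  # degenerate axial extent: longest -> shortest -> diameter
  qd3 <- buildCylindricalScanner(list(axial_cm = 1e-6, n_rings = 1L,
                                      tangential_pitch_mm = 3.2))
  ext3 <- lorExtremes(qd3)
  expect_equal(unname(ext3["longest"]), unname(ext3["shortest"]),
               tolerance = 1e-6)
})

test_that("invalid configurations are rejected", {
  expect_error(buildFlatPanelScanner(list(panel_separation_cm = -1)),
               "positive")
  expect_error(buildFlatPanelScanner(list(blocks_z = 30L)), "overlap")
  expect_error(buildCylindricalScanner(list(tangential_pitch_mm = 1000)),
               "circumference")
  expect_error(buildFlatPanelScanner(list(nonsense = 1)), "unknown config")
})

test_that("summed crystal volume and coupling area are linear in block count", {
  wt <- buildFlatPanelScanner()
  wt2 <- buildFlatPanelScanner(list(blocks_x = 28L, panel_width_cm = 140))
  expect_equal(crystalVolume(wt2), 2 * crystalVolume(wt))
  expect_equal(sipmArea(wt2), 2 * sipmArea(wt))
})

test_that("locateCrystal round-trips crystalCenter over a small geometry", {
  wt <- buildFlatPanelScanner(list(blocks_x = 3L, blocks_z = 4L,
                                   panel_width_cm = 15, panel_axial_cm = 25))
  for (det in 0:1) for (ia in 0:2) for (ib in 0:3) {
    a <- new("CrystalAddress", det = as.integer(det), ia = as.integer(ia),
             ib = as.integer(ib))
    b <- locateCrystal(wt, crystalCenter(wt, a))
    expect_equal(c(b@det, b@ia, b@ib), c(det, ia, ib))
  }
  qd <- buildCylindricalScanner(list(n_rings = 5L, axial_cm = 2,
                                     ring_diameter_cm = 10,
                                     crystal_mm = c(3.2, 3.2, 20)))
  for (ia in c(0L, 7L, qd@crystalsPerRing - 1L)) for (ib in 0:4) {
    a <- new("CrystalAddress", det = 0L, ia = ia, ib = as.integer(ib))
    b <- locateCrystal(qd, crystalCenter(qd, a))
    expect_equal(c(b@ia, b@ib), c(ia, ib))
  }
})

test_that("locateCrystal handles gaps, outside points and boundary ties", {
  wt <- buildFlatPanelScanner()
  expect_null(locateCrystal(wt, c(0, 0, 0)))          # isocenter: air gap
  expect_null(locateCrystal(wt, c(0, 258, 0)))        # axial inter-block gap
  expect_null(locateCrystal(wt, c(400, 258, 25)))     # beyond panel width
  # half-open [low, high) boundaries: a point on a shared x face belongs
  # deterministically to the block whose lower edge it is
  hit <- locateCrystal(wt, c(0, 258, 25))
  expect_equal(hit@ia, 7L) # x = 0 is the boundary between blocks 6 and 7
  expect_equal(hit@det, 0L)
})

test_that("scanner presets reproduce the built-in defaults", {
  wt <- loadScannerPreset("wt_pet")
  expect_s4_class(wt, "FlatPanelScanner")
  expect_equal(wt@ctrPs, 327)
  expect_equal(wt@energyWindow, c(434, 645))
  qd <- loadScannerPreset("quadra_like")
  expect_s4_class(qd, "CylindricalScanner")
  expect_equal(qd@ctwNs, 4.7)
  expect_equal(qd@mrd, 85L)
  expect_error(loadScannerPreset("no_such_preset"), "unknown")
})
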