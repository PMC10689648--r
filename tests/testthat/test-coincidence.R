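mkSingles <- function(time, det, ia = 0L, ib = 0L) {
  n <- length(time)
  data.frame(eventId = seq_len(n), det = as.integer(det),
             ia = rep_len(as.integer(ia), n), ib = rep_len(as.integer(ib), n),
             x = 0, y = ifelse(det == 0, 255, -255), z = 0, edep = 511,
             time = time, scatter = FALSE)
}

test_that("window pairing follows the stated examples", {
  wt <- buildFlatPanelScanner()
  # opposite panels, 2 ns apart, 5 ns window: one coincidence
  co <- sortCoincidences(mkSingles(c(0, 2e-9), c(0, 1)), wt)
  expect_equal(nrow(co), 1L)
  expect_equal(co$dtPs, -2000, tolerance = 1e-6) # panel-0 single is endpoint 1
  # 6 ns apart: none
  expect_equal(nrow(sortCoincidences(mkSingles(c(0, 6e-9), c(0, 1)), wt)), 0L)
  # three mutually-in-window singles, all pairs valid: C(3,2) = 3
  co3 <- sortCoincidences(mkSingles(c(0, 1e-9, 2e-9), c(0, 1, 0)), wt)
  expect_equal(nrow(co3), 2L) # takeAllGoods: same-panel pair dropped silently
  # all three pairs valid on the cylinder when tangentially well separated
  qd <- buildCylindricalScanner()
  sCyl <- mkSingles(c(0, 1e-9, 2e-9), 0L, c(0L, 260L, 520L))
  expect_equal(nrow(sortCoincidences(sCyl, qd)), 3L)
  expect_error(sortCoincidences(mkSingles(c(2e-9, 0), c(0, 1)), wt), "sorted")
})

test_that("sorter agrees exactly with the brute-force all-pairs oracle", {
  wt <- buildFlatPanelScanner()
  qd <- buildCylindricalScanner()
  set.seed(20)
  for (rep in 1:5) {
    n <- 800
    tm <- sort(cumsum(rexp(n, 2e8)))  # dense stream: many multi-clusters
    det <- sample(0:1, n, replace = TRUE)
    ia <- sample(0:(qd@crystalsPerRing - 1L), n, replace = TRUE)
    s <- mkSingles(tm, det, ia)
    # flat-panel rule
    got <- wtpet:::cpp_sort_coincidences(s$time, s$det, s$ia, 5e-9, 1L, 0L, 0L)
    want <- oracleSortCoincidences(s$time, s$det, s$ia, 5e-9, 1)
    expect_equal(got[order(got[, 1], got[, 2]), , drop = FALSE],
                 want[order(want[, 1], want[, 2]), , drop = FALSE],
                 ignore_attr = TRUE)
    # cylindrical rule
    msep <- qd@minTangSep
    got2 <- wtpet:::cpp_sort_coincidences(s$time, s$det, s$ia, 4.7e-9, 2L,
                                          msep, qd@crystalsPerRing)
    want2 <- oracleSortCoincidences(s$time, s$det, s$ia, 4.7e-9, 2,
                                    msep, qd@crystalsPerRing)
    expect_equal(got2[order(got2[, 1], got2[, 2]), , drop = FALSE],
                 want2[order(want2[, 1], want2[, 2]), , drop = FALSE],
                 ignore_attr = TRUE)
  }
})

test_that("classification uses only the ground-truth tags and partitions", {
  co <- data.frame(eventId1 = c(1, 2, 3), eventId2 = c(1, 2, 4),
                   scatter1 = c(FALSE, TRUE, TRUE),
                   scatter2 = c(FALSE, FALSE, TRUE))
  cl <- classifyCoincidences(co)$class
  expect_equal(as.character(cl), c("true", "scatter", "random"))
  # partition: every coincidence gets exactly one class
  expect_false(anyNA(cl))
})

test_that("timestamp blur reproduces the coincidence time resolution", {
  wt <- buildFlatPanelScanner()
  s <- mkSingles(rep(0, 4e4), rep(c(0, 1), 2e4))
  # CTR 0 is the identity
  expect_equal(blurTimestamps(s, 0)$time, s$time)
  set.seed(21)
  b <- blurTimestamps(s, wt)
  dt <- (b$time[seq(1, nrow(b), 2)] - b$time[seq(2, nrow(b), 2)]) * 1e12
  # per-single sigma = CTR/(2.3548 sqrt(2)); difference FWHM = CTR
  expect_equal(sd(dt) * 2.354820045, 327, tolerance = 0.02)
})

test_that("maximum ring difference cut filters cylindrical events only", {
  co <- data.frame(eventId1 = 1:3, eventId2 = 1:3, ringDiff = c(0L, 85L, 86L))
  expect_equal(nrow(applyMRD(co, 85)), 2L)
  expect_equal(applyMRD(co, 85)$ringDiff, c(0L, 85L))
  expect_equal(nrow(applyMRD(co, NA)), 3L)     # no cut
  expect_equal(nrow(applyMRD(co, 322)), 3L)    # cannot exceed on a 322-ring scanner
  coFlat <- data.frame(eventId1 = 1, eventId2 = 1)
  expect_equal(nrow(applyMRD(coFlat, 85)), 1L) # no-op without ring indices
})

test_that("randoms fraction vanishes at low activity", {
  wt <- buildFlatPanelScanner()
  set.seed(22)
  fr <- sapply(c(2, 20), function(a) {
    sc <- makeScatterScene("X", activityKBqMl = a)
    co <- simulateCoincidences(sc, wt, nDecays = 6e4)
    counts <- table(co$coincidences$class)
    counts[["random"]] / sum(counts)
  })
  expect_lt(fr[1], fr[2]) # monotone growth with activity
  sc <- makeScatterScene("X", activityKBqMl = 0.045)
  co <- simulateCoincidences(sc, wt, nDecays = 6e4)
  counts <- table(co$coincidences$class)
  expect_lt(counts[["random"]] / sum(counts), 0.01)
})
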