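test_that("ROI trace extraction averages the right pixels", {
  uni <- FluorescenceMovie(array(7, c(5, 4, 4)))
  roi <- circleROI(2, 2, 3, c(4, 4))
  expect_equal(extractTrace(uni, roi), rep(7, 5))

  arr <- array(0, c(3, 3, 3))
  for (t in 1:3) arr[t, , ] <- outer(1:3, 1:3, "+") * t
  mv <- FluorescenceMovie(arr)
  expect_equal(extractTrace(mv, cbind(2, 3)), c(5, 10, 15))
  # 2x2 corner block: mean of (1+1, 1+2, 2+1, 2+2) = 3, scaled by t
  block <- cbind(c(1, 1, 2, 2), c(1, 2, 1, 2))
  expect_equal(extractTrace(mv, block), 3 * (1:3))

  expect_error(extractTrace(mv, cbind(numeric(0), numeric(0))), "empty")
  expect_error(extractTrace(mv, cbind(5, 1)), "bounds")
})

test_that("delta-F/F0 matches hand-computed values in both baseline modes", {
  raw <- c(100, 102, 98, 100, 100, 120, 140, 90, 160, 200)
  d <- computeDff(raw, baselineFrames = 1:5)
  expect_equal(d$dff, c(0, 0.02, -0.02, 0, 0, 0.2, 0.4, -0.1, 0.6, 1))
  expect_equal(d$time_s, 0.8 * (0:9))

  ref <- rep(50, 10)
  expect_equal(computeDff(ref, reference = ref)$dff, rep(0, 10))
  expect_equal(computeDff(2 * ref, reference = ref)$dff, rep(1, 10))

  expect_error(computeDff(raw, baselineFrames = 1:5, reference = ref),
               "exactly one")
  expect_error(computeDff(raw - 200, baselineFrames = 1:5), "positive")
  expect_error(computeDff(raw, reference = rep(0, 10)), "positive")
})

test_that("time-dependent baseline cancels shared multiplicative artefacts exactly", {
  withr::with_seed(8, {
    sig <- 100 + cumsum(rnorm(60))
    ref <- 80 + cumsum(rnorm(60)) * 0.1
    gain <- exp(rnorm(60, 0, 0.3))   # per-frame artefact hitting both regions
    clean <- computeDff(sig, reference = ref)$dff
    dirty <- computeDff(sig * gain, reference = ref * gain)$dff
    expect_equal(dirty, clean, tolerance = 1e-12)
  })
})

test_that("correlation maps equal the per-pixel Pearson oracle and stay in [-1, 1]", {
  withr::with_seed(13, {
    arr <- array(rnorm(8 * 8 * 50, 100, 10), c(50, 8, 8))
    arr[, 3, 3] <- 7                       # zero-variance pixel
    mv <- FluorescenceMovie(arr)
    seedTrace <- arr[, 1, 1]
    cm <- correlationMap(mv, seedTrace)
    expect_equal(cm, oracleCorrelationMap(arr, seedTrace), tolerance = 1e-12)
    expect_true(all(cm >= -1 & cm <= 1))
    expect_equal(cm[1, 1], 1)
    expect_equal(cm[3, 3], 0)

    neg <- FluorescenceMovie(array(rep(-seedTrace + 500, 4), c(50, 2, 2)))
    expect_equal(correlationMap(neg, seedTrace), matrix(-1, 2, 2))
  })
  expect_error(correlationMap(FluorescenceMovie(array(0, c(5, 2, 2))), 1:4),
               "length")
})

test_that("correlation maps render as a PNG heat map", {
  f <- withr::local_tempfile(fileext = ".png")
  plotCorrelationMap(matrix(seq(-1, 1, length.out = 64), 8, 8), f)
  expect_true(file.exists(f) && file.size(f) > 0)
})

test_that("response detection separates biphasic, dip-only, and flat traces", {
  tm <- seq(0, 119.2, by = 0.8)
  onset <- 20; offset <- 80
  mk <- function(v) data.frame(time_s = tm, dff = v)

  bip <- numeric(length(tm))
  bip[tm >= onset & tm < onset + 16] <- -0.4
  ramp <- tm >= onset + 16
  bip[ramp] <- 2 * (1 - exp(-(tm[ramp] - onset - 16) / 10))
  r <- detectResponse(mk(bip), onset, offset, dipThreshold = 0.1,
                      depolThreshold = 0.1)
  expect_equal(r$response_class, "biphasic_cPRC")
  expect_true(r$dip_present)
  expect_gte(r$depol_onset_time_s, r$dip_min_time_s)

  dip <- numeric(length(tm)); dip[tm >= onset] <- -0.4
  expect_equal(detectResponse(mk(dip), onset, offset, dipThreshold = 0.1,
                              depolThreshold = 0.1)$response_class,
               "hyperpolarizing_only")

  expect_equal(detectResponse(mk(numeric(length(tm))), onset,
                              offset)$response_class, "none")

  # depolarization after stimulus offset is still counted
  late <- numeric(length(tm))
  late[tm >= onset & tm < offset] <- -0.4
  late[tm >= offset + 5] <- 1.5
  rl <- detectResponse(mk(late), onset, offset, dipThreshold = 0.1,
                       depolThreshold = 0.1)
  expect_equal(rl$response_class, "biphasic_cPRC")
  expect_gt(rl$depol_onset_time_s, offset)

  # single-frame spikes are rejected as unsustained
  spike <- numeric(length(tm)); spike[30] <- 5
  expect_equal(detectResponse(mk(spike), onset, offset, dipThreshold = 0.1,
                              depolThreshold = 0.1)$response_class, "none")

  expect_error(detectResponse(mk(bip), onset, offset, dipThreshold = -1,
                              depolThreshold = 0.1), "positive")
  expect_error(detectResponse(mk(bip), 80, 20), "onset < offset")
})

test_that("joint 405/488 classification recovers every planted generator class", {
  onset_s <- 24 * 0.8; offset_s <- 99 * 0.8

  # noise-free: exact recovery
  p0 <- movieModelParams(photonNoise = 0)
  tr0 <- movieTraceTable(simulateMovie(p0, 405, seed = 1),
                         simulateMovie(p0, 488, seed = 1))
  cls0 <- classifyCells(tr0, onset_s, offset_s)
  expected <- c(cPRC_a = "cPRC_like", RGW_a = "RGW_follower",
                SNe_a = "SN_early", SNl_a = "SN_late")
  expect_equal(cls0$joint_class[match(names(expected), cls0$cell)],
               unname(expected))

  # default photon noise, fixed seeds: >= 90% recovery over repeats
  hits <- 0; total <- 0
  for (s in 1:5) {
    tr <- movieTraceTable(simulateMovie(movieModelParams(), 405, seed = s),
                          simulateMovie(movieModelParams(), 488, seed = s + 100))
    cls <- classifyCells(tr, onset_s, offset_s)
    hits <- hits + sum(cls$joint_class[match(names(expected), cls$cell)] ==
                         unname(expected))
    total <- total + length(expected)
  }
  expect_gte(hits / total, 0.9)

  # all-flat traces classify as none
  flat <- expand.grid(cell = "c1", wavelength_nm = c(405, 488),
                      time_s = seq(0, 119.2, 0.8))
  flat$dff <- 0
  expect_equal(classifyCells(flat, onset_s, offset_s)$joint_class, "none")

  # an SN_early cell under a 488 nm program shows no response
  pSNe <- movieModelParams(cells = data.frame(
    cell = "e", class = "SN_early", row = 32, col = 32, radius_px = 4),
    photonNoise = 0)
  s488 <- simulateMovie(pSNe, 488, seed = 2)
  roi <- circleROI(32, 32, 8, c(64, 64))
  d <- computeDff(extractTrace(s488$movie, roi), baselineFrames = 1:24)
  expect_equal(detectResponse(d, onset_s, offset_s)$response_class, "none")

  expect_error(classifyCells(flat[flat$wavelength_nm == 405, ],
                             onset_s, offset_s), "missing a wavelength")
})

test_that("movies round-trip through multi-page TIFF", {
  withr::with_seed(4, {
    arr <- array(runif(5 * 6 * 7, 0, 200), c(5, 6, 7))
    mv <- FluorescenceMovie(arr)
    f <- withr::local_tempfile(fileext = ".tif")
    writeMovieTiff(mv, f, maxIntensity = 200)
    back <- readMovieTiff(f, maxIntensity = 200)
    expect_equal(movieFrames(back), arr, tolerance = 1e-5)
  })
})
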