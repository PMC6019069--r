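test_that("every generator is bit-reproducible under a fixed seed", {
  expect_identical(makeReferenceConnectome(seed = 7),
                   makeReferenceConnectome(seed = 7))
  expect_identical(makeBranchSet(seed = 7), makeBranchSet(seed = 7))
  expect_identical(simulateSpectrum(seed = 7), simulateSpectrum(seed = 7))
  expect_identical(simulateMovie(seed = 7), simulateMovie(seed = 7))
  expect_identical(
    simulateTrajectories(nLarvae = 5, duration_s = 20, seed = 7),
    simulateTrajectories(nLarvae = 5, duration_s = 20, seed = 7))
  tj <- simulateTrajectories(nLarvae = 3, duration_s = 10, seed = 1)
  expect_identical(renderVideo(tj, frameDim = c(40, 20), mmPerPx = 4, seed = 7),
                   renderVideo(tj, frameDim = c(40, 20), mmPerPx = 4, seed = 7))
})

test_that("the fixture connectome realizes the prescribed circuit topology", {
  sm <- makeReferenceConnectome(seed = 3)
  cells <- cellTable(sm)
  counts <- table(cells$cell_class)
  expect_equal(as.integer(counts[c("cPRC", "IN_RGW", "IN_NOS", "IN_preMN",
                                   "MS", "Ser_h1", "MC")]),
               c(4L, 4L, 4L, 6L, 2L, 2L, 1L))

  m <- synapseCounts(sm)
  flask <- cells$cell_id[cells$cell_class == "SN_flask"]
  expect_true(all(m[flask, ] == 0))      # flask neurons have no outputs

  # no rPRC-circuit cell is presynaptic to any cPRC-circuit cell
  circ <- circuitDefinition()
  rIds <- cells$cell_id[cells$cell_class %in% circ@rprcCircuit]
  cIds <- cells$cell_id[cells$cell_class %in% circ@cprcCircuit]
  expect_true(all(m[rIds, cIds] == 0))

  # the adult-eye pathway descends through three interneuron layers
  g <- groupMatrix(sm)
  expect_gt(g["rPRC_adult_eye", "IN_pro"], 0)
  expect_gt(g["IN_pro", "IN_sn"], 0)
  expect_gt(g["IN_sn", "vMN"], 0)

  expect_error(makeReferenceConnectome(
    within(connectomeFixtureSpec(), counts["IN_preMN"] <- 5L)), "fixed")
  expect_error(connectomeFixtureSpec(IN_sn = 1), "minima")
})

test_that("branch sets hit their length target and reproduce the membrane area", {
  bs <- makeBranchSet(nBranches = 50, seed = 2)
  expect_lt(abs(sum(branchLengths(bs)) - 677), 1e-9)
  expect_true(all(branchDiameters(bs) > 0))

  pinned <- makeBranchSet(nBranches = 40, diameterSd_nm = 0, seed = 5)
  expect_lt(abs(membraneArea(pinned) - 276) / 276, 0.01)

  single <- CiliaryBranchSet(100, 1)
  expect_equal(membraneArea(single), pi * 0.1)
})

test_that("knockout movies lose the ciliary-photoreceptor response", {
  ko <- simulateMovie(movieModelParams(knockout = TRUE, photonNoise = 0),
                      405, seed = 1)
  roi <- circleROI(16, 16, 8, c(64, 64))
  d <- computeDff(extractTrace(ko$movie, roi), baselineFrames = 1:24)
  expect_equal(detectResponse(d, 24 * 0.8, 99 * 0.8)$response_class, "none")

  # knockout resting signal is lowered relative to wild type
  wt <- simulateMovie(movieModelParams(photonNoise = 0), 405, seed = 1)
  expect_lt(mean(movieFrames(ko$movie)[1:10, 16, 16]),
            mean(movieFrames(wt$movie)[1:10, 16, 16]))

  # a movie with no planted cells is background only
  bare <- simulateMovie(movieModelParams(cells = data.frame(
    cell = character(0), class = character(0), row = numeric(0),
    col = numeric(0), radius_px = numeric(0)), photonNoise = 0), 405, seed = 1)
  expect_equal(max(movieFrames(bare$movie)), 100)
  expect_error(movieModelParams(cells = data.frame(
    cell = "x", class = "cPRC", row = 300, col = 1, radius_px = 2)),
    "outside")
})

test_that("spectrum generator recovers its peak under default noise", {
  ok <- 0
  for (s in 1:50) {
    sp <- simulateSpectrum(seed = s)
    if (abs(spectrumPeak(sp$dark, smoothWindow = 10) - 384) <= 2)
      ok <- ok + 1
  }
  expect_gte(ok / 50, 0.95)
})

test_that("trajectory drift matches the closed-form drive equation", {
  # tall arena so boundary reflections cannot bias the empirical mean
  pars <- behaviorModelParams(noise_mm_sqrt_s = 0.4, arenaHeight_mm = 2000)
  sch <- dutyCycleSchedule(0.2, 380, 480)
  tj <- simulateTrajectories(pars, sch, nLarvae = 1000, duration_s = 40,
                             seed = 77)
  # pre-latency window, away from the boundaries
  nd <- netDisplacement(tj, c(5, 35))
  expected <- expectedDrift(pars, sch, "pre") * 30
  expect_lt(abs(nd$mean_mm - expected), 3 * nd$se_mm)
})

test_that("monochromatic programs produce the expected swimming phenotypes", {
  pars <- behaviorModelParams(noise_mm_sqrt_s = 0.2)

  blue <- simulateTrajectories(pars, dutyCycleSchedule(0, 380, 480),
                               nLarvae = 40, seed = 61)
  expect_gt(netDisplacement(blue, c(90, 210))$mean_mm, 0)

  uv <- simulateTrajectories(pars, dutyCycleSchedule(1, 395, 480),
                             nLarvae = 60, seed = 62)
  b <- binDisplacement(uv, 30)
  expect_true(all(b$mean_mm[b$bin_end_s <= 60] > 0))   # up before latency
  expect_true(all(b$mean_mm[b$bin_start_s >= 90] < 0)) # down after

  ko <- behaviorModelParams(noise_mm_sqrt_s = 0.2, knockout = TRUE)
  uvko <- simulateTrajectories(ko, dutyCycleSchedule(1, 395, 480),
                               nLarvae = 60, seed = 63)
  bko <- binDisplacement(uvko, 30)
  expect_true(all(bko$mean_mm > 0))
})
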