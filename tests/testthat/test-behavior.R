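constantVelocityTrajs <- function(v_mm_per_30s = 1, n = 3, duration = 300,
                                  z0 = 20) {
  times <- seq(0, duration, 5)
  s <- do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(larva_id = paste0("l", i), t_s = times, x_mm = i,
               z_mm = z0 + v_mm_per_30s / 30 * times)))
  TrajectorySet(s, 160)
}

test_that("binned displacement is exact for constant-velocity swimmers", {
  tj <- constantVelocityTrajs(1)
  b <- binDisplacement(tj, 30)
  expect_equal(b$mean_mm, rep(1, nrow(b)))
  expect_equal(b$n, rep(3, nrow(b)))

  # opposite-velocity pair averages to zero
  times <- seq(0, 120, 2)
  s <- rbind(data.frame(larva_id = "up", t_s = times, x_mm = 1,
                        z_mm = 50 + 2 / 30 * times),
             data.frame(larva_id = "down", t_s = times, x_mm = 2,
                        z_mm = 50 - 2 / 30 * times))
  b2 <- binDisplacement(TrajectorySet(s, 160), 30)
  expect_equal(b2$mean_mm, rep(0, 4))

  # a larva absent for part of a bin is excluded from that bin
  s3 <- rbind(data.frame(larva_id = "full", t_s = times, x_mm = 1,
                         z_mm = 50 + times / 30),
              data.frame(larva_id = "part", t_s = times[times >= 45], x_mm = 2,
                         z_mm = 100))
  b3 <- binDisplacement(TrajectorySet(s3, 160), 30)
  expect_equal(b3$n, c(1, 1, 2, 2))

  expect_error(binDisplacement(tj, 0), "positive")
})

test_that("net displacement matches per-larva subtraction and telescopes over bins", {
  still <- constantVelocityTrajs(0)
  expect_equal(netDisplacement(still, c(0, 120))$mean_mm, 0)

  times <- seq(0, 150, 1)
  s <- data.frame(larva_id = "d", t_s = times, x_mm = 0,
                  z_mm = 120 - 0.5 * times)
  desc <- TrajectorySet(s, 160)
  expect_equal(netDisplacement(desc, c(10, 130))$mean_mm, -60)

  withr::with_seed(31, {
    tj <- simulateTrajectories(nLarvae = 20, duration_s = 120, seed = 17)
    nd <- netDisplacement(tj, c(0, 120))
    direct <- vapply(split(trajectorySamples(tj),
                           trajectorySamples(tj)$larva_id),
                     function(s) s$z_mm[nrow(s)] - s$z_mm[1], numeric(1))
    expect_equal(unname(sort(nd$per_larva)), unname(sort(direct)))
    expect_equal(nd$mean_mm, mean(direct))
    # sum of 30-s bin displacements telescopes to the window net value
    b <- binDisplacement(tj, 30)
    expect_equal(sum(b$mean_mm), nd$mean_mm, tolerance = 1e-9)
  })

  expect_error(netDisplacement(desc, c(100, 500)), "outside")
})

test_that("centre-of-mass displacement equals the per-larva mean for full tracks", {
  tj <- simulateTrajectories(nLarvae = 15, duration_s = 60, seed = 23)
  pl <- netDisplacement(tj, c(0, 60), method = "per_larva")
  cm <- netDisplacement(tj, c(0, 60), method = "center_of_mass")
  expect_equal(cm$mean_mm, pl$mean_mm, tolerance = 1e-12)
})

test_that("heading classification uses a dead-band on vertical velocity", {
  s <- rbind(data.frame(larva_id = "a", t_s = 0:3, x_mm = 0,
                        z_mm = c(10, 12, 12.05, 10)),
             data.frame(larva_id = "b", t_s = 0:1, x_mm = 0, z_mm = c(5, 5)))
  h <- headingDirection(TrajectorySet(s, 160), deadband_mm_s = 0.1)
  a <- h[h$larva_id == "a", ]
  expect_equal(a$heading, c("up", "neutral", "down", "down"))
  expect_equal(h$heading[h$larva_id == "b"], c("neutral", "neutral"))
})

test_that("action spectra show avoidance below 420 nm and phototaxis above", {
  win <- analysisWindow("fig3E")
  expect_equal(win, c(90, 210))
  pars <- behaviorModelParams(noise_mm_sqrt_s = 0.2)
  wls <- c(340, 380, 400, 440, 480, 520, 600)
  trials <- setNames(lapply(seq_along(wls), function(i)
    simulateTrajectories(pars, dutyCycleSchedule(1, wls[i], 480,
                                                 totalDuration_s = 240),
                         nLarvae = 40, seed = 300 + i)), wls)
  as <- actionSpectrum(trials, win)
  expect_true(all(as$net_mm[as$wavelength_nm <= 400] < 0))
  expect_true(all(as$net_mm[as$wavelength_nm >= 440] > 0))

  # knockout larvae keep swimming up under UV
  ko <- behaviorModelParams(knockout = TRUE, noise_mm_sqrt_s = 0.2)
  tko <- simulateTrajectories(ko, dutyCycleSchedule(1, 395, 480),
                              nLarvae = 40, seed = 41)
  expect_gt(netDisplacement(tko, win)$mean_mm, 0)

  # no drive, no displacement (only diffusion)
  null <- behaviorModelParams(vPhototaxis_mm_s = 0, noise_mm_sqrt_s = 0.3)
  tnull <- simulateTrajectories(null, dutyCycleSchedule(1, 395, 480),
                                nLarvae = 60, seed = 42)
  nd <- netDisplacement(tnull, win)
  expect_lt(abs(nd$mean_mm), 4 * nd$se_mm + 1)

  expect_error(actionSpectrum(list(), win), "empty")
})

test_that("balance-point interpolation finds the zero crossing", {
  expect_equal(balancePoint(c(0.2, 0.6), c(10, -10)), 0.4)
  expect_equal(balancePoint(c(0, 0.5, 1), c(4, 0, -4)), 0.5)
  # with several crossings, the one after the largest positive response wins
  expect_equal(balancePoint(c(0.1, 0.2, 0.3, 0.4, 0.5),
                            c(1, -1, 8, -8, -2)), 0.35)
  expect_error(balancePoint(c(0.2, 0.6), c(-5, -10)), "no sign change")
  expect_error(balancePoint(c(0.6, 0.2), c(5, -10)), "increasing")
})

test_that("group comparisons apply Sidak-style corrections correctly", {
  withr::with_seed(51, {
    x <- rnorm(10)
    same <- compareGroups(x, x + 1e-12)
    expect_gt(same$p, 0.99)
    expect_false(same$reject)

    # m = 1: Holm-Sidak reduces to a plain t-test at alpha
    a1 <- rnorm(10); b1 <- rnorm(10, 3)
    hs <- compareGroups(a1, b1, "holm_sidak", alpha = 0.05)
    expect_equal(hs$alpha_adj, 0.05)
    expect_equal(hs$p, t.test(a1, b1)$p.value)
    expect_true(hs$reject)

    # step-down rejections dominate the single-step correction
    for (rep in 1:20) {
      m <- 6
      as <- lapply(1:m, function(i) rnorm(8, mean = sample(0:2, 1)))
      bs <- lapply(1:m, function(i) rnorm(8))
      rHS <- compareGroups(as, bs, "holm_sidak")$reject
      rSB <- compareGroups(as, bs, "sidak_bonferroni")$reject
      expect_true(all(rHS[rSB]))
    }
  })

  deg <- compareGroups(list(rep(1, 5), rnorm(5)), list(rep(1, 5), rnorm(5, 4)))
  expect_true(deg$degenerate[1])
  expect_false(deg$reject[1])
  expect_true(deg$reject[2])
  expect_error(compareGroups(1, 1:5), "at least 2")
})

test_that("particle tracking recovers planted trajectories from rendered video", {
  # a single stationary particle
  one <- TrajectorySet(data.frame(larva_id = "s", t_s = 0:9, x_mm = 10,
                                  z_mm = 20), 40)
  v1 <- renderVideo(one, frameDim = c(41, 21), mmPerPx = 1, noise = 0.5,
                    seed = 2)
  t1 <- trackParticles(v1$frames, 30, maxLinkDistance_px = 3,
                       minTrackLength = 5, mmPerPx = 1)
  s1 <- trajectorySamples(t1)
  expect_equal(length(unique(s1$larva_id)), 1)
  expect_lt(max(abs(s1$x_mm - 10)), 1)
  expect_lt(max(abs(s1$z_mm - 20)), 1.5)

  # all-black frames yield no tracks
  empty <- trackParticles(array(0, c(5, 20, 20)), 10, mmPerPx = 1)
  expect_equal(nrow(trajectorySamples(empty)), 0)

  # 20 non-crossing larvae: positions within 2 px for >= 95% of samples
  tj <- laneTrajectories(20, seed = 9)
  vid <- renderVideo(tj, mmPerPx = 1, noise = 1, seed = 10)
  tk <- trackParticles(vid$frames, 50, maxLinkDistance_px = 5,
                       minTrackLength = 5, mmPerPx = 1, frameInterval_s = 1)
  ts <- trajectorySamples(tk)
  gs <- trajectorySamples(tj)
  m <- merge(ts, gs, by = "t_s", suffixes = c(".tk", ".gt"))
  m <- m[abs(m$x_mm.tk - m$x_mm.gt) < 4, ]   # pair tracks by lane
  expect_gte(nrow(m), 0.95 * nrow(gs))
  err <- sqrt((m$x_mm.tk - m$x_mm.gt)^2 + (m$z_mm.tk - m$z_mm.gt)^2)
  expect_gte(mean(err < 2), 0.95)

  # tracking-then-binning matches truth-based binning within 5%
  ndT <- netDisplacement(tj, c(0, 30))$mean_mm
  ndK <- netDisplacement(tk, c(0, 30))$mean_mm
  expect_lt(abs(ndK - ndT), 0.05 * max(abs(ndT), 1))

  expect_error(trackParticles(vid$frames, 50), "calibration")
})
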