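# Trajectory and morphology estimators against closed forms and generated
# fixtures with known properties.

test_that("MSD matches closed forms on canonical tracks", {
  # stationary track: identically zero
  still <- data.frame(t = seq(0, 990, 10), x = 3, y = -2)
  expect_true(all(msd(still)$msd == 0))
  # ballistic: MSD = v^2 tau^2, exponent 2 exactly
  v <- 0.07
  tr <- syntheticTrack("ballistic", n = 500, dt = 10, speed = v)
  m <- msd(tr)
  expect_equal(m$msd, v^2 * m$tau^2, tolerance = 1e-12)
  f <- fitMsdExponent(m)
  expect_equal(f$alpha, 2, tolerance = 1e-10)
  # diffusive fixture: exponent 1 within the fit uncertainty
  trb <- syntheticTrack("brownian", n = 4000, dt = 10, D = 0.05, seed = 5)
  fb <- fitMsdExponent(msd(trb, lags = 10 * (1:40)))
  expect_equal(fb$alpha, 1, tolerance = 0.12)
  # and the diffusion coefficient is recovered from the amplitude: 4 D tau
  expect_equal(fb$A, 4 * 0.05, tolerance = 0.2)
})

test_that("windowed classification applies both directedness criteria", {
  # ballistic: high alpha, tiny spread of velocity angles -> directed
  tr <- syntheticTrack("ballistic", n = 121, dt = 10, speed = 0.05)
  la <- localAlpha(tr, window = 300)
  expect_equal(la$alpha, rep(2, nrow(la)), tolerance = 0.01)
  expect_true(all(la$dphi < 0.05))
  expect_true(all(la$label == "directed"))
  # Brownian: alpha near 1, wide angles -> random
  trb <- syntheticTrack("brownian", n = 301, dt = 10, D = 0.05, seed = 2)
  lb <- localAlpha(trb, window = 300)
  expect_true(mean(lb$label == "random") > 0.8)
  expect_gt(mean(lb$dphi, na.rm = TRUE), 0.9)
  # smooth circular arc turning ~3.5 rad per window: locally still
  # super-diffusive (alpha > 1.7 over the fitted lags) but the angular
  # dispersion fails the dphi < 0.9 criterion -> random by the joint rule
  n <- 121
  heading <- (3.5 / 30) * (0:(n - 2))
  zig <- data.frame(t = 10 * (0:(n - 1)),
                    x = cumsum(c(0, cos(heading))) * 0.6,
                    y = cumsum(c(0, sin(heading))) * 0.6)
  lz <- localAlpha(zig, window = 300)
  expect_true(all(lz$alpha > 1.7))
  expect_true(all(lz$dphi > 0.9))
  expect_true(all(lz$label == "random"))
  # zero-displacement window is flagged and random
  still <- data.frame(t = seq(0, 310, 10), x = 1, y = 1)
  ls <- localAlpha(still, window = 300)
  expect_true(all(ls$flagged))
  expect_true(all(ls$label == "random"))
})

test_that("piecewise fixtures are relabelled with high window accuracy", {
  tr <- syntheticTrack("piecewise", n = 1801, dt = 10, speed = 0.05,
                       D = 0.04, segment_len = 90, seed = 3)
  la <- localAlpha(tr, window = 300)
  # window truth from the fixture's per-frame labels (windows are 30 frames,
  # segments 90 frames, so most windows are pure)
  per <- 30
  truth <- vapply(seq_len(nrow(la)), function(w) {
    idx <- ((w - 1) * per + 1):(w * per + 1)
    names(which.max(table(tr$truth[idx])))
  }, "")
  pred <- ifelse(la$label == "directed", "ballistic", "brownian")
  expect_gte(mean(pred == truth), 0.95)
})

test_that("global and windowed exponents agree when one window spans all", {
  tr <- syntheticTrack("wlc", n = 121, dt = 10, Lp = 500, step = 0.5, seed = 9)
  la <- localAlpha(tr, window = 1200)
  g <- fitMsdExponent(msd(tr, lags = 10 * (1:40)), c(10, 400))
  expect_equal(la$alpha[1], g$alpha, tolerance = 0.1)
})

test_that("persistence length estimator recovers generator parameters", {
  # worm-like-chain fixture with known Lp
  tr <- syntheticTrack("wlc", n = 10000, dt = 10, Lp = 30, step = 0.3,
                       seed = 4)
  lp <- persistenceLength(tr)
  expect_equal(lp, 30, tolerance = 0.15)
  # straight path: only a lower bound, the path length
  trs <- syntheticTrack("ballistic", n = 500, dt = 10, speed = 0.05)
  lps <- persistenceLength(trs)
  expect_true(isTRUE(attr(lps, "lower_bound")))
  expect_equal(as.numeric(lps), 0.05 * 10 * 499, tolerance = 1e-6)
  # uncorrelated headings: persistence collapses to the single-step scale
  set.seed(6)
  nw <- 2000
  ang <- runif(nw, 0, 2 * pi)
  trw <- data.frame(t = 10 * (0:nw),
                    x = cumsum(c(0, cos(ang))), y = cumsum(c(0, sin(ang))))
  lpw <- persistenceLength(trw)
  expect_lt(as.numeric(lpw), 2) # below two step lengths
})

test_that("polarity angle reproduces the constructed geometry", {
  n <- 11
  base <- data.frame(t = 10 * (0:(n - 1)), x = 0.05 * 10 * (0:(n - 1)), y = 0)
  along <- transform(base, cx = x + 1, cy = 0, nx = x, ny = 0)
  expect_equal(polarityAngle(along)$theta, rep(0, n - 2), tolerance = 1e-9)
  perp <- transform(base, cx = x, cy = 1, nx = x, ny = 0)
  expect_equal(polarityAngle(perp)$theta, rep(90, n - 2), tolerance = 1e-9)
  anti <- transform(base, cx = x - 1, cy = 0, nx = x, ny = 0)
  expect_equal(polarityAngle(anti)$theta, rep(180, n - 2), tolerance = 1e-9)
  # frames below the speed floor are excluded
  slow <- along
  slow$x <- slow$x / 1e4
  slow$cx <- slow$x + 1
  slow$nx <- slow$x
  expect_equal(nrow(polarityAngle(slow, v_floor = 1e-3)), 0)
})

test_that("morphology metrics match closed forms", {
  p <- fast_params()
  st <- initialState(p)
  m <- morphology(st, Rcell = p$Rcell)
  n <- p$n_mem_beads
  expect_equal(m$area_ratio, (n / (2 * pi)) * sin(2 * pi / n), tolerance = 1e-12)
  expect_equal(m$aspect_ratio, 1, tolerance = 1e-6)
  expect_equal(m$d_nuc_center, 0, tolerance = 1e-9)
  expect_equal(m$d_cen_center, p$Rnuc + 1, tolerance = 1e-9)
  # 2:1 ellipse sampling: gyration aspect ratio equals the axis ratio
  th <- 2 * pi * (0:199) / 200
  ell <- st
  ell$membrane <- cbind(6 * cos(th), 3 * sin(th))
  me <- morphology(ell, Rcell = p$Rcell)
  expect_equal(me$aspect_ratio, 2, tolerance = 0.01)
})

test_that("channel-choice statistics partition runs", {
  entries <- data.frame(
    channel = c(rep("w8", 9), "w6", NA, NA),
    time = c(seq(1000, 1800, by = 100), 2500, NA, NA))
  s <- channelChoiceStats(entries, labels = c("w2", "w4", "w6", "w8"))
  expect_equal(sum(s$fractions), 1)
  expect_equal(unname(s$fractions["w8"]), 9 / 12)
  expect_equal(unname(s$fractions["w2"]), 0)
  expect_equal(unname(s$fractions["censored"]), 2 / 12)
  expect_equal(s$entry_time$n, 10)
  expect_equal(s$entry_time$mean, mean(c(seq(1000, 1800, 100), 2500)))
})
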