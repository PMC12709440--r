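# Confinement geometries, entry scoring, chemotactic bias.

test_that("obstacle park builds the documented lattice", {
  env <- obstaclePark(Robs = 4, spacing = 20, extent = 100)
  ob <- env$obstacles
  expect_equal(nrow(ob), 36) # 6 x 6
  expect_equal(sort(unique(ob$x)), c(-50, -30, -10, 10, 30, 50))
  # minimum surface-to-surface gap
  d <- as.matrix(dist(ob[, c("x", "y")]))
  diag(d) <- Inf
  expect_equal(min(d) - 2 * 4, 12)
  env5 <- obstaclePark(Robs = 5, spacing = 20, extent = 100)
  d5 <- as.matrix(dist(env5$obstacles[, c("x", "y")]))
  diag(d5) <- Inf
  expect_equal(min(d5) - 2 * 5, 10)
  expect_error(obstaclePark(Robs = 4, spacing = 7), "exceed")
  # signed distance: an obstacle centre lies at depth -Robs
  expect_equal(envDistance(c(ob$x[1], ob$y[1]), env), -4)
  # builders are pure
  expect_identical(env, obstaclePark(Robs = 4, spacing = 20, extent = 100))
})

test_that("equal-width Y-junction is mirror symmetric about the stem axis", {
  env <- yJunction(w_left = 10, w_right = 10)
  w <- env$walls
  flipped <- data.frame(x1 = w$x1, y1 = -w$y1, x2 = w$x2, y2 = -w$y2)
  key <- function(d) sort(apply(round(cbind(
    pmin(d$x1, d$x2), pmin(d$y1, d$y2),
    pmax(d$x1, d$x2), pmax(d$y1, d$y2)), 9), 1, paste, collapse = ","))
  expect_equal(key(w), key(flipped))
  # a point on the stem axis sits half the stem width from the walls
  expect_equal(envDistance(c(-10, 0), env), 5 - env$wall_half)
  # channel mouths are mirror images
  ch <- env$channels
  expect_equal(ch$my[1], -ch$my[2])
  expect_equal(ch$dy[1], -ch$dy[2])
})

test_that("asymmetric Y-junction carries the requested widths", {
  env <- yJunction(w_left = 10, w_right = 6)
  expect_equal(env$channels$width, c(10, 6))
  expect_false(isTRUE(all.equal(env$channels$my[1], -env$channels$my[2])))
})

test_that("multi-channel device exposes one labelled mouth per width", {
  env <- multiChannel(c(2, 4, 6, 8))
  expect_equal(env$channels$width, c(2, 4, 6, 8))
  expect_equal(env$channels$label, c("w2", "w4", "w6", "w8"))
  # feeder chamber spans all the mouths with margin
  hw <- max(abs(env$walls$y1), abs(env$walls$y2))
  expect_gte(2 * hw, sum(env$channels$width) + 3 * 4)
  # degenerate single channel
  env1 <- multiChannel(10)
  expect_equal(nrow(env1$channels), 1)
})

test_that("channel entry requires every bead to pass the mouth by the depth", {
  env <- multiChannel(c(6, 8), septum = 8, channel_len = 40)
  p <- fast_params()
  st <- initialState(p, env = freeSpace())
  ch <- env$channels
  # place the whole cell 5.1 um past the mouth of channel 2 (scaled down)
  st$membrane <- ngon(p$n_mem_beads, 2, center = c(ch$mx[2] + 7.1, ch$my[2]))
  st$nucleus <- ngon(p$n_nuc_beads, 1, center = c(ch$mx[2] + 7.1, ch$my[2]))
  expect_equal(channelEntry(st, env, depth = 5), "w8")
  # one bead short of the line: no entry
  st2 <- st
  st2$membrane[1, ] <- c(ch$mx[2] + 4.9, ch$my[2])
  expect_true(is.na(channelEntry(st2, env, depth = 5)))
  # cell still in the feeder chamber: no entry
  st3 <- st
  st3$membrane <- ngon(p$n_mem_beads, 2, center = c(-10, 0))
  expect_true(is.na(channelEntry(st3, env, depth = 5)))
})

test_that("chemotactic bias translates an isolated cell rigidly", {
  p <- cellParams(Nmt = 0, v_prot0 = 0, f_contr0 = 0, v_chemo = 0.05,
                  t_total = 100, record_every = 10, seed = 2,
                  dynein = list(rho_cortex = 0, rho_nuc = 0))
  run <- simulateCell(p) # free space, bias along +x
  tr <- run$track
  n <- nrow(tr)
  # the biased membrane tows the passive nucleus through the coupling, so
  # the steady translation speed is the drag-weighted share of v_chemo
  v <- (tr$x[n] - tr$x[n - 5]) / (tr$t[n] - tr$t[n - 5])
  p_ <- p
  v_pred <- 0.05 * (p_$n_mem_beads * p_$gamma_mem) /
    (p_$n_mem_beads * p_$gamma_mem + p_$n_nuc_beads * p_$gamma_nuc)
  expect_equal(v, v_pred, tolerance = 0.05)
  # the bias itself is divergence-free; the only area change is the slow
  # ovalization from towing the nucleus, bounded over the run
  expect_lt(abs(tr$area[n] - tr$area[1]) / tr$area[1], 0.05)
  expect_equal(tr$y[n], 0, tolerance = 1e-6)
})

test_that("environment round-trips through its YAML serialization", {
  for (env in list(obstaclePark(4, 20, 60), yJunction(10, 6),
                   multiChannel(c(4, 8)))) {
    f <- tempfile(fileext = ".yaml")
    writeEnv(env, f)
    back <- readEnv(f)
    expect_equal(back$obstacles, env$obstacles)
    expect_equal(back$walls, env$walls)
    expect_equal(back$channels$label, env$channels$label)
    expect_equal(back$chemo_dir, env$chemo_dir)
    unlink(f)
  }
})
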