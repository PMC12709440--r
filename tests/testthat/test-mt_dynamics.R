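# Dynamic instability: switching statistics, tip bookkeeping, length law,
# and filament mechanics.

test_that("free filament mean length matches the two-state stationary law", {
  p <- cellParams(lmt_target = 9.3)
  # a small population of independent filaments, 1e5 s each (the stationary
  # length sd equals the mean, so a lone filament is noisy at the 4% level)
  lbar_sim <- mean(vapply(1:6, function(s) {
    mean(freeMtLengths(p, t_max = 1e5, seed = s, sample_every = 2))
  }, numeric(1)))
  target <- p$vg * p$vs / (p$fc * p$vs - p$fr * p$vg)
  expect_equal(target, 9.3)
  expect_equal(lbar_sim, target, tolerance = 0.05)
  # and agrees with the independent event-driven oracle
  lbar_or <- mean(vapply(1:6, function(s) {
    two_state_oracle(p$vg, p$vs, p$fc, p$fr, t_max = 1e5, seed = s)
  }, numeric(1)))
  expect_equal(lbar_sim, lbar_or, tolerance = 0.05)
})

test_that("switching probabilities follow the exponential waiting law", {
  # binomial check of the per-step catastrophe fraction: simulate one long
  # run and count growth-phase terminations per growth step
  pp <- cellParams(lmt_target = 10, dt = 0.01)
  lens <- freeMtLengths(pp, t_max = 2000, seed = 5, sample_every = 0.01)
  d <- diff(lens)
  # growth steps add vg*dt, shrink steps remove vs*dt
  grow_steps <- sum(abs(d - pp$vg * pp$dt) < 1e-9)
  shrink_after_grow <- sum(abs(d[-length(d)] - pp$vg * pp$dt) < 1e-9 &
                             d[-1] < 0)
  fc <- cellParams(lmt_target = 10)$fc
  phat <- shrink_after_grow / grow_steps
  p_theory <- 1 - exp(-fc * 0.01)
  se <- sqrt(p_theory * (1 - p_theory) / grow_steps)
  expect_lt(abs(phat - p_theory), 4 * se)
})

test_that("rescue-free shrink phases are deterministic and re-nucleate", {
  # fr = 0: a shrinking filament of length L survives exactly L / vs
  p <- cellParams(fr = 0, lmt_target = 5, dt = 0.01)
  lens <- freeMtLengths(p, t_max = 2e4, seed = 13, sample_every = 0.01)
  # find a shrink phase: from each local maximum, length decreases linearly
  # at vs until (near) zero, then growth resumes from ~0 (re-nucleation)
  drops <- which(diff(lens) < -1e-9)
  expect_gt(length(drops), 100)
  runs <- split(drops, cumsum(c(1, diff(drops) != 1)))
  long_run <- runs[[which.max(lengths(runs))]]
  l0 <- lens[long_run[1]]
  expected_steps <- l0 / (p$vs * p$dt)
  expect_equal(length(long_run), expected_steps, tolerance = 0.02)
  # lengths stay non-negative and the process continues after hitting zero
  expect_true(all(lens >= 0))
  expect_gt(lens[length(lens)], 0)
})

test_that("length distribution over a long free run is exponential", {
  p <- cellParams(lmt_target = 9.3)
  # sparse sampling for near-independence
  lens <- freeMtLengths(p, t_max = 1e6, seed = 17, sample_every = 100)
  expect_gte(length(lens), 1e4)
  ks <- suppressWarnings(stats::ks.test(lens, "pexp", 1 / 9.3))
  expect_gt(ks$p.value, 0.01)
})

test_that("filament count is conserved through re-nucleation", {
  p <- cellParams(Nmt = 15, lmt_target = 2, t_total = 200, seed = 21)
  run <- simulateCell(p)
  expect_length(run$state$mts, 15)
  expect_equal(run$track$n_grow + run$track$n_shrink, rep(15, nrow(run$track)))
})

test_that("an axially loaded filament buckles beyond the Euler threshold", {
  # discrete chain clamped at one end, compressed by an end load; the Euler
  # threshold for a pinned-pinned chain of length L is ~ pi^2 kappa / L^2
  kappa <- 0.5; l0 <- 0.5; nb <- 21
  L <- (nb - 1) * l0
  f_euler <- pi^2 * kappa / L^2
  relax <- function(load, steps = 20000, dt = 0.005) {
    pos <- cbind(seq(0, L, by = l0), 0)
    set.seed(4)
    pos[, 2] <- pos[, 2] + rnorm(nb, 0, 0.03) # seed perturbation
    for (s in seq_len(steps)) {
      f <- stretchForces(pos, ks = 30, rest = l0, closed = FALSE) +
        bendForces(pos, kappa = kappa, rest_angle = 0, rest_bond = l0)
      f[nb, 1] <- f[nb, 1] - load
      f[1, ] <- 0                      # hold the minus end
      f[nb, 2] <- 0                    # keep the load axial (pinned ends)
      pos <- pos + dt * f
    }
    max(abs(pos[, 2]))
  }
  expect_lt(relax(0.3 * f_euler), 0.1)  # subcritical: stays straight
  expect_gt(relax(10 * f_euler), 0.3)   # supercritical: bows out
})
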