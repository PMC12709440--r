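# Force kernels: stretching, bending, WCA sterics, and the time stepper.

test_that("stretch forces follow Hooke's law with reciprocity", {
  # two beads at rest separation: no force
  pos <- rbind(c(0, 0), c(1, 0))
  expect_equal(stretchForces(pos, ks = 10, rest = 1, closed = FALSE),
               matrix(0, 2, 2))
  # stretched by 1 um at ks = 10: 10 pN attraction each, antiparallel
  pos2 <- rbind(c(0, 0), c(2, 0))
  f <- stretchForces(pos2, ks = 10, rest = 1, closed = FALSE)
  expect_equal(f[1, ], c(10, 0))
  expect_equal(f[2, ], c(-10, 0))
  # random ring: internal forces sum to zero (Newton's third law)
  set.seed(1)
  ring <- matrix(rnorm(40), ncol = 2)
  fr <- stretchForces(ring, ks = 3, rest = 0.7, closed = TRUE)
  expect_equal(colSums(fr), c(0, 0), tolerance = 1e-12)
})

test_that("bend forces are the exact gradient of the discrete WLC energy", {
  # straight chain at rest angle zero: no force
  chain <- rbind(c(0, 0), c(1, 0), c(2, 0))
  expect_equal(bendForces(chain, kappa = 2, rest_angle = 0, rest_bond = 1),
               matrix(0, 3, 2))
  # regular polygon ring at its preferred exterior angle: no force
  ring <- ngon(12, 3)
  f0 <- bendForces(ring, kappa = 1, rest_angle = 2 * pi / 12,
                   rest_bond = sqrt(sum((ring[2, ] - ring[1, ])^2)),
                   closed = TRUE)
  expect_lt(max(abs(f0)), 1e-12)
  # bent chain: forces match the central-difference gradient of the energy
  set.seed(7)
  for (rep in 1:3) {
    pos <- matrix(cumsum(rnorm(10, 0.5, 0.3)), ncol = 2) + rnorm(10, 0, 0.2)
    f <- bendForces(pos, kappa = 1.5, rest_angle = 0, rest_bond = 0.5)
    h <- 1e-6
    for (i in seq_len(nrow(pos))) {
      for (d in 1:2) {
        pp <- pos; pp[i, d] <- pp[i, d] + h
        pm <- pos; pm[i, d] <- pm[i, d] - h
        num <- -(bendEnergy(pp, 1.5, 0, 0.5) -
                   bendEnergy(pm, 1.5, 0, 0.5)) / (2 * h)
        expect_equal(f[i, d], num, tolerance = 1e-5)
      }
    }
  }
})

test_that("WCA force matches the closed form and its cutoff", {
  expect_equal(wcaForce(1.13, sigma = 1, eps = 1), 0)           # beyond cutoff
  expect_equal(wcaForce(2^(1 / 6), sigma = 1, eps = 1), 0)      # at the minimum
  expect_equal(wcaForce(1, sigma = 1, eps = 1), 24)             # 24 eps / sigma
  # closed form at an intermediate separation
  r <- 1.05
  expect_equal(wcaForce(r, 1, 1), 24 * (2 / r^13 - 1 / r^7))
  # repulsion grows monotonically as beads approach, then saturates bounded
  expect_warning(f <- wcaForce(seq(1.12, 0.05, by = -0.01), sigma = 1,
                               eps = 1), "overlap")
  expect_true(all(diff(f) >= 0))
  expect_true(all(is.finite(f)))
})

test_that("grid-accelerated steric forces equal brute-force all-pairs", {
  p <- fast_params()
  for (seed in c(1, 2, 3)) {
    st <- random_cloud_state(seed = seed)
    g <- stericForces(st, p, use_grid = TRUE)
    b <- stericForces(st, p, use_grid = FALSE)
    # same pair set; summation order differs, so agreement is to rounding
    expect_equal(g$membrane, b$membrane, tolerance = 1e-12)
    expect_equal(g$nucleus, b$nucleus, tolerance = 1e-12)
    expect_equal(g$mts, b$mts, tolerance = 1e-12)
    expect_equal(g$centrosome, b$centrosome, tolerance = 1e-12)
  }
})

test_that("steric pair forces are internal: reciprocity and isolation", {
  p <- fast_params()
  st <- random_cloud_state(seed = 5)
  f <- stericForces(st, p)
  tot <- colSums(f$membrane) + colSums(f$nucleus) + f$centrosome +
    Reduce(`+`, lapply(f$mts, colSums))
  expect_equal(unname(tot), c(0, 0), tolerance = 1e-9)
  # an isolated relaxed cell has no steric force anywhere
  st0 <- initialState(p)
  f0 <- stericForces(st0, p)
  expect_equal(max(abs(f0$membrane)), 0)
  expect_equal(max(abs(f0$nucleus)), 0)
})

test_that("a perturbed passive cell relaxes to a circle with decaying energy", {
  # crosstalk and motors off, no MTs: pure elastic relaxation
  p <- cellParams(Nmt = 0, v_prot0 = 0, f_contr0 = 0, t_total = 400,
                  record_every = 10, seed = 2,
                  dynein = list(rho_cortex = 0, rho_nuc = 0))
  st <- initialState(p)
  set.seed(9)
  st$membrane <- st$membrane * (1 + 0.1 * sin(4 * atan2(st$membrane[, 2],
                                                        st$membrane[, 1])))
  run <- simulateCell(p, state = st, with_energy = TRUE, check_forces = TRUE)
  e <- run$track$energy
  expect_true(all(diff(e) <= 1e-9))
  expect_lt(run$track$aspect[nrow(run$track)], 1.02)
  expect_lt(run$diag$max_internal_force_sum, 1e-9)
})

test_that("the stepper guards against oversized displacements", {
  # a pathological spring constant would move beads too far in one step:
  # the validator rejects it before the engine can run
  expect_error(cellParams(ks_mem = 1e5), "timestep")
  # an absurdly stretched bond yanks its bead too far in one step
  p <- fast_params()
  st <- initialState(p)
  st$membrane[3, ] <- st$membrane[3, ] + c(40, 0)
  expect_error(
    suppressWarnings(simulateCell(p, state = st, t_total = 5)),
    "timestep too large")
})
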