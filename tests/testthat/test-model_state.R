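# Parameter registry, catastrophe-rate derivation, and state construction.

test_that("catastrophe rate reproduces the target mean length", {
  # fr = 0 limit: fc = vg / lmt
  expect_equal(catastropheRate(0.1, 0.2, 0, 9.3), 0.1 / 9.3)
  # general case satisfies the stationary-mean relation exactly
  fc <- catastropheRate(0.1, 0.2, 0.04, 9.3)
  expect_equal(0.1 * 0.2 / (fc * 0.2 - 0.04 * 0.1), 9.3)
  # monotone limit: infinite target length drives fc to the boundary
  expect_lt(abs(catastropheRate(0.1, 0.2, 0, 1e9)), 1e-9)
  expect_error(catastropheRate(0.1, 0.2, 0.04, -3))
})

test_that("derived catastrophe rate verified against an event-driven oracle", {
  p <- cellParams(lmt_target = 9.3)
  # independent continuous-time simulation of the same two-state process
  lbar <- two_state_oracle(p$vg, p$vs, p$fc, p$fr, t_max = 2e5, seed = 7)
  expect_equal(lbar, 9.3, tolerance = 0.06)
})

test_that("parameter validation enforces the physical regime", {
  expect_error(cellParams(vg = -1), "positive")
  expect_error(cellParams(dt = 10), "timestep")
  expect_error(cellParams(Rnuc = 8), "below cell radius")
  expect_error(cellParams(nonsense = 1), "unknown parameter")
  expect_error(cellParams(dynein = list(bogus = 2)), "unknown dynein")
  # overriding dynein keeps unnamed entries at their defaults
  p <- cellParams(dynein = list(k_on = 3))
  expect_equal(p$dynein$k_on, 3)
  expect_equal(p$dynein$k_off, cellParams()$dynein$k_off)
})

test_that("provenance table covers every constant with units", {
  prov <- paramProvenance()
  expect_true(all(c("Rcell", "fr", "dynein.v_motor", "fc") %in% prov$name))
  expect_true(all(prov$provenance %in% c("printed", "reconstructed", "derived")))
  expect_false(any(prov$unit == ""))
})

test_that("initial state geometry matches the registered radii", {
  p <- fast_params()
  st <- initialState(p)
  # regular-polygon area: (n/2pi) sin(2pi/n) R^2 * pi R^2, within 1% of disc
  n <- p$n_mem_beads
  area <- abs(sum(st$membrane[, 1] * st$membrane[c(2:n, 1), 2] -
                    st$membrane[c(2:n, 1), 1] * st$membrane[, 2]) / 2)
  expect_equal(area, (n / (2 * pi)) * sin(2 * pi / n) * p$Rcell^2 * pi,
               tolerance = 1e-12)
  expect_lt(abs(area - pi * p$Rcell^2) / (pi * p$Rcell^2), 0.01)
  expect_equal(unname(st$centrosome), c(p$Rnuc + 1, 0))
  expect_length(st$mts, p$Nmt)
  expect_true(all(mtLengths(st, p) <= p$sigma_mt))
  expect_true(all(vapply(st$mts, function(m) m$state, "") == "GROW"))
})

test_that("state construction is deterministic given the seed", {
  a <- initialState(fast_params())
  b <- initialState(fast_params())
  expect_identical(a, b)
  c2 <- initialState(fast_params(seed = 43))
  expect_false(identical(a$mts[[1]]$dir, c2$mts[[1]]$dir))
})

test_that("containment of the initial centrosome is enforced", {
  expect_error(initialState(cellParams(Rnuc = 5.8, Rcell = 7)), "fit inside")
})

test_that("state validation catches broken invariants", {
  p <- fast_params()
  st <- initialState(p)
  bad <- st
  bad$mts[[1]]$beads[1, ] <- c(99, 99)
  expect_error(validateState(bad, p), "anchored")
  bad2 <- st
  bad2$motors <- rbind(st$motors, st$motors[1, ])
  expect_error(validateState(bad2, p), "duplicate")
})
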