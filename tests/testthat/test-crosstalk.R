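# Tip-signal field and the crosstalk rules.

test_that("tip counts match a brute-force double loop", {
  set.seed(8)
  mem <- ngon(60, 7)
  tips <- matrix(runif(60, -8, 8), ncol = 2)
  states <- sample(c("GROW", "SHRINK"), 30, replace = TRUE)
  sig <- tipSignals(mem, tips, states, r_signal = 1.5)
  for (i in seq_len(nrow(mem))) {
    d <- sqrt((tips[, 1] - mem[i, 1])^2 + (tips[, 2] - mem[i, 2])^2)
    expect_equal(sig$n_grow[i], sum(d < 1.5 & states == "GROW"))
    expect_equal(sig$n_shrink[i], sum(d < 1.5 & states == "SHRINK"))
  }
})

test_that("a tip near two beads is counted by both", {
  mem <- ngon(100, 7)
  # place a growing tip equidistant from beads 1 and 2, inside r_signal
  mid <- (mem[1, ] + mem[2, ]) / 2
  sig <- tipSignals(mem, rbind(mid), "GROW", r_signal = 1)
  expect_equal(sig$n_grow[1], 1)
  expect_equal(sig$n_grow[2], 1)
})

test_that("signal locality: crossing the radius only flips marginal beads", {
  mem <- ngon(80, 7)
  r <- 1.2
  eps <- 1e-4
  base <- mem[1, ] + c(r - eps, 0) * 0 # build a tip at distance r -+ eps
  dir <- c(1, 0)
  tip_in <- rbind(mem[1, ] + (r - eps) * dir)
  tip_out <- rbind(mem[1, ] + (r + eps) * dir)
  a <- tipSignals(mem, tip_in, "GROW", r)
  b <- tipSignals(mem, tip_out, "GROW", r)
  changed <- which(a$n_grow != b$n_grow)
  # only beads whose distance to the tip is within ~2 eps of the threshold
  for (i in changed) {
    d <- sqrt(sum((tip_in[1, ] - mem[i, ])^2))
    expect_lt(abs(d - r), 10 * eps)
  }
})

test_that("outward normals are unit length and point out of the polygon", {
  mem <- ngon(50, 5, center = c(2, -1))
  sig <- tipSignals(mem, matrix(numeric(0), ncol = 2), integer(0), 1)
  nrm <- sig$normals
  expect_equal(sqrt(rowSums(nrm^2)), rep(1, 50), tolerance = 1e-12)
  # a short step along the normal leaves the polygon
  outside <- vapply(seq_len(50), function(i) {
    !mtmigrate:::.point_in_polygon(mem[i, ] + 0.2 * nrm[i, ], mem)
  }, logical(1))
  expect_true(all(outside))
  # winding direction must not matter
  sig2 <- tipSignals(mem[50:1, ], matrix(numeric(0), ncol = 2), integer(0), 1)
  expect_equal(sig2$normals[50:1, ], nrm, tolerance = 1e-12)
})

test_that("symmetric shrinking-tip ring produces no net contraction", {
  mem <- ngon(60, 7)
  tips <- ngon(60, 6.5) # one shrinking tip under each bead
  sig <- tipSignals(mem, tips, rep("SHRINK", 60), r_signal = 1)
  f_contr0 <- 0.25
  f <- -f_contr0 * sig$n_shrink * sig$normals
  expect_equal(colSums(f), c(0, 0), tolerance = 1e-9)
  expect_true(all(sig$n_shrink > 0))
})

test_that("nucleus-membrane coupling holds the rest spacing and reciprocity", {
  # a passive cell (no MTs, no signals) started at rest stays at rest:
  # all coupling springs sit at their rest length by construction
  p <- cellParams(Nmt = 0, v_prot0 = 0, f_contr0 = 0, t_total = 20,
                  record_every = 5, seed = 1,
                  dynein = list(rho_cortex = 0, rho_nuc = 0))
  run <- simulateCell(p, check_forces = TRUE, with_energy = TRUE)
  tr <- run$track
  expect_lt(max(abs(tr$x)), 1e-9)
  expect_lt(diff(range(tr$area)), 1e-6)
  expect_lt(run$diag$max_internal_force_sum, 1e-9)
  # displacing the nucleus pulls it back through the coupling springs
  st <- initialState(p)
  st$nucleus <- st$nucleus + rep(c(0.8, 0), each = nrow(st$nucleus))
  run2 <- simulateCell(p, state = st, t_total = 200)
  n_end <- nrow(run2$track)
  # the relative nucleus-membrane offset decays (the common drift is set by
  # drag weighting and is not restored by internal forces)
  expect_lt(abs(run2$track$nx[n_end] - run2$track$x[n_end]), 0.1)
})
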