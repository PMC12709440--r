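# Shared helpers: small, fast parameter sets and geometry constructors used
# across the suite. Everything is generated in code; no stored fixtures.

fast_params <- function(...) {
  cellParams(Nmt = 20, t_total = 50, record_every = 5, seed = 42, ...)
}

# regular n-gon helper mirroring the package's initial geometry
ngon <- function(n, r, center = c(0, 0)) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind(x = center[1] + r * cos(th), y = center[2] + r * sin(th))
}

# random bead cloud state for steric tests: membrane/nucleus/MTs scattered in
# a box, built as a plausible cellState-shaped list
random_cloud_state <- function(n_mem = 60, n_nuc = 30, n_mt = 8,
                               mt_beads = 12, box = 12, seed = 1) {
  set.seed(seed)
  cen <- runif(2, -1, 1)
  mts <- lapply(seq_len(n_mt), function(i) {
    start <- cen
    dir <- runif(1, 0, 2 * pi)
    steps <- cbind(cos(dir + cumsum(rnorm(mt_beads - 1, 0, 0.25))),
                   sin(dir + cumsum(rnorm(mt_beads - 1, 0, 0.25)))) * 0.5
    beads <- rbind(start, start + apply(steps, 2, cumsum))
    colnames(beads) <- c("x", "y")
    list(beads = beads, state = sample(c("GROW", "SHRINK"), 1),
         partial = runif(1, 0, 0.49), dir = dir)
  })
  st <- list(
    membrane = matrix(runif(2 * n_mem, -box, box), ncol = 2,
                      dimnames = list(NULL, c("x", "y"))),
    nucleus = matrix(runif(2 * n_nuc, -box, box), ncol = 2,
                     dimnames = list(NULL, c("x", "y"))),
    centrosome = cen, mts = mts,
    motors = data.frame(loop = integer(), bead = integer(),
                        bound = logical(), mt = integer(), arc = numeric()),
    t = 1, rng_mt = "", rng_motor = "")
  class(st) <- "cellState"
  st
}

# event-driven oracle for the two-state filament length process with
# reflection (re-nucleation) at zero length; independent of the engine's
# per-step bookkeeping
two_state_oracle <- function(vg, vs, fc, fr, t_max, seed) {
  set.seed(seed)
  t <- 0; len <- 0; grow <- TRUE
  tot_len_time <- 0
  while (t < t_max) {
    rate <- if (grow) fc else fr
    tau <- if (rate > 0) rexp(1, rate) else Inf
    if (!grow && len / vs < tau) {
      # hits zero before rescue: integrate the shrink, re-nucleate
      dtau <- len / vs
      tot_len_time <- tot_len_time + len * dtau - 0.5 * vs * dtau^2
      t <- t + dtau
      len <- 0; grow <- TRUE
      next
    }
    tau <- min(tau, t_max - t)
    v <- if (grow) vg else -vs
    tot_len_time <- tot_len_time + len * tau + 0.5 * v * tau^2
    len <- len + v * tau
    t <- t + tau
    grow <- !grow
  }
  tot_len_time / t_max # time-averaged mean length
}
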