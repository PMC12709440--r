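# Synthetic trajectory generators with known statistical properties, used to
# validate the analysis estimators and available from the command line for
# the same purpose.

#' Synthetic trajectories with known properties
#'
#' Generates centroid tracks whose MSD exponent, persistence length or
#' segment structure is known by construction:
#' \describe{
#'   \item{ballistic}{straight motion at constant `speed`; MSD
#'     `= speed^2 * tau^2` (exponent 2).}
#'   \item{brownian}{isotropic random walk with diffusion coefficient `D`;
#'     MSD `= 4 * D * tau` (exponent 1).}
#'   \item{wlc}{worm-like-chain path: constant step length with heading
#'     increments of variance `2 * step / Lp`, so the tangent correlation
#'     decays as `exp(-s / Lp)` over contour distance `s`.}
#'   \item{piecewise}{alternating ballistic and Brownian segments
#'     (`segment_len` frames each, ballistic first); the true per-frame
#'     label is attached as column `truth`.}
#' }
#'
#' @param type one of `"ballistic"`, `"brownian"`, `"wlc"`, `"piecewise"`.
#' @param n number of frames.
#' @param dt sampling interval (s).
#' @param speed ballistic speed (um/s).
#' @param D diffusion coefficient (um^2/s).
#' @param Lp worm-like-chain persistence length (um).
#' @param step worm-like-chain step length (um).
#' @param segment_len frames per piecewise segment.
#' @param seed RNG seed.
#' @return data.frame with `t`, `x`, `y` (plus `truth` for `"piecewise"`).
#' @export
syntheticTrack <- function(type = c("ballistic", "brownian", "wlc",
                                    "piecewise"),
                           n = 1000, dt = 10, speed = 0.05, D = 0.05,
                           Lp = 30, step = 0.3, segment_len = 60, seed = 1) {
  type <- match.arg(type)
  t <- dt * (seq_len(n) - 1)
  set.seed(seed)
  switch(type,
    ballistic = data.frame(t = t, x = speed * t, y = 0),
    brownian = {
      sdd <- sqrt(2 * D * dt)
      data.frame(t = t, x = cumsum(c(0, stats::rnorm(n - 1, 0, sdd))),
                 y = cumsum(c(0, stats::rnorm(n - 1, 0, sdd))))
    },
    wlc = {
      dphi <- stats::rnorm(n - 1, 0, sqrt(2 * step / Lp))
      phi <- cumsum(c(0, dphi))[seq_len(n - 1)]
      data.frame(t = t, x = cumsum(c(0, step * cos(phi))),
                 y = cumsum(c(0, step * sin(phi))))
    },
    piecewise = {
      seg <- ((seq_len(n - 1) - 1) %/% segment_len) %% 2 # 0 ballistic
      sdd <- sqrt(2 * D * dt)
      heading <- stats::runif(1, 0, 2 * pi)
      dx <- ifelse(seg == 0, speed * dt * cos(heading),
                   stats::rnorm(n - 1, 0, sdd))
      dy <- ifelse(seg == 0, speed * dt * sin(heading),
                   stats::rnorm(n - 1, 0, sdd))
      data.frame(t = t, x = cumsum(c(0, dx)), y = cumsum(c(0, dy)),
                 truth = c("ballistic",
                           ifelse(seg == 0, "ballistic", "brownian")))
    })
}
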