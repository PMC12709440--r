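# Simulation driver and the free-filament length process.

# internal: flatten S3 wrappers into the plain lists the engine expects
.cpars <- function(params) unclass(params)
.cenv <- function(env) unclass(env)

#' Run a whole-cell migration simulation
#'
#' Advances the full model from an initial (or resumed) state with the
#' forward Euler overdamped scheme `x(t + dt) = x(t) + dt * (F/gamma +
#' v_active)`. Per step: MT dynamic-instability switching and tip advance,
#' tip-signal field, passive elastic and steric forces, nucleus-membrane
#' coupling, dynein attachment/stepping, protrusion and contraction signals,
#' chemotactic bias, then the Euler update with the MT minus ends re-pinned
#' to the centrosome. A fixed seed gives bit-identical output; a bead
#' displacement above `0.5 * sigma_mt` in one step or a bead penetrating an
#' obstacle/wall aborts with a "timestep too large" error.
#'
#' @param params a [cellParams()] object (`t_total`, `dt`, `record_every` are
#'   taken from it unless overridden here).
#' @param env a `cellEnv` (default free space).
#' @param state optional `cellState` to resume from (default: a fresh
#'   [initialState()]).
#' @param t_total,record_every optional overrides (s).
#' @param check_forces track the largest per-step residual of the summed
#'   internal forces (diagnostic; small cost).
#' @param with_energy record total passive elastic energy each frame.
#' @param stop_on_entry stop as soon as the whole cell is `entry_depth` um
#'   inside any labelled channel.
#' @param entry_depth channel entry criterion (um).
#' @return an object of class `cellRun`: list with `track` (data.frame, one
#'   row per recorded frame: time, cell centroid, centrosome, nucleus centre,
#'   area, aspect ratio, growing/shrinking MT counts, protrusion resultant,
#'   energy, and per-channel penetration depths), `state` (final
#'   `cellState`), `params`, `env` and `diag`.
#' @examples
#' \donttest{
#' p <- cellParams(Nmt = 30, t_total = 100, seed = 7)
#' run <- simulateCell(p)
#' head(run$track)
#' }
#' @export
simulateCell <- function(params, env = freeSpace(), state = NULL,
                         t_total = NULL, record_every = NULL,
                         check_forces = FALSE, with_energy = FALSE,
                         stop_on_entry = FALSE, entry_depth = 5) {
  validateParams(params)
  if (is.null(state)) state <- initialState(params, env)
  ctrl <- list(
    t_total = if (is.null(t_total)) params$t_total else t_total,
    record_every = if (is.null(record_every)) params$record_every
                   else record_every,
    check_forces = check_forces, stop_on_entry = stop_on_entry,
    entry_depth = entry_depth, with_energy = with_energy)
  res <- cpp_simulate(unclass(state), .cpars(params), .cenv(env), ctrl)
  track <- as.data.frame(res$track)
  st <- res$state
  st$membrane <- `colnames<-`(st$membrane, c("x", "y"))
  st$nucleus <- `colnames<-`(st$nucleus, c("x", "y"))
  class(st) <- "cellState"
  out <- list(track = track, state = st, params = params, env = env,
              diag = res$diag)
  class(out) <- "cellRun"
  out
}

#' @export
print.cellRun <- function(x, ...) {
  tr <- x$track
  n <- nrow(tr)
  disp <- sqrt((tr$x[n] - tr$x[1])^2 + (tr$y[n] - tr$y[1])^2)
  cat(sprintf("cellRun: %d frames over %g s (%s environment)\n",
              n, tr$t[n] - tr$t[1], x$env$kind))
  cat(sprintf("  net centroid displacement %.2f um; final area %.1f um^2, aspect %.2f\n",
              disp, tr$area[n], tr$aspect[n]))
  if (isTRUE(x$diag$entered)) cat("  stopped on channel entry\n")
  invisible(x)
}

#' Free-filament two-state length process
#'
#' Runs the dynamic-instability length bookkeeping of a single unconstrained
#' microtubule (no walls, no forces): growth at `vg`, shrinkage at `vs`,
#' catastrophe at `fc`, rescue at `fr`, discrete beads of spacing `sigma_mt`
#' with a sub-bead growth accumulator, and re-nucleation on shrinking to the
#' seed bead. Uses the exact per-step switching code of the full engine.
#'
#' @param params a `cellParams` object (`vg`, `vs`, `fc`, `fr`, `sigma_mt`,
#'   `dt` are used).
#' @param t_max simulated time (s).
#' @param seed RNG seed.
#' @param sample_every sampling cadence of the returned lengths (s).
#' @return numeric vector of filament lengths (um).
#' @examples
#' p <- cellParams()
#' l <- freeMtLengths(p, t_max = 1e4, seed = 1)
#' mean(l) # close to p$lmt_target
#' @export
freeMtLengths <- function(params, t_max = 1e5, seed = params$seed,
                          sample_every = 1) {
  cpp_free_mt(params$vg, params$vs, params$fc, params$fr, params$dt, t_max,
              params$sigma_mt, as.integer(seed), sample_every)
}
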