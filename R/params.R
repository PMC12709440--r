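# Parameter registry: every model constant with units, defaults and
# provenance ("printed" = stated in the source experiments/model description,
# "reconstructed" = chosen here to reproduce the qualitative regimes).

.param_registry <- function() {
  list(
    Rcell        = list(default = 7,    unit = "um",       prov = "printed",
                        desc = "initial cell radius"),
    Rnuc         = list(default = 3,    unit = "um",       prov = "printed",
                        desc = "initial nucleus radius"),
    n_mem_beads  = list(default = 100,  unit = "count",    prov = "reconstructed",
                        desc = "membrane beads"),
    n_nuc_beads  = list(default = 50,   unit = "count",    prov = "reconstructed",
                        desc = "nucleus beads"),
    Nmt          = list(default = 100,  unit = "count",    prov = "printed",
                        desc = "number of microtubules (studied range 25-200)"),
    lmt_target   = list(default = 9.3,  unit = "um",       prov = "printed",
                        desc = "target mean MT length (3, 9.3 or 16 studied)"),
    sigma_mt     = list(default = 0.5,  unit = "um",       prov = "printed",
                        desc = "MT bead spacing / steric diameter"),
    vg           = list(default = 0.25, unit = "um/s",     prov = "reconstructed",
                        desc = "MT growth speed"),
    vs           = list(default = 0.5,  unit = "um/s",     prov = "reconstructed",
                        desc = "MT shrink speed"),
    fr           = list(default = 0.04, unit = "1/s",      prov = "printed",
                        desc = "rescue rate"),
    eps_wca      = list(default = 0.1,  unit = "pN um",    prov = "reconstructed",
                        desc = "WCA repulsion strength"),
    kappa_mt     = list(default = 0.5,  unit = "pN um^2",  prov = "reconstructed",
                        desc = "MT bending stiffness"),
    kappa_mem    = list(default = 0.5,  unit = "pN um^2",  prov = "reconstructed",
                        desc = "membrane bending stiffness"),
    kappa_nuc    = list(default = 0.2,  unit = "pN um^2",  prov = "reconstructed",
                        desc = "nuclear envelope bending stiffness"),
    ks_mem       = list(default = 40,    unit = "pN/um",    prov = "reconstructed",
                        desc = "membrane stretching stiffness"),
    ks_nuc       = list(default = 40,    unit = "pN/um",    prov = "reconstructed",
                        desc = "nucleus stretching stiffness"),
    ks_mt        = list(default = 8,    unit = "pN/um",    prov = "reconstructed",
                        desc = "MT stretching stiffness"),
    k_area_mem   = list(default = 20,   unit = "pN/um",    prov = "reconstructed",
                        desc = "cell area elasticity (cytoplasm incompressibility)"),
    k_area_nuc   = list(default = 20,   unit = "pN/um",    prov = "reconstructed",
                        desc = "nucleus area elasticity"),
    k_couple     = list(default = 0.5,  unit = "pN/um",    prov = "reconstructed",
                        desc = "nucleus-membrane elastic coupling stiffness"),
    rest_couple  = list(default = 4,    unit = "um",       prov = "reconstructed",
                        desc = "rest length of nucleus-membrane coupling"),
    v_prot0      = list(default = 0.05, unit = "um/s",     prov = "reconstructed",
                        desc = "protrusion velocity gain per growing tip"),
    f_contr0     = list(default = 0.2,  unit = "pN",       prov = "reconstructed",
                        desc = "contraction force gain per shrinking tip"),
    r_signal     = list(default = 1.12, unit = "um",       prov = "reconstructed",
                        desc = "tip-membrane signalling radius (2*1.12*sigma_mt)"),
    n_sat        = list(default = 20,   unit = "count",    prov = "reconstructed",
                        desc = "tip count per bead at which the protrusion response saturates"),
    n_sat_contr  = list(default = 10,   unit = "count",    prov = "reconstructed",
                        desc = "trace level per bead at which the contraction response saturates"),
    f_poly       = list(default = 2,    unit = "pN",       prov = "reconstructed",
                        desc = "polymerization force of a sterically stalled growing tip"),
    contract_tau = list(default = 40,    unit = "s",        prov = "reconstructed",
                        desc = "decay time of the cortical contraction trace (0 = instantaneous counts)"),
    contract_deposit = list(default = 0.5, unit = "1/s",   prov = "reconstructed",
                        desc = "deposit rate of shrink-tip signal into the contraction trace"),
    deposit_min_contact = list(default = 5, unit = "um",   prov = "reconstructed",
                        desc = "membrane-contact length of a filament required for its shrinking tip to deposit contraction signal"),
    gamma_mem    = list(default = 5,    unit = "pN s/um",  prov = "reconstructed",
                        desc = "membrane bead drag (cortex plus adhesion friction)"),
    gamma_nuc    = list(default = 5,    unit = "pN s/um",  prov = "reconstructed",
                        desc = "nucleus bead drag (envelope plus chromatin)"),
    gamma_cen    = list(default = 20,   unit = "pN s/um",  prov = "reconstructed",
                        desc = "centrosome drag (carries the whole aster reaction)"),
    gamma_mt     = list(default = 2,    unit = "pN s/um",  prov = "reconstructed",
                        desc = "MT bead drag"),
    dt           = list(default = 0.005, unit = "s",       prov = "reconstructed",
                        desc = "integration step"),
    t_total      = list(default = 3000, unit = "s",        prov = "reconstructed",
                        desc = "simulated time"),
    record_every = list(default = 10,   unit = "s",        prov = "reconstructed",
                        desc = "track recording cadence"),
    v_chemo      = list(default = 0,    unit = "um/s",     prov = "printed",
                        desc = "chemotactic forward bias on membrane beads"),
    seed         = list(default = 1,    unit = "integer",  prov = "reconstructed",
                        desc = "random seed")
  )
}

.dynein_registry <- function() {
  list(
    rho_cortex = list(default = 0.3, unit = "motors/bead", prov = "reconstructed",
                      desc = "cortical dynein anchor density"),
    rho_nuc    = list(default = 0.3, unit = "motors/bead", prov = "reconstructed",
                      desc = "perinuclear dynein anchor density"),
    k_on       = list(default = 1,   unit = "1/s",  prov = "reconstructed",
                      desc = "motor attachment rate"),
    k_off      = list(default = 0.2, unit = "1/s",  prov = "reconstructed",
                      desc = "motor detachment rate"),
    v_motor    = list(default = 0.8, unit = "um/s", prov = "reconstructed",
                      desc = "dynein walking speed (minus-end-ward)"),
    k_motor    = list(default = 5,   unit = "pN/um", prov = "reconstructed",
                      desc = "motor linkage spring stiffness"),
    r_capture  = list(default = 0.75, unit = "um",  prov = "reconstructed",
                      desc = "anchor-filament capture radius"),
    f_stall    = list(default = 4,   unit = "pN",   prov = "reconstructed",
                      desc = "forced detachment (stall) force")
  )
}

#' Model parameters
#'
#' Builds the full parameter set of the model, starting from registered
#' defaults and overriding any subset by name. Dynein motor constants live in
#' the nested `dynein` list and can be overridden via `dynein = list(...)`
#' (only the named entries are replaced). The catastrophe rate `fc` is not a
#' free parameter: it is derived from the target mean MT length via
#' [catastropheRate()] so that the free-filament two-state length process has
#' mean `lmt_target`.
#'
#' @param ... named overrides of registered parameters.
#' @param validate validate the resulting set (recommended).
#' @return an object of class `cellParams`: a named list of constants plus a
#'   derived `fc` entry; the provenance table is available via
#'   [paramProvenance()].
#' @examples
#' p <- cellParams(Nmt = 50, lmt_target = 16)
#' p$fc
#' @export
cellParams <- function(..., validate = TRUE) {
  reg <- .param_registry()
  p <- lapply(reg, `[[`, "default")
  p$dynein <- lapply(.dynein_registry(), `[[`, "default")
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), c(names(p)))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    dyn <- ov$dynein
    ov$dynein <- NULL
    p[names(ov)] <- ov
    if (!is.null(dyn)) {
      badd <- setdiff(names(dyn), names(p$dynein))
      if (length(badd)) stop("unknown dynein parameter(s): ",
                             paste(badd, collapse = ", "))
      p$dynein[names(dyn)] <- dyn
    }
  }
  p$fc <- catastropheRate(p$vg, p$vs, p$fr, p$lmt_target)
  class(p) <- "cellParams"
  if (validate) validateParams(p)
  p
}

#' Catastrophe rate for a target mean microtubule length
#'
#' For the unconstrained two-state (grow/shrink) filament with growth speed
#' `vg`, shrink speed `vs`, rescue rate `fr` and catastrophe rate `fc`, the
#' stationary length distribution in the bounded regime (`vg*fr < vs*fc`) is
#' exponential with mean `vg*vs / (fc*vs - fr*vg)`. This solves that relation
#' for `fc` given the target mean, so mean MT length is controlled directly
#' rather than through the raw switching rate.
#'
#' @param vg,vs growth and shrink speeds (um/s).
#' @param fr rescue rate (1/s).
#' @param lmt target mean length (um).
#' @return catastrophe rate `fc` (1/s).
#' @examples
#' catastropheRate(0.1, 0.2, 0, 9.3)    # fr = 0 limit: vg / lmt
#' catastropheRate(0.1, 0.2, 0.04, 9.3)
#' @export
catastropheRate <- function(vg, vs, fr, lmt) {
  if (!all(vg > 0, vs > 0, lmt > 0) || fr < 0)
    stop("vg, vs and lmt must be strictly positive and fr non-negative")
  fc <- (vg * vs / lmt + fr * vg) / vs
  if (!is.finite(fc) || fc <= 0)
    stop("no positive catastrophe rate reproduces mean length ", lmt)
  fc
}

#' Parameter provenance table
#'
#' @param params optional `cellParams` object whose current values are shown.
#' @return data.frame with name, value, unit, provenance and description for
#'   every registered constant (dynein entries prefixed `dynein.`).
#' @export
paramProvenance <- function(params = cellParams()) {
  reg <- .param_registry()
  dyn <- .dynein_registry()
  rows <- lapply(names(reg), function(n) {
    data.frame(name = n, value = params[[n]], unit = reg[[n]]$unit,
               provenance = reg[[n]]$prov, description = reg[[n]]$desc,
               stringsAsFactors = FALSE)
  })
  drows <- lapply(names(dyn), function(n) {
    data.frame(name = paste0("dynein.", n), value = params$dynein[[n]],
               unit = dyn[[n]]$unit, provenance = dyn[[n]]$prov,
               description = dyn[[n]]$desc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, drows))
  out <- rbind(out, data.frame(
    name = "fc", value = params$fc, unit = "1/s", provenance = "derived",
    description = "catastrophe rate solved from lmt_target",
    stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Validate a parameter set
#'
#' Enforces positivity, the bounded MT length regime `vg*fr < vs*fc`, the
#' stretch-spring stability bound `max(ks/gamma)*dt < 0.1`, a bending
#' stability bound `16*kappa/(gamma*l0^3)*dt < 1` (the top eigenvalue of the
#' discretized bending operator), and `dt*max(fc, fr) < 0.1`.
#'
#' @param p a `cellParams` object.
#' @return `p`, invisibly; errors on violation.
#' @export
validateParams <- function(p) {
  pos <- c("Rcell", "Rnuc", "n_mem_beads", "n_nuc_beads", "sigma_mt", "vg",
           "vs", "eps_wca", "kappa_mt", "kappa_mem", "kappa_nuc", "ks_mem",
           "ks_nuc", "ks_mt", "k_couple", "rest_couple", "r_signal",
           "gamma_mem", "gamma_nuc", "gamma_cen", "gamma_mt", "dt")
  for (n in pos)
    if (!is.numeric(p[[n]]) || p[[n]] <= 0)
      stop("parameter '", n, "' must be strictly positive")
  for (n in c("fr", "v_chemo", "v_prot0", "f_contr0", "contract_tau",
              "contract_deposit", "deposit_min_contact", "k_area_mem", "k_area_nuc"))
    if (!is.numeric(p[[n]]) || p[[n]] < 0)
      stop("parameter '", n, "' must be non-negative")
  if (p$Nmt < 0) stop("Nmt must be non-negative")
  if (p$Rnuc >= p$Rcell) stop("nucleus radius must be below cell radius")
  if (p$vg * p$fr >= p$vs * p$fc)
    stop("unbounded MT length regime: need vg*fr < vs*fc")
  rate_s <- max(p$ks_mem / p$gamma_mem, p$ks_nuc / p$gamma_nuc,
                p$ks_mt / p$gamma_mt, p$k_couple / p$gamma_nuc,
                p$dynein$k_motor / p$gamma_mem)
  if (rate_s * p$dt >= 0.1)
    stop("timestep too large for stiffest spring: ks/gamma * dt = ",
         signif(rate_s * p$dt, 3), " (need < 0.1)")
  l0m <- 2 * p$Rcell * sin(pi / p$n_mem_beads)
  l0n <- 2 * p$Rnuc * sin(pi / p$n_nuc_beads)
  rate_b <- max(16 * p$kappa_mem / (p$gamma_mem * l0m^3),
                16 * p$kappa_nuc / (p$gamma_nuc * l0n^3),
                16 * p$kappa_mt / (p$gamma_mt * p$sigma_mt^3))
  if (rate_b * p$dt >= 1)
    stop("timestep too large for bending stiffness: rate * dt = ",
         signif(rate_b * p$dt, 3), " (need < 1)")
  if (p$dt * max(p$fc, p$fr) >= 0.1)
    stop("dt too large for switching rates: dt*max(fc, fr) must be < 0.1")
  invisible(p)
}

#' @export
print.cellParams <- function(x, ...) {
  cat("Cell migration model parameters\n")
  cat(sprintf("  cell R = %g um (%d beads), nucleus R = %g um (%d beads)\n",
              x$Rcell, x$n_mem_beads, x$Rnuc, x$n_nuc_beads))
  cat(sprintf("  MTs: N = %d, target mean length = %g um (fc = %.4g /s, fr = %g /s)\n",
              x$Nmt, x$lmt_target, x$fc, x$fr))
  cat(sprintf("  crosstalk: v_prot0 = %g um/s, f_contr0 = %g pN, r_signal = %g um\n",
              x$v_prot0, x$f_contr0, x$r_signal))
  cat(sprintf("  dt = %g s, t_total = %g s, record every %g s, seed = %d\n",
              x$dt, x$t_total, x$record_every, as.integer(x$seed)))
  invisible(x)
}

#' Read parameters from a YAML configuration file
#'
#' Keys mirror [cellParams()] arguments (`dynein` as a nested section); any
#' omitted key takes the registered default.
#'
#' @param path YAML file.
#' @return a `cellParams` object.
#' @export
readParams <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  cfg$fc <- NULL # derived, recomputed from lmt_target
  do.call(cellParams, cfg)
}

#' Write a parameter echo (full resolved configuration) to YAML
#'
#' @param params a `cellParams` object.
#' @param path output file.
#' @export
writeParams <- function(params, path) {
  p <- unclass(params)
  yaml::write_yaml(p, path)
  invisible(path)
}
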