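# Simulation state construction and validation.

.regular_polygon <- function(n, radius, center = c(0, 0)) {
  th <- 2 * pi * (seq_len(n) - 1) / n # counter-clockwise winding
  cbind(x = center[1] + radius * cos(th), y = center[2] + radius * sin(th))
}

#' Initial simulation state
#'
#' Builds the starting configuration: a regular-polygon membrane of radius
#' `Rcell` and nucleus of radius `Rnuc`, both centred at the cell origin; the
#' centrosome offset by `Rnuc + 1` um along +x from the nucleus centre (the
#' broken symmetry of migration comes from MT stochasticity, not from this
#' fixed offset); `Nmt` single-bead microtubules at the centrosome with
#' uniformly random nucleation directions; and a fixed random subset of
#' membrane/nucleus beads hosting dynein anchors. All randomness is drawn
#' from dedicated streams seeded by `params$seed`, so construction is
#' deterministic.
#'
#' @param params a [cellParams()] object.
#' @param env optional environment from [freeSpace()], [obstaclePark()],
#'   [yJunction()] or [multiChannel()]; its suggested start position recentres
#'   the cell.
#' @return an object of class `cellState`.
#' @export
initialState <- function(params, env = freeSpace()) {
  validateParams(params)
  center <- if (!is.null(env$start)) env$start else c(0, 0)
  if (params$Rnuc + 1 + params$sigma_mt >= params$Rcell)
    stop("initial centrosome + MT extent does not fit inside the cell")
  mem <- .regular_polygon(params$n_mem_beads, params$Rcell, center)
  nuc <- .regular_polygon(params$n_nuc_beads, params$Rnuc, center)
  cen <- center + c(params$Rnuc + 1, 0)
  init <- cpp_init_random(as.integer(params$seed), params$Nmt,
                          params$n_mem_beads, params$n_nuc_beads,
                          params$dynein$rho_cortex, params$dynein$rho_nuc)
  mts <- lapply(seq_len(params$Nmt), function(i) {
    list(beads = matrix(cen, nrow = 1, ncol = 2),
         state = "GROW", partial = init$partials[i] * params$sigma_mt,
         dir = init$dirs[i], dep_armed = FALSE)
  })
  bm <- which(init$host_mem)
  bn <- which(init$host_nuc)
  hosts <- data.frame(loop = c(rep(0L, length(bm)), rep(1L, length(bn))),
                      bead = c(bm, bn))
  motors <- data.frame(loop = hosts$loop, bead = hosts$bead,
                       bound = rep(FALSE, nrow(hosts)),
                       mt = rep(NA_integer_, nrow(hosts)),
                       arc = rep(0, nrow(hosts)))
  st <- list(membrane = mem, nucleus = nuc, centrosome = cen, mts = mts,
             motors = motors, contract_trace = numeric(params$n_mem_beads),
             t = 0, rng_mt = init$rng_mt, rng_motor = init$rng_motor)
  class(st) <- "cellState"
  validateState(st, params)
  st
}

#' Validate a simulation state
#'
#' Checks the structural invariants: closed simple membrane and nucleus
#' rings, centrosome inside the membrane and outside the nucleus, MT minus
#' ends coincident with the centrosome, and motor attachment bookkeeping
#' (at most one attachment per anchor, arc positions within filament length).
#'
#' @param st a `cellState`.
#' @param params the matching `cellParams`.
#' @return `st` invisibly; errors on violation.
#' @export
validateState <- function(st, params) {
  stopifnot(is.matrix(st$membrane), ncol(st$membrane) == 2,
            is.matrix(st$nucleus), ncol(st$nucleus) == 2,
            length(st$centrosome) == 2, is.list(st$mts))
  if (st$t == 0) {
    if (!.polygon_simple(st$membrane)) stop("membrane ring self-intersects")
    if (!.polygon_simple(st$nucleus)) stop("nucleus ring self-intersects")
    if (!.point_in_polygon(st$centrosome, st$membrane))
      stop("centrosome outside the membrane")
    if (.point_in_polygon(st$centrosome, st$nucleus))
      stop("centrosome inside the nucleus")
  }
  for (mt in st$mts) {
    if (max(abs(mt$beads[1, ] - st$centrosome)) > 1e-9)
      stop("MT minus end not anchored at the centrosome")
    if (mt$partial < 0 || mt$partial >= params$sigma_mt)
      stop("MT partial tip outside [0, sigma_mt)")
    if (!mt$state %in% c("GROW", "SHRINK")) stop("invalid MT state")
  }
  if (nrow(st$motors)) {
    key <- paste(st$motors$loop, st$motors$bead)
    if (anyDuplicated(key)) stop("duplicate motor anchor")
    b <- which(st$motors$bound)
    for (i in b) {
      mt <- st$mts[[st$motors$mt[i]]]
      len <- (nrow(mt$beads) - 1) * params$sigma_mt + mt$partial
      if (st$motors$arc[i] < 0 || st$motors$arc[i] > len + params$sigma_mt)
        stop("motor arc position outside filament")
    }
  }
  invisible(st)
}

#' Microtubule lengths of a state
#'
#' @param st a `cellState`.
#' @param params the matching `cellParams`.
#' @return numeric vector of filament lengths
#'   (`(n_beads - 1) * sigma_mt + partial_tip`), in um.
#' @export
mtLengths <- function(st, params) {
  vapply(st$mts, function(mt) {
    (nrow(mt$beads) - 1) * params$sigma_mt + mt$partial
  }, numeric(1))
}

#' @export
print.cellState <- function(x, ...) {
  lens <- vapply(x$mts, function(m) nrow(m$beads), numeric(1))
  cat(sprintf("cellState at t = %g s\n", x$t))
  cat(sprintf("  membrane %d beads, nucleus %d beads\n",
              nrow(x$membrane), nrow(x$nucleus)))
  cat(sprintf("  centrosome at (%.2f, %.2f)\n",
              x$centrosome[1], x$centrosome[2]))
  cat(sprintf("  %d MTs (%d growing), %d motor anchors (%d bound)\n",
              length(x$mts),
              sum(vapply(x$mts, function(m) m$state == "GROW", logical(1))),
              nrow(x$motors), sum(x$motors$bound)))
  invisible(x)
}

# --- polygon helpers (initial-geometry validation only) ---------------------

.polygon_simple <- function(p) {
  n <- nrow(p)
  seg <- cbind(p, p[c(2:n, 1), ])
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    js <- js[!(i == 1 & js == n)]
    for (j in js) {
      if (.segments_cross(seg[i, 1:2], seg[i, 3:4], seg[j, 1:2], seg[j, 3:4]))
        return(FALSE)
    }
  }
  TRUE
}

.segments_cross <- function(a1, a2, b1, b2) {
  d <- function(p, q, r) (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
  d1 <- d(b1, b2, a1); d2 <- d(b1, b2, a2)
  d3 <- d(a1, a2, b1); d4 <- d(a1, a2, b2)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

.point_in_polygon <- function(pt, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((poly[i, 2] > pt[2]) != (poly[j, 2] > pt[2])) {
      xint <- poly[i, 1] + (pt[2] - poly[i, 2]) *
        (poly[j, 1] - poly[i, 1]) / (poly[j, 2] - poly[i, 2])
      if (pt[1] < xint) inside <- !inside
    }
    j <- i
  }
  inside
}
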