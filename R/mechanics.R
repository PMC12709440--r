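# R-facing surfaces of the force kernels. These call the same compiled code
# the simulation loop uses, so tests exercise the production force paths.

#' Harmonic stretching forces along a bead chain or ring
#'
#' Hookean force `-ks * (|r| - rest)` along each bond, equal and opposite on
#' the bond partners. A zero-length bond has no defined direction and
#' contributes no force (with a warning).
#'
#' @param pos n x 2 matrix of bead positions (um).
#' @param ks stretching stiffness (pN/um).
#' @param rest rest bond length (um).
#' @param closed `TRUE` for a ring (bead n bonds to bead 1).
#' @return n x 2 matrix of forces (pN).
#' @export
stretchForces <- function(pos, ks, rest, closed = TRUE) {
  stopifnot(nrow(pos) >= 2)
  n <- nrow(pos)
  idx <- if (closed) seq_len(n) else seq_len(n - 1)
  j <- idx %% n + 1
  blen <- sqrt(rowSums((pos[j, , drop = FALSE] - pos[idx, , drop = FALSE])^2))
  if (any(blen < 1e-12))
    warning("zero-length bond: stretch force capped to zero for that bond")
  cpp_stretch_forces(pos, closed, ks, rest)
}

#' Discrete worm-like-chain bending forces
#'
#' Gradient of `E = kappa/(2 * rest_bond) * sum_i (theta_i - rest_angle)^2`
#' over the signed turning angles `theta_i`. Rings bend at every vertex with
#' `rest_angle` equal to the exterior angle of the regular polygon; open
#' chains bend at interior vertices with `rest_angle = 0` and free ends.
#'
#' @param pos n x 2 matrix of bead positions (um).
#' @param kappa bending stiffness (pN um^2).
#' @param rest_angle preferred turning angle (radians).
#' @param rest_bond bond length used to normalise the discrete energy (um).
#' @param closed ring (`TRUE`) or open chain.
#' @return n x 2 matrix of forces (pN).
#' @export
bendForces <- function(pos, kappa, rest_angle = 0,
                       rest_bond = 1, closed = FALSE) {
  stopifnot(nrow(pos) >= 3)
  cpp_bend_forces(pos, closed, kappa, rest_angle, rest_bond)
}

#' Bending energy of a chain or ring
#'
#' @inheritParams bendForces
#' @return scalar energy (pN um).
#' @export
bendEnergy <- function(pos, kappa, rest_angle = 0, rest_bond = 1,
                       closed = FALSE) {
  cpp_bend_energy(pos, closed, kappa, rest_angle, rest_bond)
}

#' WCA (purely repulsive Lennard-Jones) force magnitude
#'
#' Truncated and shifted at the potential minimum `r = 2^(1/6) * sigma`, so
#' the force is zero beyond the cutoff and continuous there. For
#' `r < 0.1 * sigma` the magnitude is capped (deep overlap) with a warning.
#'
#' @param r separation distance(s) (um).
#' @param sigma steric diameter (um).
#' @param eps repulsion strength (pN um).
#' @return repulsive force magnitude(s) (pN), directed along the separation.
#' @examples
#' wcaForce(1, sigma = 1, eps = 1)             # 24 pN at r = sigma
#' wcaForce(2^(1 / 6), sigma = 1, eps = 1)     # zero at the cutoff
#' @export
wcaForce <- function(r, sigma, eps) {
  stopifnot(sigma > 0, eps > 0)
  cpp_wca_force(as.numeric(r), sigma, eps)
}

#' All steric (WCA) forces of a configuration
#'
#' Applies the WCA pair force between MT beads and membrane/nucleus beads,
#' membrane-nucleus pairs, non-bonded membrane-membrane pairs
#' (self-avoidance), the centrosome and nucleus beads, and every bead against
#' obstacles and walls. MT-MT pairs and bonded neighbours are excluded. The
#' default path uses a uniform spatial grid of cell size `2^(1/6) * sigma_mt`;
#' `use_grid = FALSE` switches to brute-force all-pairs (identical result,
#' used for verification).
#'
#' @param st a `cellState`.
#' @param params a `cellParams`.
#' @param env a `cellEnv`.
#' @param use_grid use the spatial grid (default) or all-pairs.
#' @return list of force arrays: `membrane`, `nucleus` (n x 2), `mts` (list
#'   of n x 2), `centrosome` (length 2), and the deep-overlap count.
#' @export
stericForces <- function(st, params, env = freeSpace(), use_grid = TRUE) {
  cpp_steric_forces(st, .cpars(params), .cenv(env), use_grid)
}

#' Microtubule-tip signal field at the membrane
#'
#' For each membrane bead, counts the MT plus-end tips within `r_signal`,
#' split by dynamic state, and computes the outward unit normal from the
#' local tangent (neighbours i-1, i+1) oriented by the polygon winding.
#'
#' @param membrane n x 2 membrane bead positions (um).
#' @param tips m x 2 tip positions (um).
#' @param tip_state length-m vector, `"GROW"`/`"SHRINK"` (or 0/1).
#' @param r_signal signalling radius (um).
#' @return list with integer vectors `n_grow`, `n_shrink` and an n x 2
#'   matrix `normals`.
#' @export
tipSignals <- function(membrane, tips, tip_state, r_signal) {
  if (is.character(tip_state))
    tip_state <- ifelse(tip_state == "SHRINK", 1L, 0L)
  if (!is.matrix(tips)) tips <- matrix(tips, ncol = 2)
  cpp_tip_signals(membrane, tips, as.integer(tip_state), r_signal)
}

#' Dynein motor linkage forces
#'
#' Zero-rest-length spring of stiffness `k_motor` between an anchor bead and
#' the filament point at arc position `arc` from the minus end; the filament
#' reaction is distributed to the two bracketing beads by the lever rule.
#'
#' @param anchor length-2 anchor position (um).
#' @param mt_beads n x 2 MT bead positions, minus end first.
#' @param arc arc position along the filament (um).
#' @param k_motor spring stiffness (pN/um).
#' @param sigma_mt bead spacing (um).
#' @return list with `anchor` (length-2 force on the anchor bead) and `mt`
#'   (n x 2 forces on the filament beads).
#' @export
motorForces <- function(anchor, mt_beads, arc, k_motor, sigma_mt) {
  stopifnot(arc >= 0)
  cpp_motor_forces(as.numeric(anchor), mt_beads, arc, k_motor, sigma_mt)
}
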