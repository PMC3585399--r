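# Potential energy, forces and the alchemical state of a system.

alch_mode_code <- function(mode) {
  switch(mode, none = 0L, dual_set = 1L, ion_morph = 2L, kf_interp = 3L,
         stop("unknown alchemical mode: ", mode))
}

# Lower the R-side system to the flat list consumed by the C++ engine.
as_engine_system <- function(sys) {
  a <- sys$atoms
  if (anyNA(a$charge) || anyNA(a$eps) || anyNA(a$sigma) || anyNA(a$mass))
    stop("unresolved parameters: system atoms carry NA charge/LJ/mass entries")
  anc <- sys$anchors
  if (is.null(anc)) {
    anc <- list(idx = integer(0), pos = matrix(0, 0, 3), kf = numeric(0),
                kf2 = NULL)
  }
  out <- list(
    charge = a$charge, eps = a$eps, sigma = a$sigma, mass = a$mass,
    fixed = as.integer(seq_len(nrow(a)) == 1L),
    group = as.integer(a$set),
    excl = matrix(as.integer(sys$excl - 1L), ncol = 2),
    bonds = as.matrix(cbind(sys$bonds$i - 1, sys$bonds$j - 1,
                            sys$bonds$r0, sys$bonds$k)),
    angles = as.matrix(cbind(sys$angles$i - 1, sys$angles$j - 1,
                             sys$angles$k - 1, sys$angles$theta0,
                             sys$angles$ka)),
    wall_idx = as.integer(sys$wall$atoms - 1L),
    wall_radius = sys$wall$radius, wall_k = sys$wall$k,
    anchor_idx = as.integer(anc$idx - 1L),
    anchor_pos = anc$pos, anchor_kf = anc$kf,
    anchor_kf2 = anc$kf2,
    alch_mode = alch_mode_code(sys$alchemy$mode),
    nb = list(cutoff = sys$nb$cutoff, switch_start = sys$nb$switch_start,
              softcore_shift = sys$nb$softcore_shift)
  )
  if (sys$alchemy$mode == "ion_morph") {
    ipB <- ion_params(sys$alchemy$ion_to)
    out$ion_idx <- 0L
    out$ion_epsA <- sys$ion$epsilon
    out$ion_sigmaA <- sys$ion$sigma
    out$ion_epsB <- ipB$epsilon
    out$ion_sigmaB <- ipB$sigma
  }
  if (nrow(out$bonds) == 0) out$bonds <- matrix(0, 0, 4)
  if (nrow(out$angles) == 0) out$angles <- matrix(0, 0, 5)
  out
}

#' Set the alchemical coupling parameter
#' @param sys A `particle_system`.
#' @param lambda Value in `[0, 1]`.
#' @return The modified system.
#' @export
set_lambda <- function(sys, lambda) {
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  sys$alchemy$lambda <- lambda
  sys
}

#' Potential energy breakdown of a system
#'
#' Sums bonded terms, all intermolecular nonbonded pairs (intra-ligand pairs
#' are excluded; during dual-set morphs the two ligand sets never interact
#' with each other) and the restraint terms, at the system's current
#' alchemical state.
#'
#' @param sys A `particle_system`.
#' @param coords Optional coordinates overriding `sys$coords`.
#' @return Named numeric of class `energy_breakdown`: `coulomb`, `lj`,
#'   `bonded`, `wall_restraint`, `anchor_restraint`, `total` (kcal/mol).
#'   `total` equals the sum of the components.
#' @export
total_energy <- function(sys, coords = NULL) {
  if (is.null(coords)) coords <- sys$coords
  e <- eng_energy(as_engine_system(sys), coords, sys$alchemy$lambda)
  structure(e, class = "energy_breakdown")
}

#' Analytic forces on every atom
#'
#' Gradient of [total_energy()]. The force on the fixed central ion is
#' reported but never applied during dynamics.
#'
#' @inheritParams total_energy
#' @return N x 3 matrix of forces (kcal/mol/A).
#' @export
forces <- function(sys, coords = NULL) {
  if (is.null(coords)) coords <- sys$coords
  eng_forces(as_engine_system(sys), coords, sys$alchemy$lambda)
}

#' Switched, softcore pair energy
#'
#' The single-pair energy model: 12-6 Lennard-Jones plus Coulomb, both
#' multiplied by a polynomial switch between `switch_start` and `cutoff`.
#' At `lambda_vdw < 1` the Lennard-Jones term uses the shifted-distance
#' softcore form `r^2 -> r^2 + shift * (1 - lambda_vdw) * sigma^2` and scales
#' with `lambda_vdw`; the Coulomb charge product scales linearly with
#' `lambda_elec`. The result is finite for all `r > 0` whenever
#' `lambda_vdw < 1`, and at `lambda_vdw = lambda_elec = 1` it is exactly the
#' plain switched interaction.
#'
#' @param qi,qj Charges (e).
#' @param eps_ij,sigma_ij Combined Lennard-Jones parameters (kcal/mol, A).
#' @param r Distance (A).
#' @param params A [nonbonded_params()] object.
#' @param lambda_vdw,lambda_elec Coupling parameters in `[0, 1]`.
#' @return Energy in kcal/mol.
#' @export
pair_energy <- function(qi, qj, eps_ij, sigma_ij, r,
                        params = nonbonded_params(),
                        lambda_vdw = 1, lambda_elec = 1) {
  if (r <= 0 && lambda_vdw >= 1)
    stop("singularity: r = 0 with fully coupled van der Waals interaction")
  eng_pair_energy(qi, qj, eps_ij, sigma_ij, r, params$cutoff,
                  params$switch_start, params$softcore_shift,
                  lambda_vdw, lambda_elec)
}

#' Restraint energy of a single atom
#'
#' The one-sided spherical wall contributes `0.5 * k_wall * (|r| - R)^2` only
#' beyond the wall radius (exactly zero inside); a harmonic anchor
#' contributes `0.5 * kf * |r - a|^2`. The two terms are reported separately.
#'
#' @param atom_position Numeric length-3 position (A).
#' @param spec List with `sphere = list(center, radius, k)` and optionally
#'   `anchor = list(pos, kf)`.
#' @return Named numeric: `wall`, `anchor`, `total` (kcal/mol).
#' @export
restraint_energy <- function(atom_position, spec) {
  ctr <- if (!is.null(spec$sphere$center)) spec$sphere$center else c(0, 0, 0)
  d <- sqrt(sum((atom_position - ctr)^2))
  wall <- if (d > spec$sphere$radius)
    0.5 * spec$sphere$k * (d - spec$sphere$radius)^2 else 0
  anchor <- 0
  if (!is.null(spec$anchor) && spec$anchor$kf > 0) {
    anchor <- 0.5 * spec$anchor$kf * sum((atom_position - spec$anchor$pos)^2)
  }
  c(wall = wall, anchor = anchor, total = wall + anchor)
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat("Energy (kcal/mol):\n")
  for (nm in names(x)) cat(sprintf("  %-17s %12.4f\n", nm, x[[nm]]))
  invisible(x)
}
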