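# Canonical-ensemble sampling: BAOAB Langevin dynamics with a fixed central
# ion, and re-evaluation of saved frames at other alchemical states.

#' Run Langevin dynamics
#'
#' BAOAB-discretised Langevin integration at the system's temperature with a
#' 1 fs default timestep. The central ion never moves. Identical seeds give
#' bit-identical trajectories (the noise stream is generated by a
#' platform-independent generator inside the engine).
#'
#' @param sys A `particle_system`.
#' @param nsteps Number of steps (>= 1).
#' @param seed Integer seed.
#' @param save_interval Save every this many steps; the initial state is
#'   always frame 1, so a trajectory holds `floor(nsteps/save_interval) + 1`
#'   frames.
#' @param dt Timestep (fs).
#' @param friction Langevin friction (fs^-1); default 0.005 = 5 ps^-1.
#' @param temperature Override the system temperature (K); 0 switches the
#'   thermal noise off entirely.
#' @return Object of class `trajectory`: `frames` (nframe x natom x 3 array,
#'   A), `energies` (data frame with per-frame [total_energy()] components and
#'   the instantaneous kinetic temperature `tkin`), `times` (fs), plus run
#'   metadata (`seed`, `temperature`, `timestep`) and the originating system.
#' @export
run_dynamics <- function(sys, nsteps, seed, save_interval = 100, dt = 1,
                         friction = 0.005, temperature = NULL) {
  stopifnot(nsteps >= 1)
  if (is.null(temperature)) temperature <- sys$temperature
  res <- eng_dynamics(as_engine_system(sys), sys$coords, sys$alchemy$lambda,
                      as.integer(nsteps), dt, temperature, friction,
                      as.integer(seed), as.integer(save_interval))
  en <- as.data.frame(res$energies)
  structure(list(
    frames = res$frames, energies = en, times = en$step * dt,
    seed = seed, temperature = temperature, timestep = dt,
    friction = friction, natom = nrow(sys$atoms), system = sys,
    final_coords = res$final_coords
  ), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("Trajectory:", dim(x$frames)[1], "frames,", x$natom, "atoms,",
      max(x$times) / 1000, "ps at", x$temperature, "K (seed", x$seed, ")\n")
  invisible(x)
}

#' Re-evaluate saved frames at other alchemical states
#'
#' For each saved frame the total potential energy is recomputed at every
#' requested lambda, without re-running dynamics.
#'
#' @param sys The `particle_system` the trajectory was generated from (its
#'   alchemical mode determines how lambda enters the Hamiltonian).
#' @param traj A `trajectory`.
#' @param lambdas Numeric vector of lambda values in `[0, 1]`.
#' @return Matrix with one row per frame and one column per lambda.
#' @export
sample_cross_energies <- function(sys, traj, lambdas) {
  if (any(lambdas < 0 | lambdas > 1))
    stop("lambda values must lie in [0, 1]")
  out <- eng_cross(as_engine_system(sys), traj$frames, lambdas)
  colnames(out) <- format(lambdas)
  out
}

#' RMS positional fluctuation
#'
#' RMS deviation of each selected atom from its trajectory-mean position,
#' plus the pooled value `sqrt(mean(per-atom MSF))` used to map anchor force
#' constants onto observable fluctuation scales.
#'
#' @param traj A `trajectory` with at least two frames (>= 100 recommended).
#' @param atoms Integer indices of the atoms to analyse (default: all mobile
#'   atoms).
#' @return List with `per_atom` (named numeric, A) and `pooled` (A).
#' @export
rms_fluctuation <- function(traj, atoms = NULL) {
  nf <- dim(traj$frames)[1]
  if (nf < 2) stop("fluctuations are undefined for a single frame")
  if (is.null(atoms)) atoms <- seq_len(traj$natom)[-1]
  if (length(atoms) == 0) stop("empty atom selection")
  msf <- vapply(atoms, function(a) {
    xyz <- traj$frames[, a, ]
    mu <- colMeans(xyz)
    mean(rowSums(sweep(xyz, 2, mu)^2))
  }, numeric(1))
  list(per_atom = setNames(sqrt(msf), atoms), pooled = sqrt(mean(msf)))
}
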