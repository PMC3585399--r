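# Alchemical legs: dual-topology restraint morphs and single-topology ion
# morphs, sampled window by window with configuration chaining.

derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 65536 * 31873 + 104729 * i) %% 2147483647)
}

#' Sample all windows of an alchemical leg
#'
#' Runs Langevin dynamics at every lambda of the schedule (in traversal
#' order, chaining the final configuration of each window into the next),
#' discards the first `equil_frac` of each window, and re-evaluates the kept
#' frames at the neighbouring lambdas. A pre-equilibration run of one window
#' length precedes the first window.
#'
#' @param sys A `particle_system` with its alchemical mode already set.
#' @param schedule A [lambda_schedule()].
#' @param nsteps_per_window Dynamics steps per window.
#' @param seed Integer seed; each window derives its own stream.
#' @param save_interval Steps between saved frames.
#' @param equil_frac Fraction of each window discarded as equilibration.
#' @param temperature Override system temperature (K).
#' @return A `fep_samples` object (windows in ascending lambda order, each
#'   with `u_self`, `u_lo`, `u_hi`), with attributes `endpoint_u` (mean
#'   potential energy at lambda 0 and 1) and `samples_per_window`.
#' @export
collect_fep_samples <- function(sys, schedule, nsteps_per_window, seed,
                                save_interval = 100, equil_frac = 0.1,
                                temperature = NULL) {
  values <- schedule$values
  trav <- schedule_traversal(schedule)
  K <- length(values)
  if (is.null(temperature)) temperature <- sys$temperature

  # pre-equilibration at the starting state
  sys0 <- set_lambda(sys, trav[1])
  pre <- run_dynamics(sys0, max(nsteps_per_window, 1000), derive_seed(seed, 0),
                      save_interval = max(nsteps_per_window, 1000),
                      temperature = temperature)
  coords <- pre$final_coords

  windows <- vector("list", K)
  for (m in seq_len(K)) {
    lam <- trav[m]
    i <- match(lam, values)
    sysw <- set_lambda(sys, lam)
    sysw$coords <- coords
    tr <- run_dynamics(sysw, nsteps_per_window, derive_seed(seed, m),
                       save_interval = save_interval,
                       temperature = temperature)
    coords <- tr$final_coords
    lam_lo <- if (i > 1) values[i - 1] else NA_real_
    lam_hi <- if (i < K) values[i + 1] else NA_real_
    evals <- c(lam_lo, lam, lam_hi)
    x <- sample_cross_energies(sysw, tr, evals[!is.na(evals)])
    nf <- nrow(x)
    keep <- seq.int(max(2, floor(equil_frac * nf) + 1), nf)
    col <- 1
    u_lo <- NULL
    if (!is.na(lam_lo)) { u_lo <- x[keep, col]; col <- col + 1 }
    u_self <- x[keep, col]; col <- col + 1
    u_hi <- if (!is.na(lam_hi)) x[keep, col] else NULL
    windows[[i]] <- list(lambda = lam, u_self = u_self, u_lo = u_lo,
                         u_hi = u_hi)
  }
  out <- new_fep_samples(windows, schedule$direction, temperature)
  attr(out, "endpoint_u") <- c(mean(windows[[1]]$u_self),
                               mean(windows[[K]]$u_self))
  attr(out, "samples_per_window") <- length(windows[[1]]$u_self)
  out
}

new_fep_leg <- function(leg_kind, ions, n, kf, est, schedule, seed,
                        samples_per_window, endpoint_u, samples = NULL) {
  structure(list(
    leg_kind = leg_kind, ions = ions, n = n, kf = kf,
    per_window = est$per_window, total_dG = est$total_dG,
    total_se = est$total_se, estimator = est$estimator,
    direction = schedule$direction, schedule = schedule$values,
    seed = seed, samples_per_window = samples_per_window,
    endpoint_u = endpoint_u, samples = samples
  ), class = "fep_leg")
}

#' @export
print.fep_leg <- function(x, ...) {
  cat("FEP leg:", x$leg_kind, "(", paste(x$ions, collapse = " -> "), ")",
      if (!is.null(x$n)) paste0(" n = ", x$n), " kf =", x$kf, "\n")
  cat(sprintf("  dG = %.3f +/- %.3f kcal/mol (%s, %s, %d windows, %s samples/window)\n",
              x$total_dG, x$total_se, x$estimator, x$direction,
              length(x$schedule), format(x$samples_per_window)))
  invisible(x)
}

zero_leg <- function(leg_kind, ions, n, kf, schedule, seed) {
  vals <- schedule$values
  per <- data.frame(lambda_from = vals[-length(vals)], lambda_to = vals[-1],
                    dG = 0, se = 0)
  est <- list(per_window = per, total_dG = 0, total_se = 0,
              estimator = "identity")
  new_fep_leg(leg_kind, ions, n, kf, est, schedule, seed,
              samples_per_window = NA_integer_, endpoint_u = c(0, 0))
}

#' Restraint morph: alchemically remove the harmonic anchors
#'
#' Dual-topology free energy leg between an anchored ligand set (lambda = 0:
#' fully interacting, every atom held in a harmonic potential of force
#' constant `kf_target` at its no-strain position) and a free ligand set
#' (lambda = 1: fully interacting, wall-only). One set is annihilated while
#' the other is exnihilated, so both endpoints represent n ligands
#' coordinating the ion. The returned `total_dG` is the constraint-removal
#' free energy used by [assemble_cycle()].
#'
#' Anchors must have been derived at the simulated ion's own optimal radius;
#' passing another ion's anchors is refused unless `allow_strain = TRUE`
#' (the deliberate "strained cavity" mode).
#'
#' @param ion Ion species.
#' @param n Ligand count (ignored when `system` is given).
#' @param kf_target Anchor force constant (kcal/mol/A^2). 0 returns an
#'   exactly-zero leg (the endpoints are identical).
#' @param anchors A [cage_anchors()] geometry carrying the ion it was
#'   optimised for.
#' @param schedule A [lambda_schedule()]; dense endpoints by default.
#' @param seed Integer seed.
#' @param direction "forward" or "reverse" traversal.
#' @param nsteps_per_window,save_interval,equil_frac Sampling controls (see
#'   [collect_fep_samples()]).
#' @param allow_strain Permit anchors optimised for a different ion.
#' @param system Optional prebuilt dual-set `particle_system` (e.g. a
#'   transporter-site model); its `meta$anchor_ion` is checked instead.
#' @param estimator "bar" (default) or "exp" for the reported total.
#' @param keep_samples Keep the per-window sample object on the leg.
#' @return A `fep_leg`.
#' @export
run_restraint_morph <- function(ion, n = NULL, kf_target, anchors = NULL,
                                schedule = lambda_schedule("dense_endpoints"),
                                seed = 1,
                                direction = c("forward", "reverse"),
                                nsteps_per_window = 20000,
                                save_interval = 100, equil_frac = 0.1,
                                allow_strain = FALSE, system = NULL,
                                estimator = c("bar", "exp"),
                                keep_samples = FALSE) {
  direction <- match.arg(direction)
  estimator <- match.arg(estimator)
  schedule$direction <- direction
  if (kf_target == 0)
    return(zero_leg("restraint_morph", ion, n, 0, schedule, seed))
  if (is.null(system)) {
    if (is.null(anchors) || !inherits(anchors, "anchor_geometry"))
      stop("anchors (a cage_anchors geometry) are required when no system is given")
    anchor_ion <- attr(anchors, "ion")
    if (!allow_strain && (is.null(anchor_ion) || !identical(anchor_ion, ion)))
      stop("strain contamination: anchors were optimised for ",
           if (is.null(anchor_ion)) "an unspecified ion" else anchor_ion,
           " but the simulated ion is ", ion,
           "; pass allow_strain = TRUE for the deliberate strained-cavity mode")
    system <- build_abstract_system(ion, n = anchors$n, r_opt = anchors$radius,
                                    kf = kf_target, dual_sets = TRUE,
                                    geometry = anchors)
    n <- anchors$n
  } else {
    if (is.null(system$anchors)) stop("system has no anchors to morph out")
    anchor_ion <- system$meta$anchor_ion
    if (!allow_strain && (is.null(anchor_ion) || !identical(anchor_ion, ion)))
      stop("strain contamination: system anchors belong to ",
           if (is.null(anchor_ion)) "an unspecified ion" else anchor_ion,
           " but the simulated ion is ", ion)
    if (!any(system$atoms$set == 2L))
      stop("restraint morphs need a dual-set system (dual_sets = TRUE)")
    if (is.null(n)) n <- length(unique(system$atoms$ligand[system$atoms$set == 1L]))
  }
  system$alchemy$mode <- "dual_set"
  samples <- collect_fep_samples(system, schedule, nsteps_per_window, seed,
                                 save_interval, equil_frac)
  est <- if (estimator == "bar") estimate_bar(samples, temperature = system$temperature)
         else estimate_exp(samples, temperature = system$temperature)
  new_fep_leg("restraint_morph", ion, n, kf_target, est, schedule, seed,
              attr(samples, "samples_per_window"), attr(samples, "endpoint_u"),
              samples = if (keep_samples) samples)
}

#' Ion morph: exchange the ion species in the fluctuating site
#'
#' Single-topology free energy leg morphing the central ion from one species
#' to another inside the wall-only (harmonically unrestrained) site. The
#' ion's Lennard-Jones parameters are interpolated between the two species;
#' the charge stays +1 throughout (both species are monovalent), so there is
#' no endpoint singularity. Anchored systems are refused: ion exchange is
#' defined in the fluctuating site.
#'
#' @param n Ligand count for an abstract cage (0 gives a bare ion, whose
#'   morph free energy is exactly zero).
#' @param ion_from,ion_to Species.
#' @param schedule A [lambda_schedule()] (uniform 21 windows by default).
#' @param seed Integer seed.
#' @param r_start Optional placement radius for the cage.
#' @param system Optional prebuilt wall-only system (e.g. a site model).
#' @inheritParams run_restraint_morph
#' @return A `fep_leg` whose `total_dG` is `G(site with ion_to) - G(site
#'   with ion_from)` for a forward leg.
#' @export
run_ion_morph <- function(n = NULL, ion_from, ion_to,
                          schedule = lambda_schedule("uniform", 21),
                          seed = 1, direction = c("forward", "reverse"),
                          nsteps_per_window = 20000, save_interval = 100,
                          equil_frac = 0.1, r_start = NULL, system = NULL,
                          estimator = c("bar", "exp"), keep_samples = FALSE) {
  direction <- match.arg(direction)
  estimator <- match.arg(estimator)
  schedule$direction <- direction
  if (identical(ion_from, ion_to))
    return(zero_leg("ion_morph", c(ion_from, ion_to), n, 0, schedule, seed))
  if (is.null(system)) {
    if (is.null(n)) stop("either n or a prebuilt system is required")
    if (n == 0) {
      return(zero_leg("ion_morph", c(ion_from, ion_to), 0, 0, schedule, seed))
    }
    system <- build_abstract_system(ion_from, n, r_opt = r_start)
  }
  if (!is.null(system$anchors))
    stop("protocol error: ion morphs run in the wall-only site; remove anchors first")
  if (!identical(system$ion$species, ion_from))
    stop("system ion (", system$ion$species, ") does not match ion_from (",
         ion_from, ")")
  if (is.null(n)) n <- length(unique(system$atoms$ligand[system$atoms$set == 1L]))
  system$alchemy$mode <- "ion_morph"
  system$alchemy$ion_to <- ion_to
  samples <- collect_fep_samples(system, schedule, nsteps_per_window, seed,
                                 save_interval, equil_frac)
  est <- if (estimator == "bar") estimate_bar(samples, temperature = system$temperature)
         else estimate_exp(samples, temperature = system$temperature)
  new_fep_leg("ion_morph", c(ion_from, ion_to), n, 0, est, schedule, seed,
              attr(samples, "samples_per_window"), attr(samples, "endpoint_u"),
              samples = if (keep_samples) samples)
}
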