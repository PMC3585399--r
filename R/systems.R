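# Construction of simulatable systems: one fixed central ion plus n small
# dipolar ligands in a 3.5 A flat-bottom spherical wall, optionally with
# per-atom harmonic anchors and/or a duplicate (dual-topology) ligand set.

rotation_to <- function(u) {
  # orthonormal basis (e1, e2, u) with deterministic azimuth
  a <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- c(a[2] * u[3] - a[3] * u[2],
          a[3] * u[1] - a[1] * u[3],
          a[1] * u[2] - a[2] * u[1])
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  cbind(e1, e2, u)
}

place_ligand <- function(tpl, direction, radius) {
  u <- direction / sqrt(sum(direction^2))
  rot <- rotation_to(u)
  local <- as.matrix(tpl$atoms[, c("x", "y", "z")])
  sweep(local %*% t(rot), 2, radius * u, "+")
}

#' Nonbonded interaction parameters
#'
#' @param cutoff Cutoff distance (A). Pair energies and forces are exactly
#'   zero beyond it.
#' @param switch_start Start of the switching region (A); must be below
#'   `cutoff`. The same polynomial switch multiplies both the Lennard-Jones
#'   and the Coulomb term.
#' @param softcore_shift van der Waals radius shift coefficient of the
#'   softcore form `r^2 -> r^2 + shift * (1 - lambda) * sigma^2`.
#' @return List of class `nonbonded_params`.
#' @export
nonbonded_params <- function(cutoff = 12, switch_start = 10,
                             softcore_shift = 1) {
  if (switch_start >= cutoff) stop("switch_start must be below cutoff")
  structure(list(cutoff = cutoff, switch_start = switch_start,
                 softcore_shift = softcore_shift,
                 coulomb_constant = rlf_constants()$coulomb),
            class = "nonbonded_params")
}

# Assemble a particle_system from a list of placed ligands.
# Each entry of `ligands`: list(template, coords (nat x 3), set (1 or 2)).
new_particle_system <- function(ion_species, ligands, temperature = 310,
                                wall_radius = 3.5, wall_k = 100,
                                nb = nonbonded_params(), meta = list()) {
  ip <- ion_params(ion_species)
  atoms <- data.frame(name = ion_species, element = ion_species,
                      charge = ip$charge, eps = ip$epsilon, sigma = ip$sigma,
                      mass = ip$mass, set = 0L, ligand = 0L,
                      fragment = "ion", stringsAsFactors = FALSE)
  coords <- matrix(0, 1, 3)
  bonds <- angles <- NULL
  excl <- NULL
  wall_atoms <- integer(0)
  lig_id <- 0L
  for (lg in ligands) {
    lig_id <- lig_id + 1L
    tpl <- lg$template
    off <- nrow(atoms)
    atoms <- rbind(atoms, data.frame(
      name = tpl$atoms$name, element = tpl$atoms$element,
      charge = tpl$atoms$charge, eps = tpl$atoms$eps,
      sigma = tpl$atoms$sigma, mass = tpl$atoms$mass,
      set = as.integer(lg$set), ligand = lig_id,
      fragment = tpl$name, stringsAsFactors = FALSE))
    coords <- rbind(coords, lg$coords)
    bonds <- rbind(bonds, data.frame(i = tpl$bonds$i + off,
                                     j = tpl$bonds$j + off,
                                     r0 = tpl$bonds$r0, k = tpl$bonds$k))
    angles <- rbind(angles, data.frame(i = tpl$angles$i + off,
                                       j = tpl$angles$j + off,
                                       k = tpl$angles$k + off,
                                       theta0 = tpl$angles$theta0,
                                       ka = tpl$angles$ka))
    nat <- nrow(tpl$atoms)
    prs <- t(utils::combn(seq_len(nat) + off, 2))
    excl <- rbind(excl, prs)
    wall_atoms <- c(wall_atoms, tpl$coordinating + off)
  }
  if (is.null(bonds)) bonds <- data.frame(i = integer(), j = integer(),
                                          r0 = numeric(), k = numeric())
  if (is.null(angles)) angles <- data.frame(i = integer(), j = integer(),
                                            k = integer(), theta0 = numeric(),
                                            ka = numeric())
  if (is.null(excl)) excl <- matrix(integer(), 0, 2)
  sys <- structure(list(
    ion = c(list(species = ion_species), ip[c("charge", "epsilon", "sigma", "mass")]),
    atoms = atoms, coords = coords, bonds = bonds, angles = angles,
    excl = excl,
    wall = list(atoms = wall_atoms, radius = wall_radius, k = wall_k),
    anchors = NULL,
    alchemy = list(mode = "none", lambda = 0, ion_to = NULL),
    nb = nb, temperature = temperature, meta = meta
  ), class = "particle_system")
  validate_particle_system(sys)
  sys
}

validate_particle_system <- function(sys, clash_tol = 0.5) {
  stopifnot(inherits(sys, "particle_system"))
  a <- sys$atoms
  sets <- unique(a$set[a$set > 0])
  if (length(sets) == 2) {
    for (s in sets) {
      comp <- sort(table(a$fragment[a$set == s]))
      if (s == sets[1]) comp1 <- comp
    }
    comp2 <- sort(table(a$fragment[a$set == sets[2]]))
    if (!identical(comp1, comp2))
      stop("dual ligand sets must have identical composition")
  }
  # clash check over interacting pairs only
  x <- sys$coords
  n <- nrow(x)
  if (n > 1) {
    d <- as.matrix(stats::dist(x))
    diag(d) <- Inf
    for (r in seq_len(nrow(sys$excl))) d[sys$excl[r, 1], sys$excl[r, 2]] <-
      d[sys$excl[r, 2], sys$excl[r, 1]] <- Inf
    both <- outer(a$set == 1L, a$set == 2L, "&")
    d[both | t(both)] <- Inf
    if (any(d < clash_tol))
      stop("construction clash: interacting atoms closer than ", clash_tol, " A")
  }
  invisible(sys)
}

#' Total charge of a system
#' @param sys A `particle_system`.
#' @return Ion charge plus the summed ligand charges (one ligand set), in e.
#' @export
system_charge <- function(sys) {
  a <- sys$atoms
  sum(a$charge[a$set %in% c(0L, 1L)])
}

#' @export
print.particle_system <- function(x, ...) {
  a <- x$atoms
  nlig <- length(unique(a$ligand[a$set == 1L]))
  cat("Particle system:", x$ion$species, "+ ion,", nlig, "ligand(s)",
      if (any(a$set == 2L)) "(dual topology)" else "", "\n")
  cat("  atoms:", nrow(a), " total charge:", system_charge(x), "e\n")
  cat("  wall: r =", x$wall$radius, "A, k =", x$wall$k, "kcal/mol/A^2 on",
      length(x$wall$atoms), "oxygen(s)\n")
  if (!is.null(x$anchors))
    cat("  anchors: kf =", unique(x$anchors$kf), "kcal/mol/A^2 on",
        length(x$anchors$idx), "atom(s)\n")
  cat("  alchemy:", x$alchemy$mode, " lambda =", x$alchemy$lambda, "\n")
  invisible(x)
}

# 1-D ion-ligand distance scan used for clash-free initial placement when no
# measured optimal radius is available yet.
pair_scan_minimum <- function(ion_species, tpl, grid = seq(1.2, 3.4, by = 0.005)) {
  ip <- ion_params(ion_species)
  cc <- rlf_constants()$coulomb
  co <- tpl$coordinating
  cpos <- colMeans(tpl$atoms[co, c("x", "y", "z"), drop = FALSE])
  en <- vapply(grid, function(r) {
    # ion at origin, ligand placed with coordinating point at (0, 0, r)
    e <- 0
    for (k in seq_len(nrow(tpl$atoms))) {
      p <- as.numeric(tpl$atoms[k, c("x", "y", "z")]) - as.numeric(cpos)
      d <- sqrt(p[1]^2 + p[2]^2 + (p[3] + r)^2)
      sig <- 0.5 * (ip$sigma + tpl$atoms$sigma[k])
      eps <- sqrt(ip$epsilon * tpl$atoms$eps[k])
      u <- (sig^2 / d^2)^3
      e <- e + 4 * eps * (u^2 - u) + cc * ip$charge * tpl$atoms$charge[k] / d
    }
    e
  }, numeric(1))
  grid[which.min(en)]
}

#' Build an abstract n-ligand coordination cage
#'
#' Places `n` copies of a dipolar ligand with their coordinating oxygens at
#' the vertices of the [anchor_geometry()] for `n`, carbons pointing radially
#' outward. All coordinating oxygens are confined by the one-sided spherical
#' wall; when `kf > 0` every atom of the first ligand set is additionally
#' anchored in a harmonic potential at its built position (which requires the
#' ion's optimal radius `r_opt`, the no-strain condition).
#'
#' @param ion "Li", "Na" or "K".
#' @param n Ligand count (4..8).
#' @param r_opt Optimal ion--oxygen distance (A) from [find_r_opt()];
#'   mandatory when `kf > 0`. When absent, a clash-free placement radius is
#'   taken from a 1-D ion--ligand energy scan.
#' @param kf Anchor force constant (kcal/mol/A^2); 0 means no anchors.
#' @param dual_sets Add a second, anchor-free ligand set (needed for
#'   restraint morphs).
#' @param template Ligand fragment kind (default the formaldehyde-like
#'   abstract ligand).
#' @param wall_k Wall force constant (kcal/mol/A^2).
#' @param temperature Target temperature (K).
#' @param n8 Eight-coordination polyhedron passed to [anchor_geometry()].
#' @param geometry Optional prebuilt [anchor_geometry()] overriding the
#'   default placement directions (its radius is used as the placement
#'   radius).
#' @return A `particle_system`.
#' @examples
#' sys <- build_abstract_system("Na", 6)
#' nrow(sys$atoms)  # 25: one ion + 6 x 4 atoms
#' @export
build_abstract_system <- function(ion, n, r_opt = NULL, kf = 0,
                                  dual_sets = FALSE,
                                  template = "formaldehyde_like",
                                  wall_k = 100, temperature = 310,
                                  n8 = "square_antiprism", geometry = NULL) {
  tpl <- build_ligand_template(template)
  if (kf > 0 && is.null(r_opt) && is.null(geometry))
    stop("anchors require r_opt: the ion's own optimal radius must be supplied when kf > 0")
  if (!is.null(geometry)) {
    stopifnot(inherits(geometry, "anchor_geometry"), geometry$n == n)
    radius <- geometry$radius
    geom <- geometry
  } else {
    radius <- if (!is.null(r_opt)) r_opt else pair_scan_minimum(ion, tpl)
    geom <- anchor_geometry(n, radius, n8 = n8)
  }
  ligands <- list()
  for (i in seq_len(n)) {
    u <- geom$points[i, ] / radius
    ligands[[length(ligands) + 1]] <-
      list(template = tpl, coords = place_ligand(tpl, u, radius), set = 1L)
  }
  if (dual_sets) {
    for (i in seq_len(n)) {
      u <- geom$points[i, ] / radius
      ligands[[length(ligands) + 1]] <-
        list(template = tpl, coords = place_ligand(tpl, u, radius), set = 2L)
    }
  }
  sys <- new_particle_system(ion, ligands, temperature = temperature,
                             wall_k = wall_k,
                             meta = list(kind = "abstract", n = as.integer(n),
                                         template = template, r_opt = r_opt,
                                         kf = kf, anchor_ion = if (kf > 0) ion))
  if (kf > 0) {
    idx <- which(sys$atoms$set == 1L)
    sys$anchors <- list(idx = idx, pos = sys$coords[idx, , drop = FALSE],
                        kf = rep(kf, length(idx)))
  }
  sys
}

#' Energy-minimise a system
#'
#' Adaptive-step steepest descent on the full potential (nonbonded, bonded,
#' wall and anchors) with the ion held fixed. Energy is non-increasing across
#' accepted steps.
#'
#' @param sys A `particle_system`.
#' @param max_steps Iteration budget.
#' @param tol Convergence threshold on the largest force component
#'   (kcal/mol/A).
#' @return The system with minimised coordinates; attributes `converged`,
#'   `iterations` and `max_force` report the termination state.
#' @export
minimise <- function(sys, max_steps = 5000, tol = 0.1) {
  esys <- as_engine_system(sys)
  res <- eng_minimise(esys, sys$coords, sys$alchemy$lambda, as.integer(max_steps), tol)
  sys$coords <- res$coords
  attr(sys, "converged") <- res$converged
  attr(sys, "iterations") <- res$iterations
  attr(sys, "max_force") <- res$max_force
  sys
}

#' Analytic-oracle toy system: non-interacting atoms in harmonic wells
#'
#' A fixed central ion plus `n_atoms` chargeless, dispersionless atoms, each
#' held in its own harmonic anchor. Because the atoms do not interact, the
#' configurational partition function factorises and every thermodynamic
#' quantity is known in closed form: per atom,
#' `dG(kf0 -> kf1) = (3/2) kB T log(kf1/kf0)`, the mean restraint energy is
#' `(3/2) kB T` independent of kf (equipartition), so `dH = 0` and
#' `-T dS = dG` exactly, and the positional RMS fluctuation is
#' `sqrt(3 kB T / kf)`. With `kf_target` set, the system is an alchemical
#' kf-interpolation morph (`lambda` scales the force constant linearly from
#' `kf` to `kf_target`).
#'
#' @param n_atoms Number of anchored atoms.
#' @param kf Anchor force constant (kcal/mol/A^2).
#' @param kf_target Optional target force constant for a kf morph.
#' @param mass Atom mass (amu; oxygen-like default).
#' @param wall Also apply the 3.5 A spherical wall to the atoms.
#' @param spacing Distance between anchor sites (A); they are placed on a
#'   line far apart so the atoms never see each other even with nonzero
#'   parameters.
#' @param temperature Temperature (K).
#' @return A `particle_system`.
#' @export
build_toy_oracle <- function(n_atoms = 1, kf = 1, kf_target = NULL,
                             mass = 15.999, wall = FALSE, spacing = 20,
                             temperature = 310) {
  ip <- ion_params("Na")
  atoms <- data.frame(name = "Na", element = "Na", charge = ip$charge,
                      eps = ip$epsilon, sigma = ip$sigma, mass = ip$mass,
                      set = 0L, ligand = 0L, fragment = "ion",
                      stringsAsFactors = FALSE)
  coords <- matrix(0, 1, 3)
  for (i in seq_len(n_atoms)) {
    atoms <- rbind(atoms, data.frame(
      name = paste0("X", i), element = "O", charge = 0, eps = 0, sigma = 3,
      mass = mass, set = 0L, ligand = i, fragment = "toy",
      stringsAsFactors = FALSE))
    coords <- rbind(coords, c(if (wall) 0 else spacing * i, 0, 0))
  }
  idx <- seq_len(n_atoms) + 1L
  sys <- structure(list(
    ion = c(list(species = "Na"), ip[c("charge", "epsilon", "sigma", "mass")]),
    atoms = atoms, coords = coords,
    bonds = data.frame(i = integer(), j = integer(), r0 = numeric(),
                       k = numeric()),
    angles = data.frame(i = integer(), j = integer(), k = integer(),
                        theta0 = numeric(), ka = numeric()),
    excl = matrix(c(rep(1L, n_atoms), idx), ncol = 2),
    wall = list(atoms = if (wall) idx else integer(0), radius = 3.5, k = 100),
    anchors = list(idx = idx, pos = coords[idx, , drop = FALSE],
                   kf = rep(kf, n_atoms),
                   kf2 = if (!is.null(kf_target)) rep(kf_target, n_atoms)),
    alchemy = list(mode = if (!is.null(kf_target)) "kf_interp" else "none",
                   lambda = 0, ion_to = NULL),
    nb = nonbonded_params(), temperature = temperature,
    meta = list(kind = "toy_oracle", n = n_atoms, kf = kf,
                kf_target = kf_target)
  ), class = "particle_system")
  sys
}

site_fixture_table <- function() {
  tab <- .rlfep$fixture
  if (is.null(tab)) {
    tab <- read_param_table("site_fixtures_synthetic.tsv")
    .rlfep$fixture <- tab
  }
  tab
}

#' Build a transporter-site model
#'
#' Constructs one of the four simplified dipolar-ligand models of the LeuT and
#' Glt_Ph sodium binding sites. The ligand composition follows the packaged
#' site table; starting coordinates come from a packaged synthetic fixture of
#' idealised geometry (not from a crystal structure). The system is energy
#' minimised with the requested ion, and when `kf > 0` the minimised
#' coordinates define the per-atom anchor positions -- each ion therefore gets
#' its own, strain-free anchor set.
#'
#' @param site One of "LeuT_Na1", "LeuT_Na2", "Glt_Na1", "Glt_Na2".
#' @param ion "Li", "Na" or "K".
#' @param kf Anchor force constant (kcal/mol/A^2); 0 builds the wall-only
#'   (fluctuating) site.
#' @param dual_sets Add the duplicate, anchor-free ligand set for restraint
#'   morphs.
#' @param minimise_steps,minimise_tol Passed to [minimise()].
#' @inheritParams build_abstract_system
#' @return A `particle_system` with `meta$site` and, when anchored,
#'   `meta$anchor_ion` set.
#' @export
build_site_model <- function(site, ion, kf = 0, dual_sets = FALSE,
                             wall_k = 100, temperature = 310,
                             minimise_steps = 20000, minimise_tol = 0.05) {
  comp <- site_composition_table()
  comp <- comp[comp$site == site, ]
  if (nrow(comp) == 0)
    stop("unknown site: ", site,
         " (supported: LeuT_Na1, LeuT_Na2, Glt_Na1, Glt_Na2)")
  fixture <- site_fixture_table()
  ligands <- list()
  for (r in seq_len(nrow(comp))) {
    tpl <- build_ligand_template(comp$fragment[r])
    fx <- fixture[fixture$site == site & fixture$residue == comp$residue[r], ]
    if (nrow(fx) != nrow(tpl$atoms))
      stop("fixture entry not found for ", site, "/", comp$residue[r])
    fx <- fx[match(tpl$atoms$name, fx$atom), ]
    ligands[[length(ligands) + 1]] <-
      list(template = tpl, coords = as.matrix(fx[, c("x", "y", "z")]), set = 1L)
  }
  sys <- new_particle_system(ion, ligands, temperature = temperature,
                             wall_k = wall_k,
                             meta = list(kind = "site", site = site, kf = kf,
                                         anchor_ion = if (kf > 0) ion))
  sys <- minimise(sys, max_steps = minimise_steps, tol = minimise_tol)
  if (dual_sets) {
    set1 <- which(sys$atoms$set == 1L)
    lig2 <- list()
    for (id in unique(sys$atoms$ligand[set1])) {
      rows <- which(sys$atoms$ligand == id & sys$atoms$set == 1L)
      tpl <- build_ligand_template(sys$atoms$fragment[rows[1]])
      lig2[[length(lig2) + 1]] <-
        list(template = tpl, coords = sys$coords[rows, , drop = FALSE], set = 1L)
    }
    ligboth <- c(lig2, lapply(lig2, function(l) { l$set <- 2L; l }))
    sys2 <- new_particle_system(ion, ligboth, temperature = temperature,
                                wall_k = wall_k, meta = sys$meta)
    sys <- sys2
  }
  if (kf > 0) {
    idx <- which(sys$atoms$set == 1L)
    sys$anchors <- list(idx = idx, pos = sys$coords[idx, , drop = FALSE],
                        kf = rep(kf, length(idx)))
  }
  sys
}
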