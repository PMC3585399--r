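# Post-processing: radial distribution functions and optimal radii,
# occupancy-grid sampled volumes.

#' Ion--oxygen radial distribution function
#'
#' Histogram of ion--atom distances normalised by shell volume, scaled so
#' that the mean density inside the wall sphere equals one. The first-peak
#' radius -- the optimal ion--ligand distance used for anchor placement -- is
#' the argmax of the first local maximum of the 3-bin smoothed profile above
#' g(r) = 1 (not the global tail maximum).
#'
#' @param traj A `trajectory` (>= 100 frames).
#' @param atoms Indices of the coordinating oxygens (default: the wall atoms
#'   of the originating system).
#' @param bin_width Histogram bin width (A).
#' @param r_max Histogram range (A).
#' @return Object of class `rdf_profile`: `bin_centers`, `g`, `first_peak_r`,
#'   `sample_count`.
#' @export
compute_rdf <- function(traj, atoms = NULL, bin_width = 0.05, r_max = 4.0) {
  nf <- dim(traj$frames)[1]
  if (nf < 100) stop("at least 100 frames are required for a converged RDF")
  if (is.null(atoms)) atoms <- traj$system$wall$atoms
  if (length(atoms) == 0) stop("empty atom selection")
  d <- numeric(0)
  for (a in atoms) {
    xyz <- traj$frames[, a, , drop = TRUE]
    d <- c(d, sqrt(rowSums(xyz^2)))
  }
  breaks <- seq(0, r_max, by = bin_width)
  h <- graphics::hist(d[d < r_max], breaks = breaks, plot = FALSE)
  centers <- h$mids
  shell <- 4 / 3 * pi * (breaks[-1]^3 - breaks[-length(breaks)]^3)
  wall_r <- traj$system$wall$radius
  dens0 <- length(d) / (4 / 3 * pi * wall_r^3)
  g <- h$counts / shell / dens0
  # smoothed first local maximum above 1
  gs <- stats::filter(g, rep(1 / 3, 3), sides = 2)
  gs[is.na(gs)] <- 0
  peak <- NA_real_
  for (i in 2:(length(gs) - 1)) {
    if (gs[i] > 1 && gs[i] >= gs[i - 1] && gs[i] >= gs[i + 1]) {
      window <- max(1, i - 1):min(length(g), i + 1)
      peak <- centers[window[which.max(g[window])]]
      break
    }
  }
  if (is.na(peak)) peak <- centers[which.max(g)]
  structure(list(bin_centers = centers, g = as.numeric(g),
                 first_peak_r = peak, sample_count = length(d)),
            class = "rdf_profile")
}

#' @export
print.rdf_profile <- function(x, ...) {
  cat("RDF profile:", x$sample_count, "samples, first peak at",
      format(x$first_peak_r, digits = 4), "A\n")
  invisible(x)
}

#' Optimal ion--oxygen distance of an unconstrained cage
#'
#' Runs the harmonically unconstrained (wall-only) cage and reads the
#' first-peak radius of the ion--oxygen RDF. This per-ion radius is where
#' anchors must sit for the no-strain condition.
#'
#' @param ion Ion species.
#' @param n Ligand count (4..8).
#' @param nsteps Sampling length (steps of 1 fs).
#' @param seed Integer seed.
#' @param bin_width RDF bin width (A).
#' @param ... Passed to [build_abstract_system()].
#' @return List: `ion`, `n`, `r_opt` (A), `rdf` (the `rdf_profile`), `seed`.
#' @export
find_r_opt <- function(ion, n, nsteps = 100000, seed = 1, bin_width = 0.05,
                       ...) {
  sys <- build_abstract_system(ion, n, ...)
  sys <- minimise(sys, max_steps = 2000, tol = 1)
  tr <- run_dynamics(sys, nsteps, seed = derive_seed(seed, 1))
  rdf <- compute_rdf(tr, bin_width = bin_width)
  list(ion = ion, n = n, r_opt = rdf$first_peak_r, rdf = rdf, seed = seed)
}

#' Occupancy-grid sampled volume
#'
#' Voxelises the union of atomic van der Waals spheres over the trajectory
#' on a cubic grid and reports the volume of the voxels passing the chosen
#' criterion. `"cumulative"` counts a voxel once it has ever been occupied
#' (the configurational volume sampled by the selection over the run);
#' `"frame_fraction"` counts voxels occupied in at least `isovalue` of the
#' frames (VolMap-style averaging).
#'
#' @param traj A `trajectory`.
#' @param atoms Atom indices to include (default: the coordinating oxygens).
#' @param spacing Grid resolution (A), default 0.1.
#' @param isovalue Occupancy threshold for `"frame_fraction"` mode
#'   (fraction of frames; 1.0 = occupied in every frame).
#' @param mode `"cumulative"` (default) or `"frame_fraction"`.
#' @param radii Optional per-atom radii (A); default from the packaged van
#'   der Waals table by element.
#' @return Volume in A^3 (attributes `nvoxel`, `nframes`).
#' @export
occupancy_volume <- function(traj, atoms = NULL, spacing = 0.1,
                             isovalue = 1.0,
                             mode = c("cumulative", "frame_fraction"),
                             radii = NULL) {
  mode <- match.arg(mode)
  if (is.null(atoms)) atoms <- traj$system$wall$atoms
  if (length(atoms) == 0) stop("empty atom selection")
  stopifnot(spacing > 0)
  if (is.null(radii)) {
    rt <- vdw_radii()
    el <- traj$system$atoms$element[atoms]
    if (any(!el %in% names(rt)))
      stop("no van der Waals radius for element(s): ",
           paste(setdiff(el, names(rt)), collapse = ", "))
    radii <- unname(rt[el])
  }
  res <- eng_occupancy(traj$frames, as.integer(atoms - 1L), radii, spacing,
                       isovalue, if (mode == "cumulative") 0L else 1L)
  structure(res$volume, nvoxel = res$nvoxel, nframes = res$nframes)
}
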