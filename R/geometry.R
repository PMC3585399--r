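# Anchor geometries: where the harmonic restraints sit on the sphere around
# the ion. n = 4, 6, 8 use closed-form coordination polyhedra; n = 5, 7 use a
# deterministic repulsion optimisation (circle packing on the sphere).

#' Minimum pairwise angular separation of points on a sphere
#' @param points n x 3 matrix of points (any common radius).
#' @return Smallest pairwise central angle in degrees.
#' @export
min_pair_angle <- function(points) {
  n <- nrow(points)
  r <- sqrt(rowSums(points^2))
  u <- points / r
  best <- 180
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      c_ij <- max(-1, min(1, sum(u[i, ] * u[j, ])))
      best <- min(best, acos(c_ij) * 180 / pi)
    }
  }
  best
}

#' Pack n points on the unit sphere by repulsion optimisation
#'
#' Minimises a steep inverse-power (Riesz) energy in spherical coordinates,
#' sharpening the exponent in stages so the solution approaches the maximin
#' (Tammes) packing. Deterministic for a fixed seed; for n = 4 and 6 the
#' optimum is the regular tetrahedron/octahedron, which this routine recovers
#' to high precision and which serves as its closed-form oracle.
#'
#' @param n Number of points (>= 2).
#' @param seed RNG seed for the random restarts (default 0).
#' @param restarts Number of random starting configurations.
#' @param powers Riesz exponent schedule.
#' @return n x 3 matrix of unit vectors.
#' @export
pack_points_sphere <- function(n, seed = 0, restarts = 5,
                               powers = c(2, 6, 12, 24, 48)) {
  stopifnot(n >= 2)
  ang_to_xyz <- function(a) {
    th <- a[seq_len(n)]
    ph <- a[n + seq_len(n)]
    cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  }
  energy <- function(a, pw) {
    x <- ang_to_xyz(a)
    d2 <- as.matrix(stats::dist(x))^2
    d2 <- d2[upper.tri(d2)]
    sum(pmax(d2, 1e-12)^(-pw / 2))
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  best <- NULL
  best_angle <- -Inf
  for (r in seq_len(restarts)) {
    a <- c(acos(stats::runif(n, -1, 1)), stats::runif(n, 0, 2 * pi))
    for (p in powers) {
      fit <- stats::optim(a, energy, pw = p, method = "BFGS",
                          control = list(maxit = 500, reltol = 1e-15))
      a <- fit$par
    }
    x <- ang_to_xyz(a)
    ang <- min_pair_angle(x)
    if (ang > best_angle) {
      best_angle <- ang
      best <- x
    }
  }
  best
}

#' Anchor geometry for an n-ligand coordination cage
#'
#' Directions at which the coordinating oxygens are restrained: vertices of
#' optimal coordination polyhedra for n = 4 (tetrahedron), 6 (octahedron) and
#' 8 (square antiprism by default; the cube is available), and deterministic
#' sphere packings for n = 5 and 7.
#'
#' @param n Ligand count, 4..8.
#' @param radius Sphere radius R in Angstrom (the optimal ion--oxygen
#'   distance when used for anchor placement).
#' @param n8 Eight-coordination polyhedron: "square_antiprism" (the
#'   8-point packing optimum) or "cube".
#' @param seed Seed for the n = 5, 7 packing optimiser.
#' @return Object of class `anchor_geometry`: list with `n`, `radius`,
#'   `points` (n x 3, all of norm `radius`), `source`, `min_angle` (degrees).
#' @examples
#' g <- anchor_geometry(6, 2.3)
#' g$min_angle  # 90 degrees, the octahedral optimum
#' @export
anchor_geometry <- function(n, radius, n8 = c("square_antiprism", "cube"),
                            seed = 0) {
  if (!is.numeric(n) || length(n) != 1 || n != round(n) || n < 4 || n > 8)
    stop("unsupported coordination number: n must be an integer in 4..8")
  if (!is.numeric(radius) || radius <= 0) stop("radius must be positive")
  n8 <- match.arg(n8)
  source <- "polyhedron"
  if (n == 4) {
    u <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  } else if (n == 6) {
    u <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
               c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  } else if (n == 8) {
    if (n8 == "cube") {
      u <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))) / sqrt(3)
      dimnames(u) <- NULL
    } else {
      # square antiprism with all nearest-neighbour separations equal:
      # r^2 = 1 / (1 + sqrt(2)/4), h^2 = 1 - r^2
      r <- sqrt(1 / (1 + sqrt(2) / 4))
      h <- sqrt(1 - r^2)
      phi_top <- (0:3) * pi / 2
      phi_bot <- phi_top + pi / 4
      u <- rbind(cbind(r * cos(phi_top), r * sin(phi_top), h),
                 cbind(r * cos(phi_bot), r * sin(phi_bot), -h))
    }
  } else {
    key <- paste0("pack", n, "_", seed)
    u <- .rlfep[[key]]
    if (is.null(u)) {
      u <- pack_points_sphere(n, seed = seed)
      .rlfep[[key]] <- u
    }
    source <- "sphere_packing"
  }
  pts <- u * radius
  structure(list(n = as.integer(n), radius = radius, points = pts,
                 source = source, min_angle = min_pair_angle(pts)),
            class = "anchor_geometry")
}

#' @export
print.anchor_geometry <- function(x, ...) {
  cat("Anchor geometry: n =", x$n, " R =", format(x$radius, digits = 4),
      "A  (", x$source, ")\n")
  cat("  minimum pairwise angle:", format(x$min_angle, digits = 6), "deg\n")
  if (!is.null(attr(x, "ion"))) cat("  optimised for ion:", attr(x, "ion"), "\n")
  invisible(x)
}

#' Anchor geometry at an ion's own optimal radius
#'
#' Tags the geometry with the ion it was measured for, which
#' [run_restraint_morph()] uses to guarantee the no-strain condition.
#'
#' @param ion Ion species the radius belongs to.
#' @param n Ligand count.
#' @param r_opt First-peak radius from [find_r_opt()] for this ion and n.
#' @param ... Passed to [anchor_geometry()].
#' @return `anchor_geometry` with an `ion` attribute.
#' @export
cage_anchors <- function(ion, n, r_opt, ...) {
  g <- anchor_geometry(n, r_opt, ...)
  attr(g, "ion") <- ion
  g
}
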