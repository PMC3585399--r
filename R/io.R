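# Plain-text input/output: XYZ snapshots and trajectories, energy series,
# run metadata.

#' Write coordinates as (multi-frame) XYZ
#'
#' @param x A `particle_system` (single frame) or `trajectory` (one XYZ block
#'   per saved frame).
#' @param file Output path.
#' @param comment Comment-line text; defaults to the ion species and anchor
#'   force constant.
#' @return The file path, invisibly.
#' @export
write_xyz <- function(x, file, comment = NULL) {
  con <- file(file, "w")
  on.exit(close(con))
  if (inherits(x, "particle_system")) {
    frames <- list(x$coords)
    atoms <- x$atoms
    sys <- x
  } else if (inherits(x, "trajectory")) {
    nf <- dim(x$frames)[1]
    frames <- lapply(seq_len(nf), function(f) x$frames[f, , , drop = TRUE])
    atoms <- x$system$atoms
    sys <- x$system
  } else stop("x must be a particle_system or trajectory")
  if (is.null(comment)) {
    kf <- if (is.null(sys$anchors)) 0 else sys$anchors$kf[1]
    comment <- paste0("ion=", sys$ion$species, " kf=", kf)
  }
  for (fr in frames) {
    writeLines(as.character(nrow(atoms)), con)
    writeLines(comment, con)
    writeLines(sprintf("%-2s %12.6f %12.6f %12.6f", atoms$element,
                       fr[, 1], fr[, 2], fr[, 3]), con)
  }
  invisible(file)
}

#' Read a (multi-frame) XYZ file
#' @param file Path.
#' @return List with `elements` (character vector) and `frames` (list of
#'   n x 3 matrices), plus `comments`.
#' @export
read_xyz <- function(file) {
  lines <- readLines(file)
  frames <- list()
  comments <- character(0)
  elements <- NULL
  i <- 1
  while (i <= length(lines)) {
    nat <- as.integer(lines[i])
    comments <- c(comments, lines[i + 1])
    block <- lines[(i + 2):(i + 1 + nat)]
    parts <- strsplit(trimws(block), "\\s+")
    el <- vapply(parts, `[[`, "", 1)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (is.null(elements)) elements <- el
    frames[[length(frames) + 1]] <- xyz
    i <- i + 2 + nat
  }
  list(elements = elements, frames = frames, comments = comments)
}

#' Write a trajectory's energy series as CSV
#' @param traj A `trajectory`.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_energy_series <- function(traj, file) {
  write.csv(traj$energies, file, row.names = FALSE)
  invisible(file)
}

#' Write run metadata as a JSON sidecar
#' @param traj A `trajectory`.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_run_metadata <- function(traj, file) {
  meta <- list(seed = traj$seed, temperature = traj$temperature,
               timestep = traj$timestep, friction = traj$friction,
               lambda = traj$system$alchemy$lambda,
               mode = traj$system$alchemy$mode,
               natom = traj$natom, nframes = dim(traj$frames)[1])
  jsonlite::write_json(meta, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
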