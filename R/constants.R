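# Physical constants and packaged parameter tables.

.rlfep <- new.env(parent = emptyenv())

#' Physical constants used throughout the package
#'
#' @return Named list: `kB` (kcal/mol/K), `coulomb` (kcal*A/(mol*e^2)),
#'   the CODATA-derived electrostatic prefactor, and `fconv`, the conversion
#'   from kcal/mol/A/amu to A/fs^2.
#' @export
rlf_constants <- function() {
  list(kB = 0.0019872041, coulomb = 332.0637, fconv = 4.184e-4)
}

extdata_file <- function(name) {
  path <- system.file("extdata", name, package = "rlfep")
  if (!nzchar(path) || !file.exists(path)) {
    # during in-source development
    path <- file.path("inst", "extdata", name)
  }
  if (!file.exists(path)) stop("packaged data file not found: ", name)
  path
}

read_param_table <- function(name) {
  read.delim(extdata_file(name), comment.char = "#", stringsAsFactors = FALSE)
}

#' Ion nonbonded parameters
#'
#' Lennard-Jones parameters and charges of the Li+, Na+ and K+ models
#' (Joung--Cheatham, TIP3P-compatible set). `sigma` is derived from the
#' published Rmin/2 as `sigma = 2 * rmin2 / 2^(1/6)`.
#'
#' @param species Optional species name ("Li", "Na", "K"); if given, a
#'   single-row list is returned.
#' @return Data frame (or list for one species) with `species`, `charge`,
#'   `epsilon`, `rmin2`, `sigma`, `mass`.
#' @export
ion_params <- function(species = NULL) {
  tab <- .rlfep$ions
  if (is.null(tab)) {
    tab <- read_param_table("ion_params.tsv")
    tab$sigma <- 2 * tab$rmin2 / 2^(1 / 6)
    .rlfep$ions <- tab
  }
  if (is.null(species)) return(tab)
  row <- tab[tab$species == species, ]
  if (nrow(row) != 1) stop("unknown ion species: ", species)
  as.list(row)
}

#' Hydration free-energy difference between two ions
#'
#' Bulk-water leg of the exchange cycle, taken as the difference of the
#' packaged single-ion hydration free energies of the ion models.
#'
#' @param from,to Ion species names.
#' @return `dG_hydr(to) - dG_hydr(from)` in kcal/mol.
#' @export
hydration_ddG <- function(from, to) {
  tab <- .rlfep$hydr
  if (is.null(tab)) {
    tab <- read_param_table("hydration_free_energies.tsv")
    .rlfep$hydr <- tab
  }
  g <- function(s) {
    row <- tab[tab$species == s, ]
    if (nrow(row) != 1) stop("no hydration free energy for species: ", s)
    row$dG_hydr
  }
  g(to) - g(from)
}

#' van der Waals radii used by the occupancy-volume tool
#' @return Named numeric vector of radii (Angstrom) by element.
#' @export
vdw_radii <- function() {
  tab <- .rlfep$vdw
  if (is.null(tab)) {
    tab <- read_param_table("vdw_radii.tsv")
    .rlfep$vdw <- tab
  }
  setNames(tab$radius, tab$element)
}

fragment_defs <- function() {
  defs <- .rlfep$fragments
  if (is.null(defs)) {
    defs <- yaml::read_yaml(extdata_file("fragments.yaml"))
    .rlfep$fragments <- defs
  }
  defs
}

site_composition_table <- function() {
  tab <- .rlfep$sites
  if (is.null(tab)) {
    tab <- read_param_table("site_compositions.tsv")
    .rlfep$sites <- tab
  }
  tab
}
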