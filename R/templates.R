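# Ligand templates: small dipolar fragments used to build coordination cages
# and transporter-site models.

#' Build a ligand template
#'
#' Returns one of the supported dipolar ligand fragments with its charges,
#' Lennard-Jones parameters, harmonic bond/angle terms and idealised local
#' geometry. The local frame places the coordinating point at the origin with
#' +z pointing away from the ion. The abstract cage ligand
#' (`"formaldehyde_like"`) carries partial charges C +0.5, O -0.5, H 0.0.
#'
#' @param kind One of `"formaldehyde_like"`, `"backbone_carbonyl"`,
#'   `"hydroxyl"`, `"carboxylate"`.
#' @return An object of class `ligand_template` with elements `name`, `atoms`
#'   (data frame: name, element, charge, eps, sigma, rmin2, mass, x, y, z),
#'   `bonds`, `angles` (theta0 in radians), `coordinating` (indices of the
#'   coordinating oxygens; two for the bidentate carboxylate) and `net_charge`.
#' @examples
#' tpl <- build_ligand_template("formaldehyde_like")
#' tpl$atoms$charge   # +0.5, -0.5, 0, 0
#' @export
build_ligand_template <- function(kind) {
  defs <- fragment_defs()
  if (!is.character(kind) || length(kind) != 1 || !kind %in% names(defs)) {
    stop("unsupported ligand template: ", paste(kind, collapse = ", "),
         " (supported: ", paste(names(defs), collapse = ", "), ")")
  }
  d <- defs[[kind]]
  atoms <- do.call(rbind, lapply(d$atoms, function(a) {
    data.frame(name = a$name, element = a$element, charge = a$charge,
               eps = a$eps, rmin2 = a$rmin2,
               sigma = 2 * a$rmin2 / 2^(1 / 6), mass = a$mass,
               x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE)
  }))
  bonds <- do.call(rbind, lapply(d$bonds, function(b) {
    data.frame(i = b$i, j = b$j, r0 = b$r0, k = b$k)
  }))
  angles <- do.call(rbind, lapply(d$angles, function(a) {
    data.frame(i = a$i, j = a$j, k = a$k, theta0 = a$theta0 * pi / 180,
               ka = a$ka)
  }))
  tpl <- structure(list(
    name = kind, atoms = atoms, bonds = bonds, angles = angles,
    coordinating = as.integer(unlist(d$coordinating)),
    net_charge = sum(atoms$charge)
  ), class = "ligand_template")
  validate_ligand_template(tpl)
  tpl
}

validate_ligand_template <- function(tpl) {
  stopifnot(inherits(tpl, "ligand_template"))
  if (abs(sum(tpl$atoms$charge) - tpl$net_charge) > 1e-12)
    stop("template charges do not sum to net_charge")
  nat <- nrow(tpl$atoms)
  idx <- c(tpl$bonds$i, tpl$bonds$j, tpl$angles$i, tpl$angles$j, tpl$angles$k)
  if (any(idx < 1 | idx > nat))
    stop("bond/angle references a missing atom")
  nco <- length(tpl$coordinating)
  if (!nco %in% c(1L, 2L))
    stop("template must have one (monodentate) or two (bidentate) coordinating atoms")
  invisible(tpl)
}

#' @export
print.ligand_template <- function(x, ...) {
  cat("Ligand template:", x$name, "\n")
  cat("  atoms:", nrow(x$atoms), " net charge:", x$net_charge, "e\n")
  cat("  coordinating atom(s):",
      paste(x$atoms$name[x$coordinating], collapse = ", "), "\n")
  invisible(x)
}
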