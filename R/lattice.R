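#' Build one conventional FCC cell of charged nanoparticles
#'
#' Places four nanoparticles per conventional cell -- one corner site at the
#' origin and three face-center sites -- in a cubic periodic box of edge
#' \code{lattice_constant}. All NPs carry the same positive charge and fixed
#' positions; the lattice is the rigid framework through which anions move.
#'
#' @param lattice_constant Cell edge a in nm. Must exceed twice
#'   \code{np_radius}.
#' @param np_radius Nanoparticle (hard-core) radius in nm.
#' @param np_charge Positive charge per NP in elementary charges e.
#' @return Object of class \code{lattice_model}: list with
#'   \code{lattice_constant}, \code{box} (3-vector nm), \code{np_positions}
#'   (4 x 3 matrix), \code{site_type} ("corner"/"face"), \code{np_radius},
#'   \code{np_charge_per_site}.
#' @examples
#' lat <- build_fcc(10)
#' lat$np_positions
#' @export
build_fcc <- function(lattice_constant = 10, np_radius = 1.0, np_charge = 60) {
  a <- lattice_constant
  stopifnot(a > 0, np_radius > 0, np_charge >= 0)
  if (a <= 2 * np_radius)
    stop("overlapping NPs: lattice_constant must exceed 2*np_radius ",
         sprintf("(nearest-neighbor distance a/sqrt(2) = %.3f, diameter %.3f)",
                 a / sqrt(2), 2 * np_radius))
  if (a / sqrt(2) <= 2 * np_radius)
    stop("overlapping NPs: nearest-neighbor distance a/sqrt(2) = ",
         sprintf("%.3f <= NP diameter %.3f", a / sqrt(2), 2 * np_radius))
  pos <- rbind(c(0, 0, 0),
               c(a / 2, a / 2, 0),
               c(a / 2, 0, a / 2),
               c(0, a / 2, a / 2))
  colnames(pos) <- c("x", "y", "z")
  structure(list(
    lattice_constant = a,
    box = c(a, a, a),
    np_positions = pos,
    site_type = c("corner", "face", "face", "face"),
    np_radius = np_radius,
    np_charge_per_site = rep(np_charge, nrow(pos))
  ), class = "lattice_model")
}

#' A periodic box with no nanoparticles (free-solution control)
#'
#' Used for closed-form checks of the integrator (free drift, Einstein
#' diffusion) where the lattice framework is absent.
#'
#' @param box Box edge lengths, nm (scalar recycled to 3).
#' @return A \code{lattice_model} with zero NP sites.
#' @export
empty_lattice <- function(box = c(10, 10, 10)) {
  box <- rep(box, length.out = 3)
  stopifnot(all(box > 0))
  pos <- matrix(numeric(0), nrow = 0, ncol = 3,
                dimnames = list(NULL, c("x", "y", "z")))
  structure(list(
    lattice_constant = NA_real_, box = box, np_positions = pos,
    site_type = character(0), np_radius = 0,
    np_charge_per_site = numeric(0)
  ), class = "lattice_model")
}

#' @export
print.lattice_model <- function(x, ...) {
  cat(sprintf("Lattice: %d NPs in box (%g, %g, %g) nm\n",
              nrow(x$np_positions), x$box[1], x$box[2], x$box[3]))
  if (nrow(x$np_positions) > 0)
    cat(sprintf("  radius %g nm, charge %+g e per NP, a = %g nm\n",
                x$np_radius, x$np_charge_per_site[1], x$lattice_constant))
  invisible(x)
}

#' Uniform electric field specification
#'
#' @param magnitude Field strength in V/nm, non-negative. The default working
#'   range is 0 to 0.4 V/nm; larger values require \code{override = TRUE}
#'   (strong fields deform real superlattice frameworks, which the rigid
#'   generator cannot represent).
#' @param axis Field direction (default +x); normalized internally.
#' @param max_magnitude Upper limit of the allowed range.
#' @param override Allow magnitudes above \code{max_magnitude}.
#' @return Object of class \code{field_spec}.
#' @export
field_spec <- function(magnitude = 0, axis = c(1, 0, 0),
                       max_magnitude = 0.4, override = FALSE) {
  stopifnot(length(axis) == 3, is.numeric(magnitude), length(magnitude) == 1)
  if (magnitude < 0) stop("field magnitude must be >= 0")
  if (magnitude > max_magnitude && !override)
    stop(sprintf("field %g V/nm outside [0, %g]; set override = TRUE to allow",
                 magnitude, max_magnitude))
  nrm <- sqrt(sum(axis^2))
  if (nrm == 0) stop("field axis must be a nonzero vector")
  structure(list(magnitude = magnitude, axis = axis / nrm),
            class = "field_spec")
}
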