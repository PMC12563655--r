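#' Build a multivalent anion species
#'
#' Constructs one of the four canonical phosphate-like anion models --
#' pyrophosphate \code{"P2"} (linear, 2 beads, total charge -4 e),
#' trimetaphosphate \code{"P3"} (ring, 3 beads, -3 e), tetraphosphate
#' \code{"P4"} (linear, 4 beads, -6 e) and hexametaphosphate \code{"P6"}
#' (ring, 6 beads, -6 e) -- or a user-defined species. The total charge is
#' distributed uniformly over the beads; it is the charge q entering the
#' electrophoretic force F = qE. Linear species place their beads collinearly
#' at \code{bond_length} spacing; ring species place them on a regular polygon
#' of side \code{bond_length}.
#'
#' @param name Species name. One of \code{"P2"}, \code{"P3"}, \code{"P4"},
#'   \code{"P6"}, or the \code{name} field of \code{custom}.
#' @param bead_diameter Bead diameter in nm (steric size).
#' @param bond_length Bead-bead bond length in nm.
#' @param custom Optional list defining a non-canonical species with fields
#'   \code{name}, \code{topology} (\code{"linear"} or \code{"ring"}),
#'   \code{n_beads} and \code{total_charge} (negative, in e).
#' @return An object of class \code{anion_species}: a list with fields
#'   \code{name}, \code{topology}, \code{n_beads}, \code{bead_charges},
#'   \code{bead_diameter}, \code{bond_length}, \code{total_charge} and
#'   \code{body} (n_beads x 3 body-frame coordinates about the geometric
#'   center).
#' @examples
#' p3 <- build_species("P3")
#' p3$total_charge   # -3
#' @export
build_species <- function(name, bead_diameter = 0.47, bond_length = 0.35,
                          custom = NULL) {
  canon <- list(
    P2 = list(topology = "linear", n_beads = 2L, total_charge = -4),
    P3 = list(topology = "ring",   n_beads = 3L, total_charge = -3),
    P4 = list(topology = "linear", n_beads = 4L, total_charge = -6),
    P6 = list(topology = "ring",   n_beads = 6L, total_charge = -6)
  )
  if (!is.null(custom) && identical(custom$name, name)) {
    def <- custom
  } else if (name %in% names(canon)) {
    def <- canon[[name]]
  } else {
    stop("species not found: '", name,
         "' (known: P2, P3, P4, P6; or supply a custom species block)")
  }
  topology <- match.arg(def$topology, c("linear", "ring"))
  n <- as.integer(def$n_beads)
  if (topology == "ring" && n < 3L)
    stop("ring topology requires at least 3 beads")
  if (topology == "linear" && n < 2L)
    stop("linear topology requires at least 2 beads")
  stopifnot(bead_diameter > 0, bond_length > 0)
  total <- def$total_charge
  if (!is.null(def$bead_charges)) {
    bead_charges <- def$bead_charges
    if (length(bead_charges) != n) stop("bead_charges length must equal n_beads")
    total <- sum(bead_charges)
  } else {
    bead_charges <- rep(total / n, n)
  }
  if (total >= 0) stop("anion total charge must be negative")

  body <- species_body_coords(topology, n, bond_length)
  structure(list(
    name = name, topology = topology, n_beads = n,
    bead_charges = bead_charges, bead_diameter = bead_diameter,
    bond_length = bond_length, total_charge = total, body = body
  ), class = "anion_species")
}

# Body-frame bead coordinates, centered on the geometric center.
species_body_coords <- function(topology, n, bond_length) {
  if (topology == "linear") {
    z <- (seq_len(n) - (n + 1) / 2) * bond_length
    cbind(x = numeric(n), y = numeric(n), z = z)
  } else {
    rc <- bond_length / (2 * sin(pi / n))  # circumradius of regular n-gon
    th <- 2 * pi * (seq_len(n) - 1) / n
    cbind(x = rc * cos(th), y = rc * sin(th), z = numeric(n))
  }
}

#' @export
print.anion_species <- function(x, ...) {
  cat(sprintf("Anion species %s: %s, %d beads, total charge %+g e (%g e/bead)\n",
              x$name, x$topology, x$n_beads, x$total_charge,
              x$bead_charges[1]))
  cat(sprintf("  bead diameter %g nm, bond length %g nm\n",
              x$bead_diameter, x$bond_length))
  invisible(x)
}

#' Number of anions needed to neutralize the lattice
#'
#' The superlattice cell carries a net positive charge (4 NPs x np_charge);
#' the counterion population must cancel it exactly.
#'
#' @param lattice A \code{lattice_model} from \code{\link{build_fcc}}.
#' @param species An \code{anion_species} from \code{\link{build_species}}.
#' @return Integer number of anions.
#' @examples
#' neutralize(build_fcc(), build_species("P3"))  # 240/3 = 80
#' @export
neutralize <- function(lattice, species) {
  qtot <- sum(lattice$np_charge_per_site)
  if (qtot <= 0) stop("total NP charge must be positive to neutralize")
  qa <- abs(species$total_charge)
  n <- qtot / qa
  if (abs(n - round(n)) > 1e-9)
    stop(sprintf(paste0("cannot neutralize: total NP charge %g is not divisible ",
                        "by anion charge %g; adjust np_charge"), qtot, qa))
  as.integer(round(n))
}
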