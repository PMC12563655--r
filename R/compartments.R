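#' Compartment geometry of the superlattice cell
#'
#' The void space of the cell is partitioned into three compartments by
#' radial distance to lattice sites: tetrahedral cavities (within
#' \code{r_tet} of FCC corner sites), octahedral cavities (within
#' \code{r_oct} of face-center sites), and the NP-NP interface (all
#' remaining void space). Distances are measured to the nearest periodic
#' image of each site. When a point satisfies both radial conditions the
#' tetrahedral label takes precedence (configurable; the regions are
#' disjoint at the default geometry).
#'
#' @param lattice A \code{lattice_model}; corner and face sites are taken
#'   from its site types.
#' @param r_tet Tetrahedral radius, nm (default 2.0).
#' @param r_oct Octahedral radius, nm (default 2.5).
#' @param precedence Which label wins when both conditions hold.
#' @return Object of class \code{compartment_spec}.
#' @export
compartment_spec <- function(lattice = build_fcc(), r_tet = 2.0, r_oct = 2.5,
                             precedence = c("tetrahedral", "octahedral")) {
  stopifnot(r_tet > 0, r_oct > 0)
  precedence <- match.arg(precedence)
  corners <- lattice$np_positions[lattice$site_type == "corner", , drop = FALSE]
  faces <- lattice$np_positions[lattice$site_type == "face", , drop = FALSE]
  if (nrow(corners) == 0 || nrow(faces) == 0)
    stop("lattice must have corner and face sites")
  structure(list(r_tet = r_tet, r_oct = r_oct,
                 corner_sites = corners, face_sites = faces,
                 box = lattice$box, precedence = precedence),
            class = "compartment_spec")
}

# Minimum-image distances from points (m x 3) to the nearest of a site set.
min_site_dist <- function(pts, sites, box) {
  d <- rep(Inf, nrow(pts))
  for (k in seq_len(nrow(sites))) {
    dd <- sweep(pts, 2, sites[k, ], "-")
    dd <- dd - sweep(round(sweep(dd, 2, box, "/")), 2, box, "*")
    d <- pmin(d, sqrt(rowSums(dd^2)))
  }
  d
}

#' Classify a point into a compartment
#'
#' @param p A 3-vector (or m x 3 matrix of points) inside the box.
#' @param spec A \code{compartment_spec}.
#' @return Character label(s): \code{"T"} (tetrahedral), \code{"O"}
#'   (octahedral) or \code{"I"} (interface).
#' @examples
#' spec <- compartment_spec(build_fcc(10))
#' classify_point(c(5, 5, 2), spec)  # "O": 2.0 nm from the (5,5,0) site
#' @export
classify_point <- function(p, spec) {
  pts <- if (is.matrix(p)) p else matrix(p, ncol = 3)
  d_c <- min_site_dist(pts, spec$corner_sites, spec$box)
  d_f <- min_site_dist(pts, spec$face_sites, spec$box)
  in_t <- d_c <= spec$r_tet
  in_o <- d_f <= spec$r_oct
  lab <- rep("I", nrow(pts))
  if (spec$precedence == "tetrahedral") {
    lab[in_o] <- "O"
    lab[in_t] <- "T"
  } else {
    lab[in_t] <- "T"
    lab[in_o] <- "O"
  }
  lab
}

#' Classify every anion center in every frame
#'
#' Applies \code{\link{classify_point}} to each anion geometric center in
#' each frame of a trajectory.
#'
#' @param traj A \code{trajectory}.
#' @param spec A \code{compartment_spec}; default built from a standard cell
#'   with the trajectory's box (cubic boxes only).
#' @return A \code{label_series}: character matrix n_anions x n_frames with
#'   values in \{"I","T","O"\} and attributes \code{dt} (frame spacing) and
#'   \code{times}.
#' @export
classify_trajectory <- function(traj, spec = NULL) {
  if (n_frames(traj) < 1) stop("empty trajectory")
  if (is.null(spec)) {
    if (length(unique(traj$box)) != 1)
      stop("supply a compartment_spec for non-cubic boxes")
    spec <- compartment_spec(build_fcc(traj$box[1]))
  }
  n <- n_anions(traj); nf <- n_frames(traj)
  labels <- matrix("", n, nf)
  for (f in seq_len(nf))
    labels[, f] <- classify_point(matrix(traj$centers[, , f], n, 3), spec)
  dt <- if (nf > 1) stats::median(diff(traj$frame_times)) else NA_real_
  structure(labels, dt = dt, times = traj$frame_times,
            class = "label_series")
}

#' @export
print.label_series <- function(x, ...) {
  tab <- table(factor(x, levels = c("O", "I", "T")))
  cat(sprintf("Label series: %d anions x %d frames (dt = %g)\n",
              nrow(x), ncol(x), attr(x, "dt")))
  cat(sprintf("  occupancy O %.3f | I %.3f | T %.3f\n",
              tab["O"] / length(x), tab["I"] / length(x), tab["T"] / length(x)))
  invisible(x)
}

#' Per-compartment occupancy fractions
#'
#' Fraction of all (anion, frame) cells carrying each label; the three
#' fractions sum to one.
#'
#' @param labels A \code{label_series} (or any character matrix of labels).
#' @return Named numeric vector in compartment order (O, I, T).
#' @export
occupancy <- function(labels) {
  if (length(labels) == 0) stop("labels must be non-empty")
  tab <- table(factor(labels, levels = c("O", "I", "T")))
  as.vector(tab / length(labels)) -> fr
  names(fr) <- c("O", "I", "T")
  fr
}
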