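#' Trajectory container
#'
#' Saved frames of anion geometric centers in a periodic box. Coordinates are
#' wrapped Cartesian nm in [0, box) with the origin at the corner NP; the
#' periodic image each anion currently occupies is carried separately in
#' \code{wrap_counts}, so the unwrapped position is
#' \code{centers + wrap_counts * box}.
#'
#' @param centers Numeric array n_anions x 3 x n_frames of wrapped centers.
#' @param frame_times Strictly increasing frame times (reduced units).
#' @param box Box edge lengths (3-vector, nm).
#' @param wrap_counts Optional integer array n_anions x 3 x n_frames of
#'   periodic image indices; absent (NULL) for imported files without image
#'   flags.
#' @param species_name Species label carried into output files.
#' @param beads Optional bead-position array (n_anions*n_beads) x 3 x
#'   n_frames.
#' @param metadata Named list (seed, field, config hash, ...).
#' @return Object of class \code{trajectory}.
#' @export
trajectory <- function(centers, frame_times, box, wrap_counts = NULL,
                       species_name = "X", beads = NULL, metadata = list()) {
  stopifnot(length(dim(centers)) == 3, dim(centers)[2] == 3)
  n_frames <- dim(centers)[3]
  stopifnot(length(frame_times) == n_frames, length(box) == 3)
  if (n_frames > 1 && any(diff(frame_times) <= 0))
    stop("frame_times must be strictly increasing")
  if (!is.null(wrap_counts))
    stopifnot(identical(dim(wrap_counts), dim(centers)))
  for (a in 1:3) {
    bad <- centers[, a, ] < 0 | centers[, a, ] >= box[a]
    if (any(bad))
      stop("wrapped coordinates must lie in [0, box) on every axis")
  }
  structure(list(centers = centers, wrap_counts = wrap_counts,
                 frame_times = frame_times, box = box,
                 species_name = species_name, beads = beads,
                 metadata = metadata),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d anions (%s), %d frames, box (%g, %g, %g) nm\n",
              dim(x$centers)[1], x$species_name, dim(x$centers)[3],
              x$box[1], x$box[2], x$box[3]))
  if (!is.null(x$metadata$field))
    cat(sprintf("  field %g V/nm, seed %s, config %s\n", x$metadata$field,
                format(x$metadata$seed), format(x$metadata$config_hash)))
  if (is.null(x$wrap_counts)) cat("  (no periodic image flags)\n")
  invisible(x)
}

#' Number of frames / anions in a trajectory
#' @param traj A \code{trajectory}.
#' @export
n_frames <- function(traj) dim(traj$centers)[3]

#' @rdname n_frames
#' @export
n_anions <- function(traj) dim(traj$centers)[1]

#' Unwrap a trajectory into displacements from the first frame
#'
#' If periodic image counts are present, the unwrapped position is
#' \code{wrapped + wrap_counts * box}. Otherwise frame-to-frame displacements
#' are reconstructed by the minimum-image convention, which is valid only
#' while every per-frame jump is smaller than half the box; a jump at or
#' beyond box/2 raises an ambiguity error.
#'
#' @param traj A \code{trajectory}.
#' @return Object of class \code{displacements}: array n_anions x 3 x
#'   n_frames of displacements relative to frame 1 (exactly zero there),
#'   with attributes \code{times} and \code{box}.
#' @export
unwrap <- function(traj) {
  cen <- traj$centers
  n <- dim(cen)[1]; nf <- dim(cen)[3]
  box <- traj$box
  if (!is.null(traj$wrap_counts)) {
    unwrapped <- cen
    for (a in 1:3) unwrapped[, a, ] <- cen[, a, ] + traj$wrap_counts[, a, ] * box[a]
  } else {
    unwrapped <- cen
    if (nf > 1) {
      for (f in 2:nf) {
        d <- cen[, , f, drop = FALSE] - cen[, , f - 1, drop = FALSE]
        d <- array(d, c(n, 3))
        for (a in 1:3) {
          d[, a] <- d[, a] - box[a] * round(d[, a] / box[a])
          if (any(abs(d[, a]) >= box[a] / 2 * (1 - 1e-12)))
            stop(sprintf(paste0("ambiguous unwrapping: frame-to-frame jump >= ",
                                "box/2 on axis %d between frames %d and %d ",
                                "(no image flags available)"), a, f - 1, f))
        }
        unwrapped[, , f] <- array(unwrapped[, , f - 1], c(n, 3)) + d
      }
    }
  }
  disp <- unwrapped
  for (f in seq_len(nf)) disp[, , f] <- array(unwrapped[, , f], c(n, 3)) -
    array(unwrapped[, , 1], c(n, 3))
  structure(disp, times = traj$frame_times, box = box,
            class = "displacements")
}

# Subset a trajectory to a frame range (used for concatenation properties).
#' @export
`[.trajectory` <- function(x, frames) {
  trajectory(centers = x$centers[, , frames, drop = FALSE],
             wrap_counts = if (!is.null(x$wrap_counts))
               x$wrap_counts[, , frames, drop = FALSE],
             frame_times = x$frame_times[frames], box = x$box,
             species_name = x$species_name,
             beads = if (!is.null(x$beads)) x$beads[, , frames, drop = FALSE],
             metadata = x$metadata)
}
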