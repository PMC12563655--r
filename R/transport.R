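#' Per-anion mean axial velocities
#'
#' Endpoint drift velocity of every anion along one axis: the unwrapped
#' displacement between the first and last frame divided by the elapsed
#' time. Robust to the saving stride; a windowed-slope alternative is
#' available via \code{method = "slope"} (least-squares slope of x(t)).
#'
#' @param disp A \code{displacements} object from \code{\link{unwrap}}.
#' @param axis Axis index (1 = x, the field axis by default).
#' @param method \code{"endpoint"} (default) or \code{"slope"}.
#' @return Numeric vector of per-anion mean velocities (nm per time unit).
#' @export
axial_velocities <- function(disp, axis = 1L, method = c("endpoint", "slope")) {
  method <- match.arg(method)
  times <- attr(disp, "times")
  nf <- dim(disp)[3]
  if (nf < 2) stop("need at least 2 frames")
  elapsed <- times[nf] - times[1]
  if (elapsed <= 0) stop("zero elapsed time")
  x <- matrix(disp[, axis, ], dim(disp)[1], nf)
  if (method == "endpoint") {
    (x[, nf] - x[, 1]) / elapsed
  } else {
    tc <- times - mean(times)
    as.vector(x %*% tc) / sum(tc^2)
  }
}

#' Instantaneous per-frame axial velocities
#'
#' Finite-difference velocities between consecutive frames, for displacement
#' and velocity distributions.
#'
#' @inheritParams axial_velocities
#' @return Matrix n_anions x (n_frames - 1).
#' @export
frame_velocities <- function(disp, axis = 1L) {
  times <- attr(disp, "times")
  nf <- dim(disp)[3]
  if (nf < 2) stop("need at least 2 frames")
  x <- matrix(disp[, axis, ], dim(disp)[1], nf)
  dx <- x[, -1, drop = FALSE] - x[, -nf, drop = FALSE]
  sweep(dx, 2, diff(times), "/")
}

#' Ionic current, conductivity and resistivity from drift velocities
#'
#' The box-averaged drift current along the field axis is
#' I = (1/L_x) * sum_i q_i vbar_i with q_i the anion total charge (e) and
#' vbar_i its mean axial velocity, so anions (negative q) drifting against
#' the axis carry positive conventional current. The current density is
#' J = I / (L_y L_z), the conductivity sigma = J / E for E > 0, and the
#' resistivity rho = 1/sigma. At zero field sigma and rho are undefined
#' (NA). All quantities are in reduced units (charge e, time tau, length
#' nm); E is the nominal field in V/nm.
#'
#' @param vbar Per-anion mean axial velocities from
#'   \code{\link{axial_velocities}}.
#' @param species The \code{anion_species} (its total charge enters q_i).
#' @param box Box edge lengths (3-vector nm).
#' @param field Field magnitude E in V/nm (>= 0; the axis carries the sign).
#' @return Object of class \code{transport_summary}: list with \code{vbar},
#'   \code{v_mean}, \code{v_se}, \code{current}, \code{current_density},
#'   \code{conductivity}, \code{resistivity}, \code{field}, \code{n_anions}.
#' @examples
#' sp <- build_species("P2")
#' ts <- ionic_current(-0.5, sp, box = c(20, 10, 10), field = 0.1)
#' ts$current  # +0.1 e per time unit
#' @export
ionic_current <- function(vbar, species, box, field = 0) {
  stopifnot(length(box) == 3, all(box > 0))
  if (field < 0) stop("field magnitude must be >= 0 (the axis carries sign)")
  q <- species$total_charge
  I <- sum(q * vbar) / box[1]
  J <- I / (box[2] * box[3])
  sigma <- if (field > 0) J / field else if (all(vbar == 0)) 0 else NA_real_
  rho <- if (!is.na(sigma) && sigma != 0) 1 / sigma else NA_real_
  structure(list(
    vbar = vbar, v_mean = mean(vbar),
    v_se = if (length(vbar) > 1) stats::sd(vbar) / sqrt(length(vbar)) else NA_real_,
    current = I, current_density = J, conductivity = sigma,
    resistivity = rho, field = field, n_anions = length(vbar)
  ), class = "transport_summary")
}

#' @export
print.transport_summary <- function(x, ...) {
  cat(sprintf(paste0("Transport at E = %g V/nm (%d anions): v = %.4g +/- %.2g",
                     " nm/tau, I = %.4g e/tau, rho = %.4g\n"),
              x$field, x$n_anions, x$v_mean, x$v_se, x$current, x$resistivity))
  invisible(x)
}

#' Max-normalized anion density maps
#'
#' Bins the wrapped anion geometric centers of each trajectory into a 3D
#' grid, projects onto the X-Y plane by summing over Z, and divides every
#' 2D map by the single global maximum over the whole map set, so the
#' normalized maps are mutually comparable and their joint maximum is
#' exactly 1.
#'
#' @param trajs A \code{trajectory} or a list of trajectories (one per field
#'   condition).
#' @param grid Bin counts per axis (3-vector, each >= 2), default 50^3.
#' @return A list of \code{density_map} objects (one per input trajectory),
#'   each with \code{raw3d} (counts), \code{xy} (normalized projection),
#'   \code{norm_constant} (the shared maximum) and \code{condition}
#'   (field from trajectory metadata, if any).
#' @export
density_maps <- function(trajs, grid = c(50, 50, 50)) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  stopifnot(length(trajs) >= 1, length(grid) == 3, all(grid >= 2))
  grid <- as.integer(grid)
  maps <- lapply(trajs, function(tr) {
    if (n_frames(tr) < 1) stop("empty trajectory")
    box <- tr$box
    counts <- array(0, grid)
    n <- n_anions(tr)
    for (f in seq_len(n_frames(tr))) {
      xyz <- matrix(tr$centers[, , f], n, 3)
      idx <- sapply(1:3, function(a)
        pmin(pmax(floor(xyz[, a] / box[a] * grid[a]) + 1L, 1L), grid[a]))
      idx <- matrix(idx, n, 3)
      lin <- idx[, 1] + grid[1] * (idx[, 2] - 1L) +
        grid[1] * grid[2] * (idx[, 3] - 1L)
      tab <- tabulate(lin, nbins = prod(grid))
      counts <- counts + array(tab, grid)
    }
    xy <- apply(counts, c(1, 2), sum)
    list(raw3d = counts, xy = xy,
         condition = tr$metadata$field %||% NA_real_)
  })
  gmax <- max(vapply(maps, function(m) max(m$xy), 0))
  if (gmax <= 0) stop("empty density: no anion centers binned")
  lapply(maps, function(m) {
    structure(list(raw3d = m$raw3d, xy = m$xy / gmax,
                   norm_constant = gmax, condition = m$condition),
              class = "density_map")
  })
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("Density map %s: %s grid, xy max %.3f (norm constant %g)\n",
              if (is.na(x$condition)) "" else sprintf("(E = %g V/nm)", x$condition),
              paste(dim(x$raw3d), collapse = "x"), max(x$xy), x$norm_constant))
  invisible(x)
}
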