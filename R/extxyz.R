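#' Write a trajectory to extended-XYZ
#'
#' One "atom" per anion geometric center. The comment line carries the box in
#' the \code{Lattice="ax 0 0 0 ay 0 0 0 az"} convention, a \code{Properties}
#' descriptor (species, position, and integer periodic image flags when the
#' trajectory has them), \code{Time=} and, on the first frame, the metadata
#' as \code{key=value} pairs. Metadata are also echoed to a JSON sidecar
#' \code{<path>.json}.
#'
#' @param traj A \code{trajectory}.
#' @param path Output file path.
#' @param digits Coordinate precision (decimal digits).
#' @return \code{path}, invisibly.
#' @export
write_extxyz <- function(traj, path, digits = 8) {
  n <- n_anions(traj); nf <- n_frames(traj)
  has_img <- !is.null(traj$wrap_counts)
  props <- if (has_img) "species:S:1:pos:R:3:image:I:3" else "species:S:1:pos:R:3"
  lat <- sprintf("%g 0 0 0 %g 0 0 0 %g", traj$box[1], traj$box[2], traj$box[3])
  fmt <- paste0("%.", digits, "f")
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nf)) {
    meta <- ""
    if (f == 1 && length(traj$metadata)) {
      scal <- Filter(function(v) is.atomic(v) && length(v) == 1, traj$metadata)
      if (length(scal))
        meta <- paste0(" ", paste(sprintf("%s=%s", names(scal),
                                          vapply(scal, format, "")),
                                  collapse = " "))
    }
    writeLines(as.character(n), con)
    writeLines(sprintf('Lattice="%s" Properties=%s Time=%.10g%s',
                       lat, props, traj$frame_times[f], meta), con)
    xyz <- matrix(traj$centers[, , f], n, 3)
    if (has_img) {
      img <- matrix(traj$wrap_counts[, , f], n, 3)
      writeLines(sprintf("%s %s %s %s %d %d %d", traj$species_name,
                         sprintf(fmt, xyz[, 1]), sprintf(fmt, xyz[, 2]),
                         sprintf(fmt, xyz[, 3]),
                         img[, 1], img[, 2], img[, 3]), con)
    } else {
      writeLines(sprintf("%s %s %s %s", traj$species_name,
                         sprintf(fmt, xyz[, 1]), sprintf(fmt, xyz[, 2]),
                         sprintf(fmt, xyz[, 3])), con)
    }
  }
  jsonlite::write_json(traj$metadata, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an extended-XYZ trajectory
#'
#' Parses the format written by \code{\link{write_extxyz}} (and compatible
#' files). Image-flag columns are optional; when absent the returned
#' trajectory has no \code{wrap_counts} and \code{metadata$has_image_flags}
#' is \code{FALSE}. A JSON sidecar \code{<path>.json}, if present, supplies
#' metadata.
#'
#' @param path Path to the file.
#' @return A \code{trajectory}.
#' @export
read_extxyz <- function(path) {
  lines <- readLines(path)
  i <- 1L; f <- 0L
  frames <- list(); times <- numeric(); n_ref <- NA_integer_
  box <- NULL; has_img <- NA; species <- "X"; meta_kv <- list()
  while (i <= length(lines)) {
    if (!grepl("^\\s*[0-9]+\\s*$", lines[i]))
      stop(sprintf("parse error at line %d: expected atom count", i))
    n <- as.integer(lines[i])
    f <- f + 1L
    if (is.na(n_ref)) n_ref <- n
    else if (n != n_ref)
      stop(sprintf("parse error: frame %d has %d atoms, frame 1 has %d (line %d)",
                   f, n, n_ref, i))
    if (i + 1L > length(lines))
      stop(sprintf("parse error at line %d: missing comment line", i + 1L))
    comment <- lines[i + 1L]
    lat <- regmatches(comment, regexec('Lattice="([^"]+)"', comment))[[1]]
    if (length(lat) < 2)
      stop(sprintf("parse error at line %d: no Lattice in comment", i + 1L))
    lv <- as.numeric(strsplit(trimws(lat[2]), "\\s+")[[1]])
    if (length(lv) != 9 || any(!is.finite(lv)))
      stop(sprintf("parse error at line %d: malformed Lattice", i + 1L))
    box_f <- lv[c(1, 5, 9)]
    if (is.null(box)) box <- box_f
    tm <- regmatches(comment, regexec("Time=([-0-9.eE+]+)", comment))[[1]]
    times <- c(times, if (length(tm) >= 2) as.numeric(tm[2]) else f - 1)
    prop <- regmatches(comment, regexec("Properties=(\\S+)", comment))[[1]]
    frame_has_img <- length(prop) >= 2 && grepl("image:I:3", prop[2])
    if (is.na(has_img)) has_img <- frame_has_img
    if (f == 1L) {
      kv <- regmatches(comment,
                       gregexpr('\\b([A-Za-z_][A-Za-z0-9_]*)=([^"\\s]+)', comment))[[1]]
      for (pair in kv) {
        p <- strsplit(pair, "=", fixed = TRUE)[[1]]
        if (!p[1] %in% c("Time", "Properties", "Lattice"))
          meta_kv[[p[1]]] <- utils::type.convert(p[2], as.is = TRUE)
      }
    }
    if (i + 1L + n > length(lines))
      stop(sprintf("parse error: truncated frame %d (line %d)", f, i + 2L))
    block <- lines[(i + 2L):(i + 1L + n)]
    toks <- strsplit(trimws(block), "\\s+")
    ncol_f <- lengths(toks)
    need <- if (frame_has_img) 7L else 4L
    if (any(ncol_f < need))
      stop(sprintf("parse error at line %d: expected %d columns",
                   i + 1L + which(ncol_f < need)[1], need))
    m <- do.call(rbind, toks)
    species <- m[1, 1]
    xyz <- matrix(as.numeric(m[, 2:4]), n, 3)
    if (any(!is.finite(xyz)))
      stop(sprintf("parse error in frame %d: non-numeric coordinates", f))
    img <- if (frame_has_img) matrix(as.integer(m[, 5:7]), n, 3)
    frames[[f]] <- list(xyz = xyz, img = img)
    i <- i + 2L + n
  }
  if (f == 0L) stop("parse error: empty file")
  nf <- f
  centers <- array(0, c(n_ref, 3, nf))
  wraps <- if (isTRUE(has_img)) array(0L, c(n_ref, 3, nf))
  for (f in seq_len(nf)) {
    centers[, , f] <- frames[[f]]$xyz
    if (!is.null(wraps) && !is.null(frames[[f]]$img))
      wraps[, , f] <- frames[[f]]$img
  }
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar, simplifyVector = TRUE)
  else meta_kv
  meta$has_image_flags <- isTRUE(has_img)
  trajectory(centers = centers, wrap_counts = wraps, frame_times = times,
             box = box, species_name = species, metadata = meta)
}

#' Import a GRO coordinate/trajectory file (read-only)
#'
#' Fixed-column GROMACS .gro reader; each atom line becomes one anion center.
#' Multiple concatenated frames are supported; velocities are ignored. GRO
#' carries no periodic image flags, so the result has no \code{wrap_counts}.
#'
#' @param path Path to the .gro file.
#' @param dt Frame spacing used when the title lines carry no \code{t=}.
#' @return A \code{trajectory}.
#' @export
read_gro <- function(path, dt = 1) {
  lines <- readLines(path)
  i <- 1L; f <- 0L
  frames <- list(); times <- numeric(); box <- NULL; species <- "X"
  while (i <= length(lines)) {
    title <- lines[i]
    if (i + 1L > length(lines)) stop("parse error: truncated GRO header")
    n <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(n)) stop(sprintf("parse error at line %d: bad atom count", i + 1L))
    if (i + 2L + n > length(lines))
      stop(sprintf("parse error: truncated GRO frame at line %d", i))
    f <- f + 1L
    tm <- regmatches(title, regexec("t=\\s*([-0-9.eE+]+)", title))[[1]]
    times <- c(times, if (length(tm) >= 2) as.numeric(tm[2]) else (f - 1) * dt)
    block <- lines[(i + 2L):(i + 1L + n)]
    x <- as.numeric(substr(block, 21, 28))
    y <- as.numeric(substr(block, 29, 36))
    z <- as.numeric(substr(block, 37, 44))
    if (any(!is.finite(c(x, y, z))))
      stop(sprintf("parse error in GRO frame %d: bad coordinates", f))
    species <- trimws(substr(block[1], 11, 15))
    bl <- as.numeric(strsplit(trimws(lines[i + 2L + n]), "\\s+")[[1]])
    box_f <- bl[1:3]
    if (is.null(box)) box <- box_f
    frames[[f]] <- cbind(x, y, z)
    i <- i + 3L + n
  }
  nf <- f
  n <- nrow(frames[[1]])
  centers <- array(0, c(n, 3, nf))
  for (f in seq_len(nf)) {
    xyz <- frames[[f]]
    for (a in 1:3) xyz[, a] <- xyz[, a] %% box[a]  # GRO may hold tiny negatives
    centers[, , f] <- xyz
  }
  trajectory(centers = centers, frame_times = times, box = box,
             species_name = species,
             metadata = list(source = "gro", has_image_flags = FALSE))
}
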