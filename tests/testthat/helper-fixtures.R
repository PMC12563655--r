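# Small trajectory and label fixtures built in code.

# Trajectory from an explicit list of per-frame n x 3 center matrices.
make_traj <- function(frames, box = c(10, 10, 10), wraps = NULL,
                      times = NULL, species = "P3", metadata = list()) {
  n <- nrow(frames[[1]])
  nf <- length(frames)
  cen <- array(0, c(n, 3, nf))
  for (f in seq_len(nf)) cen[, , f] <- frames[[f]]
  wr <- NULL
  if (!is.null(wraps)) {
    wr <- array(0L, c(n, 3, nf))
    for (f in seq_len(nf)) wr[, , f] <- wraps[[f]]
  }
  trajectory(centers = cen, wrap_counts = wr,
             frame_times = times %||% (seq_len(nf) - 1),
             box = box, species_name = species, metadata = metadata)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Label series with attributes, from a character matrix.
make_labels <- function(m, dt = 1) {
  structure(m, dt = dt, times = (seq_len(ncol(m)) - 1) * dt,
            class = "label_series")
}

# Random label matrix for property tests.
random_labels <- function(n, nf, seed) {
  set.seed(seed)
  make_labels(matrix(sample(c("O", "I", "T"), n * nf, replace = TRUE), n, nf))
}

# Short default-parameter run, cached per (species, field, seed, n_steps).
.run_cache <- new.env(parent = emptyenv())
cached_run <- function(species, field, seed, n_steps = 6000L, ...) {
  key <- paste(species, field, seed, n_steps, sep = "_")
  if (is.null(.run_cache[[key]])) {
    cfg <- build_config(species, field = field, seed = seed,
                        n_steps = n_steps, ...)
    .run_cache[[key]] <- run_bd(cfg, save_beads = FALSE)
  }
  .run_cache[[key]]
}
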