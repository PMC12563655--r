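#' Compartment transition matrix from a label series
#'
#' Counts (origin, destination) label pairs separated by \code{lag} saved
#' frames, pooled over anions, and row-normalizes the counts so every
#' defined row sums to one. Rows whose compartment is never visited (zero
#' counts) are reported as undefined (NA), never filled. Compartment order
#' is octahedral, interface, tetrahedral.
#'
#' With \code{mode = "event"} the frame sequence of each anion is first
#' collapsed to its sequence of distinct consecutive compartments, and
#' transitions are counted between successive residences instead of between
#' lagged frames.
#'
#' @param labels A \code{label_series} (character matrix anions x frames).
#' @param lag Lag in saved frames (>= 1, < n_frames).
#' @param mode \code{"frame"} (lagged frame pairs, default) or
#'   \code{"event"} (consecutive distinct residences).
#' @param per_anion If \code{TRUE}, return a list of per-anion matrices
#'   instead of pooling (heterogeneity check).
#' @return Object of class \code{transition_matrix}: list with \code{P}
#'   (3 x 3 probabilities), \code{counts} (3 x 3 integers), \code{lag},
#'   \code{mode}, \code{defined_rows} (logical 3-vector). Row/column order
#'   \code{c("O", "I", "T")}.
#' @examples
#' lab <- matrix(c("T", "T", "I", "I", "O"), nrow = 1)
#' transition_matrix(lab, lag = 1)$P
#' @export
transition_matrix <- function(labels, lag = 1L, mode = c("frame", "event"),
                              per_anion = FALSE) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(labels))
  lev <- c("O", "I", "T")
  nf <- ncol(labels)
  lag <- as.integer(lag)
  if (mode == "frame" && (lag < 1L || lag >= nf))
    stop(sprintf("lag must satisfy 1 <= lag < n_frames (%d)", nf))

  count_one <- function(rows) {
    if (mode == "frame") {
      from <- factor(as.vector(labels[rows, seq_len(nf - lag), drop = FALSE]),
                     levels = lev)
      to <- factor(as.vector(labels[rows, (lag + 1):nf, drop = FALSE]),
                   levels = lev)
      table(from, to)
    } else {
      cnt <- matrix(0L, 3, 3, dimnames = list(lev, lev))
      for (i in rows) {
        seq_cp <- rle(labels[i, ])$values
        if (length(seq_cp) > lag)
          for (k in seq_len(length(seq_cp) - lag))
            cnt[seq_cp[k], seq_cp[k + lag]] <- cnt[seq_cp[k], seq_cp[k + lag]] + 1L
      }
      cnt
    }
  }

  build <- function(cnt) {
    cnt <- matrix(as.numeric(cnt), 3, 3, dimnames = list(lev, lev))
    rs <- rowSums(cnt)
    P <- cnt / ifelse(rs > 0, rs, NA)
    structure(list(P = P, counts = cnt, lag = lag, mode = mode,
                   defined_rows = stats::setNames(rs > 0, lev)),
              class = "transition_matrix")
  }
  if (per_anion)
    return(lapply(seq_len(nrow(labels)), function(i) build(count_one(i))))
  build(count_one(seq_len(nrow(labels))))
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("Transition matrix (lag %d, %s mode), rows sum to 1:\n",
              x$lag, x$mode))
  print(round(x$P, 3))
  if (!all(x$defined_rows))
    cat("  undefined rows:",
        paste(names(x$defined_rows)[!x$defined_rows], collapse = ", "), "\n")
  invisible(x)
}
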