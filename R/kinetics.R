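#' Continuous residence events in a compartment
#'
#' A residence event is a maximal uninterrupted run of frames during which an
#' anion carries the target compartment label. A single frame outside the
#' compartment ends the event (\code{gap_tolerance = 0}); short excursions of
#' up to \code{gap_tolerance} frames can be bridged if requested. Runs that
#' touch the final frame are censored: the true residence is only known to
#' be at least the observed duration.
#'
#' @param labels A \code{label_series} (character matrix anions x frames).
#' @param compartment Target label, one of \code{"I"}, \code{"T"}, \code{"O"}.
#' @param dt Frame spacing; defaults to the \code{dt} attribute of
#'   \code{labels} (or 1).
#' @param gap_tolerance Number of consecutive off-compartment frames bridged
#'   inside an event (default 0: literal uninterrupted sequences).
#' @return data.frame with columns \code{anion_id}, \code{compartment},
#'   \code{start_frame} (0-based), \code{duration} (frames x dt),
#'   \code{censored}.
#' @export
find_events <- function(labels, compartment, dt = NULL, gap_tolerance = 0L) {
  stopifnot(is.matrix(labels), nrow(labels) >= 1, ncol(labels) >= 1)
  if (is.null(dt)) dt <- attr(labels, "dt") %||% 1
  nf <- ncol(labels)
  out <- list()
  for (i in seq_len(nrow(labels))) {
    inside <- labels[i, ] == compartment
    if (gap_tolerance > 0L && any(inside)) {
      r <- rle(inside)
      gaps <- which(!r$values & r$lengths <= gap_tolerance)
      gaps <- gaps[gaps > 1 & gaps < length(r$values)]  # interior gaps only
      if (length(gaps)) {
        r$values[gaps] <- TRUE
        inside <- inverse.rle(r)
      }
    }
    r <- rle(inside)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    if (length(keep))
      out[[length(out) + 1L]] <- data.frame(
        anion_id = i, compartment = compartment,
        start_frame = starts[keep] - 1L,
        duration = r$lengths[keep] * dt,
        censored = ends[keep] == nf)
  }
  if (!length(out))
    return(data.frame(anion_id = integer(), compartment = character(),
                      start_frame = integer(), duration = numeric(),
                      censored = logical()))
  do.call(rbind, out)
}

#' Survival curve of residence events
#'
#' All events are aligned at their start; C(t) is the fraction still inside
#' the compartment at elapsed time t (C(t) = N(t)/N0 when no event is
#' censored). Censored events are handled by the risk set: a censored event
#' counts as resident up to its censoring time and is removed from both
#' numerator and denominator beyond it (product-limit form, which reduces
#' exactly to N(t)/N0 in the censor-free case); alternatively
#' \code{censoring = "drop"} discards censored events.
#'
#' @param events data.frame from \code{\link{find_events}} (or any frame
#'   with \code{duration} and optional \code{censored}).
#' @param dt Time grid spacing; default the smallest positive duration.
#' @param min_events Minimum number of events required (insufficient
#'   statistics otherwise).
#' @param censoring \code{"risk-set"} (default) or \code{"drop"}.
#' @return Object of class \code{survival_curve}: list with \code{times},
#'   \code{C}, \code{n_risk} (events still under observation), \code{N0},
#'   \code{n_events}, \code{n_censored}.
#' @examples
#' ev <- data.frame(duration = c(3, 5), censored = FALSE)
#' sc <- survival_curve(ev, dt = 1, min_events = 1)
#' sc$C[sc$times == 3]  # 0.5
#' @export
survival_curve <- function(events, dt = NULL, min_events = 20,
                           censoring = c("risk-set", "drop")) {
  censoring <- match.arg(censoring)
  if (is.null(events$censored)) events$censored <- FALSE
  if (censoring == "drop") events <- events[!events$censored, , drop = FALSE]
  if (!nrow(events) || all(events$censored))
    stop("insufficient statistics: no uncensored residence events",
         if (length(unique(events$compartment)) == 1)
           paste0(" in compartment ", events$compartment[1]) else "")
  if (nrow(events) < min_events)
    stop(sprintf(paste0("insufficient statistics: %d events < minimum %d",
                        "%s"), nrow(events), min_events,
                 if (length(unique(events$compartment)) == 1)
                   paste0(" (compartment ", events$compartment[1], ")") else ""))
  dur <- events$duration
  cens <- events$censored
  stopifnot(all(dur > 0))
  if (is.null(dt)) dt <- min(dur)
  tmax <- max(dur)
  times <- seq(0, tmax, by = dt)
  if (times[length(times)] < tmax) times <- c(times, tmax)
  N0 <- length(dur)

  if (!any(cens)) {
    n_risk <- vapply(times, function(t) sum(dur > t), 0)
    C <- n_risk / N0
  } else {
    # product-limit over exit times; censored events leave the risk set
    # without an exit
    o <- order(dur, !cens)
    d_s <- dur[o]; c_s <- cens[o]
    uniq_t <- sort(unique(d_s[!c_s]))
    S <- numeric(length(uniq_t))
    s_cur <- 1
    for (k in seq_along(uniq_t)) {
      tk <- uniq_t[k]
      at_risk <- sum(d_s >= tk)
      deaths <- sum(d_s == tk & !c_s)
      s_cur <- s_cur * (1 - deaths / at_risk)
      S[k] <- s_cur
    }
    C <- vapply(times, function(t) {
      k <- findInterval(t, uniq_t)     # exits at exactly t count as exited
      if (k == 0) 1 else S[k]
    }, 0)
    n_risk <- vapply(times, function(t) sum(dur > t), 0)
  }
  structure(list(times = times, C = C, n_risk = n_risk, N0 = N0,
                 n_events = N0, n_censored = sum(cens)),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("Survival curve: N0 = %d events (%d censored), %d time points\n",
              x$N0, x$n_censored, length(x$times)))
  invisible(x)
}

#' Fit a double-exponential decay to a survival curve
#'
#' Nonlinear least squares of C(t) = A1 exp(-t/lambda1) + A2 exp(-t/lambda2)
#' with A1, A2 >= 0 and lambda1, lambda2 > 0, started from a log-linear
#' single-exponential fit whose rate is split into lambda/3 and 3 lambda
#' (plus further spreads). The single-exponential model is fitted too and
#' the better model by small-sample AIC is reported; A2 = 0 denotes an
#' effectively single-exponential decay. Only grid points where at least
#' \code{n_min} events remain under observation (and C > 0) enter the fit.
#' The fit is deterministic given the curve.
#'
#' @param curve A \code{survival_curve}.
#' @param n_min Risk-set truncation threshold (default 5 events).
#' @return Object of class \code{double_exp_fit}: list with \code{A1},
#'   \code{lambda1}, \code{A2}, \code{lambda2} (sorted so lambda1 <=
#'   lambda2), \code{tau} (amplitude-weighted mean residence time),
#'   \code{rss}, \code{model} ("single" or "double"), \code{n_points}.
#' @export
fit_double_exp <- function(curve, n_min = 5) {
  keep <- curve$C > 0 & curve$n_risk >= n_min
  keep[1] <- TRUE  # always anchor C(0) = 1
  t <- curve$times[keep]
  y <- curve$C[keep]
  if (sum(y > 0) < 6)
    stop("fit requires at least 6 points with C > 0 after truncation")
  # log-linear single-exponential start
  pos <- y > 0
  lf <- stats::lm(log(y[pos]) ~ t[pos])
  lam0 <- max(-1 / min(stats::coef(lf)[2], -1e-12), 1e-8)
  A0 <- min(max(exp(stats::coef(lf)[1]), 1e-3), 2)

  # time constants are capped at 50x the observed range: the data cannot
  # support slower decays, and unbounded rates run away on flat tails
  lmax <- 50 * max(t)
  lam0 <- min(lam0, lmax / 10)
  fit1 <- try(minpack.lm::nlsLM(
    y ~ A1 * exp(-t / l1), start = list(A1 = A0, l1 = lam0),
    lower = c(0, 1e-10), upper = c(Inf, lmax),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)

  starts <- list(
    list(A1 = A0 / 2, l1 = lam0 / 3, A2 = A0 / 2, l2 = lam0 * 3),
    list(A1 = 0.7 * A0, l1 = lam0 / 10, A2 = 0.3 * A0, l2 = lam0 * 2),
    list(A1 = 0.3 * A0, l1 = lam0 / 2, A2 = 0.7 * A0, l2 = lam0 * 10))
  best2 <- NULL
  for (st in starts) {
    f <- try(minpack.lm::nlsLM(
      y ~ A1 * exp(-t / l1) + A2 * exp(-t / l2),
      start = lapply(st, function(v) min(v, lmax)),
      lower = c(0, 1e-10, 0, 1e-10), upper = c(Inf, lmax, Inf, lmax),
      control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
    if (!inherits(f, "try-error")) {
      if (is.null(best2) || sum(stats::resid(f)^2) < sum(stats::resid(best2)^2))
        best2 <- f
    }
  }
  if (is.null(best2) && inherits(fit1, "try-error"))
    stop("fit failure: neither the double- nor the single-exponential ",
         "model converged from any start")

  aicc <- function(rss, k, n) {
    if (n - k - 1 <= 0) return(Inf)
    n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  }
  n <- length(y)
  rss1 <- if (!inherits(fit1, "try-error")) sum(stats::resid(fit1)^2) else Inf
  rss2 <- if (!is.null(best2)) sum(stats::resid(best2)^2) else Inf
  use_double <- aicc(rss2, 4, n) < aicc(rss1, 2, n)

  if (use_double) {
    p <- stats::coef(best2)
    A <- c(p[["A1"]], p[["A2"]]); l <- c(p[["l1"]], p[["l2"]])
    o <- order(l)
    A <- A[o]; l <- l[o]
    rss <- rss2; model <- "double"
  } else {
    p <- stats::coef(fit1)
    A <- c(p[["A1"]], 0); l <- c(p[["l1"]], p[["l1"]])
    rss <- rss1; model <- "single"
  }
  fit <- structure(list(A1 = A[1], lambda1 = l[1], A2 = A[2], lambda2 = l[2],
                        rss = rss, model = model, n_points = n),
                   class = "double_exp_fit")
  fit$tau <- mean_residence_time(fit)
  fit
}

#' @export
print.double_exp_fit <- function(x, ...) {
  cat(sprintf(paste0("Double-exponential fit (%s model): A1=%.3g l1=%.3g | ",
                     "A2=%.3g l2=%.3g | tau=%.4g (rss %.3g, %d pts)\n"),
              x$model, x$A1, x$lambda1, x$A2, x$lambda2, x$tau, x$rss,
              x$n_points))
  invisible(x)
}

#' Amplitude-weighted mean residence time
#'
#' tau = (A1 lambda1 + A2 lambda2) / (A1 + A2): a convex combination of the
#' two fitted time constants weighted by their amplitudes.
#'
#' @param fit A \code{double_exp_fit} (or list with A1, lambda1, A2, lambda2).
#' @return The mean residence time (same units as the time constants).
#' @examples
#' mean_residence_time(list(A1 = 2, lambda1 = 10, A2 = 1, lambda2 = 100)) # 40
#' @export
mean_residence_time <- function(fit) {
  s <- fit$A1 + fit$A2
  if (s <= 0) stop("degenerate fit: A1 + A2 must be positive")
  (fit$A1 * fit$lambda1 + fit$A2 * fit$lambda2) / s
}

#' Residence-time summary for every compartment
#'
#' Convenience wrapper: events, survival curve, double-exponential fit and
#' mean residence time per compartment.
#'
#' @param labels A \code{label_series}.
#' @param dt Frame spacing (default from \code{labels}).
#' @param compartments Labels to analyze.
#' @param min_events Passed to \code{\link{survival_curve}}.
#' @param censoring Passed to \code{\link{survival_curve}}.
#' @return data.frame with one row per compartment: A1, lambda1, A2,
#'   lambda2, tau, model, n_events, n_censored.
#' @export
residence_times <- function(labels, dt = NULL,
                            compartments = c("I", "T", "O"),
                            min_events = 20, censoring = "risk-set") {
  if (is.null(dt)) dt <- attr(labels, "dt") %||% 1
  rows <- lapply(compartments, function(cp) {
    ev <- find_events(labels, cp, dt = dt)
    sc <- survival_curve(ev, dt = dt, min_events = min_events,
                         censoring = censoring)
    ft <- fit_double_exp(sc)
    data.frame(compartment = cp, A1 = ft$A1, lambda1 = ft$lambda1,
               A2 = ft$A2, lambda2 = ft$lambda2, tau = ft$tau,
               model = ft$model, n_events = sc$n_events,
               n_censored = sc$n_censored)
  })
  do.call(rbind, rows)
}
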