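test_that("find_events extracts maximal runs with censoring at the last frame", {
  lab <- make_labels(matrix(c("T", "T", "I", "I", "T"), nrow = 1))
  ev <- find_events(lab, "T")
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$start_frame, c(0L, 4L))
  expect_equal(ev$duration, c(2, 1))
  expect_equal(ev$censored, c(FALSE, TRUE))

  expect_equal(nrow(find_events(make_labels(matrix("I", 1, 6)), "T")), 0L)

  ev5 <- find_events(make_labels(matrix("T", 1, 5)), "T")
  expect_equal(nrow(ev5), 1L)
  expect_equal(ev5$duration, 5)
  expect_true(ev5$censored)

  # durations scale with the frame spacing
  ev_dt <- find_events(lab, "T", dt = 0.5)
  expect_equal(ev_dt$duration, c(1, 0.5))
})

test_that("gap tolerance bridges single-frame excursions when asked", {
  lab <- make_labels(matrix(c("T", "T", "I", "T", "T", "O", "O"), nrow = 1))
  strict <- find_events(lab, "T")
  expect_equal(strict$duration, c(2, 2))
  bridged <- find_events(lab, "T", gap_tolerance = 1L)
  expect_equal(bridged$duration, 5)
})

test_that("survival curve counts events still resident beyond each time", {
  ev <- data.frame(duration = c(3, 5), censored = FALSE)
  sc <- survival_curve(ev, dt = 1, min_events = 1)
  expect_equal(sc$C[sc$times == 0], 1)
  expect_equal(sc$C[sc$times == 3], 0.5)
  expect_equal(sc$C[sc$times == 4], 0.5)
  expect_equal(sc$C[sc$times == 5], 0)
  expect_equal(sc$N0, 2L)

  sc1 <- survival_curve(data.frame(duration = 1, censored = FALSE),
                        dt = 1, min_events = 1)
  expect_equal(sc1$C, c(1, 0))

  # degenerate distribution: step from 1 to 0 at the common duration
  scd <- survival_curve(data.frame(duration = rep(4, 30), censored = FALSE),
                        dt = 1, min_events = 1)
  expect_equal(scd$C, c(1, 1, 1, 1, 0))
})

test_that("too few events is an insufficient-statistics error", {
  ev <- data.frame(duration = c(3, 5), censored = FALSE,
                   compartment = "T")
  expect_error(survival_curve(ev, dt = 1, min_events = 20),
               "insufficient statistics.*T")
})

test_that("risk-set censoring matches the survival-package product limit", {
  skip_if_not_installed("survival")
  set.seed(31)
  for (k in 1:5) {
    dur <- ceiling(rexp(60, 1 / 8))
    cens <- runif(60) < 0.3
    ev <- data.frame(duration = dur, censored = cens)
    if (all(cens)) next
    sc <- survival_curve(ev, dt = 1, min_events = 1)
    km <- survival::survfit(survival::Surv(dur, !cens) ~ 1)
    km_at <- stats::stepfun(km$time, c(1, km$surv), right = FALSE)
    # survfit treats S(t) as right-continuous: compare just after each grid time
    expect_equal(sc$C, km_at(sc$times + 1e-9), tolerance = 1e-12,
                 info = paste("replicate", k))
  }
})

test_that("C(0) = 1 and C is non-increasing on randomized event lists", {
  set.seed(77)
  for (k in 1:20) {
    n <- sample(21:200, 1)
    ev <- data.frame(duration = ceiling(rexp(n, 1 / sample(3:30, 1))),
                     censored = runif(n) < runif(1, 0, 0.4))
    if (all(!ev$censored) || any(!ev$censored)) {
      sc <- survival_curve(ev, dt = 1, min_events = 1)
      expect_equal(sc$C[1], 1)
      expect_true(all(diff(sc$C) <= 1e-12))
      expect_true(all(sc$C >= 0 & sc$C <= 1))
    }
  }
})

test_that("noiseless single-exponential decay is recovered", {
  t <- 0:200
  sc <- structure(list(times = t, C = exp(-t / 50),
                       n_risk = rep(1000, length(t)), N0 = 1000,
                       n_events = 1000, n_censored = 0),
                  class = "survival_curve")
  ft <- fit_double_exp(sc)
  expect_equal(ft$tau, 50, tolerance = 0.02)
})

test_that("noiseless double-exponential parameters are recovered", {
  t <- seq(0, 400, by = 2)
  sc <- structure(list(times = t, C = 0.5 * exp(-t / 10) + 0.5 * exp(-t / 100),
                       n_risk = rep(1000, length(t)), N0 = 1000,
                       n_events = 1000, n_censored = 0),
                  class = "survival_curve")
  ft <- fit_double_exp(sc)
  expect_identical(ft$model, "double")
  expect_equal(ft$lambda1, 10, tolerance = 0.05)
  expect_equal(ft$lambda2, 100, tolerance = 0.05)
  expect_equal(ft$tau, 55, tolerance = 0.05)
  expect_true(ft$lambda1 <= ft$lambda2)
})

test_that("the fit is deterministic given the curve", {
  set.seed(12)
  dur <- c(rexp(500, 1 / 10), rexp(500, 1 / 100))
  sc <- survival_curve(data.frame(duration = dur), dt = 1)
  f1 <- fit_double_exp(sc)
  f2 <- fit_double_exp(sc)
  expect_identical(f1, f2)
})

test_that("tau is recovered from sampled two-exponential mixtures", {
  # durations from 0.5 Exp(10) + 0.5 Exp(100); true tau = 55
  errs <- sapply(1:10, function(s) {
    set.seed(s)
    n <- 2000
    dur <- ifelse(runif(n) < 0.5, rexp(n, 1 / 10), rexp(n, 1 / 100))
    sc <- survival_curve(data.frame(duration = dur), dt = 0.5)
    abs(fit_double_exp(sc)$tau - 55) / 55
  })
  expect_lt(median(errs), 0.10)
})

test_that("mean residence time is the amplitude-weighted lambda mixture", {
  expect_equal(mean_residence_time(
    list(A1 = 1, lambda1 = 10, A2 = 1, lambda2 = 100)), 55)
  expect_equal(mean_residence_time(
    list(A1 = 0.8, lambda1 = 7, A2 = 0, lambda2 = 3)), 7)
  expect_equal(mean_residence_time(
    list(A1 = 2, lambda1 = 10, A2 = 1, lambda2 = 100)), 40)
  expect_error(mean_residence_time(
    list(A1 = 0, lambda1 = 10, A2 = 0, lambda2 = 100)), "degenerate")
})

test_that("tau always lies between the two time constants", {
  set.seed(99)
  for (k in 1:25) {
    A <- runif(2); l <- sort(rexp(2, 1 / 50) + 1)
    if (sum(A) == 0) next
    tau <- mean_residence_time(list(A1 = A[1], lambda1 = l[1],
                                    A2 = A[2], lambda2 = l[2]))
    expect_true(tau >= l[1] - 1e-12 && tau <= l[2] + 1e-12)
  }
})

test_that("residence_times summarizes all compartments from a label series", {
  set.seed(4)
  # sticky 3-state chain so every compartment has multi-frame dwells
  P <- rbind(c(0.9, 0.05, 0.05), c(0.05, 0.9, 0.05), c(0.05, 0.05, 0.9))
  lev <- c("O", "I", "T")
  sim_row <- function(nf) {
    s <- integer(nf); s[1] <- sample.int(3, 1)
    for (k in 2:nf) s[k] <- sample.int(3, 1, prob = P[s[k - 1], ])
    lev[s]
  }
  lab <- make_labels(t(sapply(1:50, function(i) sim_row(200))), dt = 1)
  out <- residence_times(lab, min_events = 20)
  expect_setequal(out$compartment, c("I", "T", "O"))
  expect_true(all(out$tau > 0))
  expect_true(all(out$n_events > 20))
})
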