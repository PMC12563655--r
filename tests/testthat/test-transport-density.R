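test_that("endpoint axial velocities divide displacement by elapsed time", {
  # one anion moving +0.1 nm per frame in x over 500 time units; wrap
  # counts carry the laps so the displacement is 50 nm over 500 tau
  nfr <- 501
  wr <- lapply(seq_len(nfr), function(f)
    matrix(c(((f - 1) * 0.1) %/% 10, 0, 0), 1))
  tr <- make_traj(lapply(seq_len(nfr), function(f)
    matrix(c(((f - 1) * 0.1) %% 10, 5, 5), 1)), wraps = wr,
    times = (seq_len(nfr) - 1))
  v <- axial_velocities(unwrap(tr))
  expect_equal(v, 0.1, tolerance = 1e-9)

  # stationary anion
  tr0 <- make_traj(replicate(10, matrix(c(1, 1, 1), 1), simplify = FALSE))
  expect_equal(axial_velocities(unwrap(tr0)), 0)
})

test_that("reversing a trajectory in time negates the mean velocity", {
  run <- cached_run("P2", 0.3, seed = 13, n_steps = 2000L)
  d <- unwrap(run)
  v <- axial_velocities(d)
  nf <- dim(d)[3]
  drev <- d[, , nf:1, drop = FALSE]
  for (f in seq_len(nf)) drev[, , f] <- drev[, , f] - d[, , nf]
  attr(drev, "times") <- attr(d, "times")
  vr <- axial_velocities(structure(drev, class = "displacements"))
  expect_equal(vr, -v, tolerance = 1e-10)
})

test_that("ionic current follows the drift sign convention", {
  sp2 <- build_species("P2")   # q = -4
  ts <- ionic_current(-0.5, sp2, box = c(20, 10, 10), field = 0.1)
  expect_equal(ts$current, 0.1)  # anions moving -x carry +x current

  ts0 <- ionic_current(rep(0, 5), sp2, box = c(10, 10, 10), field = 0.2)
  expect_equal(ts0$current, 0)
  expect_equal(ts0$conductivity, 0)
  expect_true(is.na(ts0$resistivity))

  expect_error(ionic_current(1, sp2, c(10, 10, 10), field = -0.1), ">= 0")
})

test_that("current is bilinear in charge and velocity", {
  sp3 <- build_species("P3")
  sp6 <- build_species("P6")  # double the charge of P3
  v <- c(-0.2, -0.1, -0.3)
  I1 <- ionic_current(v, sp3, c(10, 10, 10), 0.1)$current
  I2 <- ionic_current(2 * v, sp6, c(10, 10, 10), 0.1)$current
  expect_equal(I2, 4 * I1)
})

test_that("rho and sigma are mutual inverses and E = 0 leaves them undefined", {
  run <- cached_run("P3", 0.3, seed = 3, n_steps = 2000L)
  v <- axial_velocities(unwrap(run))
  ts <- ionic_current(v, build_species("P3"), run$box, field = 0.3)
  expect_equal(ts$resistivity * ts$conductivity, 1)
  ts0 <- ionic_current(v, build_species("P3"), run$box, field = 0)
  expect_true(is.na(ts0$conductivity) && is.na(ts0$resistivity))
})

test_that("summed per-anion current equals the ensemble-displacement current", {
  run <- cached_run("P3", 0.3, seed = 3, n_steps = 2000L)
  d <- unwrap(run)
  v <- axial_velocities(d)
  sp <- build_species("P3")
  I_sum <- ionic_current(v, sp, run$box, 0.3)$current
  nf <- dim(d)[3]
  total_dx <- sum(d[, 1, nf])
  elapsed <- attr(d, "times")[nf] - attr(d, "times")[1]
  I_ens <- sp$total_charge * total_dx / elapsed / run$box[1]
  expect_equal(I_sum, I_ens, tolerance = 1e-10)
})

test_that("density maps bin, project and normalize as a set", {
  # all centers in one cell
  fr <- replicate(4, matrix(c(1.1, 2.2, 3.3), 1), simplify = FALSE)
  m <- density_maps(make_traj(fr), grid = c(5, 5, 5))[[1]]
  expect_equal(max(m$xy), 1)
  expect_equal(sum(m$xy > 0), 1)
  expect_equal(sum(m$raw3d), 4)

  # identical trajectories in a set give identical maps, joint max exactly 1
  tr <- cached_run("P3", 0.2, seed = 3, n_steps = 2000L)
  ms <- density_maps(list(tr, tr), grid = c(10, 10, 10))
  expect_identical(ms[[1]]$xy, ms[[2]]$xy)
  expect_equal(max(sapply(ms, function(m) max(m$xy))), 1)
})

test_that("uniform random centers give near-uniform projected density", {
  set.seed(123)
  n <- 1e5
  cen <- array(0, c(n, 3, 1))
  cen[, , 1] <- matrix(runif(3 * n, 0, 10), n, 3)
  tr <- trajectory(cen, frame_times = 0, box = c(10, 10, 10))
  m <- density_maps(tr, grid = c(10, 10, 10))[[1]]
  counts <- m$xy * m$norm_constant
  expect_lt(sd(counts) / mean(counts), 0.05)
})

test_that("windowed-slope velocities agree with endpoints for uniform drift", {
  nfr <- 51
  wr <- lapply(seq_len(nfr), function(f) matrix(c((f - 1) %/% 5, 0, 0), 1))
  fr <- lapply(seq_len(nfr), function(f)
    matrix(c(((f - 1) * 2) %% 10, 3, 3), 1))
  tr <- make_traj(fr, wraps = wr, times = seq_len(nfr) - 1)
  d <- unwrap(tr)
  expect_equal(axial_velocities(d, method = "slope"),
               axial_velocities(d, method = "endpoint"), tolerance = 1e-9)
  # instantaneous velocities: constant 2 nm per time unit
  fv <- frame_velocities(d)
  expect_true(all(abs(fv - 2) < 1e-9))
})
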