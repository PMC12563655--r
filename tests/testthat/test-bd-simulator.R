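# Small helper: a sim_state at given centers/orientations.
state_at <- function(centers, quats = NULL) {
  n <- nrow(centers)
  if (is.null(quats)) quats <- cbind(rep(1, n), 0, 0, 0)
  structure(list(centers = centers, quats = quats,
                 wrap_counts = matrix(0L, n, 3), time = 0),
            class = "sim_state")
}

test_that("an isolated anion beyond all cutoffs feels no force or torque", {
  cfg <- build_config("P3", field = 0, seed = 1, n_anions = 1,
                      check_neutrality = FALSE)
  # (2.6, 2.6, 2.6) is > 4.2 nm from every NP, past the 3.2 nm Yukawa cutoff
  f <- compute_forces(state_at(matrix(c(2.6, 2.6, 2.6), 1)), cfg)
  expect_equal(f$force, matrix(0, 1, 3))
  expect_equal(f$torque, matrix(0, 1, 3))
})

test_that("WCA pair force vanishes at and beyond its cutoff", {
  sp <- build_species("X1", custom = list(name = "X1", topology = "linear",
                                          n_beads = 2, total_charge = -2))
  cfg <- build_config(sp, lattice = empty_lattice(20), field = 0,
                      n_anions = 2, seed = 1, check_neutrality = FALSE,
                      bjerrum_scale = 0, adsorption_depth = 0)
  rc <- 2^(1 / 6) * sp$bead_diameter
  # both molecules along z; centers separated along x by exactly the cutoff
  st <- state_at(rbind(c(5, 5, 5), c(5 + rc, 5, 5)))
  f <- compute_forces(st, cfg)
  expect_equal(f$force, matrix(0, 2, 3), tolerance = 1e-12)
  st2 <- state_at(rbind(c(5, 5, 5), c(5 + 0.95 * rc, 5, 5)))
  f2 <- compute_forces(st2, cfg)
  expect_gt(f2$force[2, 1], 0)  # repulsion pushes the second molecule +x
  expect_equal(f2$force[1, 1], -f2$force[2, 1])
})

test_that("forces equal the negative potential-energy gradient", {
  # Yukawa + WCA + adsorption against central finite differences of the
  # energy reported by the same model, over random two-anion configurations
  # in the full lattice
  cfg <- build_config("P3", field = 0.2, seed = 1, n_anions = 2,
                      check_neutrality = FALSE)
  set.seed(10)
  h <- 1e-6
  for (rep in 1:5) {
    cen <- matrix(runif(6, 1.8, 8), 2, 3)
    q <- matrix(rnorm(8), 2, 4)
    q <- q / sqrt(rowSums(q^2))
    st <- state_at(cen, q)
    f <- compute_forces(st, cfg)
    for (i in 1:2) for (a in 1:3) {
      cp <- cen; cm <- cen
      cp[i, a] <- cp[i, a] + h
      cm[i, a] <- cm[i, a] - h
      up <- compute_forces(state_at(cp, q), cfg)$energy
      um <- compute_forces(state_at(cm, q), cfg)$energy
      expect_equal(f$force[i, a], -(up - um) / (2 * h),
                   tolerance = 1e-5)
    }
  }
})

test_that("the Yukawa pair force matches the analytic screened-Coulomb form", {
  sp <- build_species("X1", custom = list(name = "X1", topology = "linear",
                                          n_beads = 2, total_charge = -2))
  lam <- 0.8; A <- 0.1
  cfg <- build_config(sp, lattice = empty_lattice(20), field = 0,
                      n_anions = 2, seed = 1, check_neutrality = FALSE,
                      debye_length = lam, bjerrum_scale = A,
                      wca_epsilon = 1, adsorption_depth = 0)
  # place single pairs of beads far apart except along x at r = lambda
  r <- lam + 2^(1/6) * sp$bead_diameter  # beyond WCA cutoff? keep r > rc
  st <- state_at(rbind(c(5, 5, 5), c(5 + r, 5, 5)))
  f <- compute_forces(st, cfg)
  # beads sit at z offsets +-bond/2; compute expected force by direct sum
  bod <- sp$body
  p1 <- sweep(bod, 2, c(5, 5, 5), "+")
  p2 <- sweep(bod, 2, c(5 + r, 5, 5), "+")
  fx <- 0
  for (i in 1:2) for (j in 1:2) {
    d <- p2[j, ] - p1[i, ]
    rr <- sqrt(sum(d^2))
    qq <- sp$bead_charges[i] * sp$bead_charges[j]
    if (rr < 4 * lam)
      fx <- fx + A * qq * exp(-rr / lam) * (1 / rr^2 + 1 / (lam * rr)) * d[1] / rr
  }
  expect_equal(f$force[2, 1], unname(fx), tolerance = 1e-10)
})

test_that("the integrator is bit-reproducible for identical seeds", {
  cfg <- build_config("P3", field = 0.2, seed = 42, n_steps = 300,
                      save_every = 50)
  t1 <- run_bd(cfg)
  t2 <- run_bd(cfg)
  expect_identical(t1$centers, t2$centers)
  expect_identical(t1$wrap_counts, t2$wrap_counts)
  t3 <- run_bd(build_config("P3", field = 0.2, seed = 43, n_steps = 300,
                            save_every = 50))
  expect_false(identical(t1$centers, t3$centers))
})

test_that("field-free diffusion is unbiased and satisfies the Einstein relation", {
  sp <- build_species("P2")
  cfg <- build_config(sp, lattice = empty_lattice(12), field = 0,
                      n_anions = 400, n_steps = 1500, save_every = 100,
                      seed = 5, check_neutrality = FALSE,
                      bjerrum_scale = 0, adsorption_depth = 0)
  traj <- run_bd(cfg, save_beads = FALSE)
  disp <- unwrap(traj)
  D_t <- cfg$temperature_energy / (sp$n_beads * cfg$friction)
  t_end <- traj$frame_times[n_frames(traj)]
  # mean displacement ~ 0 within 4 standard errors of sqrt(2 D t)
  for (a in 1:3) {
    m <- mean(disp[, a, n_frames(traj)])
    se <- sqrt(2 * D_t * t_end / 400)
    expect_lt(abs(m), 4 * se)
  }
  # MSD slope = 6 D within 5%
  msd <- sapply(seq_len(n_frames(traj)), function(f)
    mean(rowSums(matrix(disp[, , f], 400, 3)^2)))
  slope <- coef(lm(msd ~ traj$frame_times))[2]
  expect_equal(unname(slope), 6 * D_t, tolerance = 0.05)
})

test_that("free-anion drift matches the closed-form overdamped mobility", {
  sp <- build_species("P2")
  cfg <- build_config(sp, lattice = empty_lattice(12), field = 0.3,
                      n_anions = 200, n_steps = 2000, save_every = 200,
                      seed = 8, check_neutrality = FALSE,
                      bjerrum_scale = 0, adsorption_depth = 0)
  traj <- run_bd(cfg, save_beads = FALSE)
  v <- axial_velocities(unwrap(traj))
  v_th <- cfg$field_energy_scale * 0.3 * sp$total_charge /
    (sp$n_beads * cfg$friction)
  expect_equal(mean(v), v_th, tolerance = 0.02)
})

test_that("orientations stay unit quaternions and frames stay finite", {
  cfg <- build_config("P6", field = 0.3, seed = 3, n_steps = 500,
                      save_every = 100)
  st <- ionlattice:::init_state(cfg)
  st2 <- step_bd(st, cfg, 500)
  expect_equal(sqrt(rowSums(st2$quats^2)), rep(1, cfg$n_anions),
               tolerance = 1e-9)
  tr <- run_bd(cfg)
  expect_true(all(is.finite(tr$centers)))
  expect_true(all(is.finite(tr$beads)))
})

test_that("two seeds give different paths but consistent drift statistics", {
  sp <- build_species("P2")
  mk <- function(s) build_config(sp, lattice = empty_lattice(12),
                                 field = 0.3, n_anions = 200,
                                 n_steps = 1500, save_every = 300, seed = s,
                                 check_neutrality = FALSE, bjerrum_scale = 0,
                                 adsorption_depth = 0)
  v1 <- axial_velocities(unwrap(run_bd(mk(1), save_beads = FALSE)))
  v2 <- axial_velocities(unwrap(run_bd(mk(2), save_beads = FALSE)))
  expect_false(identical(v1, v2))
  se <- sqrt(var(v1) / 200 + var(v2) / 200)
  expect_lt(abs(mean(v1) - mean(v2)), 5 * se)
})

test_that("point-like anions drift identically whatever their topology", {
  # same total charge, bead count and a vanishing bond length: the linear
  # and ring variants are physically the same particle
  mk <- function(topo, s) {
    sp <- build_species("Z", custom = list(name = "Z", topology = topo,
                                           n_beads = 3, total_charge = -3),
                        bond_length = 1e-3)
    cfg <- build_config(sp, lattice = build_fcc(), field = 0.3, seed = s,
                        n_steps = 2000, adsorption_depth = 0)
    mean(axial_velocities(unwrap(run_bd(cfg, save_beads = FALSE))))
  }
  v_lin <- sapply(1:3, function(s) mk("linear", s))
  v_ring <- sapply(1:3, function(s) mk("ring", s))
  se <- sqrt(var(v_lin) / 3 + var(v_ring) / 3)
  expect_lt(abs(mean(v_lin) - mean(v_ring)), 4 * se + 0.01)
})

test_that("initialization places anions clear of the NPs", {
  cfg <- build_config("P6", field = 0, seed = 9)
  set.seed(9)
  st <- ionlattice:::init_state(cfg)
  d <- ionlattice:::min_site_dist(st$centers, cfg$lattice$np_positions,
                                  cfg$lattice$box)
  expect_true(all(d > cfg$lattice$np_radius))
  expect_equal(nrow(st$centers), 40L)
})
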