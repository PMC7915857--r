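test_that("configuration and calibration are validated", {
  expect_error(sim_config(dt = 0), "dt")
  expect_error(sim_config(n_steps = -1), "n_steps")
  expect_error(sim_config(dt = 0.001, steps_per_rotation = 36000),
               "90 time units")
  expect_silent(sim_config(dt = 0.0025, steps_per_rotation = 36000,
                           n_steps = 0))
})

test_that("the Stokes'-time calibration maps time units to seconds", {
  expect_equal(seconds_per_time_unit(1), 4.5e-6)
  expect_equal(seconds_per_time_unit(240), 1.08e-3)
  expect_error(seconds_per_time_unit(0), "positive")
  # first-principles recomputation 6 pi eta sigma^3 / kT at ~room temp
  expect_equal(stokes_time(1.0e-3, 1.0e-8, 300), 4.5e-6, tolerance = 0.02)
})

test_that("identical seed and configuration reproduce a run bit-exactly", {
  loaded <- make_fixture("mini_fiber_40", seed = 2)
  cfg <- sim_config(n_steps = 20000, seed = 42, frame_interval = 5000,
                    gamma_c = 50)
  t1 <- integrate_dynamics(loaded$fiber, loaded$ring, motor_params(), cfg)
  t2 <- integrate_dynamics(loaded$fiber, loaded$ring, motor_params(), cfg)
  expect_identical(t1$frames_pos, t2$frames_pos)
  expect_identical(t1$frames_ring, t2$frames_ring)
  t3 <- integrate_dynamics(loaded$fiber, loaded$ring, motor_params(),
                           sim_config(n_steps = 20000, seed = 43,
                                      frame_interval = 5000, gamma_c = 50))
  expect_false(identical(t1$frames_pos, t3$frames_pos))
})

test_that("a free bead diffuses with MSD = 6 D t", {
  p <- fiber_params(n_beads = 3L, bond_k = 1e-12, bend_Kb = 0,
                    wca_epsilon = 1e-12, torsion_C = 1e-12,
                    tether_k = 1e-12, perp_k = 1e-12)
  f <- build_linear_fiber(p)
  tr <- integrate_dynamics(f, NULL, NULL,
                           sim_config(n_steps = 200000, seed = 11,
                                      frame_interval = 100,
                                      motor_enabled = FALSE))
  # lag-based estimator: displacement over a fixed lag, averaged over
  # windows and the three independent beads
  lag <- 20L
  nf <- length(tr$times)
  d2 <- unlist(lapply(seq_len(nf - lag), function(k)
    rowSums((frame_positions(tr, k + lag) - frame_positions(tr, k))^2)))
  dt_lag <- tr$times[1 + lag] - tr$times[1]
  expect_equal(mean(d2), 6 * 1 * dt_lag, tolerance = 0.05)
})

test_that("the linking number of a closed torsion-active fiber is conserved", {
  fib <- build_circular_fiber(fiber_params(n_beads = 40L))
  tr <- integrate_dynamics(fib, NULL, NULL,
                           sim_config(n_steps = 100000, seed = 5,
                                      frame_interval = 5000,
                                      motor_enabled = FALSE))
  lk <- vapply(seq_along(tr$times), function(k)
    fiber_frame_linking(frame_positions(tr, k), frame_paxs(tr, k)),
    numeric(1))
  expect_lt(max(abs(lk - lk[1])), 0.05)
  # the Tw + Wr decomposition reproduces the invariant within the
  # discrete White-identity scatter
  tw <- vapply(seq_along(tr$times), function(k)
    tw_plus_wr(frame_positions(tr, k), frame_paxs(tr, k)), numeric(1))
  expect_lt(max(abs(tw - lk)), 0.35)
})

test_that("equilibrium statistics follow the Boltzmann weights", {
  fib <- build_circular_fiber(fiber_params(n_beads = 40L))
  tr <- integrate_dynamics(fib, NULL, NULL,
                           sim_config(n_steps = 60000, seed = 9,
                                      frame_interval = 1000,
                                      motor_enabled = FALSE))
  use <- seq_along(tr$times) > 20
  bonds <- unlist(lapply(which(use), function(k) {
    pos <- frame_positions(tr, k)
    sqrt(rowSums((rbind(pos[-1, ], pos[1, ]) - pos)^2))
  }))
  cosb <- unlist(lapply(which(use), function(k) {
    pos <- frame_positions(tr, k)
    tg <- rbind(pos[-1, ], pos[1, ]) - pos
    tg <- tg / sqrt(rowSums(tg^2))
    rowSums(tg * rbind(tg[-1, ], tg[1, ]))
  }))
  # bond-length fluctuation ~ sqrt(kT / k)
  expect_equal(sd(bonds), sqrt(1 / 100), tolerance = 0.15)
  # mean bend cosine of the Kratky-Porod chain: coth(K) - 1/K at K = 5,
  # mildly swollen by excluded volume
  expect_equal(mean(cosb), 1 / tanh(5) - 1 / 5, tolerance = 0.03)
  # KS check of bond lengths against the Boltzmann density r^2 e^{-k(r-r0)^2/2}
  rs <- seq(0.5, 1.5, length.out = 4096)
  dens <- rs^2 * exp(-100 * (rs - 1)^2 / 2)
  cdf <- cumsum(dens) / sum(dens)
  samp <- sample(bonds, 400)
  ks <- suppressWarnings(ks.test(samp, function(q)
    approx(rs, cdf, xout = q, yleft = 0, yright = 1)$y))
  expect_gt(ks$p.value, 0.01)
})

test_that("zero steps yield a single-frame trajectory", {
  fib <- build_circular_fiber(fiber_params(n_beads = 20L))
  tr <- integrate_dynamics(fib, NULL, NULL,
                           sim_config(n_steps = 0, motor_enabled = FALSE))
  expect_equal(length(tr$times), 1L)
  expect_equal(tr$status, "budget")
})

test_that("uncapped force blow-up raises the instability error", {
  set.seed(1)
  fib <- build_circular_fiber(fiber_params(n_beads = 12L))
  fib$pos[3, ] <- fib$pos[4, ] + c(0.05, 0, 0)   # deep WCA overlap
  expect_error(
    integrate_dynamics(fib, NULL, NULL,
                       sim_config(n_steps = 100, dt = 0.01,
                                  motor_enabled = FALSE, force_cap = -1)),
    "instability")
})

test_that("a ring displaced from the fiber terminates the run as an escape", {
  loaded <- make_fixture("mini_fiber_40", seed = 2)
  ring <- loaded$ring
  ring$pos <- ring$pos + matrix(rep(c(0, 0, 25), each = 14), ncol = 3)
  tr <- integrate_dynamics(loaded$fiber, ring, motor_params(),
                           sim_config(n_steps = 50000, seed = 1,
                                      frame_interval = 10000, gamma_c = 50))
  expect_equal(tr$status, "escape")
  expect_lt(tr$steps_done, 50000)
})
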