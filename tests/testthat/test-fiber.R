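test_that("fiber parameters are validated and carry fixed conversions", {
  p <- fiber_params()
  expect_equal(p$n_beads, 150L)
  expect_equal(p$bp_per_bead, 400)
  expect_equal(p$nm_per_bead, 10)
  expect_error(fiber_params(n_beads = 2), "n_beads")
  expect_error(fiber_params(bond_k = -1), "positive")
  expect_error(fiber_params(torsion_C = 0), "positive")
})

test_that("the built circle has the right geometry and bookkeeping", {
  f <- build_circular_fiber(fiber_params(), seed = 7)
  expect_equal(f$radius, 150 / (2 * pi), tolerance = 1e-12)
  expect_equal(nrow(f$pos), 150)
  expect_equal(nrow(f$pax), 150)          # one periaxial bead per backbone bead
  expect_equal(f$loop_bp, 60000)          # 150 beads x 400 bp
  expect_true(all(f$torsion_active))
  expect_true(all(f$gamma_bb == 1) && all(f$gamma_pax == 1))
  # closure: last bond joins bead 150 back to bead 1 (chord of the
  # 150-gon, marginally below the arc length)
  expect_equal(sqrt(sum((f$pos[150, ] - f$pos[1, ])^2)), 1.0,
               tolerance = 1e-3)
  # periaxial offsets at r_p, perpendicular to the local tangent
  u <- f$pax - f$pos
  expect_equal(sqrt(rowSums(u^2)), rep(0.5, 150), tolerance = 1e-9)
  # as built the fiber is torsionally relaxed
  expect_lt(max(abs(wrapa(twist_angles(f) - f$phi0))), 1e-9)
})

test_that("forces equal the negative energy gradient for every block", {
  # modest perturbations and twist stress: large angular stress at sharp
  # kinks enters the capped-lever regularization, which is deliberately
  # not a gradient
  set.seed(2)
  f <- build_circular_fiber(fiber_params(n_beads = 16L))
  f$pos <- f$pos + matrix(rnorm(48, 0, 0.05), ncol = 3)
  f$pax <- f$pax + matrix(rnorm(48, 0, 0.03), ncol = 3)
  f$phi0 <- wrapa(twist_angles(f) - rnorm(16, 0, 0.05))
  f$torsion_active[4] <- FALSE
  th <- 2 * pi * (0:13) / 14
  ring <- supercoilex:::new_ring_state(
    cbind(5.2, 2.23 * cos(th), 0.3 + 2.23 * sin(th)), ring_params())
  fr <- compute_forces(f, ring)
  for (blk in c("pos", "pax", "ring")) {
    g <- numeric_gradient(f, ring, blk)
    analytic <- fr[[c(pos = "f_pos", pax = "f_pax", ring = "f_ring")[blk]]]
    expect_lt(max(abs(g - analytic)) / max(abs(g)), 1e-5)
  }
  # pair terms are equal and opposite: an isolated system feels no net force
  expect_lt(max(abs(colSums(fr$f_pos) + colSums(fr$f_pax) +
                      colSums(fr$f_ring))), 1e-8)
})

test_that("bond and excluded-volume forces vanish at their special points", {
  # collinear trimer at the equilibrium bond length: no bond or bending
  # force; next-nearest neighbours sit beyond the WCA cutoff
  p <- fiber_params(n_beads = 3L, bend_Kb = 0, torsion_C = 1e-12,
                    tether_k = 1e-12, perp_k = 1e-12)
  f <- build_linear_fiber(p)
  fr <- compute_forces(f)
  expect_lt(max(abs(fr$f_pos)), 1e-10)
  # bringing beads 1 and 3 exactly to the WCA minimum keeps the energy at
  # the truncation value (zero) and the pair force zero
  f$pos[3, 1] <- 2^(1 / 6)
  e_cut <- potential_energy(f)
  f$pos[3, 1] <- 2^(1 / 6) - 1e-4
  expect_gt(potential_energy(f), e_cut)
})

test_that("local twist angles follow the material frame", {
  f <- build_linear_fiber(fiber_params(n_beads = 5L))
  expect_lt(max(abs(twist_angles(f))), 1e-12)   # parallel frames
  a <- pi / 6
  f2 <- f
  f2$pax[3, ] <- f2$pos[3, ] + 0.5 * c(0, -sin(a), cos(a))
  expect_equal(local_twist_angle(f2, 2), a, tolerance = 1e-10)
  expect_equal(local_twist_angle(f2, 3), -a, tolerance = 1e-10)
  expect_error(local_twist_angle(f2, 99), "out of range")
  # offset dragged onto the bond axis: degenerate geometry
  f3 <- f
  f3$pax[2, ] <- f3$pos[2, ] + c(0.5, 0, 0)
  expect_error(local_twist_angle(f3, 2), "degenerate")
})

test_that("torsional energy honours the spring form and the nicks", {
  f <- build_linear_fiber(fiber_params(n_beads = 5L,
                                       torsion_form = "harmonic"))
  a <- 0.2
  f$pax[3, ] <- f$pos[3, ] + 0.5 * c(0, -sin(a), cos(a))
  f$torsion_active[3] <- FALSE  # only bond 2 carries the 0.2 rad twist
  expect_equal(torsional_energy(f), 0.5 * 50 * 0.2^2, tolerance = 1e-10)
  # nicking the stressed bond removes its contribution
  f$torsion_active[2] <- FALSE
  expect_equal(torsional_energy(f), 0)
  # the bounded cosine default agrees with the harmonic form to second order
  fc <- build_linear_fiber(fiber_params(n_beads = 5L))
  fc$pax[3, ] <- fc$pos[3, ] + 0.5 * c(0, -sin(a), cos(a))
  fc$torsion_active[3] <- FALSE
  expect_equal(torsional_energy(fc), 50 * (1 - cos(a)), tolerance = 1e-10)
  expect_equal(torsional_energy(fc), 1.0, tolerance = 5e-3)
})

test_that("a relaxed circle is a stationary point of the potential", {
  f <- build_circular_fiber(fiber_params(n_beads = 40L))
  tr <- integrate_dynamics(f, NULL, NULL,
                           sim_config(n_steps = 5000, temperature = 0,
                                      seed = 1, frame_interval = 5000,
                                      motor_enabled = FALSE))
  fr <- compute_forces(tr$fiber_final)
  expect_lt(max(abs(fr$f_pos)), 0.3)
  expect_lt(max(abs(fr$f_pax)), 0.3)
})
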