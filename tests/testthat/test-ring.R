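test_that("ring parameters are validated", {
  expect_equal(ring_params()$n_ring_beads, 14L)
  expect_error(ring_params(n_ring_beads = 13), "even")
  expect_error(ring_params(gamma_c = 0.5), "gamma_R")
})

test_that("loading entraps both arms pseudo-topologically", {
  fiber <- build_circular_fiber(fiber_params(n_beads = 40L))
  loaded <- load_ring(fiber, ring_params(gamma_c = 50), seed = 1)
  ring <- loaded$ring
  expect_equal(nrow(ring$pos), 14)
  expect_true(ring$loaded)
  # Gauss linking number ring vs closed fiber is zero: entrapment is
  # geometric, not topological
  expect_lt(abs(linking_number(loaded$fiber$pos, ring$pos)), 0.05)
  # the two arms pierce the ring disc once each, in opposite directions
  pierce <- fiber_ring_piercings(loaded$fiber$pos, ring$pos)
  expect_equal(sum(pierce), 0)
  expect_equal(sort(range(pierce)), c(-1, 1))
  expect_equal(sum(pierce != 0), 2)
  lm_ <- loop_metrics(loaded$fiber, ring)
  expect_true(all(lm_$arm_sizes >= 1))
  expect_lt(lm_$loop_size, 12)
})

test_that("threaded-bead detection follows the plane rule and tie-break", {
  fx <- make_fixture("ring_on_rod")
  idx <- threaded_beads(fx$fiber, fx$ring, on_escape = "na")
  # the rod passes the ring once; the plane sits equidistant from beads 10
  # and 11, so the tie breaks to the lower index
  expect_true(10L %in% idx)
  expect_true(any(is.na(idx)))  # a single strand is not a loaded loop
  # a ring displaced far from the fiber signals escape
  far <- fx$ring
  far$pos <- far$pos + matrix(rep(c(0, 10, 0), each = 14), ncol = 3)
  expect_error(threaded_beads(fx$fiber, far), class = "escaped_ring")
  expect_true(all(is.na(threaded_beads(fx$fiber, far, on_escape = "na"))))
})

test_that("ring friction bookkeeping is exact and reversible", {
  fiber <- build_circular_fiber(fiber_params(n_beads = 30L))
  ring <- supercoilex:::new_ring_state(matrix(0, 14, 3),
                                       ring_params(gamma_c = 200))
  ring$loaded <- TRUE
  ring$threaded <- c(5L, 25L)
  fiber <- apply_ring_friction(fiber, ring)
  expect_equal(sum(fiber$gamma_bb == 200), 2)  # 2 backbone ...
  expect_equal(sum(fiber$gamma_pax == 200), 2) # ... + 2 periaxial partners
  expect_equal(sum(fiber$gamma_bb == 1), 28)
  # the ring moves by one bead: the old bead is restored
  ring$threaded <- c(6L, 25L)
  fiber <- apply_ring_friction(fiber, ring)
  expect_equal(fiber$gamma_bb[5], 1)
  expect_equal(fiber$gamma_bb[6], 200)
  # idempotent
  expect_identical(apply_ring_friction(fiber, ring), fiber)
  # single-threaded-bead variant touches one bead only
  ring1 <- ring
  ring1$params <- ring_params(gamma_c = 200, single_threaded_bead = TRUE)
  fiber <- apply_ring_friction(fiber, ring1, ring1$params)
  expect_equal(sum(fiber$gamma_bb == 200), 1)
})

test_that("pseudo-topology and the motor-body exclusion hold during dynamics", {
  loaded <- make_fixture("mini_fiber_40", seed = 3)
  cfg <- sim_config(n_steps = 200000, seed = 3, frame_interval = 10000,
                    gamma_c = 50)
  traj <- integrate_dynamics(loaded$fiber, loaded$ring, motor_params(), cfg)
  keep <- which(!is.na(traj$threaded_plus) & !is.na(traj$threaded_minus))
  lks <- vapply(keep, function(k)
    linking_number(frame_positions(traj, k), frame_rings(traj, k)),
    numeric(1))
  expect_gt(length(lks), 3)
  expect_lt(max(abs(lks)), 0.5)
  # the ring cannot pass the loading bead: the 3-sigma exclusion keeps
  # every ring bead away from it (5% soft tolerance)
  dmin <- min(vapply(seq_along(traj$times), function(k) {
    rp <- frame_rings(traj, k)
    lb <- frame_positions(traj, k)[traj$loading_bead, ]
    min(sqrt(rowSums(sweep(rp, 2, lb)^2)))
  }, numeric(1)))
  expect_gte(dmin, 2.85)
})
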