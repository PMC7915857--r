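test_that("writhe obeys the planar, chirality and orientation identities", {
  circ <- make_fixture("planar_circle", n = 64)
  expect_lt(abs(writhe(circ)), 1e-10)
  f8 <- make_fixture("figure_eight", n = 2000, eps = 0.005)
  w <- writhe(f8)
  expect_equal(abs(w), 1, tolerance = 0.02)       # one signed crossing
  mirror <- f8
  mirror[, 3] <- -mirror[, 3]
  expect_equal(writhe(mirror), -w, tolerance = 1e-9)
  expect_equal(writhe(f8[nrow(f8):1, ]), w, tolerance = 1e-6)
  expect_error(writhe(f8[1:3, ]), "4 points")
  expect_error(writhe(rbind(circ, circ[64, ])), "coincident")
})

test_that("the discretized Gauss integral matches dense quadrature", {
  for (eps in c(0.1, 0.02)) {
    f <- function(t) cbind(cos(t), sin(t) * cos(t), eps * sin(t))
    t <- 2 * pi * (0:799) / 800
    expect_equal(abs(writhe(f(t))), abs(writhe_quadrature(f, 1000)),
                 tolerance = 0.02)
  }
})

test_that("the Gauss linking number distinguishes linked from unlinked", {
  th <- 2 * pi * (0:39) / 40
  c1 <- cbind(cos(th), sin(th), 0)
  c2 <- cbind(1 + cos(th), 0 * th, sin(th))
  expect_equal(abs(linking_number(c1, c2)), 1, tolerance = 1e-6)
  expect_lt(abs(linking_number(c1, cbind(5 + cos(th), sin(th), 0))), 1e-9)
})

test_that("White's identity holds for a constructed twisted ribbon", {
  n <- 100
  th <- 2 * pi * (0:(n - 1)) / n
  pos <- cbind(10 * cos(th), 10 * sin(th), 0)
  for (k in c(-3, 2)) {
    ang <- k * th
    pax <- pos + 0.5 * (cbind(cos(th), sin(th), 0) * cos(ang) +
                          cbind(0, 0, 1)[rep(1, n), ] * sin(ang))
    tw <- sum(wrapa(supercoilex:::cpp_twist_angles(pos, pax, TRUE))) / (2 * pi)
    expect_equal(tw + writhe(pos), linking_number(pos, pax),
                 tolerance = 0.02)
  }
})

test_that("twist is measured relative to the relaxed reference", {
  f <- build_circular_fiber(fiber_params(n_beads = 30L))
  expect_equal(twist(f), 0, tolerance = 1e-9)
  # one full turn distributed uniformly over a 10-bond region
  region <- 5:15
  for (i in seq_along(region)) {
    b <- region[i]
    th <- 2 * pi * (b - 1) / 30
    ang <- 2 * pi * (i - 1) / 10
    f$pax[b, ] <- f$pos[b, ] + 0.5 * (c(cos(th), sin(th), 0) * cos(ang) -
                                        c(0, 0, 1) * sin(ang))
  }
  expect_equal(twist(f, region), 1.0, tolerance = 1e-9)
})

test_that("loop and arm sizes follow the threading bookkeeping", {
  fiber <- build_circular_fiber(fiber_params(n_beads = 150L))
  ring <- supercoilex:::new_ring_state(matrix(0, 14, 3), ring_params())
  ring$loaded <- TRUE
  ring$threaded <- c(31L, 106L)   # 30 beads up, 45 beads down from bead 1
  lm_ <- loop_metrics(fiber, ring)
  expect_equal(lm_$arm_sizes, c(30, 45))
  expect_equal(lm_$loop_size, 75)
  ring$threaded <- c(2L, 150L)    # just-loaded configuration
  expect_equal(loop_metrics(fiber, ring)$loop_size, 2)
  ring$threaded <- c(NA_integer_, NA_integer_)
  expect_error(loop_metrics(fiber, ring), "escaped")
})

test_that("supercoiling density uses Lk0 = 40 turns per bead", {
  expect_equal(supercoil_density(0, 150), 0)
  expect_equal(supercoil_density(-10, 150), -10 / 6000)
  expect_equal(supercoil_density(-40, 1), -1)
  expect_error(supercoil_density(-1, 0), "zero-length")
})

test_that("extrusion rate converts bead slopes to kbp per second", {
  m <- data.frame(time = seq(0, 1000, by = 10))
  m$l <- 0.075 * m$time
  r <- extrusion_rate(m, seconds_per_time_unit(240))
  expect_equal(r$rate_kbps, 0.075 * 400 / 1.08e-3 / 1000, tolerance = 1e-9)
  expect_equal(r$rate_kbps, 27.78, tolerance = 1e-3)
  flat <- data.frame(time = m$time, l = 20)
  expect_warning(r0 <- extrusion_rate(flat), "constant")
  expect_equal(r0$rate_kbps, 0)
  # averaging over runs
  avg <- extrusion_rate(list(m, m))
  expect_equal(avg$rate_kbps, r$rate_kbps)
  expect_length(avg$per_run, 2)
})

test_that("contact maps count close pairs and average idempotently", {
  f <- build_linear_fiber(fiber_params(n_beads = 20L))
  traj <- structure(list(times = 0,
                         frames_pos = array(t(f$pos), c(3, 20, 1)),
                         n_beads = 20L), class = "sc_trajectory")
  cm <- contact_map(traj, cutoff = 1.5)
  m <- cm$matrix
  expect_true(isSymmetric(m))
  expect_true(all(diag(m) == 1))
  expect_true(all(m >= 0 & m <= 1))
  # a straight line at unit spacing has contacts only between neighbours
  off <- abs(row(m) - col(m))
  expect_true(all(m[off == 1] == 1))
  expect_true(all(m[off > 1] == 0))
  cm2 <- contact_map(list(traj, traj), cutoff = 1.5)
  expect_equal(cm2$matrix, cm$matrix)      # averaging idempotence
  expect_equal(cm2$n_runs, 2)
  expect_error(contact_map(list()), "empty")
})

test_that("a plectonemically ordered loop shows the anti-diagonal signature", {
  # interwound superhelix: two antiparallel strands wound around a common
  # axis, so bead i contacts bead n - i
  n <- 40
  s <- seq(0, 1, length.out = n / 2)
  up <- cbind(1.2 * cos(8 * pi * s), 1.2 * sin(8 * pi * s), 10 * s)
  down <- cbind(1.2 * cos(8 * pi * rev(s) + pi),
                1.2 * sin(8 * pi * rev(s) + pi), 10 * rev(s))
  plect <- rbind(up, down)
  tr_p <- structure(list(times = 0, frames_pos = array(t(plect), c(3, n, 1)),
                         n_beads = n), class = "sc_trajectory")
  mp <- contact_map(tr_p, cutoff = 2.5)$matrix
  anti <- mean(mp[cbind(2:(n - 1), n + 1 - (2:(n - 1)))])
  # a random coil has no preference for the anti-diagonal
  set.seed(8)
  steps <- matrix(rnorm(3 * n), ncol = 3)
  steps <- steps / sqrt(rowSums(steps^2))
  coil <- apply(steps, 2, cumsum)
  tr_c <- structure(list(times = 0, frames_pos = array(t(coil), c(3, n, 1)),
                         n_beads = n), class = "sc_trajectory")
  mc <- contact_map(tr_c, cutoff = 2.5)$matrix
  anti_c <- mean(mc[cbind(2:(n - 1), n + 1 - (2:(n - 1)))])
  expect_gt(anti, 0.8)
  expect_lt(anti_c, 0.3)
})

test_that("persistence length estimators behave at the limits", {
  # freely jointed limit: decay on the one-bead scale
  p <- fiber_params(n_beads = 30L, bend_Kb = 0, torsion_C = 1e-12,
                    tether_k = 1e-12, perp_k = 1e-12)
  f <- build_linear_fiber(p)
  tr <- integrate_dynamics(f, NULL, NULL,
                           sim_config(n_steps = 400000, dt = 2.5e-4,
                                      seed = 4, frame_interval = 4000,
                                      motor_enabled = FALSE))
  lp <- persistence_length(tr)
  expect_lt(lp$lp_nm, 25)      # about one bead (10 nm) once swollen
  # a rigid ring never decorrelates on the fitted scale: fit-quality error
  circ <- build_circular_fiber(fiber_params(n_beads = 100L))
  rigid <- structure(list(times = c(0, 1),
                          frames_pos = array(t(circ$pos), c(3, 100, 2)),
                          n_beads = 100L, closed = TRUE,
                          params = circ$params), class = "sc_trajectory")
  expect_error(persistence_length(rigid), "fit-quality")
})
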