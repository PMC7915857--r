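test_that("continuum parameters and stability bounds are enforced", {
  p <- continuum_params()
  expect_equal(p$D_c, 1.6 / 200)
  expect_lte(p$D_c, p$D_sigma)
  expect_error(continuum_params(D_sigma = -1), "positive")
  expect_error(continuum_solve(continuum_params(dtau = 0.5)), "stability")
})

test_that("without a source the profile stays flat and the boundary still", {
  p <- continuum_params(sigma_dot_P = 0, domain_length = 30)
  sol <- continuum_solve(p, t_end = 50)
  expect_true(all(sol$profile == 0))
  expect_equal(sol$series$x_c[nrow(sol$series)], p$x0)
  expect_error(relaxed_fraction(sol), "injected")
})

test_that("supercoiling energy forms behave as declared", {
  p <- continuum_params()
  expect_equal(supercoiling_energy(0, 10, p), 0)
  expect_equal(supercoiling_energy(4, 10, p) / supercoiling_energy(2, 10, p),
               4)                                        # quadratic
  expect_equal(supercoiling_energy(2, 20, p),
               supercoiling_energy(2, 10, p) / 2)        # per-length
  pp <- continuum_params(energy_form = "plain")
  expect_equal(supercoiling_energy(2, 20, pp), supercoiling_energy(2, 10, pp))
  pe <- continuum_params(use_extended_energy = TRUE, l_p = 5, c = 0.03)
  expect_equal(supercoiling_energy(0, 10, pe), 8 * 5 / 100 + 0.03 * log(10))
  expect_error(supercoiling_energy(1, 0, p), "positive")
})

test_that("the loop stiffness term alone extrudes a small loop", {
  pe <- continuum_params(sigma_dot_P = 0, use_extended_energy = TRUE,
                         domain_length = 20, gamma_c = 2, dtau = 0.05)
  sol <- continuum_solve(pe, t_end = 1500)
  expect_gt(sol$series$x_c[nrow(sol$series)], pe$x0 + 3)
})

test_that("linking-number bookkeeping closes to solver precision", {
  for (g in c(2, 200)) {
    sol <- continuum_solve(continuum_params(gamma_c = g, domain_length = 60))
    expect_lt(sol$max_balance_error, 1e-6)
    expect_equal(sum(abs(sol$profile)), sol$injected - sol$leaked,
                 tolerance = 1e-9)
  }
})

test_that("an impermeable boundary retains every injected rotation", {
  sol <- continuum_solve(continuum_params(gamma_c = 1e12, domain_length = 40,
                                          dtau = 0.05),
                         t_end = 2000)
  expect_gt(sol$injected, 20)
  expect_equal(relaxed_fraction(sol), 0, tolerance = 0.01)
})

test_that("with a frozen boundary and no source the profile relaxes to uniform", {
  p <- continuum_params(sigma_dot_P = 0, K = 1e-12, gamma_c = 1e12,
                        domain_length = 40, x0 = 30)
  p$dtau <- 0.05
  bump <- c(rep(0, 10), rep(-0.5, 5), rep(0, 15))
  sol <- continuum_solve(p, t_end = 400, initial_profile = bump)
  expect_equal(sum(sol$profile), sum(bump), tolerance = 1e-9)  # conservation
  expect_lt(sd(sol$profile), 0.02 * sd(bump))                  # uniformized
})

test_that("higher friction accumulates more linking number", {
  dlk <- vapply(c(2, 20, 200), function(g)
    abs(continuum_solve(continuum_params(gamma_c = g))$final_dLk),
    numeric(1))
  expect_true(all(diff(dlk) > 0))
})

test_that("the concatenated fit recovers known parameters from noisy data", {
  errs <- sapply(1:2, function(seed) {
    truth <- continuum_params(gamma_c = 5, domain_length = 40,
                              D_sigma = 1.6, K = 3400, dtau = 0.05)
    trajs <- synthetic_continuum_trajectories(truth, n_traj = 3,
                                              noise_sd = 0.05, seed = seed)
    start <- continuum_params(gamma_c = 5, domain_length = 40,
                              D_sigma = 1.0, K = 2000, dtau = 0.05)
    fit <- continuum_fit(trajs, gamma_c = 5, params = start)
    abs(fit$estimates[c("D_sigma", "K")] / c(1.6, 3400) - 1)
  })
  expect_lt(max(errs), 0.10)
})

test_that("a noiseless trajectory fits itself with near-zero residual", {
  truth <- continuum_params(gamma_c = 50, domain_length = 30, dtau = 0.05)
  trajs <- synthetic_continuum_trajectories(truth, n_traj = 1, noise_sd = 0,
                                            seed = 1)
  fit <- continuum_fit(trajs, gamma_c = 50, params = truth)
  expect_lt(fit$residual, 1)
  # the per-arm convention halves the two-fiber constants
  expect_equal(unname(fit$per_arm["K"]), unname(fit$estimates["K"]) / 2)
  expect_equal(3400 / 2, 1700)
})

test_that("the extended energy functional fits as well as the plain one", {
  truth <- continuum_params(gamma_c = 5, domain_length = 40, dtau = 0.05)
  trajs <- synthetic_continuum_trajectories(truth, n_traj = 2,
                                            noise_sd = 0.05, seed = 3)
  plain <- continuum_fit(trajs, gamma_c = 5, params = truth)
  ext_start <- continuum_params(gamma_c = 5, domain_length = 40, K = 1550,
                                c = 0.03, use_extended_energy = TRUE,
                                dtau = 0.05)
  extended <- continuum_fit(trajs, gamma_c = 5, params = ext_start,
                            fit_c = TRUE)
  expect_lt(extended$residual, 2 * plain$residual)
})
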