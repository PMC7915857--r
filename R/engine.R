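#' Simulation configuration
#'
#' @param n_steps number of integration steps.
#' @param dt integration time step in simulation time units.
#' @param temperature thermal energy k_B T.
#' @param seed integer seed for the (compiled) random number generator;
#'   identical seed and configuration reproduce a run bit-exactly.
#' @param frame_interval steps between recorded frames.
#' @param gamma_c ring-fiber friction handed to the extrusion pipeline.
#' @param eta_rel viscosity of the medium relative to water; 240 maps one
#'   time unit to 1.08 ms via Stokes' time.
#' @param motor_enabled whether the supercoiling motor runs.
#' @param steps_per_rotation motor calibration; with `motor_enabled` the
#'   product `dt * steps_per_rotation` must equal 90 time units (one
#'   rotation per 90 time units, i.e. 10 rotations per second at the
#'   240x-water calibration; the coarser pairing 0.0025 x 36,000
#'   satisfies the same identity).
#' @param force_cap permanent per-particle force cap. Bounds the
#'   single-step displacement of the first-order integrator against rare
#'   near-singular excluded-volume or torsional-lever configurations; at
#'   the default step the cap only engages at Boltzmann-negligible
#'   energies, leaving equilibrium statistics intact. Set to a
#'   non-positive value to disable (an integration-instability error is
#'   raised if a displacement then exceeds half a bead diameter).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_steps = 100000L, dt = 5e-4, temperature = 1.0,
                       seed = 1L, frame_interval = 1000L, gamma_c = 20,
                       eta_rel = 240, motor_enabled = TRUE,
                       steps_per_rotation = 90 / dt, force_cap = 150) {
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (n_steps < 0) stop("n_steps must be >= 0", call. = FALSE)
  if (motor_enabled && abs(dt * steps_per_rotation - 90) > 1e-9)
    stop("motor calibration violated: dt * steps_per_rotation must equal ",
         "90 time units per rotation", call. = FALSE)
  cfg <- list(n_steps = as.integer(n_steps), dt = dt,
              temperature = temperature, seed = as.integer(seed),
              frame_interval = as.integer(frame_interval), gamma_c = gamma_c,
              eta_rel = eta_rel, motor_enabled = isTRUE(motor_enabled),
              steps_per_rotation = steps_per_rotation,
              force_cap = force_cap)
  class(cfg) <- "sim_config"
  cfg
}

#' Seconds per simulation time unit
#'
#' One time unit corresponds to the Stokes' time of a 10 nm bead,
#' \eqn{6\pi\eta\sigma^3/k_BT = 4.5\,\mu s \times \eta_{rel}}, where
#' `eta_rel` is the viscosity of the surrounding medium relative to water.
#'
#' @param eta_rel relative viscosity (> 0); the extrusion calibration uses
#'   240, giving 1.08 ms per time unit.
#' @return seconds per simulation time unit.
#' @export
seconds_per_time_unit <- function(eta_rel = 240) {
  if (!is.numeric(eta_rel) || eta_rel <= 0)
    stop("eta_rel must be positive", call. = FALSE)
  4.5e-6 * eta_rel
}

#' @param eta_Pa_s solvent viscosity in Pa s.
#' @param sigma_m bead diameter in meters.
#' @param T_K temperature in kelvin.
#' @rdname seconds_per_time_unit
#' @export
stokes_time <- function(eta_Pa_s = 1.0e-3, sigma_m = 1.0e-8, T_K = 300) {
  kB <- 1.380649e-23
  6 * pi * eta_Pa_s * sigma_m^3 / (kB * T_K)
}

#' Integrate the overdamped Langevin dynamics
#'
#' Per-bead update \eqn{\Delta x = (dt/\gamma_i) F_i + \sqrt{2 k_BT\,
#' dt/\gamma_i}\,\xi}. When a ring is present, threading detection, the
#' friction field and the moving nicks are refreshed every step; the
#' motor, when enabled, rotates the loading bead's frame every step. The
#' run terminates early when the ring escapes the fiber or the loop spans
#' the whole chain.
#'
#' @param fiber a `fiber_state`.
#' @param ring optional `ring_state`.
#' @param motor optional [motor_params()]; `NULL` disables the motor.
#' @param config a [sim_config()].
#' @param nicks_on,friction_on individually disable the moving nicks or
#'   the friction field (used by calibration and control runs).
#' @param cap_steps cap pair forces during this many initial equilibration
#'   steps.
#' @return an object of class `sc_trajectory`: recorded frames (backbone,
#'   periaxial, ring coordinates and torsional references), time stamps,
#'   cumulative motor turns, threaded-bead indices per frame, final
#'   states, and the termination status (`"budget"`, `"complete"` or
#'   `"escape"`).
#' @export
integrate_dynamics <- function(fiber, ring = NULL, motor = motor_params(),
                               config = sim_config(), nicks_on = TRUE,
                               friction_on = TRUE, cap_steps = 0L) {
  ring_present <- !is.null(ring)
  ring_pos <- if (ring_present) ring$pos else matrix(0, 0, 3)
  gamma_ring <- if (ring_present)
    rep(ring$params$gamma_ring, nrow(ring$pos)) else numeric(0)
  motor_on <- config$motor_enabled && !is.null(motor)
  if (motor_on && abs(config$dt * motor$steps_per_rotation - 90) > 1e-9)
    stop("motor calibration violated: dt * steps_per_rotation must equal ",
         "90 time units per rotation", call. = FALSE)
  res <- cpp_integrate(fiber$pos, fiber$pax, ring_pos,
                       fiber$gamma_bb, fiber$gamma_pax, gamma_ring,
                       as.integer(fiber$torsion_active), fiber$phi0,
                       cpp_param_list(fiber,
                                      ring_params = if (ring_present) ring$params,
                                      dt = config$dt,
                                      kT = config$temperature,
                                      force_cap = config$force_cap %||% 150),
                       config$n_steps, config$frame_interval, config$seed,
                       motor_on,
                       if (motor_on) motor$steps_per_rotation else 36000,
                       if (motor_on) motor$rotation_sign else -1,
                       ring_present, config$gamma_c, nicks_on, friction_on,
                       as.integer(cap_steps), 0.0, fiber$motor_turns,
                       if (ring_present && ring$params$single_threaded_bead) 1L else 0L)

  if (identical(res$status, "unstable"))
    stop("integration-instability: a per-step displacement exceeded half ",
         "a bead diameter; use a smaller dt (or a finite force_cap)",
         call. = FALSE)
  fiber_final <- fiber
  fiber_final$pos <- res$final_pos
  fiber_final$pax <- res$final_pax
  fiber_final$gamma_bb <- res$gamma_bb
  fiber_final$gamma_pax <- res$gamma_pax
  fiber_final$torsion_active <- as.logical(res$torsion_active)
  fiber_final$phi0 <- res$phi0
  fiber_final$motor_turns <- res$end_motor_turns
  ring_final <- NULL
  if (ring_present) {
    ring_final <- ring
    ring_final$pos <- res$final_ring
    thr <- c(res$threaded_plus[length(res$threaded_plus)],
             res$threaded_minus[length(res$threaded_minus)])
    thr[thr < 0] <- NA_integer_
    ring_final$threaded <- thr + 1L
    ring_final$loaded <- !any(is.na(ring_final$threaded)) &&
      res$status != "escape"
  }
  traj <- list(times = res$times,
               frames_pos = res$frames_pos,
               frames_pax = res$frames_pax,
               frames_ring = if (ring_present) res$frames_ring else NULL,
               frames_phi0 = res$frames_phi0,
               motor_turns = res$motor_turns,
               threaded_plus = ifelse(res$threaded_plus < 0, NA_integer_,
                                      res$threaded_plus + 1L),
               threaded_minus = ifelse(res$threaded_minus < 0, NA_integer_,
                                       res$threaded_minus + 1L),
               status = res$status, steps_done = res$steps_done,
               released_lk = res$released_lk,
               fiber_final = fiber_final, ring_final = ring_final,
               config = config,
               loading_bead = fiber$loading_bead, closed = fiber$closed,
               n_beads = nrow(fiber$pos),
               params = fiber$params,
               ring_params = if (ring_present) ring$params else NULL)
  class(traj) <- "sc_trajectory"
  traj
}

#' @export
print.sc_trajectory <- function(x, ...) {
  cat(sprintf("<sc_trajectory> %d frames, %d beads, %d steps, status '%s'\n",
              length(x$times), x$n_beads, x$steps_done, x$status))
  invisible(x)
}

n_frames <- function(traj) length(traj$times)

# coordinates of frame k as an n x 3 matrix
frame_pos <- function(traj, k) t(traj$frames_pos[, , k])
frame_pax <- function(traj, k) t(traj$frames_pax[, , k])
frame_ring <- function(traj, k) {
  if (is.null(traj$frames_ring)) NULL else t(traj$frames_ring[, , k])
}

#' Run a full extrusion simulation
#'
#' Orchestrates build, pseudo-topological loading and integration with the
#' motor, moving nicks and ring friction, until the ring escapes, the loop
#' spans the chain, or the step budget is exhausted. Per-frame topology
#' metrics are attached (see [trajectory_metrics()]).
#'
#' @param config a [sim_config()]; `config$gamma_c` sets the ring-fiber
#'   friction.
#' @param fiber_params_ a [fiber_params()] object.
#' @param ring_params_ a [ring_params()] object (its `gamma_c` is taken
#'   from `config`).
#' @param motor a [motor_params()] object.
#' @param out_dir optional directory: the trajectory, metrics CSV and a
#'   run manifest are written there.
#' @return an `sc_trajectory` with a `metrics` data frame attached.
#' @export
run_extrusion <- function(config = sim_config(),
                          fiber_params_ = fiber_params(),
                          ring_params_ = ring_params(),
                          motor = motor_params(), out_dir = NULL) {
  ring_params_$gamma_c <- config$gamma_c
  fiber <- build_circular_fiber(fiber_params_, seed = config$seed)
  loaded <- load_ring(fiber, ring_params_, seed = config$seed)
  traj <- integrate_dynamics(loaded$fiber, loaded$ring, motor, config)
  traj$metrics <- trajectory_metrics(traj)
  if (!is.null(out_dir)) write_trajectory(traj, out_dir)
  traj
}
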