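#' Parameters of the supercoiling motor
#'
#' The motor stands for an RNA polymerase associated with a type-I
#' topoisomerase: it rotates the fiber's material frame at the loading
#' bead at constant speed, leaving a flux of purely negative supercoiling.
#' Biologically the speed is fixed at 10 rotations per second; at the
#' simulation calibration (time step 0.0025, viscosity 240x water) this is
#' one rotation per 36,000 integration steps, i.e. 90 time units per turn.
#'
#' @param steps_per_rotation integration steps per full motor rotation;
#'   must pair with the integrator step so that one rotation takes 90
#'   time units (36,000 steps at 0.0025, or the default 180,000 at the
#'   package's 5e-4 step).
#' @param rotation_sign -1 for negative supercoiling.
#' @param rotations_per_second fixed biological rotation rate.
#' @return an object of class `motor_params`.
#' @export
motor_params <- function(steps_per_rotation = 180000, rotation_sign = -1,
                         rotations_per_second = 10) {
  if (abs(rotation_sign) != 1) stop("rotation_sign must be +1 or -1",
                                    call. = FALSE)
  p <- list(steps_per_rotation = steps_per_rotation,
            rotation_sign = rotation_sign,
            rotations_per_second = rotations_per_second)
  class(p) <- "motor_params"
  p
}

#' Apply one motor increment to the loading bead's frame
#'
#' Rotates the periaxial frame of the loading bead about the local bond
#' tangent by `rotation_sign * 2 pi / steps_per_rotation`, injecting twist
#' of that sign into the downstream bond. The torsional reference of the
#' upstream bond co-rotates (the co-localized topoisomerase absorbs the
#' positive twin domain), and the cumulative applied rotation is tracked
#' exactly in `fiber$motor_turns`.
#'
#' This is the single-step R-level form used in tests and small
#' constructions; inside [integrate_dynamics()] the same operation runs in
#' compiled code every step.
#'
#' @param fiber a `fiber_state`.
#' @param motor a [motor_params()] object.
#' @param n_increments number of single-step increments to apply.
#' @return the updated `fiber_state`.
#' @export
motor_step <- function(fiber, motor = motor_params(), n_increments = 1L) {
  n <- nrow(fiber$pos)
  lb <- fiber$loading_bead
  jn <- (lb %% n) + 1L
  delta <- -motor$rotation_sign * 2 * pi / motor$steps_per_rotation
  up_bond <- if (fiber$closed) ((lb - 2L) %% n) + 1L else lb - 1L
  for (k in seq_len(n_increments)) {
    t <- fiber$pos[jn, ] - fiber$pos[lb, ]
    t <- t / sqrt(sum(t^2))
    u <- fiber$pax[lb, ] - fiber$pos[lb, ]
    old_up <- if (!is.na(up_bond) && up_bond >= 1L)
      local_twist_angle(fiber, up_bond) else NA_real_
    cs <- cos(delta); sn <- sin(delta)
    u_rot <- u * cs + cross3_r(t, u) * sn + t * sum(t * u) * (1 - cs)
    fiber$pax[lb, ] <- fiber$pos[lb, ] + u_rot
    if (!is.na(old_up) && fiber$torsion_active[up_bond]) {
      new_up <- local_twist_angle(fiber, up_bond)
      fiber$phi0[up_bond] <- wrap_angle(fiber$phi0[up_bond] +
                                          wrap_angle(new_up - old_up))
    }
    fiber$motor_turns <- fiber$motor_turns +
      motor$rotation_sign / motor$steps_per_rotation
  }
  fiber
}

cross3_r <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Place the moving nicks around the extruded loop
#'
#' For each arm the first bond outside the loop boundary loses its
#' torsional coupling (`torsion_active = FALSE`), letting supercoiling
#' that crosses the threaded bead swivel away freely, as if relaxed by
#' topoisomerase at the domain border. When a nick moves on, the abandoned
#' bond is re-activated with its torsional reference reset to the
#' instantaneous twist angle, so no stored torsion remains outside the
#' loop. Exactly two bonds are nicked while the ring is loaded; none when
#' it is not.
#'
#' @param fiber a `fiber_state`.
#' @param ring a `ring_state` (threaded beads define the loop).
#' @return list with `fiber` (updated) and `nicks` (integer vector of
#'   nicked bond indices, 1-based; empty if the ring is unloaded).
#' @export
update_nicks <- function(fiber, ring) {
  n <- nrow(fiber$pos)
  old <- which(!fiber$torsion_active)
  if (is.null(ring) || !ring$loaded || any(is.na(ring$threaded))) {
    for (b in old) {
      fiber$phi0[b] <- local_twist_angle(fiber, b)
      fiber$torsion_active[b] <- TRUE
    }
    return(list(fiber = fiber, nicks = integer(0)))
  }
  lb <- fiber$loading_bead
  arms <- arm_split(n, lb, ring$threaded)
  # + arm boundary bead c_plus: first bond outside the loop is the bond
  # leaving c_plus in the + direction, i.e. bond index c_plus
  nick_p <- arms$c_plus
  # - arm boundary bead c_minus: first bond outside is the bond arriving
  # at c_minus from the - direction, i.e. bond index c_minus - 1
  nick_m <- ((arms$c_minus - 2L) %% n) + 1L
  nicks <- sort(unique(c(nick_p, nick_m)))
  for (b in setdiff(old, nicks)) {
    fiber$phi0[b] <- local_twist_angle(fiber, b)
    fiber$torsion_active[b] <- TRUE
  }
  fiber$torsion_active[nicks] <- FALSE
  list(fiber = fiber, nicks = nicks)
}

# split the circle into the two arms of the loop containing the loading
# bead; returns boundary beads and arm lengths (in beads)
arm_split <- function(n, loading_bead, threaded) {
  dp <- (threaded - loading_bead) %% n
  if (dp[1] <= dp[2]) {
    c_plus <- threaded[1]; c_minus <- threaded[2]
    arm_p <- dp[1]; arm_m <- (n - dp[2]) %% n
  } else {
    c_plus <- threaded[2]; c_minus <- threaded[1]
    arm_p <- dp[2]; arm_m <- (n - dp[1]) %% n
  }
  list(c_plus = c_plus, c_minus = c_minus, arm_plus = arm_p,
       arm_minus = arm_m)
}
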