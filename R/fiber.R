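#' Parameters of the torsionally stiff chromatin fiber
#'
#' One bead corresponds to 10 nm of chromatin fiber carrying 400 bp of DNA,
#' so the default 150-bead circle represents a 60 kbp domain. Torsional
#' stiffness is carried by one periaxial virtual bead per backbone bead,
#' attached at distance `periaxial_offset` from the backbone axis and
#' interlocked with its neighbours by a harmonic twist potential.
#'
#' @param n_beads number of backbone beads (>= 3; the chain is closed).
#' @param bead_size bead diameter \eqn{\sigma_b} in simulation length units
#'   (1 unit = 10 nm = 400 bp).
#' @param bond_k harmonic bond stiffness (kT per sigma^2).
#' @param bond_r0 equilibrium bond length.
#' @param wca_epsilon strength of the purely repulsive (WCA) excluded
#'   volume, in kT.
#' @param bend_Kb bending stiffness of the Kratky-Porod angle potential
#'   \eqn{K_b (1 - \cos\theta)}; the default 5 gives a persistence length
#'   of about 50 nm.
#' @param torsion_C torsional interlock stiffness (kT per rad^2).
#' @param torsion_form `"cosine"` for the bounded form
#'   \eqn{C(1-\cos\Delta\phi)} (harmonic to second order, continuous
#'   torque across the wrap point, the default used in dynamics) or
#'   `"harmonic"` for the textbook \eqn{(C/2)\Delta\phi^2}.
#' @param periaxial_offset distance of the periaxial virtual bead from the
#'   backbone axis.
#' @param gamma_R reference drag of backbone and periaxial beads.
#' @param tether_k stiffness of the radial tether holding each periaxial
#'   bead at `periaxial_offset` from its backbone bead (the attachment is
#'   a stiff spring, not a rigid constraint; at the default the radial
#'   fluctuation is about 4 percent of `periaxial_offset`).
#' @param perp_k stiffness of the penalty keeping the periaxial offset
#'   perpendicular to the local chain axis.
#'
#' @return an object of class `fiber_params`.
#' @export
fiber_params <- function(n_beads = 150L, bead_size = 1.0, bond_k = 100,
                         bond_r0 = 1.0, wca_epsilon = 1.0, bend_Kb = 5,
                         torsion_C = 50, periaxial_offset = 0.5,
                         gamma_R = 1.0, tether_k = 600, perp_k = 100,
                         torsion_form = c("cosine", "harmonic")) {
  torsion_form <- match.arg(torsion_form)
  p <- list(n_beads = as.integer(n_beads), bead_size = bead_size,
            bond_k = bond_k, bond_r0 = bond_r0, wca_epsilon = wca_epsilon,
            bend_Kb = bend_Kb, torsion_C = torsion_C,
            periaxial_offset = periaxial_offset, gamma_R = gamma_R,
            torsion_form = torsion_form, tether_k = tether_k,
            perp_k = perp_k,
            bp_per_bead = 400, nm_per_bead = 10)
  class(p) <- "fiber_params"
  validate_fiber_params(p)
  p
}

validate_fiber_params <- function(p) {
  if (p$n_beads < 3L)
    stop("invalid fiber parameters: n_beads must be >= 3 (closed chain)",
         call. = FALSE)
  pos <- c(bead_size = p$bead_size, bond_k = p$bond_k, bond_r0 = p$bond_r0,
           torsion_C = p$torsion_C, periaxial_offset = p$periaxial_offset,
           gamma_R = p$gamma_R)
  if (any(pos <= 0))
    stop("invalid fiber parameters: ", paste(names(pos)[pos <= 0],
         collapse = ", "), " must be strictly positive", call. = FALSE)
  if (p$wca_epsilon < 0 || p$bend_Kb < 0)
    stop("invalid fiber parameters: wca_epsilon and bend_Kb must be >= 0",
         call. = FALSE)
  if (p$bp_per_bead != 400 || p$nm_per_bead != 10)
    stop("bp_per_bead = 400 and nm_per_bead = 10 are fixed conversion
constants", call. = FALSE)
  invisible(p)
}

n_bonds <- function(fiber) {
  if (fiber$closed) nrow(fiber$pos) else nrow(fiber$pos) - 1L
}

# flat parameter list handed to the compiled kernels
cpp_param_list <- function(fiber, ring_params = NULL, dt = 0.0025, kT = 1.0,
                           force_cap = -1) {
  p <- fiber$params
  out <- list(bond_k = p$bond_k, bond_r0 = p$bond_r0,
              torsion_form = p$torsion_form %||% "cosine",
              tether_k = p$tether_k %||% 600, perp_k = p$perp_k %||% 100,
              wca_epsilon = p$wca_epsilon, bead_size = p$bead_size,
              bend_Kb = p$bend_Kb, torsion_C = p$torsion_C,
              periaxial_offset = p$periaxial_offset, gamma_R = p$gamma_R,
              loading_bead = fiber$loading_bead - 1L, closed = fiber$closed,
              dt = dt, kT = kT, force_cap = force_cap)
  if (!is.null(ring_params)) {
    out$ring_bond_k <- ring_params$bond_k
    out$ring_bond_r0 <- ring_params$bond_r0
    out$ring_Kb <- ring_params$bend_Kb
    out$ring_excl_sigma <- ring_params$exclusion_vs_loading_bead
  }
  out
}

new_fiber_state <- function(pos, pax, params, loading_bead = 1L,
                            closed = TRUE) {
  n <- nrow(pos)
  nb <- if (closed) n else n - 1L
  f <- list(pos = pos, pax = pax,
            gamma_bb = rep(params$gamma_R, n),
            gamma_pax = rep(params$gamma_R, n),
            torsion_active = rep(TRUE, nb),
            phi0 = numeric(nb),
            loading_bead = as.integer(loading_bead),
            closed = closed, motor_turns = 0,
            params = params)
  class(f) <- "fiber_state"
  # torsionally relaxed reference: phi0 equals the as-built twist angles
  f$phi0 <- twist_angles(f)
  f
}

#' Build the circular chromatin fiber
#'
#' Backbone beads are placed on a planar circle of radius
#' \eqn{n r_0 / 2\pi}; periaxial beads sit at `periaxial_offset` along the
#' outward radial direction (perpendicular to the local tangent), which
#' makes the as-built fiber torsionally relaxed. All bonds are
#' torsion-active and every bead carries the reference drag `gamma_R`.
#'
#' @param params a [fiber_params()] object.
#' @param seed integer seed stored with the state (the construction itself
#'   is deterministic).
#' @param loading_bead index (1-based) of the motor/polymerase bead.
#' @return a `fiber_state`.
#' @export
build_circular_fiber <- function(params = fiber_params(), seed = 1L,
                                 loading_bead = 1L) {
  validate_fiber_params(params)
  n <- params$n_beads
  R <- n * params$bond_r0 / (2 * pi)
  theta <- 2 * pi * (seq_len(n) - 1) / n
  pos <- cbind(R * cos(theta), R * sin(theta), 0)
  radial <- cbind(cos(theta), sin(theta), 0)
  pax <- pos + params$periaxial_offset * radial
  f <- new_fiber_state(pos, pax, params, loading_bead, closed = TRUE)
  f$seed <- as.integer(seed)
  f$radius <- R
  f$loop_bp <- n * params$bp_per_bead
  f
}

#' Build a linear (open) fiber
#'
#' Open-chain variant used for control runs such as persistence-length
#' estimation, where the closure constraint of the circular fiber would
#' bias tangent correlations.
#'
#' @inheritParams build_circular_fiber
#' @export
build_linear_fiber <- function(params = fiber_params(n_beads = 60L),
                               seed = 1L, loading_bead = 1L) {
  validate_fiber_params(params)
  n <- params$n_beads
  pos <- cbind((seq_len(n) - 1) * params$bond_r0, 0, 0)
  pax <- pos
  pax[, 3] <- pax[, 3] + params$periaxial_offset
  f <- new_fiber_state(pos, pax, params, loading_bead, closed = FALSE)
  f$seed <- as.integer(seed)
  f
}

#' @export
print.fiber_state <- function(x, ...) {
  cat(sprintf("<fiber_state> %d beads (%s), %d kbp, %d torsion-active bonds\n",
              nrow(x$pos), if (x$closed) "closed" else "open",
              nrow(x$pos) * x$params$bp_per_bead / 1000,
              sum(x$torsion_active)))
  invisible(x)
}

#' Forces and potential energy of the current configuration
#'
#' Evaluates the sum of harmonic-bond, purely repulsive excluded-volume
#' (WCA, truncated and shifted at its minimum), bending and torsional
#' forces. Pair forces are equal and opposite, so all pair contributions
#' sum to zero. Torsion-inactive (nicked) bonds contribute no torque.
#'
#' @param fiber a `fiber_state`.
#' @param ring optional `ring_state` whose bonded/bending/excluded-volume
#'   terms are included (the ring has no torsional degree of freedom).
#' @return list with `energy` and force matrices `f_pos`, `f_pax`,
#'   `f_ring` (rows = beads, columns = x,y,z).
#' @export
compute_forces <- function(fiber, ring = NULL) {
  ring_pos <- if (is.null(ring)) matrix(0, 0, 3) else ring$pos
  cpp_forces(fiber$pos, fiber$pax, ring_pos,
             as.integer(fiber$torsion_active), fiber$phi0,
             cpp_param_list(fiber, ring_params = ring$params))
}

#' @rdname compute_forces
#' @export
potential_energy <- function(fiber, ring = NULL) {
  compute_forces(fiber, ring)$energy
}

#' Twist angles of all bonds
#'
#' For bond i the twist angle is the signed rotation, about the bond
#' direction, carrying the periaxial offset of bead i onto that of bead
#' i+1 (both projected perpendicular to the bond), in (-pi, pi]. Zero for
#' parallel-transported frames.
#'
#' @param fiber a `fiber_state`.
#' @return numeric vector of length `n_bonds(fiber)`; `NA` marks
#'   geometrically degenerate bonds.
#' @export
twist_angles <- function(fiber) {
  cpp_twist_angles(fiber$pos, fiber$pax, fiber$closed)
}

#' @param bond_index bond index (1-based; bond i joins beads i and i+1,
#'   with the last bond closing the chain).
#' @rdname twist_angles
#' @export
local_twist_angle <- function(fiber, bond_index) {
  nb <- n_bonds(fiber)
  if (bond_index < 1 || bond_index > nb)
    stop("bond_index out of range", call. = FALSE)
  phi <- twist_angles(fiber)[bond_index]
  if (is.na(phi))
    stop("degenerate geometry: periaxial offset parallel to the bond tangent",
         call. = FALSE)
  phi
}

wrap_angle <- function(x) {
  w <- x - 2 * pi * round(x / (2 * pi))
  w[w <= -pi] <- w[w <= -pi] + 2 * pi
  w
}

#' Torsional energy of the fiber
#'
#' Sum over torsion-active bonds of \eqn{(C/2)\,(\phi_i - \phi_{0,i})^2};
#' nicked bonds contribute zero.
#'
#' @param fiber a `fiber_state`.
#' @export
torsional_energy <- function(fiber) {
  phi <- twist_angles(fiber)
  act <- fiber$torsion_active & !is.na(phi)
  d <- wrap_angle(phi[act] - fiber$phi0[act])
  C <- fiber$params$torsion_C
  if (identical(fiber$params$torsion_form, "harmonic"))
    0.5 * C * sum(d^2)
  else
    C * sum(1 - cos(d))
}
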