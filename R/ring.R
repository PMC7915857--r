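#' Parameters of the cohesin ring
#'
#' The ring is a closed chain of `n_ring_beads` 10-nm beads sharing the
#' fiber's bond, bending and excluded-volume forms. Friction with the
#' chromatin fiber is imposed by raising the drag of the threaded fiber
#' bead(s) and their periaxial partners to `gamma_c`. The excluded volume
#' between ring beads and the loading bead is enlarged (default 3 sigma),
#' standing in for the polymerase + topoisomerase body that prevents the
#' pseudo-topologically threaded ring from sliding off backwards.
#'
#' @param n_ring_beads even number of ring beads (default 14, i.e. a ring
#'   of maximal extension about 50 nm whose threaded opening is in the
#'   10-20 nm range).
#' @param gamma_c drag imposed at the threaded fiber bead(s); studied
#'   values span 2 to 200 times `gamma_R`.
#' @param exclusion_vs_loading_bead WCA diameter between ring beads and
#'   the loading bead.
#' @param bond_k,bond_r0,bend_Kb mechanical constants of the ring chain;
#'   bending is the stiffness reinstalled when the folded loading
#'   conformation opens.
#' @param gamma_ring drag of the ring beads themselves.
#' @param single_threaded_bead apply `gamma_c` to only one threaded bead
#'   (one arm) instead of one bead per embraced arm.
#' @param gamma_R reference drag used for validation.
#' @return an object of class `ring_params`.
#' @export
ring_params <- function(n_ring_beads = 14L, gamma_c = 20,
                        exclusion_vs_loading_bead = 3.0, bond_k = 100,
                        bond_r0 = 1.0, bend_Kb = 20, gamma_ring = 1.0,
                        single_threaded_bead = FALSE, gamma_R = 1.0) {
  p <- list(n_ring_beads = as.integer(n_ring_beads), gamma_c = gamma_c,
            exclusion_vs_loading_bead = exclusion_vs_loading_bead,
            bond_k = bond_k, bond_r0 = bond_r0, bend_Kb = bend_Kb,
            gamma_ring = gamma_ring,
            single_threaded_bead = isTRUE(single_threaded_bead),
            gamma_R = gamma_R)
  class(p) <- "ring_params"
  if (p$n_ring_beads %% 2L != 0L)
    stop("n_ring_beads must be even (the loading protocol folds the ring ",
         "into two half-rings)", call. = FALSE)
  if (p$gamma_c < p$gamma_R)
    stop("gamma_c must be >= gamma_R", call. = FALSE)
  p
}

new_ring_state <- function(pos, params) {
  r <- list(pos = pos, params = params, loaded = FALSE,
            threaded = c(NA_integer_, NA_integer_))
  class(r) <- "ring_state"
  r
}

#' @export
print.ring_state <- function(x, ...) {
  cat(sprintf("<ring_state> %d beads, %s; threaded beads: %s\n",
              nrow(x$pos), if (x$loaded) "loaded" else "not loaded",
              paste(x$threaded, collapse = ", ")))
  invisible(x)
}

#' Load the cohesin ring pseudo-topologically
#'
#' Places the ring around the loading bead so that it embraces both fiber
#' arms with zero Gauss linking number (pseudo-topological entrapment):
#' the fiber is locally folded into a hairpin whose two strands pierce the
#' ring disc in opposite directions, the opened 14-bead ring is installed
#' with its bending stiffness active in the plane perpendicular to the
#' hairpin axis, and the enlarged ring/loading-bead excluded volume (3
#' sigma, while fiber-fiber excluded volume stays at 1 sigma) is switched
#' on. A short capped-force relaxation heals the constructed geometry
#' before the state is returned.
#'
#' @param fiber a freshly built circular `fiber_state`.
#' @param params a [ring_params()] object.
#' @param seed seed for the relaxation dynamics.
#' @param relax_steps number of capped-force relaxation steps.
#' @return list with elements `fiber` (deformed, relaxed fiber) and
#'   `ring` (loaded `ring_state`).
#' @export
load_ring <- function(fiber, params = ring_params(), seed = 1L,
                      relax_steps = 1500L, max_attempts = 5L) {
  if (!fiber$closed) stop("the ring loads on the circular fiber",
                          call. = FALSE)
  # the relaxation is stochastic; a loading attempt can occasionally fail
  # to keep both arms threaded, so retry with deterministically derived
  # relaxation seeds before giving up
  last <- NULL
  for (attempt in seq_len(max_attempts)) {
    res <- tryCatch(load_ring_once(fiber, params,
                                   seed + 7919L * (attempt - 1L),
                                   relax_steps),
                    error = function(e) e)
    if (!inherits(res, "error")) return(res)
    last <- res
  }
  stop(conditionMessage(last), call. = FALSE)
}

load_ring_once <- function(fiber, params, seed, relax_steps) {
  n <- nrow(fiber$pos)
  if (n < 12L)
    stop("fiber too small to fold a loading hairpin", call. = FALSE)
  lb <- fiber$loading_bead
  R <- n * fiber$params$bond_r0 / (2 * pi)

  # local frame at the loading bead: e_r = hairpin axis (outward radial),
  # e_t = chain tangent, e_z = circle normal
  theta0 <- 2 * pi * (lb - 1) / n
  e_r <- c(cos(theta0), sin(theta0), 0)
  e_t <- c(-sin(theta0), cos(theta0), 0)
  centre0 <- R * e_r

  # hairpin template: axial (along e_r, relative to the circle radius)
  # and lateral (along e_t) offsets for beads lb-4 .. lb+4
  axial <- c(-0.45, -0.15, -1.05, -2.10, -3.00, -2.10, -1.05, -0.15, -0.45)
  later <- c(-3.10, -1.40, -0.85, -0.50, 0.00, 0.50, 0.85, 1.40, 3.10)
  pos <- fiber$pos
  for (k in -4:4) {
    i <- ((lb - 1 + k) %% n) + 1L
    pos[i, ] <- centre0 + axial[k + 5] * e_r + later[k + 5] * e_t
  }
  # rebuild periaxial offsets perpendicular to the new local tangents and
  # reset the torsional reference so the deformed fiber starts relaxed
  fiber$pos <- pos
  fiber$pax <- rebuild_periaxial(pos, fiber$params$periaxial_offset,
                                 fiber$closed)
  fiber$phi0 <- twist_angles(fiber)

  # opened ring in the plane perpendicular to the hairpin axis, one bead
  # radius ahead of the tip so both strands pierce its disc
  m <- params$n_ring_beads
  r_ring <- m * params$bond_r0 / (2 * pi)
  ring_centre <- centre0 - 1.00 * e_r
  ang <- 2 * pi * (seq_len(m) - 1) / m
  e_z <- c(0, 0, 1)
  ring_pos <- t(vapply(ang, function(a)
    ring_centre + r_ring * (cos(a) * e_t + sin(a) * e_z), numeric(3)))
  ring <- new_ring_state(ring_pos, params)

  # stage one: heal the constructed backbone geometry with the torsional
  # springs off and a reduced time step (the initial bond stretches would
  # otherwise pump twist waves into the fiber)
  fiber_heal <- fiber
  fiber_heal$params$torsion_C <- 1e-12
  healed <- integrate_dynamics(fiber_heal, ring, motor = NULL,
                               config = sim_config(n_steps = 4L * relax_steps,
                                                   dt = 5e-4, seed = seed,
                                                   frame_interval = 4L * relax_steps,
                                                   gamma_c = params$gamma_c,
                                                   motor_enabled = FALSE),
                               nicks_on = FALSE, friction_on = FALSE,
                               cap_steps = 4L * relax_steps)
  fiber$pos <- healed$fiber_final$pos
  ring <- healed$ring_final
  fiber$pax <- rebuild_periaxial(fiber$pos, fiber$params$periaxial_offset,
                                 fiber$closed)
  fiber$phi0 <- twist_angles(fiber)
  # stage two: short full-model equilibration from the torsionally relaxed
  # healed state
  relaxed <- integrate_dynamics(fiber, ring, motor = NULL,
                                config = sim_config(n_steps = relax_steps,
                                                    dt = 5e-4, seed = seed + 1L,
                                                    frame_interval = relax_steps,
                                                    gamma_c = params$gamma_c,
                                                    motor_enabled = FALSE),
                                nicks_on = FALSE, friction_on = FALSE,
                                cap_steps = relax_steps)
  fiber <- relaxed$fiber_final
  ring <- relaxed$ring_final
  # torsionally relaxed start after loading
  fiber$phi0 <- twist_angles(fiber)

  thr <- threaded_beads(fiber, ring, on_escape = "na")
  if (any(is.na(thr)))
    stop("ring loading failed: fewer than two arms threaded after ",
         "relaxation; retry with a different seed", call. = FALSE)
  lk <- linking_number(fiber$pos, ring$pos)
  if (abs(lk) > 0.5)
    stop(sprintf("ring loading failed: ring-fiber Gauss linking number %.2f
(expected 0 for pseudo-topological binding); retry with a different seed",
                 lk), call. = FALSE)
  # stability probe: a marginally engaged ring can swing off over the
  # hairpin tip within a few time units; accept the loaded state only if
  # it stays threaded with zero linking through a short unforced run
  probe <- integrate_dynamics(fiber, ring, motor = NULL,
                              config = sim_config(n_steps = 30000L,
                                                  dt = 5e-4,
                                                  seed = seed + 13L,
                                                  frame_interval = 30000L,
                                                  gamma_c = params$gamma_c,
                                                  motor_enabled = FALSE),
                              nicks_on = TRUE, friction_on = TRUE)
  pthr <- threaded_beads(probe$fiber_final, probe$ring_final,
                         on_escape = "na")
  if (any(is.na(pthr)) ||
      abs(linking_number(probe$fiber_final$pos, probe$ring_final$pos)) > 0.3)
    stop("ring loading failed: the ring did not stay threaded through ",
         "the stability probe; retry with a different seed", call. = FALSE)
  ring$loaded <- TRUE
  ring$threaded <- thr
  list(fiber = fiber, ring = ring)
}

rebuild_periaxial <- function(pos, r_p, closed) {
  n <- nrow(pos)
  pax <- pos
  for (i in seq_len(n)) {
    ip <- if (closed) (i %% n) + 1L else min(i + 1L, n)
    im <- if (closed) ((i - 2L) %% n) + 1L else max(i - 1L, 1L)
    t <- pos[ip, ] - pos[im, ]
    t <- t / sqrt(sum(t^2))
    u <- c(0, 0, 1)
    u <- u - sum(u * t) * t
    if (sqrt(sum(u^2)) < 1e-6) {
      u <- c(1, 0, 0)
      u <- u - sum(u * t) * t
    }
    pax[i, ] <- pos[i, ] + r_p * u / sqrt(sum(u^2))
  }
  pax
}

#' Identify the threaded fiber beads
#'
#' For each embraced arm, the fiber bead closest to the ring's best-fit
#' plane among beads lying inside the ring radius. Arms are told apart by
#' the sign of the local chain direction projected on the ring normal;
#' ties on plane distance break to the lower bead index. The two indices
#' define the loop boundary x_c on each arm.
#'
#' @param fiber a `fiber_state`.
#' @param ring a `ring_state`.
#' @param on_escape `"error"` to signal an `escaped_ring` condition when
#'   fewer than two arms pierce the ring, `"na"` to return `NA` indices.
#' @return integer vector of two 1-based fiber bead indices.
#' @export
threaded_beads <- function(fiber, ring, on_escape = c("error", "na")) {
  on_escape <- match.arg(on_escape)
  idx <- cpp_threaded_beads(fiber$pos, ring$pos, fiber$closed,
                            2.5 * fiber$params$bead_size)
  idx[idx < 0] <- NA_integer_
  idx <- idx + 1L
  if (any(is.na(idx)) && on_escape == "error") {
    cond <- structure(class = c("escaped_ring", "error", "condition"),
                      list(message = "escaped ring: fewer than two arms threaded",
                           call = sys.call()))
    stop(cond)
  }
  idx
}

#' Impose the cohesin friction on the threaded beads
#'
#' Sets the drag of each threaded backbone bead and of its periaxial
#' partner to `gamma_c`, restoring every previously modified bead that is
#' no longer threaded to `gamma_R`. Idempotent.
#'
#' @param fiber a `fiber_state`.
#' @param ring a `ring_state` with known threaded beads.
#' @param params a [ring_params()] object.
#' @return the updated `fiber_state`.
#' @export
apply_ring_friction <- function(fiber, ring, params = ring$params) {
  gR <- fiber$params$gamma_R
  fiber$gamma_bb[] <- gR
  fiber$gamma_pax[] <- gR
  thr <- ring$threaded
  if (params$single_threaded_bead) thr <- thr[1]
  thr <- thr[!is.na(thr)]
  fiber$gamma_bb[thr] <- params$gamma_c
  fiber$gamma_pax[thr] <- params$gamma_c
  fiber
}
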