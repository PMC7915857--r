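#' Parameters of the continuum moving-boundary model
#'
#' Supercoiling injected at the transcription site (x = 0) diffuses along
#' the extruded loop by Fick's second law with diffusivity `D_sigma`, and
#' escapes through the semipermeable boundary held by the cohesin at
#' `x = x_c`, where the local supercoiling diffusivity is reduced to
#' \eqn{D_c = D_\sigma \gamma_R / \gamma_c}. The boundary itself moves
#' down the gradient of the supercoiling energy by a noiseless overdamped
#' Langevin equation, \eqn{dx_c/d\tau = -(1/\gamma_c)\,\partial u/\partial
#' x_c}. Fiber entering the loop enters torsionally relaxed.
#'
#' The solver state is the linear linking-number density (turns per
#' bead); total loop linking number is its integral over the loop.
#'
#' @param D_sigma supercoiling diffusivity, beads^2 per time unit (fitted
#'   value 1.6).
#' @param K supercoiling energy constant (fitted 3.4e3; the per-arm
#'   convention halves it).
#' @param gamma_c ring-fiber friction (boundary drag).
#' @param sigma_dot_P source rate at x = 0, turns per time unit (1/90 =
#'   10 rotations per second at the 240x-water calibration).
#' @param use_extended_energy add the loop-stiffness and entropic-cost
#'   terms \eqn{8 l_p / x_c^2 + c \log x_c} to the energy.
#' @param l_p persistence length in beads (for the extended term).
#' @param c entropic-cost coefficient (fitted 0.03).
#' @param Lk0_per_bead relaxed turns per bead (40), used to express loop
#'   supercoiling density.
#' @param domain_length loop size at completion, beads.
#' @param x0 initial loop size (a just-loaded ring embraces about 2
#'   beads).
#' @param dtau solver time step; must satisfy the CFL bound
#'   `D_sigma * dtau < 0.5` on the unit-bead grid.
#' @param energy_form `"per_length"` for \eqn{u = K \Delta Lk^2 / x_c}
#'   (an energy that decreases when relaxed fiber dilutes the loop, so a
#'   constant-\eqn{\Delta Lk} loop still pushes the boundary), or
#'   `"plain"` for the bare quadratic \eqn{u = K \Delta Lk^2}.
#' @param rotation_sign sign of the injected supercoiling.
#' @return an object of class `continuum_params`.
#' @export
continuum_params <- function(D_sigma = 1.6, K = 3.4e3, gamma_c = 200,
                             sigma_dot_P = 1 / 90,
                             use_extended_energy = FALSE, l_p = 5,
                             c = 0.03, Lk0_per_bead = 40,
                             domain_length = 150, x0 = 2, dtau = 0.01,
                             energy_form = c("per_length", "plain"),
                             rotation_sign = -1) {
  energy_form <- match.arg(energy_form)
  if (D_sigma <= 0 || K <= 0 || gamma_c <= 0)
    stop("D_sigma, K and gamma_c must be positive", call. = FALSE)
  p <- list(D_sigma = D_sigma, K = K, gamma_c = gamma_c,
            sigma_dot_P = sigma_dot_P,
            use_extended_energy = isTRUE(use_extended_energy), l_p = l_p,
            c = c, Lk0_per_bead = Lk0_per_bead,
            domain_length = domain_length, x0 = x0, dtau = dtau,
            energy_form = energy_form, rotation_sign = rotation_sign)
  p$D_c <- D_sigma / gamma_c  # boundary diffusivity (gamma_R = 1)
  class(p) <- "continuum_params"
  p
}

#' Supercoiling energy of the loop
#'
#' \eqn{u = K\,\Delta Lk^2 / x_c} (default per-length form) or
#' \eqn{u = K\,\Delta Lk^2} (`"plain"`), optionally extended by the
#' loop-stiffness penalty and entropic looping cost
#' \eqn{8 l_p/x_c^2 + c\,\log x_c}.
#'
#' @param delta_Lk loop linking number (turns).
#' @param x_c loop size (beads, > 0).
#' @param params a [continuum_params()] object.
#' @export
supercoiling_energy <- function(delta_Lk, x_c, params = continuum_params()) {
  if (any(x_c <= 0)) stop("x_c must be positive", call. = FALSE)
  u <- if (params$energy_form == "per_length")
    params$K * delta_Lk^2 / x_c else params$K * delta_Lk^2
  if (params$use_extended_energy)
    u <- u + 8 * params$l_p / x_c^2 + params$c * log(x_c)
  u
}

# -du/dx_c at fixed dLk
boundary_force <- function(delta_Lk, x_c, params) {
  f <- if (params$energy_form == "per_length")
    params$K * delta_Lk^2 / x_c^2 else 0
  if (params$use_extended_energy)
    f <- f + 16 * params$l_p / x_c^3 - params$c / x_c
  f
}

#' Solve the moving-boundary supercoiling model
#'
#' Explicit finite differences on a unit-bead grid spanning the current
#' loop: interior diffusion with `D_sigma`, the source flux at x = 0,
#' the leak flux \eqn{J = D_c\,\sigma(x_c)/\Delta x} through the
#' semipermeable boundary (the exterior is absorbing: the moving nicks
#' relax everything outside the loop), and boundary motion down the
#' energy gradient. Cells entered by the boundary start torsionally
#' relaxed. Integration stops when the loop spans `domain_length` (or at
#' `t_end`).
#'
#' @param params a [continuum_params()] object.
#' @param t_end optional time horizon (time units).
#' @param record_interval spacing of recorded time points.
#' @param initial_profile optional starting linking-density profile
#'   (turns per bead, one cell per bead); the boundary starts at its
#'   length. Used for diffusion-limit checks.
#' @return object of class `continuum_solution`: a `series` data frame
#'   (tau, x_c, dLk), the final density profile, injected and leaked
#'   turns, the completion time and the worst linking-number balance
#'   error of the run.
#' @export
continuum_solve <- function(params = continuum_params(), t_end = Inf,
                            record_interval = 5, initial_profile = NULL) {
  if (params$D_sigma * params$dtau >= 0.5)
    stop("stability error: D_sigma * dtau must be < 0.5 (CFL bound on the ",
         "unit-bead grid)", call. = FALSE)
  dtau <- params$dtau
  P <- abs(params$sigma_dot_P)
  L <- params$domain_length
  Dc <- params$D_c
  D <- params$D_sigma
  xc <- params$x0
  lam <- numeric(max(1L, floor(xc)))   # |linking| density, turns/bead
  if (!is.null(initial_profile)) {
    lam <- abs(initial_profile)
    xc <- max(xc, length(lam))
  }
  inj <- sum(lam); leak <- 0; tau <- 0
  rec_t <- numeric(0); rec_x <- numeric(0); rec_l <- numeric(0)
  next_rec <- 0
  max_balance <- 0
  repeat {
    if (tau >= next_rec || xc >= L || tau >= t_end) {
      rec_t <- c(rec_t, tau); rec_x <- c(rec_x, xc)
      rec_l <- c(rec_l, params$rotation_sign * sum(lam))
      next_rec <- next_rec + record_interval
      max_balance <- max(max_balance, abs(sum(lam) - (inj - leak)))
    }
    if (xc >= L || tau >= t_end) break
    n <- length(lam)
    if (n > 1) {
      flux <- D * diff(lam)
      dl <- numeric(n)
      dl[1] <- flux[1]
      if (n > 2) dl[2:(n - 1)] <- flux[2:(n - 1)] - flux[1:(n - 2)]
      dl[n] <- -flux[n - 1]
      lam <- lam + dtau * dl
    }
    lam[1] <- lam[1] + dtau * P
    inj <- inj + dtau * P
    J <- Dc * lam[n]
    lam[n] <- lam[n] - dtau * J
    leak <- leak + dtau * J
    dLk <- sum(lam)
    xc_new <- xc + dtau * boundary_force(dLk, xc, params) / params$gamma_c
    if (xc_new < xc && xc_new < params$x0)
      warning("model-degenerate: boundary regressed below its initial position")
    xc <- xc_new
    while (floor(xc) > length(lam) && length(lam) < L)
      lam <- c(lam, 0)  # dilution: new fiber enters relaxed
    tau <- tau + dtau
  }
  structure(list(series = data.frame(tau = rec_t, x_c = rec_x, dLk = rec_l),
                 profile = params$rotation_sign * lam,
                 injected = inj, leaked = leak,
                 final_dLk = params$rotation_sign * sum(lam),
                 completion_tau = if (xc >= L) tau else NA_real_,
                 max_balance_error = max_balance,
                 params = params),
            class = "continuum_solution")
}

#' @export
print.continuum_solution <- function(x, ...) {
  cat(sprintf(paste0("<continuum_solution> gamma_c=%g: x_c %.1f beads at tau=",
                     "%.0f, dLk=%.2f turns (injected %.1f, leaked %.1f)\n"),
              x$params$gamma_c, x$series$x_c[nrow(x$series)],
              x$series$tau[nrow(x$series)], x$final_dLk, x$injected,
              x$leaked))
  invisible(x)
}

#' Fraction of injected rotations relaxed away
#'
#' `100 * (1 - |final loop linking number| / injected rotations)`: the
#' percentage of motor rotations not retained in the loop at the end of
#' the solve.
#'
#' @param solution a `continuum_solution`.
#' @return percentage.
#' @export
relaxed_fraction <- function(solution) {
  if (solution$injected <= 0)
    stop("undefined: no rotations injected", call. = FALSE)
  100 * (1 - abs(solution$final_dLk) / solution$injected)
}

#' Extrusion rate implied by a continuum solution
#'
#' Domain length times 400 bp per bead divided by the completion time
#' converted to seconds.
#'
#' @param solution a `continuum_solution` that ran to completion.
#' @param seconds_per_tu calibration, see [seconds_per_time_unit()].
#' @return kilobase pairs per second.
#' @export
continuum_rate <- function(solution,
                           seconds_per_tu = seconds_per_time_unit()) {
  if (is.na(solution$completion_tau))
    stop("solution did not run to completion", call. = FALSE)
  kbp <- solution$params$domain_length * 400 / 1000
  kbp / (solution$completion_tau * seconds_per_tu)
}

#' Fit (D_sigma, K) to loop-size and linking-number trajectories
#'
#' Concatenated least squares: for candidate parameters the model is
#' solved once and its \eqn{x_c(\tau)} and \eqn{\Delta Lk(\tau)} are
#' compared against all supplied trajectories simultaneously, each series
#' normalized by its spread so loop size and linking number carry
#' comparable weight. Optimization is Nelder-Mead on log-parameters.
#'
#' @param trajectories a data frame or list of data frames with columns
#'   `tau` (or `time`), `l` (loop size, beads) and `dLk` (turns).
#' @param gamma_c friction setting shared by the trajectories.
#' @param params template [continuum_params()] (domain length, source
#'   rate, energy form...); `D_sigma` and `K` act as starting values.
#' @param fit_c also fit the entropic coefficient `c` (extended energy).
#' @return object of class `continuum_fit`: `estimates` (per two fibers),
#'   `per_arm` (halved convention: the 1-D model lumps the two fiber
#'   arms passing through one ring), `residual`, `n_trajectories`,
#'   `convergence`.
#' @export
continuum_fit <- function(trajectories, gamma_c,
                          params = continuum_params(gamma_c = gamma_c),
                          fit_c = FALSE) {
  if (is.data.frame(trajectories)) trajectories <- list(trajectories)
  if (length(trajectories) < 1) stop("need at least one trajectory",
                                     call. = FALSE)
  trajectories <- lapply(trajectories, function(d) {
    if (!"tau" %in% names(d) && "time" %in% names(d)) d$tau <- d$time
    stopifnot(all(c("tau", "l", "dLk") %in% names(d)))
    d[!is.na(d$l) & !is.na(d$dLk), c("tau", "l", "dLk")]
  })
  params$gamma_c <- gamma_c
  params$D_c <- params$D_sigma / gamma_c
  t_max <- max(vapply(trajectories, function(d) max(d$tau), numeric(1)))
  scl <- lapply(trajectories, function(d)
    c(l = max(sd(d$l), 1e-6), dLk = max(sd(d$dLk), 1e-6)))

  objective <- function(theta) {
    p <- params
    p$D_sigma <- exp(theta[1])
    p$K <- exp(theta[2])
    if (fit_c) {
      p$c <- exp(theta[3])
      p$use_extended_energy <- TRUE
    }
    p$D_c <- p$D_sigma / p$gamma_c
    if (p$D_sigma * p$dtau >= 0.5) p$dtau <- 0.4 / p$D_sigma
    sol <- try(continuum_solve(p, t_end = t_max * 1.05,
                               record_interval = max(t_max / 200, p$dtau)),
               silent = TRUE)
    if (inherits(sol, "try-error")) return(1e10)
    s <- sol$series
    sse <- 0
    for (i in seq_along(trajectories)) {
      d <- trajectories[[i]]
      ml <- stats::approx(s$tau, s$x_c, xout = d$tau, rule = 2)$y
      mk <- stats::approx(s$tau, s$dLk, xout = d$tau, rule = 2)$y
      sse <- sse + sum(((d$l - ml) / scl[[i]]["l"])^2) +
        sum(((d$dLk - mk) / scl[[i]]["dLk"])^2)
    }
    sse
  }
  theta0 <- log(c(params$D_sigma, params$K, if (fit_c) max(params$c, 1e-4)))
  opt <- optim(theta0, objective, method = "Nelder-Mead",
               control = list(maxit = 200, reltol = 1e-5))
  est <- c(D_sigma = exp(opt$par[1]), K = exp(opt$par[2]),
           if (fit_c) c(c = exp(opt$par[3])))
  if (opt$convergence != 0 && opt$value > 1e9)
    stop("fit error: optimizer failed to converge; residual ", opt$value,
         call. = FALSE)
  structure(list(estimates = est,
                 per_arm = est / c(2, 2, if (fit_c) 1),
                 residual = opt$value,
                 n_trajectories = length(trajectories),
                 convergence = opt$convergence, gamma_c = gamma_c),
            class = "continuum_fit")
}

#' @export
print.continuum_fit <- function(x, ...) {
  cat(sprintf("<continuum_fit> gamma_c=%g over %d trajectories: %s (residual %.3g)\n",
              x$gamma_c, x$n_trajectories,
              paste(names(x$estimates), signif(x$estimates, 4), sep = "=",
                    collapse = ", "), x$residual))
  invisible(x)
}

#' Synthetic continuum trajectories
#'
#' Generates loop-size and linking-number series from a model solve with
#' known parameters plus multiplicative Gaussian noise; used to exercise
#' parameter recovery.
#'
#' @param params a [continuum_params()] object (the ground truth).
#' @param n_traj number of trajectories.
#' @param noise_sd relative noise level.
#' @param n_points time points per trajectory.
#' @param seed RNG seed.
#' @return list of data frames with columns `tau`, `l`, `dLk`.
#' @export
synthetic_continuum_trajectories <- function(params = continuum_params(),
                                             n_traj = 3, noise_sd = 0.05,
                                             n_points = 60, seed = 1L) {
  sol <- continuum_solve(params, record_interval = params$dtau * 20)
  s <- sol$series
  taus <- seq(min(s$tau), max(s$tau), length.out = n_points)
  base_l <- stats::approx(s$tau, s$x_c, xout = taus)$y
  base_k <- stats::approx(s$tau, s$dLk, xout = taus)$y
  set.seed(seed)
  lapply(seq_len(n_traj), function(i)
    data.frame(tau = taus,
               l = base_l * (1 + rnorm(n_points, 0, noise_sd)),
               dLk = base_k * (1 + rnorm(n_points, 0, noise_sd))))
}
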