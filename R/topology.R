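#' Writhe of a space curve
#'
#' Discretized double Gauss integral: for every pair of non-adjacent
#' segments the exact solid-angle contribution of the two straight
#' segments is accumulated. For closed curves the result converges to an
#' integer-valued quantity as the discretization refines; planar curves
#' have writhe zero and mirror images have opposite sign.
#'
#' @param points numeric matrix (n x 3) of curve vertices, n >= 4.
#' @param closed treat the last vertex as bonded to the first.
#' @return writhe in turns.
#' @export
writhe <- function(points, closed = TRUE) {
  points <- as.matrix(points)
  if (nrow(points) < 4) stop("need at least 4 points", call. = FALSE)
  seg <- diff(rbind(points, if (closed) points[1, , drop = FALSE]))
  if (any(rowSums(seg^2) < 1e-20))
    stop("numerical-geometry error: coincident consecutive points",
         call. = FALSE)
  cpp_writhe(points, closed)
}

#' Gauss linking number of two closed curves
#'
#' @param curve_a,curve_b numeric matrices (n x 3) of vertices of two
#'   closed polygonal curves.
#' @return the (near-integer) Gauss linking number.
#' @export
linking_number <- function(curve_a, curve_b) {
  cpp_linking_number(as.matrix(curve_a), as.matrix(curve_b))
}

#' Excess twist of a bead range
#'
#' Sum of the local twist angles, relative to the torsionally relaxed
#' reference, over the bonds joining consecutive beads of `region`,
#' divided by 2 pi.
#'
#' @param fiber a `fiber_state`.
#' @param region integer vector of consecutive bead indices (a path along
#'   the chain); bonds between consecutive listed beads are summed.
#'   Defaults to the whole chain.
#' @return twist in turns.
#' @export
twist <- function(fiber, region = NULL) {
  n <- nrow(fiber$pos)
  phi <- twist_angles(fiber)
  if (is.null(region)) {
    act <- !is.na(phi)
    return(sum(wrap_angle(phi[act] - fiber$phi0[act])) / (2 * pi))
  }
  bonds <- path_bonds(region, n, fiber$closed)
  d <- wrap_angle(phi[bonds] - fiber$phi0[bonds])
  sum(d, na.rm = TRUE) / (2 * pi)
}

# bond indices joining consecutive beads of a path (1-based; bond i joins
# beads i and i+1 modulo n)
path_bonds <- function(region, n, closed) {
  a <- region[-length(region)]
  b <- region[-1]
  fw <- (b - a) %% n == 1
  bonds <- ifelse(fw, a, b)
  if (!closed && any(bonds >= n)) stop("region crosses the open end",
                                       call. = FALSE)
  bonds
}

#' Loop size and arm sizes
#'
#' Arm sizes are the number of beads between the loading bead and each
#' threaded bead measured along the loop; the loop size is their sum.
#'
#' @param fiber a `fiber_state`.
#' @param ring a loaded `ring_state`.
#' @return list with `loop_size`, `arm_sizes` (a length-2 vector, + arm
#'   first) and the boundary beads `c_plus`, `c_minus`.
#' @export
loop_metrics <- function(fiber, ring) {
  if (any(is.na(ring$threaded)))
    stop("escaped ring: loop undefined", call. = FALSE)
  a <- arm_split(nrow(fiber$pos), fiber$loading_bead, ring$threaded)
  list(loop_size = a$arm_plus + a$arm_minus,
       arm_sizes = c(a$arm_plus, a$arm_minus),
       c_plus = a$c_plus, c_minus = a$c_minus)
}

#' Supercoiling density
#'
#' \eqn{\sigma = \Delta Lk / (Lk_0 \times \mathrm{beads})} with the
#' relaxed linking number fixed at `Lk0_per_bead` = 40 turns per 400-bp
#' bead.
#'
#' @param delta_Lk linking-number change in turns.
#' @param region_beads number of beads in the region (>= 1).
#' @param Lk0_per_bead relaxed turns per bead.
#' @export
supercoil_density <- function(delta_Lk, region_beads, Lk0_per_bead = 40) {
  if (any(region_beads < 1)) stop("zero-length region", call. = FALSE)
  delta_Lk / (Lk0_per_bead * region_beads)
}

#' Per-frame topology metrics of an extrusion trajectory
#'
#' For every recorded frame: loop size and arm sizes, excess twist and
#' writhe of the extruded loop (open sub-chain from one threaded bead
#' through the loading bead to the other; the open-curve Gauss integral is
#' used directly, without artificial closure), their sum
#' \eqn{\Delta Lk = \Delta Tw + \Delta Wr}, the supercoiling density of
#' the loop, and the cumulative motor rotation.
#'
#' @param traj an `sc_trajectory` from a run with a loaded ring.
#' @return data frame with columns `time`, `l`, `arm1`, `arm2`, `dTw`,
#'   `dWr`, `dLk`, `sigma`, `motor_turns`.
#' @export
trajectory_metrics <- function(traj) {
  nf <- n_frames(traj)
  n <- traj$n_beads
  lb <- traj$loading_bead
  out <- data.frame(time = traj$times, l = NA_real_, arm1 = NA_real_,
                    arm2 = NA_real_, dTw = NA_real_, dWr = NA_real_,
                    dLk = NA_real_, sigma = NA_real_,
                    motor_turns = traj$motor_turns)
  for (k in seq_len(nf)) {
    cp <- traj$threaded_plus[k]
    cm <- traj$threaded_minus[k]
    if (is.na(cp) || is.na(cm)) next
    a <- arm_split(n, lb, c(cp, cm))
    out$arm1[k] <- a$arm_plus
    out$arm2[k] <- a$arm_minus
    out$l[k] <- a$arm_plus + a$arm_minus
    # ordered loop path c_minus -> loading bead -> c_plus
    len <- a$arm_plus + a$arm_minus
    beads <- ((a$c_minus - 1L + 0:len) %% n) + 1L
    pos <- frame_pos(traj, k)
    pax <- frame_pax(traj, k)
    phi <- cpp_twist_angles(pos, pax, traj$closed)
    phi0 <- traj$frames_phi0[, k]
    bonds <- path_bonds(beads, n, traj$closed)
    dtw <- sum(wrap_angle(phi[bonds] - phi0[bonds]), na.rm = TRUE) / (2 * pi)
    dwr <- if (len >= 3) cpp_writhe(pos[beads, ], FALSE) else 0
    out$dTw[k] <- dtw
    out$dWr[k] <- dwr
    out$dLk[k] <- dtw + dwr
    out$sigma[k] <- supercoil_density(dtw + dwr, max(len, 1))
  }
  out
}

#' Loop extrusion rate
#'
#' Least-squares slope of the loop size over time, converted to kilobase
#' pairs per second with 400 bp per bead and the Stokes'-time calibration.
#'
#' @param traj an `sc_trajectory` with metrics, a metrics data frame, or a
#'   list of either (averaged over runs).
#' @param seconds_per_tu seconds per simulation time unit, see
#'   [seconds_per_time_unit()].
#' @return for a single run, a list with `rate_kbps` and
#'   `slope_beads_per_tu`; for a list of runs, additionally `per_run`
#'   rates and their mean.
#' @export
extrusion_rate <- function(traj, seconds_per_tu = seconds_per_time_unit()) {
  if (is.list(traj) && !inherits(traj, "sc_trajectory") &&
      !is.data.frame(traj)) {
    per <- vapply(traj, function(x)
      extrusion_rate(x, seconds_per_tu)$rate_kbps, numeric(1))
    return(list(rate_kbps = mean(per), per_run = per))
  }
  m <- if (is.data.frame(traj)) traj else
    if (!is.null(traj$metrics)) traj$metrics else trajectory_metrics(traj)
  m <- m[!is.na(m$l), ]
  if (nrow(m) < 2) stop("need at least two frames", call. = FALSE)
  if (stats::var(m$l) == 0 || stats::var(m$time) == 0) {
    warning("constant loop size; rate is zero")
    return(list(rate_kbps = 0, slope_beads_per_tu = 0))
  }
  slope <- unname(coef(lm(l ~ time, data = m))[2])
  rate_bp_s <- slope * 400 / seconds_per_tu
  list(rate_kbps = rate_bp_s / 1000, slope_beads_per_tu = slope)
}

#' Contact map from one or more trajectories
#'
#' Frequency with which each bead pair is found within `cutoff`, averaged
#' over the frames of each run and then over runs. Data acquisition for a
#' run automatically stops where its trajectory stopped (ring escape or
#' completion).
#'
#' @param trajectories an `sc_trajectory` or a list of them (all sharing
#'   `n_beads`).
#' @param cutoff contact distance in bead diameters.
#' @return object of class `contact_map`: a symmetric matrix with unit
#'   diagonal and entries between 0 and 1, plus counts of frames and runs.
#' @export
contact_map <- function(trajectories, cutoff = 2.5) {
  if (inherits(trajectories, "sc_trajectory"))
    trajectories <- list(trajectories)
  if (length(trajectories) == 0) stop("empty trajectory list", call. = FALSE)
  nb <- unique(vapply(trajectories, function(t) t$n_beads, numeric(1)))
  if (length(nb) != 1) stop("trajectories disagree on n_beads", call. = FALSE)
  total <- matrix(0, nb, nb)
  nfr <- 0L
  for (traj in trajectories) {
    acc <- matrix(0, nb, nb)
    for (k in seq_len(n_frames(traj)))
      cpp_accumulate_contacts(frame_pos(traj, k), cutoff, acc)
    total <- total + acc / n_frames(traj)
    nfr <- nfr + n_frames(traj)
  }
  m <- total / length(trajectories)
  structure(list(matrix = m, cutoff = cutoff, n_frames = nfr,
                 n_runs = length(trajectories)), class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> %d x %d beads, cutoff %.2f, %d frames / %d runs\n",
              nrow(x$matrix), ncol(x$matrix), x$cutoff, x$n_frames, x$n_runs))
  invisible(x)
}

#' Persistence length from tangent-tangent correlations
#'
#' Fits \eqn{\langle t(s) \cdot t(s+k) \rangle = e^{-k/l_p}} through the
#' origin over short contour separations `1..max_lag`, averaging over
#' frames (after discarding an equilibration fraction) and positions, and
#' converts with 10 nm per bead. Only short separations enter the fit
#' because excluded volume makes longer-range correlations of a
#' self-avoiding chain decay slower than exponentially (swelling); the
#' persistence length is the local decay constant. Intended for a free,
#' motor-less control run; a non-decaying correlation (e.g. a rigid ring,
#' or a run too short to decorrelate) raises a fit-quality error.
#'
#' @param traj an `sc_trajectory` of a free fiber.
#' @param max_lag largest contour separation (beads) entering the fit.
#' @param burn_in fraction of initial frames discarded.
#' @param edge beads trimmed from each end of an open chain.
#' @return list with `lp_nm`, `lp_beads` and the correlation table.
#' @export
persistence_length <- function(traj, max_lag = 2L, burn_in = 0.5,
                               edge = 3L) {
  nf <- n_frames(traj)
  use <- seq_len(nf) > max(1, floor(burn_in * nf))
  n <- traj$n_beads
  corr <- numeric(max_lag)
  cnt <- numeric(max_lag)
  for (k in which(use)) {
    pos <- frame_pos(traj, k)
    tg <- diff(pos)
    tg <- tg / sqrt(rowSums(tg^2))
    nt <- nrow(tg)
    lo <- if (traj$closed) 1L else 1L + edge
    hi <- if (traj$closed) nt else nt - edge
    for (lag in seq_len(max_lag)) {
      if (traj$closed) {
        i <- lo:hi
        j <- ((i - 1L + lag) %% nt) + 1L
      } else {
        i <- lo:(hi - lag)
        if (length(i) < 4) next
        j <- i + lag
      }
      corr[lag] <- corr[lag] + sum(rowSums(tg[i, , drop = FALSE] *
                                             tg[j, , drop = FALSE]))
      cnt[lag] <- cnt[lag] + length(i)
    }
  }
  corr <- corr / pmax(cnt, 1)
  ok <- corr > 0.05
  if (sum(ok) < 2 || corr[1] > 0.995)
    stop("fit-quality error: tangent correlation does not decay",
         call. = FALSE)
  lag <- seq_len(max_lag)[ok]
  fit <- lm(log(corr[ok]) ~ 0 + lag)
  slope <- unname(coef(fit)[1])
  if (slope >= 0)
    stop("fit-quality error: non-decaying tangent correlation",
         call. = FALSE)
  lp_beads <- -1 / slope
  list(lp_nm = lp_beads * traj$params$nm_per_bead, lp_beads = lp_beads,
       correlation = data.frame(lag = seq_len(max_lag), corr = corr))
}
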