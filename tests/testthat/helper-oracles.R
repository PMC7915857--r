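# Independent oracles used across the suite.

# central-difference gradient of the potential energy w.r.t. one coordinate
# block of the state
numeric_gradient <- function(fiber, ring = NULL,
                             block = c("pos", "pax", "ring"), h = 1e-6) {
  block <- match.arg(block)
  target <- if (block == "ring") ring$pos else fiber[[block]]
  g <- matrix(0, nrow(target), 3)
  for (i in seq_len(nrow(target))) {
    for (q in 1:3) {
      bump <- function(s) {
        f2 <- fiber; r2 <- ring
        if (block == "ring") r2$pos[i, q] <- r2$pos[i, q] + s
        else f2[[block]][i, q] <- f2[[block]][i, q] + s
        potential_energy(f2, r2)
      }
      g[i, q] <- -(bump(h) - bump(-h)) / (2 * h)
    }
  }
  g
}

# dense midpoint quadrature of the Gauss writhe integral for a smooth
# closed parametric curve f(t), t in [0, 2pi)
writhe_quadrature <- function(f, n = 1200) {
  t <- 2 * pi * (0:(n - 1)) / n
  P <- f(t)
  seg <- rbind(P[-1, ], P[1, ]) - P
  mid <- P + seg / 2
  W <- 0
  for (i in seq_len(n)) {
    j <- setdiff(seq_len(n), c(i, i %% n + 1, (i - 2) %% n + 1))
    r <- sweep(mid[i, , drop = FALSE][rep(1, length(j)), ], 1, 0) -
      mid[j, , drop = FALSE]
    d3 <- (rowSums(r^2))^1.5
    cr <- cbind(seg[i, 2] * seg[j, 3] - seg[i, 3] * seg[j, 2],
                seg[i, 3] * seg[j, 1] - seg[i, 1] * seg[j, 3],
                seg[i, 1] * seg[j, 2] - seg[i, 2] * seg[j, 1])
    W <- W + sum(rowSums(cr * r) / d3)
  }
  W / (4 * pi)
}

# signed piercings of the fan-triangulated disc of a closed polygon by a
# directed segment p1 -> p2 (Moller-Trumbore)
segment_disc_piercing <- function(ring_pts, p1, p2) {
  centre <- colMeans(ring_pts)
  m <- nrow(ring_pts)
  dir <- p2 - p1
  total <- 0
  for (k in seq_len(m)) {
    a <- ring_pts[k, ]; b <- ring_pts[k %% m + 1, ]
    e1 <- a - centre; e2 <- b - centre
    pv <- c(dir[2] * e2[3] - dir[3] * e2[2],
            dir[3] * e2[1] - dir[1] * e2[3],
            dir[1] * e2[2] - dir[2] * e2[1])
    det <- sum(e1 * pv)
    if (abs(det) < 1e-12) next
    tv <- p1 - centre
    u <- sum(tv * pv) / det
    if (u < 0 || u > 1) next
    qv <- c(tv[2] * e1[3] - tv[3] * e1[2],
            tv[3] * e1[1] - tv[1] * e1[3],
            tv[1] * e1[2] - tv[2] * e1[1])
    v <- sum(dir * qv) / det
    if (v < 0 || u + v > 1) next
    tt <- sum(e2 * qv) / det
    if (tt < 0 || tt > 1) next
    total <- total + sign(det)
  }
  total
}

# signed piercings of a ring disc by every segment of a closed fiber
fiber_ring_piercings <- function(fiber_pos, ring_pts) {
  n <- nrow(fiber_pos)
  sapply(seq_len(n), function(i)
    segment_disc_piercing(ring_pts, fiber_pos[i, ],
                          fiber_pos[i %% n + 1, ]))
}

# topological linking number of the backbone and periaxial edge polygons
fiber_frame_linking <- function(pos, pax) linking_number(pos, pax)

wrapa <- supercoilex:::wrap_angle

frame_positions <- function(traj, k) t(traj$frames_pos[, , k])
frame_paxs <- function(traj, k) t(traj$frames_pax[, , k])
frame_rings <- function(traj, k) t(traj$frames_ring[, , k])

tw_plus_wr <- function(pos, pax) {
  sum(wrapa(supercoilex:::cpp_twist_angles(pos, pax, TRUE))) / (2 * pi) +
    writhe(pos, TRUE)
}
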