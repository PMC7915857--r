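#' Read and write simulation configurations
#'
#' Configurations are YAML files with sections `fiber`, `ring`, `motor`,
#' `sim` and (optionally) `continuum`, each holding the fields of the
#' corresponding parameter constructor. Unknown sections or keys are
#' rejected, and the motor calibration (`dt * steps_per_rotation` = 90
#' time units) is validated on read.
#'
#' @param path file path.
#' @return `read_config()` returns a list with elements `fiber`, `ring`,
#'   `motor`, `sim` and optionally `continuum`, each a validated
#'   parameter object.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("fiber", "ring", "motor", "sim", "continuum")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("config error: unknown section(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  check_keys <- function(x, allowed, section) {
    bad <- setdiff(names(x), allowed)
    if (length(bad))
      stop("config error in section '", section, "': unknown key(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    x
  }
  out <- list()
  out$fiber <- do.call(fiber_params,
                       check_keys(drop_fixed(raw$fiber),
                                  names(formals(fiber_params)), "fiber"))
  out$ring <- do.call(ring_params,
                      check_keys(raw$ring %||% list(),
                                 names(formals(ring_params)), "ring"))
  out$motor <- do.call(motor_params,
                       check_keys(raw$motor %||% list(),
                                  names(formals(motor_params)), "motor"))
  out$sim <- do.call(sim_config,
                     check_keys(raw$sim %||% list(),
                                names(formals(sim_config)), "sim"))
  if (!is.null(raw$continuum))
    out$continuum <- do.call(continuum_params,
                             check_keys(raw$continuum,
                                        names(formals(continuum_params)),
                                        "continuum"))
  if (out$sim$motor_enabled &&
      abs(out$sim$dt * out$motor$steps_per_rotation - 90) > 1e-9)
    stop("config error: dt * steps_per_rotation must equal 90 time units",
         call. = FALSE)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

drop_fixed <- function(x) {
  x <- x %||% list()
  x$bp_per_bead <- NULL
  x$nm_per_bead <- NULL
  x
}

#' @param config a list as returned by [read_config()], or assembled from
#'   the parameter constructors.
#' @rdname read_config
#' @export
write_config <- function(config, path) {
  strip <- function(p, fixed = character(0)) {
    p <- unclass(p)
    p[setdiff(names(p), fixed)]
  }
  out <- list(fiber = strip(config$fiber, c("bp_per_bead", "nm_per_bead")),
              ring = strip(config$ring),
              motor = strip(config$motor),
              sim = strip(config$sim))
  if (!is.null(config$continuum))
    out$continuum <- strip(config$continuum, "D_c")
  yaml::write_yaml(out, path)
  invisible(path)
}

#' The shipped default configuration
#'
#' Production-scale defaults: a 150-bead (60 kbp) circular fiber, 14-bead ring,
#' time step 0.0025, one motor rotation per 36,000 steps, friction
#' `gamma_c` = 20.
#'
#' @export
default_config <- function() {
  list(fiber = fiber_params(), ring = ring_params(),
       motor = motor_params(),
       sim = sim_config(gamma_c = 20), continuum = continuum_params())
}

#' Write / read a trajectory
#'
#' Frames go to `trajectory.xyz` in extended-XYZ form (one block per
#' frame; the species column distinguishes `M` = loading/motor bead,
#' `B` = backbone, `P` = periaxial, `R` = ring beads), per-frame topology
#' metrics to `metrics.csv`, and the run manifest (configuration
#' snapshot, seed, version, frame counts, termination reason) to
#' `manifest.json`. Coordinates survive a round trip to 1e-8.
#'
#' @param traj an `sc_trajectory`.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_trajectory <- function(traj, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nf <- n_frames(traj)
  n <- traj$n_beads
  m <- if (is.null(traj$frames_ring)) 0L else dim(traj$frames_ring)[2]
  con <- file(file.path(dir, "trajectory.xyz"), "w")
  on.exit(close(con))
  species <- c(ifelse(seq_len(n) == traj$loading_bead, "M", "B"),
               rep("P", n), rep("R", m))
  for (k in seq_len(nf)) {
    coords <- rbind(frame_pos(traj, k), frame_pax(traj, k),
                    if (m > 0) frame_ring(traj, k))
    writeLines(c(sprintf("%d", n + n + m),
                 sprintf("time=%.10g frame=%d", traj$times[k], k),
                 sprintf("%s %.12g %.12g %.12g", species,
                         coords[, 1], coords[, 2], coords[, 3])), con)
  }
  metrics <- traj$metrics %||% trajectory_metrics(traj)
  write.csv(metrics, file.path(dir, "metrics.csv"), row.names = FALSE)
  jsonlite::write_json(run_manifest(traj), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(dir) {
  path <- file.path(dir, "trajectory.xyz")
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    nat <- suppressWarnings(as.integer(lines[i]))
    if (is.na(nat))
      stop("parse error in ", path, " near line ", i, call. = FALSE)
    if (i + 1 + nat > length(lines))
      stop("parse error: truncated frame ", length(frames) + 1, " in ",
           path, call. = FALSE)
    hdr <- lines[i + 1]
    time <- as.numeric(sub(".*time=([^ ]+).*", "\\1", hdr))
    block <- lines[(i + 2):(i + 1 + nat)]
    parts <- strsplit(block, " +")
    sp <- vapply(parts, `[`, "", 1)
    xyz <- matrix(as.numeric(unlist(lapply(parts, `[`, 2:4))),
                  ncol = 3, byrow = TRUE)
    frames[[length(frames) + 1]] <-
      list(time = time,
           pos = xyz[sp %in% c("B", "M"), , drop = FALSE],
           pax = xyz[sp == "P", , drop = FALSE],
           ring = if (any(sp == "R")) xyz[sp == "R", , drop = FALSE],
           loading_bead = which(sp[sp %in% c("B", "M")] == "M" |
                                  sp[sp %in% c("M", "B")] == "M")[1])
    i <- i + 2L + nat
  }
  metrics_path <- file.path(dir, "metrics.csv")
  metrics <- if (file.exists(metrics_path)) read.csv(metrics_path)
  manifest_path <- file.path(dir, "manifest.json")
  manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  list(frames = frames, metrics = metrics, manifest = manifest)
}

#' Run manifest
#'
#' Snapshot of everything needed to reproduce a run bit-exactly:
#' configuration, fiber/ring/motor parameters, seed, package version,
#' frame count and termination reason.
#'
#' @param traj an `sc_trajectory`.
#' @export
run_manifest <- function(traj) {
  list(package_version =
         as.character(utils::packageVersion("supercoilex")),
       seed = traj$config$seed,
       sim = unclass(traj$config),
       fiber = unclass(traj$params),
       ring = if (!is.null(traj$ring_params)) unclass(traj$ring_params),
       n_frames = n_frames(traj),
       steps_done = traj$steps_done,
       termination = traj$status)
}

#' Re-run an extrusion from its manifest
#'
#' @param manifest a manifest list (as written by [write_trajectory()] or
#'   returned by [run_manifest()]).
#' @return an `sc_trajectory`; identical seed and configuration give a
#'   bit-identical trajectory.
#' @export
rerun_from_manifest <- function(manifest) {
  sim <- do.call(sim_config, manifest$sim[names(formals(sim_config))])
  fib <- do.call(fiber_params,
                 drop_fixed(manifest$fiber)[intersect(names(manifest$fiber),
                                              names(formals(fiber_params)))])
  rng <- do.call(ring_params,
                 manifest$ring[intersect(names(manifest$ring),
                                         names(formals(ring_params)))])
  run_extrusion(sim, fib, rng)
}

#' Deterministic small test systems
#'
#' Named fixtures used throughout the test suite:
#' \describe{
#'   \item{planar_circle}{n-point circle in the xy plane (zero writhe).}
#'   \item{figure_eight}{closed figure-eight curve with one signed
#'     crossing (writhe near +-1), `n` points, crossing separation `eps`.}
#'   \item{clamped_rod}{straight open torsion-active fiber whose backbone
#'     and far-end frame are immobilized (huge drag), with the motor at
#'     bead 1: a twist-conservation testbed.}
#'   \item{ring_on_rod}{straight fiber threaded once through a planar
#'     14-bead ring centered between beads 10 and 11.}
#'   \item{mini_fiber_40}{40-bead circular fiber with a loaded ring:
#'     the desk-scale extrusion system.}
#' }
#'
#' @param name fixture name.
#' @param seed seed forwarded to any stochastic construction step.
#' @param n point count for the curve fixtures.
#' @param eps crossing separation of the figure-eight.
#' @return a matrix of coordinates or a list of states, depending on the
#'   fixture.
#' @export
make_fixture <- function(name, seed = 1L, n = 64L, eps = 0.15) {
  switch(name,
    planar_circle = {
      th <- 2 * pi * (seq_len(n) - 1) / n
      cbind(cos(th), sin(th), 0)
    },
    figure_eight = {
      t <- 2 * pi * (seq_len(max(n, 128L)) - 1) / max(n, 128L)
      cbind(cos(t), sin(t) * cos(t), eps * sin(t))
    },
    clamped_rod = {
      p <- fiber_params(n_beads = 20L, bend_Kb = 0, wca_epsilon = 0)
      f <- build_linear_fiber(p, seed = seed)
      f$gamma_bb[] <- 1e12                  # backbone frozen straight
      f$gamma_pax[nrow(f$pos)] <- 1e12      # far-end frame clamped
      f
    },
    ring_on_rod = {
      p <- fiber_params(n_beads = 24L)
      f <- build_linear_fiber(p, seed = seed)
      rp <- ring_params()
      m <- rp$n_ring_beads
      r_ring <- m * rp$bond_r0 / (2 * pi)
      centre <- c(9.5, 0, 0)                # between beads 10 and 11
      ang <- 2 * pi * (seq_len(m) - 1) / m
      ring <- new_ring_state(t(vapply(ang, function(a)
        centre + r_ring * c(0, cos(a), sin(a)), numeric(3))), rp)
      list(fiber = f, ring = ring)
    },
    mini_fiber_40 = {
      fp <- fiber_params(n_beads = 40L)
      fiber <- build_circular_fiber(fp, seed = seed)
      load_ring(fiber, ring_params(gamma_c = 50), seed = seed)
    },
    stop("unknown fixture name: ", name, call. = FALSE)
  )
}
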