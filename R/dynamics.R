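#' Langevin integrator parameters
#'
#' Underdamped Langevin dynamics integrated with the BAOAB splitting:
#' velocity-Verlet drift/kick with an exact Ornstein-Uhlenbeck thermostat
#' step, friction -gamma m v and Gaussian noise at temperature kBT. The
#' thermostat noise is a counter-based stream indexed by
#' (seed, global step, bead, component), so a run split across restarts
#' reproduces the uninterrupted trajectory bit-exactly.
#'
#' @param dt Time step, tau (default 0.01).
#' @param kBT Temperature, eps (default 1).
#' @param gamma Friction, 1/tau (default 1).
#' @param mass Bead mass (default 1).
#' @param particle_mass Tracer mass; `"unit"` (default, diffusive-regime
#'   observables are mass-insensitive) or `"volume"` for mass proportional to
#'   r_p^3 (mass of a sigma-diameter bead times (2 r_p / sigma)^3).
#' @param seed Integer seed of the noise stream.
#' @return An `fb_langevin_params` list.
#' @export
langevin_params <- function(dt = 0.01, kBT = 1, gamma = 1, mass = 1,
                            particle_mass = c("unit", "volume"), seed = 1L) {
  particle_mass <- match.arg(particle_mass)
  stopifnot(dt > 0, kBT > 0, gamma > 0, mass > 0)
  structure(list(dt = dt, kBT = kBT, gamma = gamma, mass = mass,
                 particle_mass = particle_mass, seed = as.integer(seed)),
            class = "fb_langevin_params")
}

#' Run plan
#'
#' Lengths of the equilibration and production phases and the output
#' cadence. The full-scale protocol is 1e7 equilibration steps followed by
#' 1e8 production steps with frames every 100 steps (1 tau).
#'
#' @param equil_steps Equilibration steps (not recorded).
#' @param prod_steps Production steps.
#' @param dump_every Frame interval in steps (default 100).
#' @param thermo_every Log interval in steps (default 1000; 0 disables).
#' @param tracked `"loci"` (nine loci plus tracer, the default), `"all"`, or
#'   an integer vector of bead indices.
#' @return An `fb_run_plan` list.
#' @export
run_plan <- function(equil_steps = 1e7, prod_steps = 1e8, dump_every = 100,
                     thermo_every = 1000, tracked = "loci") {
  stopifnot(equil_steps >= 0, prod_steps >= 0, dump_every >= 1,
            thermo_every >= 0)
  structure(list(equil_steps = equil_steps, prod_steps = prod_steps,
                 dump_every = dump_every, thermo_every = thermo_every,
                 tracked = tracked),
            class = "fb_run_plan")
}

bead_masses <- function(topology, lang) {
  mass <- rep(lang$mass, topology$n_beads)
  if (isTRUE(topology$particle) && lang$particle_mass == "volume")
    mass[topology$n_beads] <- lang$mass * (2 * topology$particle_radius)^3
  mass
}

tracked_ids <- function(topology, tracked) {
  if (is.numeric(tracked)) {
    ids <- as.integer(tracked)
    roles <- paste0("bead", ids)
    loci <- topology$loci
    if (!is.null(loci)) {
      hit <- match(ids, loci)
      roles[!is.na(hit)] <- names(loci)[hit[!is.na(hit)]]
    }
    if (isTRUE(topology$particle)) roles[ids == topology$n_beads] <- "particle"
  } else if (identical(tracked, "all")) {
    ids <- seq_len(topology$n_beads)
    return(tracked_ids(topology, ids))
  } else if (identical(tracked, "loci")) {
    if (is.null(topology$loci) && !isTRUE(topology$particle))
      stop("topology has neither loci nor a tracer; use tracked = 'all' ",
           "or bead indices", call. = FALSE)
    ids <- unname(topology$loci)
    roles <- names(topology$loci)
    if (isTRUE(topology$particle)) {
      ids <- c(ids, topology$n_beads)
      roles <- c(roles, "particle")
    }
  } else stop("tracked must be 'loci', 'all', or bead indices", call. = FALSE)
  list(ids = ids, roles = roles)
}

#' Advance a state by a fixed number of Langevin steps
#'
#' Low-level stepper behind [run_dynamics()]. Because the thermostat noise is
#' indexed by the absolute step counter carried in `state$step`, advancing
#' 2n steps equals advancing n steps twice.
#'
#' @param state An `fb_state`.
#' @param topology,spec,ff,lang System definition ([build_feather_boa()],
#'   confinement spec, [ff_params()], [langevin_params()]).
#' @param nsteps Number of steps.
#' @param dump_every If > 0, collect frames of `tracked` beads.
#' @param thermo_every Log cadence in steps (0 disables).
#' @param tracked As in [run_plan()].
#' @return List with the advanced `state`, a `trajectory` (or `NULL`), and a
#'   `thermo` tibble.
#' @export
advance <- function(state, topology, spec, ff = ff_params(),
                    lang = langevin_params(), nsteps, dump_every = 0,
                    thermo_every = 0, tracked = "loci") {
  stopifnot(inherits(state, "fb_state"))
  tr <- tracked_ids(topology, tracked)
  collect <- dump_every > 0
  out <- cpp_run(state$positions, state$velocities,
                 as.integer(topology$species == "particle"),
                 topology$bonds - 1L, unclass(spec),
                 ff_cpp_params(ff, topology),
                 bead_masses(topology, lang),
                 lang$dt, lang$kBT, lang$gamma, as.numeric(nsteps),
                 state$time, as.numeric(state$step), lang$seed,
                 as.integer(max(dump_every, 1)), as.integer(thermo_every),
                 tr$ids - 1L, collect)
  new_state <- structure(list(positions = out$positions,
                              velocities = out$velocities,
                              time = out$end_time, step = out$end_step),
                         class = "fb_state")
  traj <- NULL
  if (collect) {
    frames <- aperm(out$traj, c(3, 2, 1))  # [frame, id, xyz]
    traj <- new_trajectory(out$frame_time, frames, tr$ids, tr$roles,
                           dump_every * lang$dt)
  }
  list(state = new_state, trajectory = traj,
       thermo = tibble::as_tibble(out$thermo))
}

#' Run the equilibration + production protocol
#'
#' Executes the run plan: an equilibration phase (no frames recorded)
#' followed by a production phase whose tracked-bead frames are collected
#' every `dump_every` steps. Thermodynamic output (temperature, kinetic and
#' potential energy, minimum wall gap) is logged every `thermo_every` steps
#' of both phases.
#'
#' @inheritParams advance
#' @param plan A [run_plan()].
#' @return List with `trajectory` (an `fb_trajectory`), `thermo` (tibble,
#'   column `phase` marking equilibration/production) and the final `state`.
#' @export
run_dynamics <- function(state, topology, spec, ff = ff_params(),
                         lang = langevin_params(), plan = run_plan()) {
  eq <- list(state = state, thermo = NULL)
  if (plan$equil_steps > 0) {
    eq <- advance(state, topology, spec, ff, lang, plan$equil_steps,
                  dump_every = 0, thermo_every = plan$thermo_every,
                  tracked = plan$tracked)
  }
  pr <- advance(eq$state, topology, spec, ff, lang, plan$prod_steps,
                dump_every = plan$dump_every, thermo_every = plan$thermo_every,
                tracked = plan$tracked)
  thermo <- dplyr::bind_rows(
    if (!is.null(eq$thermo)) dplyr::mutate(eq$thermo, phase = "equilibration"),
    dplyr::mutate(pr$thermo, phase = "production"))
  list(trajectory = pr$trajectory, thermo = thermo, state = pr$state)
}

#' Instantaneous temperature and kinetic energy
#'
#' T = 2 KE / (3 N kB) with KE = sum of m v^2 / 2.
#'
#' @param state An `fb_state`.
#' @param topology The matching topology.
#' @param lang [langevin_params()] (for the mass convention).
#' @return List with `temperature` and `kinetic`.
#' @export
thermo <- function(state, topology, lang = langevin_params()) {
  m <- bead_masses(topology, lang)
  ke <- 0.5 * sum(m * rowSums(state$velocities^2))
  list(temperature = 2 * ke / (3 * nrow(state$positions)), kinetic = ke)
}

#' Write / read a simulation checkpoint
#'
#' Plain-text checkpoint (positions, velocities, time, absolute step counter)
#' with a header checksum; a run restarted from a checkpoint continues the
#' noise stream exactly where it stopped.
#'
#' @param state An `fb_state`.
#' @param file Path.
#' @return `read_checkpoint()` returns the restored `fb_state`.
#' @export
write_checkpoint <- function(state, file) {
  n <- nrow(state$positions)
  body <- c(format(c(state$time, state$step), digits = 17),
            format(t(cbind(state$positions, state$velocities)), digits = 17))
  payload <- paste(body, collapse = "\n")
  header <- sprintf("featherboa-checkpoint n=%d crc=%.0f", n,
                    sum(utf8ToInt(payload)))
  writeLines(c(header, payload), file)
  invisible(file)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(file) {
  lines <- readLines(file)
  hdr <- strsplit(lines[1], " ")[[1]]
  if (hdr[1] != "featherboa-checkpoint")
    stop("not a checkpoint file", call. = FALSE)
  n <- as.integer(sub("n=", "", hdr[2]))
  crc <- as.numeric(sub("crc=", "", hdr[3]))
  payload <- paste(lines[-1], collapse = "\n")
  if (abs(sum(utf8ToInt(payload)) - crc) > 0.5)
    stop("checkpoint corrupted: checksum mismatch", call. = FALSE)
  vals <- as.numeric(lines[-1])
  meta <- vals[1:2]
  arr <- matrix(vals[-(1:2)], nrow = n, ncol = 6, byrow = TRUE)
  structure(list(positions = arr[, 1:3], velocities = arr[, 4:6],
                 time = meta[1], step = meta[2]),
            class = "fb_state")
}
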