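#' Build the feather-boa chromosome topology
#'
#' Constructs the coarse-grained bacterial-chromosome topology: a linear
#' backbone of `n_backbone` beads joined by harmonic bonds, one (or more)
#' closed side loops of `loop_size` beads attached at every backbone bead,
#' and optionally a single non-bonded cytoplasmic tracer particle. Each loop
#' is closed through its anchor backbone bead: bonds run anchor -> l1 ->
#' ... -> lm -> anchor, so every loop bead has exactly two bonds. At the
#' defaults (200 backbone beads, 200 loops of 40 beads, one tracer) the
#' system has 8201 beads and 8399 bonds.
#'
#' @param n_backbone Number of backbone beads (>= 2).
#' @param loop_size Number of beads per side loop (>= 2).
#' @param particle_radius Tracer radius r_p in sigma (tracer diameter
#'   `2 * particle_radius`); the polymer-tracer contact distance is
#'   `0.5 + particle_radius`.
#' @param loops_per_bead Side loops attached per backbone bead (default 1).
#' @param particle Include the tracer bead? (default `TRUE`).
#' @param closed_loops If `FALSE`, the loop-end-to-anchor closure bond is
#'   omitted, giving an open-brush variant for sensitivity checks.
#' @return An `fb_topology` object: bead count, per-bead `species`
#'   (`"backbone"`, `"loop"`, `"particle"`), a two-column 1-based `bonds`
#'   matrix, and the default locus labels of [default_loci()].
#' @examples
#' topo <- build_feather_boa(2, 2, 0.5)  # 7 beads, 7 bonds
#' topo$n_beads
#' @export
build_feather_boa <- function(n_backbone = 200, loop_size = 40,
                              particle_radius = 0.5, loops_per_bead = 1,
                              particle = TRUE, closed_loops = TRUE) {
  stopifnot(n_backbone >= 2, loop_size >= 2, loops_per_bead >= 0,
            particle_radius > 0)
  nb <- as.integer(n_backbone)
  m <- as.integer(loop_size)
  lpb <- as.integer(loops_per_bead)
  n_poly <- nb * (1L + lpb * m)
  n_beads <- n_poly + as.integer(particle)

  species <- rep("loop", n_beads)
  species[seq_len(nb)] <- "backbone"
  if (particle) species[n_beads] <- "particle"

  bonds_bb <- cbind(seq_len(nb - 1L), seq_len(nb - 1L) + 1L)
  loop_bonds <- vector("list", nb * lpb)
  anchors <- integer(nb * lpb)
  idx <- 0L
  for (a in seq_len(nb)) {
    for (l in seq_len(lpb)) {
      idx <- idx + 1L
      s <- nb + (idx - 1L) * m + 1L  # first bead of this loop
      beads <- s:(s + m - 1L)
      anchors[idx] <- a
      b <- cbind(c(a, beads[-m]), beads)
      if (closed_loops) b <- rbind(b, c(beads[m], a))
      loop_bonds[[idx]] <- b
    }
  }
  bonds <- rbind(bonds_bb, do.call(rbind, loop_bonds))
  storage.mode(bonds) <- "integer"

  topo <- structure(list(
    n_backbone = nb, loop_size = m, loops_per_bead = lpb,
    particle = particle, particle_radius = particle_radius,
    closed_loops = closed_loops,
    n_beads = n_beads, n_polymer = n_poly,
    species = species, bonds = bonds, loop_anchor = anchors
  ), class = "fb_topology")
  topo$loci <- tryCatch(default_loci(topo), error = function(e) NULL)
  topo
}

#' @export
print.fb_topology <- function(x, ...) {
  cat("<feather-boa topology> ", x$n_backbone, " backbone beads, ",
      x$n_backbone * x$loops_per_bead, " ",
      if (x$closed_loops) "closed" else "open",
      " loops of ", x$loop_size, " beads",
      if (x$particle) paste0(", tracer r_p = ", x$particle_radius), "\n",
      "  ", x$n_beads, " beads, ", nrow(x$bonds), " bonds\n", sep = "")
  invisible(x)
}

#' Default tracked chromosomal loci
#'
#' Labels nine beads whose trajectories mimic fluorescently tagged
#' chromosomal sites: locus 1 at the first backbone bead, locus 2 at the
#' backbone midpoint, locus 3 at the last backbone bead, and loci 4-9 in
#' mid-loop/quarter-loop pairs on the three loops anchored at those backbone
#' positions. Mid-loop beads (intra-loop position `loop_size/2`) are the
#' beads at maximal bond-graph distance from the backbone; loci 6 and 8 are
#' mid-loop by construction.
#'
#' @param topology An `fb_topology` with at least one loop per backbone bead.
#' @return Named integer vector `locus1` ... `locus9` of bead indices.
#' @export
default_loci <- function(topology) {
  stopifnot(inherits(topology, "fb_topology"))
  if (topology$loops_per_bead < 1)
    stop("default loci require a topology with side loops", call. = FALSE)
  nb <- topology$n_backbone
  m <- topology$loop_size
  anchors <- c(1L, nb %/% 2L + 1L, nb)
  quarter <- max(1L, m %/% 4L)
  mid <- m %/% 2L
  loop_bead <- function(anchor, pos) {
    # first loop attached at `anchor`; loops are laid out in anchor order
    s <- nb + ((anchor - 1L) * topology$loops_per_bead) * m
    s + pos
  }
  loci <- c(
    anchors[1], anchors[2], anchors[3],
    loop_bead(anchors[1], mid), loop_bead(anchors[1], quarter),
    loop_bead(anchors[2], mid), loop_bead(anchors[2], quarter),
    loop_bead(anchors[3], mid), loop_bead(anchors[3], quarter)
  )
  names(loci) <- paste0("locus", 1:9)
  loci
}

clamp_inside <- function(pos, spec, margin) {
  kind <- spec$kind
  if (kind %in% c("cylinder", "compressed")) {
    R <- (if (kind == "cylinder") spec$diameter else spec$width) / 2 - margin
    halfL <- spec$length / 2 - margin
    rho <- sqrt(pos[, 1]^2 + pos[, 2]^2)
    over <- rho > R
    if (any(over)) {
      sc <- R / rho[over]
      pos[over, 1] <- pos[over, 1] * sc
      pos[over, 2] <- pos[over, 2] * sc
    }
    pos[, 3] <- pmin(pmax(pos[, 3], -halfL), halfL)
    if (kind == "compressed") {
      halfH <- spec$height / 2 - margin
      pos[, 2] <- pmin(pmax(pos[, 2], -halfH), halfH)
    }
  } else {
    R <- spec$diameter / 2 - margin
    halfC <- spec$cyl_length / 2
    zc <- pmin(pmax(pos[, 3], -halfC), halfC)
    d <- sqrt(pos[, 1]^2 + pos[, 2]^2 + (pos[, 3] - zc)^2)
    over <- d > R
    if (any(over)) {
      sc <- R / d[over]
      pos[over, 1] <- pos[over, 1] * sc
      pos[over, 2] <- pos[over, 2] * sc
      pos[over, 3] <- zc[over] + (pos[over, 3] - zc[over]) * sc
    }
  }
  pos
}

#' Initial configuration inside a confinement
#'
#' Places the backbone on a uniform helix along the confinement axis (a
#' straight axial line when it fits), lays each closed loop on a circle of
#' the matching circumference through its anchor (alternating up/down along
#' the axis to reduce clashes), drops the tracer at a random interior point
#' with wall clearance, and then removes residual overlaps by a capped-force
#' steepest-descent push-off over soft pair/wall repulsions plus the harmonic
#' bonds. Velocities are drawn from the Maxwell-Boltzmann distribution at
#' kBT = 1 (unit mass). Identical seeds give bit-identical states.
#'
#' @param topology An [build_feather_boa()] topology.
#' @param spec A confinement spec.
#' @param seed Integer seed for tracer placement and velocities.
#' @param max_iter Push-off iteration budget.
#' @return An `fb_state`: `positions`, `velocities` (N x 3), `time`, `step`.
#' @export
init_configuration <- function(topology, spec, seed = 1L, max_iter = 20000L) {
  stopifnot(inherits(topology, "fb_topology"), inherits(spec, "fb_confinement"))
  set.seed(seed)
  nb <- topology$n_backbone
  m <- topology$loop_size
  n <- topology$n_beads
  margin <- 1.0
  rc <- if (topology$loops_per_bead > 0) (m + 1) / (2 * pi) else 0

  dims <- switch(spec$kind,
    cylinder = list(R = spec$diameter / 2, halfL = spec$length / 2,
                    halfH = spec$diameter / 2),
    spherocylinder = list(R = spec$diameter / 2, halfL = spec$cyl_length / 2,
                          halfH = spec$diameter / 2),
    compressed = list(R = spec$width / 2, halfL = spec$length / 2,
                      halfH = spec$height / 2))

  pos <- matrix(0, n, 3)
  if (nb > 0 && any(topology$species != "particle")) {
    # Backbone on a helix near the wall; each loop on a circle through its
    # anchor lying in the radial-axial plane and extending inward, so the
    # loop beads fill the interior rather than crowding a thin shell.
    z_extent <- max(dims$halfL - margin - rc, 0.2 * dims$halfL)
    path <- nb - 1
    if (path <= 2 * z_extent + 1e-9 || nb < 3) {
      zs <- seq(-path / 2, path / 2, length.out = nb)
      golden <- 2.399963
      u_in <- cbind(cos(golden * seq_len(nb)), sin(golden * seq_len(nb)), 0)
      bb <- cbind(0, 0, zs)
    } else {
      r_h <- max(dims$R - 1.2, 0.6 * dims$R)
      r_hy <- min(r_h, max(dims$halfH - margin, 0.5))
      t_tot <- sqrt(max(path^2 - (2 * z_extent)^2, 1)) / r_h
      tt <- seq(0, t_tot, length.out = nb)
      bb <- cbind(r_h * cos(tt), r_hy * sin(tt),
                  seq(-z_extent, z_extent, length.out = nb))
      u_in <- cbind(-cos(tt), -sin(tt), 0)  # inward radial at each anchor
      rc_in <- min(rc, (r_h - 0.5) / 2)     # don't overshoot past the axis
    }
    pos[seq_len(nb), ] <- bb
    if (topology$loops_per_bead > 0) {
      if (!exists("rc_in", inherits = FALSE)) rc_in <- rc
      phi <- 2 * pi * seq_len(m) / (m + 1)
      ez <- c(0, 0, 1)
      idx <- 0L
      for (a in seq_len(nb)) {
        for (l in seq_len(topology$loops_per_bead)) {
          idx <- idx + 1L
          s <- nb + (idx - 1L) * m
          for (j in seq_len(m)) {
            pos[s + j, ] <- pos[a, ] + (1 - cos(phi[j])) * rc_in * u_in[a, ] +
              sin(phi[j]) * rc * ez
          }
        }
      }
    }
    pos[seq_len(topology$n_polymer), ] <-
      clamp_inside(pos[seq_len(topology$n_polymer), , drop = FALSE], spec, 0.9)
  }

  if (topology$particle) {
    clear <- 0.5 + topology$particle_radius + 1.0
    for (try in 1:10000) {
      cand <- c(stats::runif(1, -dims$R, dims$R),
                stats::runif(1, -dims$halfH, dims$halfH),
                stats::runif(1, -dims$halfL - dims$R, dims$halfL + dims$R))
      if (cpp_min_gap(cand, unclass(spec)) >= clear) break
      cand <- NULL
    }
    if (is.null(cand))
      stop("could not place the tracer with the required wall clearance",
           call. = FALSE)
    pos[n, ] <- cand
  }

  rel <- cpp_relax(pos, as.integer(topology$species == "particle"),
                   topology$bonds - 1L, unclass(spec),
                   ff_cpp_params(ff_params(), topology),
                   as.integer(max_iter), 0.004, 0.05, 0.05, 0.9)
  if (!rel$converged)
    stop(sprintf(paste0("push-off relaxation did not converge in %d steps ",
                        "(worst residual overlap %.3f sigma, min wall gap %.3f)"),
                 max_iter, rel$worst_overlap, rel$min_gap), call. = FALSE)

  vel <- matrix(stats::rnorm(3 * n), n, 3)  # kBT = 1, unit mass
  structure(list(positions = rel$positions, velocities = vel,
                 time = 0, step = 0),
            class = "fb_state")
}

#' @export
print.fb_state <- function(x, ...) {
  cat("<simulation state> ", nrow(x$positions), " beads, t = ", x$time,
      " tau (step ", format(x$step, scientific = FALSE), ")\n", sep = "")
  invisible(x)
}
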