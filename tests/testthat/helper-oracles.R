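# Independent oracles and small-system builders shared across test files.

# O(T^2) double-loop reference for the time-averaged 2D MSD.
msd_oracle <- function(xyz, ax, lags_frames) {
  vapply(lags_frames, function(k) {
    nf <- nrow(xyz)
    acc <- 0
    for (s in seq_len(nf - k))
      acc <- acc + (xyz[s + k, ax[1]] - xyz[s, ax[1]])^2 +
                   (xyz[s + k, ax[2]] - xyz[s, ax[2]])^2
    acc / (nf - k)
  }, numeric(1))
}

# Brute-force O(N^2) pair list (independent of the C++ cell grid).
pairs_oracle <- function(pos, cutoff, exclude = NULL) {
  n <- nrow(pos)
  out <- NULL
  ex <- if (is.null(exclude)) character(0)
        else paste(pmin(exclude[, 1], exclude[, 2]),
                   pmax(exclude[, 1], exclude[, 2]))
  for (i in seq_len(n - 1))
    for (j in (i + 1):n) {
      if (sqrt(sum((pos[i, ] - pos[j, ])^2)) < cutoff &&
          !(paste(i, j) %in% ex))
        out <- rbind(out, c(i, j))
    }
  if (is.null(out)) matrix(integer(0), 0, 2) else out
}

# A random bonded bead cluster (with tracer) inside a cylinder, used for
# force-consistency checks.
random_small_system <- function(n = 20, seed = 42, rp = 0.75) {
  set.seed(seed)
  topo <- structure(list(
    n_backbone = n - 1L, loop_size = 0L, loops_per_bead = 0L,
    particle = TRUE, particle_radius = rp, closed_loops = TRUE,
    n_beads = as.integer(n), n_polymer = n - 1L,
    species = c(rep("backbone", n - 1L), "particle"),
    bonds = cbind(seq_len(n - 2L), seq_len(n - 2L) + 1L),
    loop_anchor = integer(0), loci = NULL), class = "fb_topology")
  storage.mode(topo$bonds) <- "integer"
  spec <- cylinder_spec(12, 16)
  # chain laid loosely along z with jitter; tracer off-centre
  pos <- cbind(stats::runif(n, -2, 2), stats::runif(n, -2, 2),
               seq(-5, 5, length.out = n) + stats::runif(n, -0.2, 0.2))
  pos[n, ] <- c(3, 1, 0)
  state <- structure(list(positions = pos,
                          velocities = matrix(0, n, 3),
                          time = 0, step = 0), class = "fb_state")
  list(topology = topo, state = state, spec = spec)
}

# Monte-Carlo hit-or-miss volume estimate with standard error.
mc_volume <- function(spec, n = 2e5, seed = 7) {
  set.seed(seed)
  box <- switch(spec$kind,
    cylinder = c(spec$diameter / 2, spec$diameter / 2, spec$length / 2),
    spherocylinder = c(spec$diameter / 2, spec$diameter / 2,
                       spec$cyl_length / 2 + spec$diameter / 2),
    compressed = c(spec$width / 2, spec$height / 2, spec$length / 2))
  pts <- cbind(stats::runif(n, -box[1], box[1]),
               stats::runif(n, -box[2], box[2]),
               stats::runif(n, -box[3], box[3]))
  hit <- apply(pts, 1, function(p) contains(p, spec))
  vbox <- prod(2 * box)
  p <- mean(hit)
  list(volume = vbox * p, se = vbox * sqrt(p * (1 - p) / n))
}
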