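#' Force-field parameters
#'
#' Parameters of the three interaction terms: harmonic bonds
#' U = 1/2 k_bond (r - r0)^2, purely repulsive WCA pair repulsion with
#' species-dependent contact distance b (cut and shifted at 2^(1/6) b), and
#' the 9-3 Lennard-Jones wall U = eps \[(2/15)(b/r)^9 - (b/r)^3\] acting on
#' the gap to every wall element.
#'
#' @param epsilon Energy unit (default 1).
#' @param k_bond Bond stiffness, eps/sigma^2 (default 100).
#' @param r0 Equilibrium bond length, sigma (default 1).
#' @param sigma Bead diameter and bead-bead contact distance b (default 1).
#' @param wall_cutoff One of `"printed"` (cutoff 2^(1/6) b, retaining part of
#'   the attractive branch of the 9-3 form) or `"repulsive"` (cutoff at the
#'   potential minimum (2/5)^(1/6) b, purely repulsive wall).
#' @param wall_shift Shift the wall energy (not the force) to zero at the
#'   cutoff (default `TRUE`).
#' @param exclude_bonded Exclude directly bonded pairs from the WCA sum
#'   (default `TRUE`): with r0 = b the harmonic minimum sits inside the WCA
#'   core and double counting would shift the effective bond length.
#' @param skin Verlet-list skin, sigma (default 0.4).
#' @return An `fb_ff_params` list.
#' @export
ff_params <- function(epsilon = 1, k_bond = 100, r0 = 1, sigma = 1,
                      wall_cutoff = c("printed", "repulsive"),
                      wall_shift = TRUE, exclude_bonded = TRUE, skin = 0.4) {
  wall_cutoff <- match.arg(wall_cutoff)
  stopifnot(epsilon > 0, k_bond > 0, r0 > 0, sigma > 0, skin >= 0)
  structure(list(epsilon = epsilon, k_bond = k_bond, r0 = r0, sigma = sigma,
                 wall_cutoff = wall_cutoff, wall_shift = wall_shift,
                 exclude_bonded = exclude_bonded, skin = skin),
            class = "fb_ff_params")
}

wall_cut_factor <- function(params) {
  if (params$wall_cutoff == "printed") 2^(1 / 6) else (2 / 5)^(1 / 6)
}

# flat parameter list for the C++ core
ff_cpp_params <- function(params, topology) {
  list(epsilon = params$epsilon, k_bond = params$k_bond, r0 = params$r0,
       sigma = params$sigma,
       particle_radius = if (isTRUE(topology$particle)) topology$particle_radius else 0.5,
       wall_cut_factor = wall_cut_factor(params),
       wall_shift = params$wall_shift,
       exclude_bonded = params$exclude_bonded,
       skin = params$skin)
}

#' Harmonic bond energy and derivative
#'
#' @param r Bead separation, sigma (vectorised).
#' @param k_bond,r0 Bond stiffness and equilibrium length.
#' @return List with `energy` U(r) and `dU_dr`.
#' @export
bond_energy_force <- function(r, k_bond = 100, r0 = 1) {
  stopifnot(all(r > 0))
  list(energy = 0.5 * k_bond * (r - r0)^2, dU_dr = k_bond * (r - r0))
}

#' WCA pair energy and derivative
#'
#' Lennard-Jones truncated at its minimum 2^(1/6) b and shifted up by
#' epsilon/4 so that both the energy and the force vanish continuously at the
#' cutoff; purely repulsive.
#'
#' @param r Separation, sigma (vectorised).
#' @param b Contact distance, sigma.
#' @param epsilon Energy scale.
#' @return List with `energy` and `dU_dr`.
#' @export
wca_energy_force <- function(r, b = 1, epsilon = 1) {
  if (any(r <= 0)) stop("separation must be positive", call. = FALSE)
  sr6 <- (b / r)^6
  inside <- r <= 2^(1 / 6) * b
  list(
    energy = ifelse(inside, 4 * epsilon * (sr6^2 - sr6) + epsilon, 0),
    dU_dr = ifelse(inside, 4 * epsilon * (-12 * sr6^2 + 6 * sr6) / r, 0)
  )
}

#' 9-3 wall energy and derivative
#'
#' Evaluates U(gap) = eps \[(2/15)(b/gap)^9 - (b/gap)^3\] for the gap to one
#' wall element, cut off at `wall_cutoff` and, by default, energy-shifted to
#' zero there. The force on a bead acts along the wall element's inward
#' normal with magnitude `-dU_dgap`.
#'
#' @param gap Distance to the wall surface, sigma (vectorised, must be > 0).
#' @param b Wall contact distance for the species, sigma.
#' @param params An [ff_params()] object (controls cutoff mode and shift).
#' @return List with `energy` and `dU_dgap`.
#' @export
wall_energy_force <- function(gap, b = 1, params = ff_params()) {
  if (any(gap <= 0))
    stop("escaped-bead: non-positive wall gap", call. = FALSE)
  cut <- wall_cut_factor(params) * b
  eps <- params$epsilon
  u93 <- function(g) eps * (2 / 15 * (b / g)^9 - (b / g)^3)
  shift <- if (params$wall_shift) u93(cut) else 0
  inside <- gap <= cut
  list(
    energy = ifelse(inside, u93(gap) - shift, 0),
    dU_dgap = ifelse(inside,
                     eps * (-9 * 2 / 15 * b^9 / gap^10 + 3 * b^3 / gap^4), 0)
  )
}

#' WCA contact distance for a species pair
#'
#' b = sigma for any polymer-polymer pair and b = sigma/2 + r_p for a
#' polymer-tracer pair.
#'
#' @param species_i,species_j Bead species (`"backbone"`, `"loop"`,
#'   `"particle"`).
#' @param topology Topology carrying the tracer radius.
#' @param sigma Bead diameter (default 1).
#' @return Contact distance in sigma.
#' @export
pair_b <- function(species_i, species_j, topology, sigma = 1) {
  ok <- c("backbone", "loop", "particle")
  if (!(species_i %in% ok) || !(species_j %in% ok))
    stop("unknown species", call. = FALSE)
  np <- (species_i == "particle") + (species_j == "particle")
  if (np == 0) return(sigma)
  if (np == 2)
    stop("particle-particle interactions are not defined (single tracer)",
         call. = FALSE)
  sigma / 2 + topology$particle_radius
}

#' Total forces and potential energy
#'
#' Sums bond, WCA pair (bonded pairs excluded by default) and wall
#' contributions; the returned forces are the exact negative gradient of the
#' returned energy. Uses the linked-cell neighbour search unless
#' `use_cells = FALSE` (brute-force O(N^2), for cross-checks).
#'
#' @param state An `fb_state` (or an N x 3 position matrix).
#' @param topology An `fb_topology`.
#' @param spec A confinement spec.
#' @param params [ff_params()].
#' @param use_cells Use the cell list (default `TRUE`).
#' @return List with `energy`, `forces` (N x 3), `min_gap` (smallest wall
#'   gap over all beads) and `n_pairs` in the neighbour list.
#' @export
total_forces <- function(state, topology, spec, params = ff_params(),
                         use_cells = TRUE) {
  pos <- if (inherits(state, "fb_state")) state$positions else state
  stopifnot(nrow(pos) == topology$n_beads)
  cpp_ff_eval(pos, as.integer(topology$species == "particle"),
              topology$bonds - 1L, unclass(spec),
              ff_cpp_params(params, topology), use_cells)
}

#' Neighbour pair list
#'
#' All bead pairs within `cutoff`, via the linked-cell grid (or brute force),
#' excluding directly bonded pairs when `params$exclude_bonded` is set.
#'
#' @inheritParams total_forces
#' @param cutoff Listing radius, sigma; defaults to the largest WCA cutoff
#'   plus the skin.
#' @return Two-column integer matrix of 1-based bead indices (i < j).
#' @export
neighbor_pairs <- function(state, topology, params = ff_params(),
                           cutoff = NULL, use_cells = TRUE) {
  pos <- if (inherits(state, "fb_state")) state$positions else state
  if (is.null(cutoff)) {
    bmax <- if (isTRUE(topology$particle))
      max(params$sigma, params$sigma / 2 + topology$particle_radius)
    else params$sigma
    cutoff <- 2^(1 / 6) * bmax + params$skin
  }
  excl <- if (params$exclude_bonded) topology$bonds - 1L
          else matrix(integer(0), 0, 2)
  cpp_pair_list(pos, cutoff, use_cells, excl) + 1L
}
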