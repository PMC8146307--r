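#' Confinement geometries
#'
#' Constructors for the three cell-wall confinement shapes, all centred at the
#' origin with the long axis along z (the observation plane is xz):
#' a flat-capped cylinder, a spherocylinder (cylinder closed by two
#' hemispherical caps, the "cell-like" wall), and a compressed cell modelled
#' as the intersection of a cylinder with a slab of two parallel planes
#' normal to y. All lengths are in units of the bead diameter sigma.
#'
#' @param diameter Cylinder (or cap) diameter, sigma.
#' @param length Axis length of the cylinder, closed by flat end planes at
#'   z = +/- length/2, sigma.
#' @param cyl_length Length of the cylindrical section of a spherocylinder
#'   (total axial extent is `cyl_length + diameter`), sigma.
#' @param width Cylinder diameter of the compressed cell, sigma.
#' @param height Gap between the two compression planes (at y = +/- height/2),
#'   sigma. Must not exceed `width`.
#' @return A confinement spec object of class `fb_confinement` (and a
#'   kind-specific subclass).
#' @examples
#' cylinder_spec(29.5, 50.75)
#' spherocylinder_spec(29.5, 45.83)
#' compressed_spec(width = 31.626, height = 24.269, length = 50.75)
#' @name confinement
NULL

new_confinement <- function(kind, fields) {
  spec <- c(list(kind = kind), fields)
  class(spec) <- c(paste0("fb_", kind), "fb_confinement")
  spec
}

#' @rdname confinement
#' @export
cylinder_spec <- function(diameter, length) {
  stopifnot(is.numeric(diameter), diameter > 0, is.numeric(length), length > 0)
  new_confinement("cylinder", list(diameter = diameter, length = length))
}

#' @rdname confinement
#' @export
spherocylinder_spec <- function(diameter, cyl_length) {
  stopifnot(is.numeric(diameter), diameter > 0,
            is.numeric(cyl_length), cyl_length >= 0)
  new_confinement("spherocylinder",
                  list(diameter = diameter, cyl_length = cyl_length))
}

#' @rdname confinement
#' @export
compressed_spec <- function(width, height, length) {
  stopifnot(is.numeric(width), width > 0, is.numeric(height), height > 0,
            is.numeric(length), length > 0)
  if (height > width)
    stop("compressed cell height must not exceed its width", call. = FALSE)
  new_confinement("compressed",
                  list(width = width, height = height, length = length))
}

#' @export
print.fb_confinement <- function(x, ...) {
  dims <- vapply(x[-1], format, character(1))
  cat("<confinement: ", x$kind, "> ",
      paste(names(dims), dims, sep = " = ", collapse = ", "),
      " [sigma]\n", sep = "")
  invisible(x)
}

# plain list <-> spec, for config files
as_confinement <- function(x) {
  if (inherits(x, "fb_confinement")) return(x)
  switch(x$kind,
    cylinder = cylinder_spec(x$diameter, x$length),
    spherocylinder = spherocylinder_spec(x$diameter, x$cyl_length),
    compressed = compressed_spec(x$width, x$height, x$length),
    stop("unknown confinement kind: ", x$kind)
  )
}

wall_element_names <- c("lateral", "end+z", "end-z", "slab+y", "slab-y", "cap")

#' Distances from an interior point to the confining wall elements
#'
#' Enumerates every wall element of the confinement (lateral cylindrical
#' surface, flat end planes, compression planes, hemispherical caps, as
#' applicable) and reports the Euclidean gap from `point` to each surface
#' together with the inward unit normal. The per-element gaps drive the 9-3
#' wall potential: each element interacts independently.
#'
#' @param point Numeric length-3 coordinate (sigma).
#' @param spec A confinement from [cylinder_spec()], [spherocylinder_spec()]
#'   or [compressed_spec()].
#' @param cutoff Only elements with gap below `cutoff` are returned
#'   (default `Inf`: all elements).
#' @return A tibble with columns `element`, `gap` and `nx`, `ny`, `nz`
#'   (inward unit normal).
#' @export
wall_contacts <- function(point, spec, cutoff = Inf) {
  stopifnot(inherits(spec, "fb_confinement"), length(point) == 3)
  res <- cpp_wall_contacts(as.numeric(point), unclass(spec))
  if (any(res$gap <= 0))
    stop("escaped-bead: point (", paste(signif(point, 6), collapse = ", "),
         ") lies outside the confinement", call. = FALSE)
  keep <- res$gap < cutoff
  tibble::tibble(
    element = wall_element_names[res$code[keep] + 1L],
    gap = res$gap[keep],
    nx = res$normal[keep, 1], ny = res$normal[keep, 2], nz = res$normal[keep, 3]
  )
}

#' Is a point strictly inside the confinement?
#'
#' @inheritParams wall_contacts
#' @return `TRUE` iff `point` lies strictly inside all wall surfaces.
#' @export
contains <- function(point, spec) {
  stopifnot(inherits(spec, "fb_confinement"), length(point) == 3)
  cpp_min_gap(as.numeric(point), unclass(spec)) > 0
}

#' Confinement volume
#'
#' Closed-form volume: cylinder pi R^2 L; spherocylinder
#' pi R^2 L_cyl + (4/3) pi R^3; compressed cell L times the circle-slab
#' intersection area of [cross_section_area()].
#'
#' @param spec A confinement spec.
#' @return Volume in sigma^3.
#' @export
volume <- function(spec) {
  UseMethod("volume")
}

#' @export
volume.fb_cylinder <- function(spec) {
  pi * (spec$diameter / 2)^2 * spec$length
}

#' @export
volume.fb_spherocylinder <- function(spec) {
  R <- spec$diameter / 2
  pi * R^2 * spec$cyl_length + 4 / 3 * pi * R^3
}

#' @export
volume.fb_compressed <- function(spec) {
  spec$length * cross_section_area(spec$width, spec$height)
}

#' Cross-sectional area of a compressed cell
#'
#' Area of the intersection of a circle of diameter `width` with a centred
#' slab of thickness `height`: with R = width/2 and h = height/2,
#' area = 2 \[ h sqrt(R^2 - h^2) + R^2 asin(h / R) \]. Equals the full circle
#' pi width^2 / 4 when `height == width` and tends to `width * height` in the
#' thin-slab limit.
#'
#' @param width Circle diameter, sigma.
#' @param height Slab thickness, sigma; must satisfy 0 < height <= width.
#' @return Area in sigma^2. Vectorised over both arguments.
#' @export
cross_section_area <- function(width, height) {
  if (any(height <= 0) || any(width <= 0))
    stop("width and height must be positive", call. = FALSE)
  if (any(height > width * (1 + 1e-12)))
    stop("height must not exceed width", call. = FALSE)
  R <- width / 2
  h <- pmin(height / 2, R)
  2 * (h * sqrt(pmax(R^2 - h^2, 0)) + R^2 * asin(h / R))
}

#' Compressed-cell width at fixed cross-sectional area
#'
#' Solves for the cylinder width W of a compressed cell with slab height
#' `height` such that its cross-sectional area equals that of the reference
#' uncompressed circular cross-section of diameter `ref_diameter`. Since the
#' cell length is held fixed under compression, matching the cross-sectional
#' area keeps the volume, and hence the monomer packing fraction, constant.
#' Compression always widens the cell, so the root is bracketed on
#' \[ref_diameter, 10 ref_diameter\].
#'
#' @param height Slab height H, sigma.
#' @param ref_diameter Uncompressed cylinder diameter, sigma.
#' @return Width W in sigma, accurate to relative tolerance 1e-10.
#' @examples
#' solve_width_for_height(24.269, 29.5)  # 31.626
#' solve_width_for_height(19.037, 29.5)  # 37.5798
#' @export
solve_width_for_height <- function(height, ref_diameter) {
  stopifnot(height > 0, ref_diameter > 0)
  target <- pi * ref_diameter^2 / 4
  if (height >= ref_diameter) return(ref_diameter)
  f <- function(W) cross_section_area(W, height) - target
  hi <- 10 * ref_diameter
  if (f(hi) < 0)
    stop("infeasible geometry: no width in [ref_diameter, 10 ref_diameter] ",
         "matches the reference area for height ", height, call. = FALSE)
  stats::uniroot(f, c(ref_diameter, hi), tol = 1e-10 * ref_diameter)$root
}

#' Monomer packing fraction
#'
#' Total bead volume over confinement volume,
#' `n_beads * (pi/6) * bead_diameter^3 / volume(spec)`. The bead diameter
#' entering the bead-volume convention is an explicit argument; ratios of
#' packing fractions between confinements are independent of it.
#'
#' @param n_beads Number of beads.
#' @param bead_diameter Bead diameter used for the bead-volume convention,
#'   sigma.
#' @param spec A confinement spec.
#' @return Dimensionless fraction.
#' @export
packing_fraction <- function(n_beads, bead_diameter, spec) {
  stopifnot(n_beads >= 0, bead_diameter > 0)
  v <- volume(spec)
  if (v <= 0) stop("confinement has zero volume", call. = FALSE)
  n_beads * pi / 6 * bead_diameter^3 / v
}
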