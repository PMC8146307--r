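#' Write / read trajectories as extended-XYZ text
#'
#' One block per frame: atom count, a comment line carrying
#' `time=<tau> frame_interval=<tau> ids=<bead indices>`, then one
#' `<role> x y z` line per tracked bead. The reader reconstructs an
#' `fb_trajectory` from this dialect.
#'
#' @param traj An `fb_trajectory`.
#' @param file Path.
#' @return `read_xyz()` returns an `fb_trajectory`; `write_xyz()` its file
#'   path, invisibly.
#' @export
write_xyz <- function(traj, file) {
  nf <- dim(traj$frames)[1]
  ni <- dim(traj$frames)[2]
  con <- file(file, "w")
  on.exit(close(con))
  for (f in seq_len(nf)) {
    writeLines(as.character(ni), con)
    writeLines(sprintf("time=%.10g frame_interval=%.10g ids=%s",
                       traj$times[f], traj$dt_frame,
                       paste(traj$ids, collapse = ",")), con)
    writeLines(sprintf("%s %.10g %.10g %.10g", traj$roles,
                       traj$frames[f, , 1], traj$frames[f, , 2],
                       traj$frames[f, , 3]), con)
  }
  invisible(file)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(file) {
  lines <- readLines(file)
  ni <- as.integer(lines[1])
  block <- ni + 2L
  nf <- length(lines) %/% block
  kv <- function(line, key) sub(paste0(".*", key, "="), "", line)
  times <- numeric(nf)
  frames <- array(NA_real_, c(nf, ni, 3))
  roles <- character(ni)
  ids <- seq_len(ni)
  for (f in seq_len(nf)) {
    off <- (f - 1L) * block
    comment <- lines[off + 2L]
    times[f] <- as.numeric(strsplit(kv(comment, "time"), " ")[[1]][1])
    if (f == 1L) {
      ids <- as.integer(strsplit(strsplit(kv(comment, "ids"), " ")[[1]][1],
                                 ",")[[1]])
      dtf <- as.numeric(strsplit(kv(comment, "frame_interval"), " ")[[1]][1])
    }
    rows <- strsplit(lines[off + 2L + seq_len(ni)], "[ \t]+")
    for (k in seq_len(ni)) {
      if (f == 1L) roles[k] <- rows[[k]][1]
      frames[f, k, ] <- as.numeric(rows[[k]][2:4])
    }
  }
  new_trajectory(times, frames, ids, roles, dtf)
}

#' Read a LAMMPS-dialect dump file
#'
#' Parses plain-text LAMMPS dump output (`ITEM: TIMESTEP` / `ITEM: ATOMS id
#' ... x y z ...` blocks) into an `fb_trajectory`, converting time steps to
#' tau with the given integrator step.
#'
#' @param file Path to the dump text.
#' @param dt Time step used in the run, tau/step (default 0.01).
#' @param roles Optional role labels keyed by atom id (named character
#'   vector); atoms default to `"bead<id>"`.
#' @return An `fb_trajectory`.
#' @export
read_lammps_dump <- function(file, dt = 0.01, roles = NULL) {
  lines <- readLines(file)
  ts_at <- grep("^ITEM: TIMESTEP", lines)
  if (!length(ts_at)) stop("no ITEM: TIMESTEP blocks found", call. = FALSE)
  nf <- length(ts_at)
  times <- numeric(nf)
  frames <- NULL
  ids <- NULL
  for (f in seq_len(nf)) {
    i <- ts_at[f]
    times[f] <- as.numeric(lines[i + 1L]) * dt
    na <- as.integer(lines[grep("^ITEM: NUMBER OF ATOMS", lines[i:length(lines)])[1] + i])
    atoms_at <- grep("^ITEM: ATOMS", lines[i:length(lines)])[1] + i - 1L
    cols <- strsplit(sub("^ITEM: ATOMS ", "", lines[atoms_at]), " ")[[1]]
    ic <- match(c("id", "x", "y", "z"), cols)
    if (any(is.na(ic)))
      stop("dump must contain id, x, y, z columns", call. = FALSE)
    rows <- do.call(rbind, lapply(strsplit(
      lines[atoms_at + seq_len(na)], "[ \t]+"), as.numeric))
    ord <- order(rows[, ic[1]])
    rows <- rows[ord, , drop = FALSE]
    if (is.null(frames)) {
      ids <- as.integer(rows[, ic[1]])
      frames <- array(NA_real_, c(nf, na, 3))
    }
    frames[f, , ] <- rows[, ic[2:4]]
  }
  role_lab <- paste0("bead", ids)
  if (!is.null(roles)) {
    hit <- match(as.character(ids), names(roles))
    role_lab[!is.na(hit)] <- roles[hit[!is.na(hit)]]
  }
  dtf <- if (nf > 1) stats::median(diff(times)) else dt
  new_trajectory(times, frames, ids, role_lab, dtf)
}

#' Export a system as a LAMMPS data file
#'
#' Writes atoms (atom_style bond: id, molecule, type, x, y, z), masses and
#' the harmonic-bond list, with the box set to the confinement bounding box,
#' for cross-validation of the model in an external MD engine. Atom type 1
#' is a polymer bead, type 2 the tracer.
#'
#' @param topology An `fb_topology`.
#' @param state An `fb_state` holding the coordinates.
#' @param spec The confinement (box bounds).
#' @param file Path.
#' @param masses Length-2 numeric: polymer bead and tracer mass.
#' @return The path, invisibly.
#' @export
write_lammps_data <- function(topology, state, spec, file, masses = c(1, 1)) {
  pos <- state$positions
  n <- topology$n_beads
  nb <- nrow(topology$bonds)
  box <- switch(spec$kind,
    cylinder = c(spec$diameter / 2, spec$diameter / 2, spec$length / 2),
    spherocylinder = c(spec$diameter / 2, spec$diameter / 2,
                       spec$cyl_length / 2 + spec$diameter / 2),
    compressed = c(spec$width / 2, spec$height / 2, spec$length / 2))
  type <- ifelse(topology$species == "particle", 2L, 1L)
  lines <- c(
    "featherboa chromosome model (bead-spring, WCA + harmonic bonds)", "",
    sprintf("%d atoms", n),
    sprintf("%d bonds", nb),
    "2 atom types",
    "1 bond types", "",
    sprintf("%.10g %.10g xlo xhi", -box[1], box[1]),
    sprintf("%.10g %.10g ylo yhi", -box[2], box[2]),
    sprintf("%.10g %.10g zlo zhi", -box[3], box[3]), "",
    "Masses", "",
    sprintf("1 %.10g", masses[1]),
    sprintf("2 %.10g", masses[2]), "",
    "Atoms # bond", "",
    sprintf("%d 1 %d %.10g %.10g %.10g", seq_len(n), type,
            pos[, 1], pos[, 2], pos[, 3]), "",
    "Bonds", "",
    sprintf("%d 1 %d %d", seq_len(nb), topology$bonds[, 1],
            topology$bonds[, 2]))
  writeLines(lines, file)
  invisible(file)
}

#' Write analysis tables as tab-separated text
#'
#' @param x A tibble or data frame (e.g. an MSD table, a sweep table, a step
#'   histogram).
#' @param file Path.
#' @return The path, invisibly.
#' @export
write_tsv_table <- function(x, file) {
  utils::write.table(x, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
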