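#' Trajectory container
#'
#' Time-stamped positions of a set of tracked beads at a uniform frame
#' interval. `frames` is a \[n_frames, n_ids, 3\] array; `roles` names each
#' tracked id (`"particle"`, `"locus1"`, ..., or `"bead<i>"`).
#'
#' @param times Frame times, tau (strictly increasing, uniformly spaced).
#' @param frames Position array \[n_frames, n_ids, 3\].
#' @param ids Bead indices of the tracked beads.
#' @param roles Character labels, one per id.
#' @param dt_frame Frame interval, tau.
#' @return An `fb_trajectory`.
#' @export
new_trajectory <- function(times, frames, ids, roles, dt_frame) {
  stopifnot(length(dim(frames)) == 3, dim(frames)[1] == length(times),
            dim(frames)[2] == length(ids), length(roles) == length(ids))
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("frame times must be strictly increasing", call. = FALSE)
  structure(list(times = times, frames = frames, ids = ids, roles = roles,
                 dt_frame = dt_frame),
            class = "fb_trajectory")
}

#' @export
print.fb_trajectory <- function(x, ...) {
  cat("<trajectory> ", dim(x$frames)[1], " frames x ", length(x$ids),
      " tracked beads, frame interval ", x$dt_frame, " tau\n",
      "  roles: ", paste(x$roles, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.fb_trajectory <- function(x, ...) {
  nf <- dim(x$frames)[1]
  ni <- dim(x$frames)[2]
  tibble::tibble(
    time = rep(x$times, ni),
    id = rep(x$ids, each = nf),
    role = rep(x$roles, each = nf),
    x = as.vector(x$frames[, , 1]),
    y = as.vector(x$frames[, , 2]),
    z = as.vector(x$frames[, , 3])
  )
}

traj_select <- function(traj, id) {
  k <- if (is.character(id)) match(id, traj$roles) else match(id, traj$ids)
  if (is.na(k))
    stop("tracked bead '", id, "' not found in trajectory (roles: ",
         paste(traj$roles, collapse = ", "), ")", call. = FALSE)
  traj$frames[, k, , drop = TRUE]
}

axis_index <- function(axis) {
  i <- match(axis, c("x", "y", "z"))
  if (any(is.na(i))) stop("axis must be one of x, y, z", call. = FALSE)
  i
}

#' Two-dimensional projected mean-squared displacement
#'
#' Time-averaged MSD of one tracked bead projected onto a focal plane
#' (default xz, the observation plane when the compression planes are normal
#' to y): MSD(t) = <\[x(s+t)-x(s)\]^2 + \[z(s+t)-z(s)\]^2> over all
#' overlapping start frames s.
#'
#' @param traj An `fb_trajectory`.
#' @param id Tracked bead, by role (e.g. `"particle"`, `"locus2"`) or bead
#'   index.
#' @param plane Two axis names (default `c("x", "z")`).
#' @param lags Lag times in tau (must be multiples of the frame interval);
#'   default: ~60 log-spaced lags from one frame to a quarter of the
#'   trajectory length. Lags exceeding the trajectory are dropped with a
#'   warning.
#' @return A tibble of class `fb_msd` with columns `lag` (tau), `msd`
#'   (sigma^2) and `n` (displacement samples per lag).
#' @export
msd_2d <- function(traj, id, plane = c("x", "z"), lags = NULL) {
  xyz <- traj_select(traj, id)
  ax <- axis_index(plane)
  nf <- nrow(xyz)
  if (is.null(lags)) {
    kmax <- max(1L, (nf - 1L) %/% 4L)
    ks <- unique(round(exp(seq(log(1), log(kmax), length.out = 60))))
  } else {
    ks <- round(lags / traj$dt_frame)
    if (any(abs(lags / traj$dt_frame - ks) > 1e-6))
      stop("lags must be multiples of the frame interval", call. = FALSE)
    drop <- ks >= nf | ks < 1
    if (any(drop)) {
      warning(sum(drop), " lag(s) exceed the trajectory length; dropped")
      ks <- ks[!drop]
    }
  }
  a <- xyz[, ax[1]]
  b <- xyz[, ax[2]]
  msd <- vapply(ks, function(k) {
    idx <- seq_len(nf - k)
    mean((a[idx + k] - a[idx])^2 + (b[idx + k] - b[idx])^2)
  }, numeric(1))
  out <- tibble::tibble(lag = ks * traj$dt_frame, msd = msd, n = nf - ks)
  class(out) <- c("fb_msd", class(out))
  attr(out, "id") <- id
  attr(out, "plane") <- plane
  out
}

#' Ensemble-averaged MSD over replicate runs and/or equivalent beads
#'
#' Averages the time-averaged MSD curves of one or more tracked beads over
#' one or more replicate trajectories (all on the same frame grid), the
#' standard way to tame the long-lag variance of single-trajectory
#' time-averaged MSDs before fitting.
#'
#' @param trajs A single `fb_trajectory` or a list of replicate
#'   trajectories.
#' @param ids One or more tracked roles/indices whose curves are pooled
#'   (e.g. the two mid-loop loci).
#' @inheritParams msd_2d
#' @return An `fb_msd` tibble (the `n` column sums samples over curves).
#' @export
msd_ensemble <- function(trajs, ids, plane = c("x", "z"), lags = NULL) {
  if (inherits(trajs, "fb_trajectory")) trajs <- list(trajs)
  curves <- list()
  for (tr in trajs)
    for (id in ids)
      curves[[length(curves) + 1]] <- msd_2d(tr, id, plane, lags)
  out <- curves[[1]]
  out$msd <- Reduce(`+`, lapply(curves, function(m) m$msd)) / length(curves)
  out$n <- Reduce(`+`, lapply(curves, function(m) m$n))
  attr(out, "id") <- paste(unique(unlist(ids)), collapse = "+")
  out
}

#' Power-law fit of an MSD curve
#'
#' Fits MSD = 4 D t^alpha by least squares on log MSD = log(4 D) +
#' alpha log t over the fit window, with 95% confidence bounds from the
#' linear-fit covariance. An optional nonlinear refinement re-fits the power
#' law directly on the linear scale starting from the log-log estimates.
#'
#' @param msd An [msd_2d()] result (or any tibble with `lag` and `msd`).
#' @param window Lag window in tau (default `c(10, 1000)`); at least five
#'   lags with positive MSD must fall inside.
#' @param refine Nonlinear least-squares refinement (default `FALSE`).
#' @return An `fb_powerlaw` object; see [tidy.fb_powerlaw()] and
#'   [glance.fb_powerlaw()]. Fields `Dxz`, `alpha`, `ci95_D`, `ci95_alpha`.
#' @export
fit_power_law <- function(msd, window = c(10, 1000), refine = FALSE) {
  sel <- msd$lag >= window[1] & msd$lag <= window[2]
  d <- msd[sel, ]
  if (nrow(d) < 5)
    stop("fewer than 5 lags in the fit window", call. = FALSE)
  if (any(d$msd <= 0))
    stop("non-positive MSD values in the fit window", call. = FALSE)
  fit <- stats::lm(log(msd) ~ log(lag), data = d)
  ci <- suppressWarnings(stats::confint(fit, level = 0.95))
  alpha <- unname(stats::coef(fit)[2])
  D <- unname(exp(stats::coef(fit)[1]) / 4)
  ci_D <- exp(ci[1, ]) / 4
  ci_a <- ci[2, ]
  if (refine) {
    nl <- try(stats::nls(msd ~ 4 * D * lag^alpha, data = d,
                         start = list(D = D, alpha = alpha)), silent = TRUE)
    if (!inherits(nl, "try-error")) {
      co <- stats::coef(nl)
      D <- unname(co["D"]); alpha <- unname(co["alpha"])
      nci <- try(suppressMessages(stats::confint.default(nl)), silent = TRUE)
      if (!inherits(nci, "try-error")) {
        ci_D <- nci["D", ]; ci_a <- nci["alpha", ]
      }
    }
  }
  structure(list(Dxz = D, alpha = alpha,
                 ci95_D = unname(ci_D), ci95_alpha = unname(ci_a),
                 window = window, n_lags = nrow(d),
                 id = attr(msd, "id"), msd = d),
            class = "fb_powerlaw")
}

#' @export
print.fb_powerlaw <- function(x, ...) {
  cat(sprintf(paste0("<power-law fit%s> MSD = 4 D t^alpha on t in [%g, %g] tau\n",
                     "  D     = %.4g  [%.4g, %.4g]  sigma^2/tau^alpha\n",
                     "  alpha = %.3f  [%.3f, %.3f]\n"),
              if (!is.null(x$id)) paste0(": ", x$id) else "",
              x$window[1], x$window[2],
              x$Dxz, x$ci95_D[1], x$ci95_D[2],
              x$alpha, x$ci95_alpha[1], x$ci95_alpha[2]))
  invisible(x)
}

#' Tidy a power-law fit
#'
#' @param x An `fb_powerlaw`.
#' @param ... Unused.
#' @return One row per parameter with estimate and 95% bounds.
#' @export
tidy.fb_powerlaw <- function(x, ...) {
  tibble::tibble(
    term = c("Dxz", "alpha"),
    estimate = c(x$Dxz, x$alpha),
    conf.low = c(x$ci95_D[1], x$ci95_alpha[1]),
    conf.high = c(x$ci95_D[2], x$ci95_alpha[2])
  )
}

#' @rdname tidy.fb_powerlaw
#' @export
glance.fb_powerlaw <- function(x, ...) {
  tibble::tibble(Dxz = x$Dxz, alpha = x$alpha,
                 D_conf.low = x$ci95_D[1], D_conf.high = x$ci95_D[2],
                 alpha_conf.low = x$ci95_alpha[1],
                 alpha_conf.high = x$ci95_alpha[2],
                 n_lags = x$n_lags,
                 window_lo = x$window[1], window_hi = x$window[2])
}

#' One-dimensional displacement distribution
#'
#' Collects all overlapping displacements Delta = q(t + t_m) - q(t) of one
#' tracked bead along an axis at measurement lag `t_m`, together with their
#' standard deviation delta and the peak-normalised histogram of
#' Delta/delta used for Gaussian-vs-Laplace shape comparison.
#'
#' @param traj An `fb_trajectory`.
#' @param id Tracked bead (role or index).
#' @param axis `"x"`, `"y"` or `"z"` (default `"z"`, the long axis).
#' @param t_m Measurement lag, tau; must be a multiple of the frame
#'   interval and shorter than the trajectory.
#' @param bins Histogram bin count over \[-5 delta, 5 delta\] (default 41).
#' @return An `fb_stepdist`: `samples` (raw), `scaled` (Delta/delta), `mu`,
#'   `delta`, `t_m`, `degenerate` flag, and `histogram` (tibble with `bin`
#'   centres in Delta/delta and peak-normalised `probability`).
#' @export
displacements_1d <- function(traj, id, axis = "z", t_m = 1000, bins = 41) {
  xyz <- traj_select(traj, id)
  q <- xyz[, axis_index(axis)]
  k <- round(t_m / traj$dt_frame)
  if (abs(t_m / traj$dt_frame - k) > 1e-6)
    stop("t_m must be a multiple of the frame interval", call. = FALSE)
  if (k < 1 || k >= length(q))
    stop("trajectory shorter than the measurement lag t_m", call. = FALSE)
  idx <- seq_len(length(q) - k)
  dz <- q[idx + k] - q[idx]
  mu <- mean(dz)
  delta <- stats::sd(dz)
  degenerate <- !is.finite(delta) || delta < 1e-12
  if (degenerate) {
    warning("degenerate displacement distribution: zero standard deviation")
    scaled <- rep(0, length(dz))
    hist_tbl <- tibble::tibble(bin = 0, probability = 1)
  } else {
    scaled <- dz / delta
    edges <- seq(-5, 5, length.out = bins + 1)
    counts <- tabulate(findInterval(pmax(pmin(scaled, 5 - 1e-9), -5),
                                    edges, all.inside = TRUE), nbins = bins)
    hist_tbl <- tibble::tibble(
      bin = (edges[-1] + edges[-(bins + 1)]) / 2,
      probability = counts / max(counts))
  }
  structure(list(samples = dz, scaled = scaled, mu = mu, delta = delta,
                 t_m = t_m, axis = axis, id = id, degenerate = degenerate,
                 histogram = hist_tbl),
            class = "fb_stepdist")
}

#' @export
print.fb_stepdist <- function(x, ...) {
  cat(sprintf(paste0("<step distribution%s> %d displacements along %s at ",
                     "t_m = %g tau\n  mu = %.4g, delta = %.4g sigma%s\n"),
              if (!is.null(x$id)) paste0(": ", x$id) else "",
              length(x$samples), x$axis, x$t_m, x$mu, x$delta,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Laplace probability density in mean / standard-deviation form
#'
#' P(dz; mu, delta) = 1/(delta sqrt(2)) exp(-|dz - mu| sqrt(2) / delta),
#' the double-exponential law parameterised by its mean `mu` and standard
#' deviation `delta` (scale parameter delta / sqrt(2)).
#'
#' @param dz Displacement values (vectorised).
#' @param mu Mean.
#' @param delta Standard deviation (> 0).
#' @return Density values.
#' @export
laplace_pdf <- function(dz, mu = 0, delta = 1) {
  if (any(delta <= 0)) stop("delta must be positive", call. = FALSE)
  exp(-abs(dz - mu) * sqrt(2) / delta) / (delta * sqrt(2))
}

#' Gaussian vs Laplace shape of a step distribution
#'
#' Maximum-likelihood (mu, delta) fits of the displacement samples under the
#' Gaussian and the Laplace law (Laplace MLE: mu = sample median, delta =
#' sqrt(2) mean |dz - median|), their log-likelihood difference (positive
#' favours Laplace), and the excess kurtosis of the samples (0 for a
#' Gaussian, 3 for a Laplace law).
#'
#' @param dist An [displacements_1d()] result, or a numeric sample vector.
#' @return A tibble with one row: `mu_gauss`, `delta_gauss`, `mu_laplace`,
#'   `delta_laplace`, `logL_gauss`, `logL_laplace`, `delta_logL`,
#'   `excess_kurtosis`, `n`.
#' @export
fit_step_shape <- function(dist) {
  dz <- if (inherits(dist, "fb_stepdist")) dist$samples else as.numeric(dist)
  if (length(dz) < 100)
    stop("need at least 100 displacement samples", call. = FALSE)
  sdev <- sqrt(mean((dz - mean(dz))^2))  # MLE (1/n) variance
  if (sdev < 1e-12)
    stop("degenerate sample: zero standard deviation", call. = FALSE)
  mu_g <- mean(dz)
  logL_g <- sum(stats::dnorm(dz, mu_g, sdev, log = TRUE))
  mu_l <- stats::median(dz)
  b <- mean(abs(dz - mu_l))        # Laplace scale MLE
  delta_l <- sqrt(2) * b           # standard deviation of that Laplace law
  logL_l <- sum(-abs(dz - mu_l) / b - log(2 * b))
  m2 <- mean((dz - mu_g)^2)
  kurt <- mean((dz - mu_g)^4) / m2^2 - 3
  tibble::tibble(mu_gauss = mu_g, delta_gauss = sdev,
                 mu_laplace = mu_l, delta_laplace = delta_l,
                 logL_gauss = logL_g, logL_laplace = logL_l,
                 delta_logL = logL_l - logL_g,
                 excess_kurtosis = kurt, n = length(dz))
}

#' Plot an MSD curve with its power-law fit
#'
#' @param object An `fb_msd` tibble.
#' @param fit Optional [fit_power_law()] result to overlay.
#' @param ... Unused.
#' @return A ggplot (log-log axes).
#' @export
autoplot.fb_msd <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$lag, y = .data$msd)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time lag t (tau)", y = "2D MSD (sigma^2)",
                  title = attr(object, "id"))
  if (!is.null(fit)) {
    line <- tibble::tibble(lag = object$lag,
                           msd = 4 * fit$Dxz * object$lag^fit$alpha)
    p <- p + ggplot2::geom_line(
      data = line,
      ggplot2::aes(x = .data$lag, y = .data$msd), colour = "red")
  }
  p
}

#' Plot a peak-normalised step distribution with Gaussian and Laplace fits
#'
#' @param dist An [displacements_1d()] result.
#' @return A ggplot: histogram of Delta/delta (log y) with both fitted
#'   shapes, each peak-normalised.
#' @export
plot_step_distribution <- function(dist) {
  stopifnot(inherits(dist, "fb_stepdist"))
  grid <- seq(-5, 5, length.out = 201)
  gauss <- stats::dnorm(grid)
  lap <- laplace_pdf(grid, 0, 1)
  curves <- tibble::tibble(
    bin = rep(grid, 2),
    probability = c(gauss / max(gauss), lap / max(lap)),
    law = rep(c("Gaussian", "Laplace"), each = length(grid)))
  ggplot2::ggplot(dist$histogram,
                  ggplot2::aes(x = .data$bin, y = .data$probability)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(colour = .data$law)) +
    ggplot2::scale_y_log10(limits = c(1e-3, 1.5)) +
    ggplot2::labs(x = expression(Delta * z / delta),
                  y = "P (peak-normalised)", colour = NULL)
}
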