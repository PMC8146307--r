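make_traj <- function(xyz, dt_frame = 1, role = "particle") {
  nf <- nrow(xyz)
  frames <- array(NA_real_, c(nf, 1, 3))
  frames[, 1, ] <- xyz
  new_trajectory(seq(0, by = dt_frame, length.out = nf), frames, 1L, role,
                 dt_frame)
}

test_that("MSD estimator handles ballistic, Brownian and frozen motion", {
  t <- 0:500
  ballistic <- make_traj(cbind(0.3 * t, 0, 0))
  m <- msd_2d(ballistic, "particle", lags = c(1, 2, 5, 10, 50))
  expect_equal(m$msd, 0.3^2 * m$lag^2)

  frozen <- make_traj(matrix(1.5, 1001, 3))
  expect_true(all(msd_2d(frozen, "particle")$msd == 0))

  set.seed(3)
  D <- 0.8; n <- 40000
  steps <- matrix(rnorm(3 * n, sd = sqrt(2 * D)), n, 3)
  bm <- make_traj(apply(steps, 2, cumsum))
  m <- msd_2d(bm, "particle", lags = c(1, 2, 5, 10))
  expect_equal(m$msd, 4 * D * m$lag, tolerance = 0.05)
})

test_that("MSD estimator equals the double-loop oracle to 1e-12", {
  set.seed(9)
  xyz <- apply(matrix(rnorm(3000), 1000, 3), 2, cumsum)
  tr <- make_traj(xyz, dt_frame = 0.5)
  lags_frames <- c(1, 3, 10, 31, 100)
  m <- msd_2d(tr, "particle", lags = lags_frames * 0.5)
  want <- msd_oracle(xyz, c(1, 3), lags_frames)
  expect_equal(m$msd, want, tolerance = 1e-12)
  # sample counts and zero-lag limit
  expect_equal(m$n, 1000 - lags_frames)
  # lags beyond the trajectory are dropped with a warning
  expect_warning(m2 <- msd_2d(tr, "particle", lags = c(5, 1000) * 0.5),
                 "dropped")
  expect_equal(nrow(m2), 1)
})

test_that("power-law fit recovers noiseless generator parameters exactly", {
  lag <- exp(seq(log(1), log(2000), length.out = 40))
  for (par in list(c(0.3, 0.7), c(1.0, 1.0))) {
    tb <- tibble::tibble(lag = lag, msd = 4 * par[1] * lag^par[2])
    class(tb) <- c("fb_msd", class(tb))
    fit <- fit_power_law(tb, window = c(10, 1000))
    expect_equal(fit$Dxz, par[1], tolerance = 1e-10)
    expect_equal(fit$alpha, par[2], tolerance = 1e-10)
    expect_true(fit$ci95_alpha[1] <= fit$alpha &&
                  fit$alpha <= fit$ci95_alpha[2])
  }
  # refinement agrees on noiseless data
  tb <- tibble::tibble(lag = lag, msd = 4 * 0.3 * lag^0.7)
  class(tb) <- c("fb_msd", class(tb))
  fit <- fit_power_law(tb, window = c(10, 1000), refine = TRUE)
  expect_equal(fit$alpha, 0.7, tolerance = 1e-6)
  expect_error(fit_power_law(tb, window = c(10, 11)), "fewer than 5")
})

test_that("power-law fit is scale-equivariant", {
  lag <- exp(seq(log(1), log(2000), length.out = 30))
  tb <- tibble::tibble(lag = lag, msd = 4 * 0.5 * lag^0.62)
  class(tb) <- c("fb_msd", class(tb))
  f1 <- fit_power_law(tb)
  tb$msd <- tb$msd * 7.3
  f2 <- fit_power_law(tb)
  expect_equal(f2$alpha, f1$alpha, tolerance = 1e-12)
  expect_equal(f2$Dxz, 7.3 * f1$Dxz, tolerance = 1e-10)
})

test_that("alpha confidence intervals cover the truth across replicates", {
  # nominal 95% coverage; demand >= 93% over enough replicates that the
  # binomial wobble of the check itself is small
  set.seed(21)
  lag <- exp(seq(log(10), log(1000), length.out = 20))
  n_rep <- 500
  hits <- 0
  for (rep in seq_len(n_rep)) {
    msd <- 4 * 0.4 * lag^0.65 * (1 + rnorm(20, sd = 0.01))
    tb <- tibble::tibble(lag = lag, msd = msd)
    class(tb) <- c("fb_msd", class(tb))
    f <- fit_power_law(tb)
    if (f$ci95_alpha[1] <= 0.65 && 0.65 <= f$ci95_alpha[2]) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.93)
})

test_that("tidy and glance expose the fit in broom style", {
  lag <- exp(seq(log(1), log(2000), length.out = 30))
  tb <- tibble::tibble(lag = lag, msd = 4 * 0.3 * lag^0.7)
  class(tb) <- c("fb_msd", class(tb))
  fit <- fit_power_law(tb)
  td <- tidy(fit)
  expect_equal(td$term, c("Dxz", "alpha"))
  expect_equal(td$estimate, c(0.3, 0.7), tolerance = 1e-8)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_named(gl, c("Dxz", "alpha", "D_conf.low", "D_conf.high",
                     "alpha_conf.low", "alpha_conf.high", "n_lags",
                     "window_lo", "window_hi"))
})

test_that("displacement collection and scaling behave as specified", {
  # linear drift: all steps equal, degenerate spread is flagged
  t <- 0:2000
  drift <- make_traj(cbind(0, 0, 0.01 * t))
  expect_warning(d <- displacements_1d(drift, "particle", t_m = 100),
                 "degenerate")
  expect_true(d$degenerate)
  expect_equal(unique(round(d$samples, 12)), 1)

  # i.i.d. Gaussian steps: scaled displacements are standard normal
  set.seed(5)
  z <- cumsum(rnorm(3000))
  g <- make_traj(cbind(0 * z, 0 * z, z))
  d1 <- displacements_1d(g, "particle", t_m = 1)  # t_m = frame interval
  expect_equal(d1$samples, diff(z), tolerance = 1e-12)
  ks <- suppressWarnings(stats::ks.test(d1$scaled, "pnorm"))
  expect_gt(ks$p.value, 0.01)
  expect_equal(max(d1$histogram$probability), 1)
  expect_error(displacements_1d(g, "particle", t_m = 5000), "shorter")
  expect_error(displacements_1d(g, "particle", t_m = 1.5), "multiple")
})

test_that("the Laplace density is normalised with the right peak and variance", {
  expect_equal(laplace_pdf(0, 0, 1), 1 / sqrt(2))
  # adaptive quadrature split at the kink
  total <- stats::integrate(laplace_pdf, -Inf, 1.2, mu = 1.2, delta = 2.5,
                            rel.tol = 1e-10)$value +
           stats::integrate(laplace_pdf, 1.2, Inf, mu = 1.2, delta = 2.5,
                            rel.tol = 1e-10)$value
  expect_equal(total, 1, tolerance = 1e-8)
  # sampled variance equals delta^2 (inverse-CDF sampling)
  set.seed(8)
  u <- runif(2e5) - 0.5
  samp <- 3 - 1.7 / sqrt(2) * sign(u) * log(1 - 2 * abs(u))
  expect_equal(var(samp), 1.7^2, tolerance = 0.02)
  expect_error(laplace_pdf(0, 0, -1), "delta")
})

test_that("Laplace MLE equals its closed form on arbitrary samples", {
  set.seed(13)
  x <- rt(500, df = 3) * 2 + 1
  fit <- fit_step_shape(x)
  expect_equal(fit$mu_laplace, median(x))
  expect_equal(fit$delta_laplace, sqrt(2) * mean(abs(x - median(x))))
})

test_that("shape selection separates Gaussian from Laplace samples", {
  set.seed(17)
  g <- rnorm(1e4)
  fg <- fit_step_shape(g)
  expect_lt(fg$delta_logL, 0)
  expect_equal(fg$excess_kurtosis, 0, tolerance = 0.2)

  u <- runif(1e4) - 0.5
  lap <- -sign(u) * log(1 - 2 * abs(u))  # Laplace(0, 1)
  fl <- fit_step_shape(lap)
  expect_gt(fl$delta_logL, 0)
  expect_equal(fl$excess_kurtosis, 3, tolerance = 1)
  expect_error(fit_step_shape(rnorm(50)), "at least 100")
})

test_that("ensemble averaging pools curves over replicates and beads", {
  set.seed(2)
  trs <- lapply(1:3, function(i)
    make_traj(apply(matrix(rnorm(900), 300, 3), 2, cumsum)))
  m_each <- lapply(trs, msd_2d, id = "particle", lags = c(1, 2, 5))
  m_ens <- msd_ensemble(trs, "particle", lags = c(1, 2, 5))
  expect_equal(m_ens$msd,
               (m_each[[1]]$msd + m_each[[2]]$msd + m_each[[3]]$msd) / 3)
  expect_equal(m_ens$n, Reduce(`+`, lapply(m_each, `[[`, "n")))
})

test_that("autoplot and step-distribution plots build without error", {
  set.seed(4)
  tr <- make_traj(apply(matrix(rnorm(1500), 500, 3), 2, cumsum))
  m <- msd_2d(tr, "particle")
  f <- fit_power_law(m, window = c(1, 100))
  expect_s3_class(autoplot(m, fit = f), "ggplot")
  d <- displacements_1d(tr, "particle", t_m = 10)
  expect_s3_class(plot_step_distribution(d), "ggplot")
})
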