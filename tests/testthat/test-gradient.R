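profile_from <- function(x, y, bin = 3) {
  structure(data.frame(bin_center_um = x, count = y, smoothed = y),
            class = c("radial_profile", "data.frame"),
            bin_um = bin, n_cells = 1L)
}

test_that("radial binning uses contiguous 3 um bins and raw counts", {
  p <- radial_particle_counts(c(1, 2, 4))
  expect_equal(p$count[1:2], c(2L, 1L))
  expect_equal(p$bin_center_um[1:2], c(1.5, 4.5))
  expect_equal(radial_particle_counts(numeric(0))$count, 0L)
  expect_error(radial_particle_counts(c(1, -2)), "nonnegative")
  # binning conserves the particle count
  set.seed(71)
  d <- rexp(500, 1 / 20)
  expect_equal(sum(radial_particle_counts(d)$count), 500L)
})

test_that("point-origin uniform points follow the annulus-area law", {
  # with a point origin, uniform points in a disk give counts proportional
  # to annulus area (documented distinction from boundary-distance mode)
  set.seed(72)
  r <- 60 * sqrt(runif(2e4))
  p <- radial_particle_counts(r, max_um = 60)
  edges <- seq(0, 60, by = 3)
  area <- diff(edges^2)
  expect_gt(cor(p$count, area), 0.99)
})

test_that("smoothing is a centered 3-bin mean with shrinking edges", {
  spike <- radial_particle_counts(rep(7.5, 3), max_um = 15)
  sm <- smooth_profile(spike)
  expect_equal(sm$smoothed, c(0, 1, 1, 1, 0))
  const <- profile_from(seq(1.5, 29, 3), rep(4, 10))
  expect_equal(smooth_profile(const)$smoothed, rep(4, 10))
  expect_error(smooth_profile(const, span_um = 6), "odd multiple")
  # white-noise variance is reduced by the window length
  set.seed(73)
  noisy <- profile_from(seq(1.5, 600, 3), rnorm(200))
  expect_equal(var(smooth_profile(noisy)$smoothed[5:195]), 1 / 3,
               tolerance = 0.25)
  # smoothing conserves total mass away from the edges
  y <- rpois(200, 5)
  pr <- profile_from(seq(1.5, 600, 3), y)
  expect_equal(sum(smooth_profile(pr)$smoothed[2:199]), sum(y[2:199]),
               tolerance = 0.02)
})

test_that("meta-gradients average per bin with SEM", {
  p1 <- profile_from(c(1.5, 4.5), c(10, 4))
  p2 <- profile_from(c(1.5, 4.5), c(10, 6))
  m <- meta_gradient(list(p1, p2))
  expect_equal(m$mean, c(10, 5))
  expect_equal(m$sem, c(0, 1))
  expect_equal(meta_gradient(list(p1, p1))$sem, c(0, 0))
  expect_error(meta_gradient(list(p1, profile_from(c(1.5, 7.5), c(1, 2)))),
               "common binning")
})

test_that("meta-gradient SEM halves when the gradient count quadruples", {
  sem_of <- function(n_cells, seed) {
    sets <- simulate_gradient_particles(60, 15, n_cells, seed = seed)
    profs <- lapply(sets, radial_particle_counts, max_um = 90)
    mean(meta_gradient(profs)$sem[1:10])
  }
  expect_equal(sem_of(120, 74) / sem_of(30, 75), 0.5, tolerance = 0.25)
})

test_that("exponential fits recover exact and noisy planted gradients", {
  x <- seq(1.5, 88.5, by = 3)
  exact <- fit_exponential_gradient(profile_from(x, 100 * exp(-x / 25)))
  expect_equal(exact$amplitude, 100, tolerance = 1e-6)
  expect_equal(exact$lambda_um, 25, tolerance = 1e-6)
  expect_false(exact$no_gradient)

  # Poisson-noised exponential over 30 replicates: mean lambda within 10%
  set.seed(76)
  lam_hat <- vapply(1:30, function(i) {
    y <- rpois(length(x), 80 * exp(-x / 17))
    fit_exponential_gradient(profile_from(x, y))$lambda_um
  }, numeric(1))
  expect_equal(mean(lam_hat), 17, tolerance = 0.1)

  # flat profile is flagged as no-gradient
  flat <- fit_exponential_gradient(profile_from(x, rep(10, length(x))))
  expect_true(flat$no_gradient)
})

test_that("lambda is scale-invariant while amplitude scales linearly", {
  x <- seq(1.5, 88.5, by = 3)
  set.seed(77)
  y <- rpois(length(x), 60 * exp(-x / 20)) + 0.0
  f1 <- fit_exponential_gradient(profile_from(x, y))
  f5 <- fit_exponential_gradient(profile_from(x, 5 * y))
  expect_equal(f5$lambda_um, f1$lambda_um, tolerance = 1e-6)
  expect_equal(f5$amplitude / f1$amplitude, 5, tolerance = 1e-6)
})

test_that("the particle-gradient generator round-trips through the fit", {
  sets <- simulate_gradient_particles(80, 17, 40, seed = 78)
  expect_length(simulate_gradient_particles(80, 17, 0, seed = 1), 0L)
  profs <- lapply(sets, radial_particle_counts, max_um = 120)
  meta <- meta_gradient(profs)
  fit <- fit_exponential_gradient(profile_from(meta$bin_center_um, meta$mean))
  expect_equal(fit$lambda_um, 17, tolerance = 0.1)
  # doubling the amplitude doubles the fitted amplitude, lambda unchanged
  sets2 <- simulate_gradient_particles(160, 17, 40, seed = 79)
  meta2 <- meta_gradient(lapply(sets2, radial_particle_counts, max_um = 120))
  fit2 <- fit_exponential_gradient(profile_from(meta2$bin_center_um,
                                                meta2$mean))
  expect_equal(fit2$amplitude / fit$amplitude, 2, tolerance = 0.2)
  expect_equal(fit2$lambda_um, fit$lambda_um, tolerance = 0.15)
})

test_that("half-decay distance matches lambda * log(2) for exponentials", {
  x <- seq(1.5, 148.5, by = 3)
  hd <- half_decay_distance(profile_from(x, 100 * exp(-x / 30)))
  expect_equal(hd, 30 * log(2) + 1.5, tolerance = 0.15)
})

test_that("larger effective diffusion in the simulator widens the fitted lengthscale", {
  # cross-module link: agent endpoints of a topology-mode run, measured from
  # the sender boundary and fed through the radial fit, give a larger
  # lengthscale at a faster switch scale (i.e. at a larger D_eff)
  lambda_at <- function(sc) {
    p <- quick_params(mode = "topology", switch_scale = sc,
                      n_agents = 3000L, n_steps = 3000L, seed = 80)
    m <- run_msd_protocol(p)
    r <- pmax(sqrt((m$final_x_um - 2.5)^2 + (m$final_y_um - 2.5)^2) - 2.5, 0)
    # 1 um bins keep enough informative bins even for the tight profile
    prof <- radial_particle_counts(r, bin_um = 1, max_um = 120)
    fit_exponential_gradient(prof)$lambda_um
  }
  expect_gt(lambda_at(5), lambda_at(0.3))
})
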