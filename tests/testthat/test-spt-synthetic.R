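test_that("the default SHH model has the four published diffusion regimes", {
  m <- default_shh_state_model()
  expect_equal(m$D_um2s[1], 20)
  expect_equal(m$D_um2s, c(20, 1, 0.2, 0.05))
  expect_equal(drop(m$pi %*% m$A), m$pi, tolerance = 1e-10)
  expect_equal(rowSums(m$A), rep(1, 4))
  # secreted Halo alone is a single fast state
  h <- secreted_halo_model()
  expect_equal(h$D_um2s, 20)
  expect_equal(h$K, 1L)
})

test_that("occupancies can be overridden without breaking stationarity", {
  m <- default_shh_state_model(occupancies = c(0.25, 0.25, 0.25, 0.25))
  expect_equal(m$pi, rep(0.25, 4))
  expect_equal(drop(m$pi %*% m$A), m$pi, tolerance = 1e-10)
})

test_that("catalysis scaling divides lifetimes and preserves occupancies", {
  m <- two_state_model(pi = c(0.3, 0.7))
  expect_equal(scale_transition_rates(m, 1)$A, m$A)
  for (f in c(0.5, 2, 3)) {
    m2 <- scale_transition_rates(m, f)
    expect_equal(m2$pi, m$pi)
    expect_equal(drop(m2$pi %*% m2$A), m2$pi, tolerance = 1e-10)
    expect_equal(state_lifetimes(m2$A, 0.006),
                 state_lifetimes(m$A, 0.006) / f)
  }
  expect_error(scale_transition_rates(m, 1e4), "too large")
})

test_that("state lifetimes follow the geometric dwell formula", {
  A <- matrix(c(0.9, 0.1, 0.05, 0.95), 2, 2, byrow = TRUE)
  expect_equal(state_lifetimes(A, 0.006), c(0.06, 0.12))
  expect_equal(state_lifetimes(diag(2), 0.006), c(Inf, Inf))
  # empirical mean dwell of a simulated chain matches the formula per state
  set.seed(21)
  s <- integer(40000)
  s[1] <- 1L
  for (i in 2:length(s)) s[i] <- sample.int(2, 1, prob = A[s[i - 1], ])
  runs <- rle(s)
  for (k in 1:2) {
    emp <- mean(runs$lengths[runs$values == k]) * 0.006
    expect_equal(emp, state_lifetimes(A, 0.006)[k], tolerance = 0.1)
  }
})

test_that("simulated displacement variances match the closed form", {
  acq <- acquisition_spec(n_tracks = 400L, mean_track_len_frames = 30)
  # sigma = 0: per-axis variance is 2 D dt
  m0 <- diffusive_state_model(1, 1, matrix(1, 1, 1), sigma_loc_um = 0)
  tr0 <- simulate_tracks(m0, acq, seed = 31)
  d0 <- tr0[order(tr0$track_id, tr0$frame), ]
  dx <- unlist(tapply(d0$x_um, d0$track_id, diff), use.names = FALSE)
  expect_equal(var(dx), 2 * 1 * 0.006, tolerance = 0.05)
  # with noise: 2 D dt + 2 sigma^2
  m1 <- diffusive_state_model(1, 1, matrix(1, 1, 1), sigma_loc_um = 0.04)
  tr1 <- simulate_tracks(m1, acq, seed = 31)
  d1 <- tr1[order(tr1$track_id, tr1$frame), ]
  dx1 <- unlist(tapply(d1$x_um, d1$track_id, diff), use.names = FALSE)
  expect_equal(var(dx1), 2 * 1 * 0.006 + 2 * 0.04^2, tolerance = 0.05)
})

test_that("variance scales linearly in frame interval with a noise intercept", {
  m <- diffusive_state_model(2, 1, matrix(1, 1, 1), sigma_loc_um = 0.04)
  v <- vapply(c(0.003, 0.006, 0.024), function(dt) {
    tr <- simulate_tracks(
      m, acquisition_spec(frame_dt_s = dt, n_tracks = 600L,
                          mean_track_len_frames = 25), seed = 32)
    d <- tr[order(tr$track_id, tr$frame), ]
    var(unlist(tapply(d$x_um, d$track_id, diff), use.names = FALSE))
  }, numeric(1))
  fit <- lm(v ~ c(0.003, 0.006, 0.024))
  expect_equal(unname(coef(fit)[2]), 2 * 2, tolerance = 0.05)
  expect_equal(unname(coef(fit)[1]), 2 * 0.04^2, tolerance = 0.3)
})

test_that("hidden-state occupancy fractions converge to pi", {
  m <- two_state_model(pi = c(0.3, 0.7), exit = c(0.2, 0.2))
  tr <- simulate_tracks(m, acquisition_spec(n_tracks = 2000L,
                                            mean_track_len_frames = 20),
                        seed = 33)
  occ <- mean(tr$true_state == 1)
  expect_equal(occ, 0.3, tolerance = 0.1)
})

test_that("an identity chain freezes the hidden state within tracks", {
  m <- diffusive_state_model(c(5, 0.1), c(0.5, 0.5), diag(2), 0.03)
  tr <- simulate_tracks(m, acquisition_spec(n_tracks = 100L), seed = 34)
  per_track <- tapply(tr$true_state, tr$track_id,
                      function(s) length(unique(s)))
  expect_true(all(per_track == 1L))
})

test_that("track lengths respect the detection bounds and frames are gapless", {
  tr <- simulate_tracks(two_state_model(),
                        acquisition_spec(n_tracks = 500L,
                                         mean_track_len_frames = 10),
                        seed = 35)
  len <- tapply(tr$frame, tr$track_id, length)
  expect_true(all(len >= 3 & len <= 100))
  gaps <- tapply(tr$frame, tr$track_id, function(f) any(diff(f) != 1L))
  expect_false(any(gaps))
})

test_that("track tables round-trip through CSV and reject malformed input", {
  tr <- simulate_tracks(two_state_model(),
                        acquisition_spec(n_tracks = 20L), seed = 36)
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracks(tr, path)
  back <- read_tracks(path)
  expect_equal(as.data.frame(back), as.data.frame(tr), tolerance = 1e-12)
  expect_equal(attr(back, "frame_dt_s"), 0.006, tolerance = 1e-9)

  # a frame gap names the offending track
  df <- as.data.frame(tr)
  df <- df[!(df$track_id == df$track_id[1] & df$frame == 1L), ]
  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, bad, row.names = FALSE)
  expect_error(read_tracks(bad), "track")

  # empty file with header parses to an empty track set
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("track_id,frame,t_s,x_um,y_um", empty)
  etr <- read_tracks(empty)
  expect_s3_class(etr, "track_set")
  expect_equal(nrow(etr), 0L)
})

test_that("generic tracker exports can be read through a column mapping", {
  tr <- simulate_tracks(two_state_model(),
                        acquisition_spec(n_tracks = 5L), seed = 37)
  df <- data.frame(TRACK_ID = tr$track_id, FRAME = tr$frame,
                   POSITION_X = tr$x_um, POSITION_Y = tr$y_um)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  back <- read_tracks(path, frame_dt_s = 0.006,
                      col_map = c(track_id = "TRACK_ID", frame = "FRAME",
                                  x_um = "POSITION_X", y_um = "POSITION_Y"))
  expect_equal(back$x_um, tr$x_um)
  expect_equal(back$t_s, tr$t_s)
})
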