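test_that("displacements follow the N(0, 2 D dt) law per axis", {
  set.seed(1)
  expect_equal(draw_displacements(0, 0.006, 100),
               matrix(0, 100, 2, dimnames = list(NULL, c("dx", "dy"))))
  d <- draw_displacements(1, 0.006, 1e5)
  expect_equal(var(d[, "dx"]), 2 * 1 * 0.006, tolerance = 0.03)
  d2 <- draw_displacements(0.5, 0.006, 1e5)
  expect_equal(mean(d2[, 1]^2 + d2[, 2]^2), 4 * 0.5 * 0.006, tolerance = 0.03)
})

test_that("transition kinetics reach the two-state stationary fraction", {
  set.seed(2)
  s <- rep(c(TRUE, FALSE), 500)
  expect_identical(apply_transitions(s, 0, 0), s)
  expect_error(apply_transitions(s, 1.2, 0), "\\[0, 1\\]")
  # p_fc = 0.02, p_cf = 0.001 -> stationary free fraction 0.001/0.021
  s <- rep(FALSE, 4000)
  frac <- numeric(3000)
  for (i in seq_along(frac)) {
    s <- apply_transitions(s, 0.02, 0.001)
    frac[i] <- mean(s)
  }
  expect_equal(mean(frac[1500:3000]), 0.001 / 0.021, tolerance = 0.12)
})

test_that("the k_eq-pinned parametrization holds the free fraction at every scale", {
  for (sc in c(0.2, 1, 5)) {
    p <- quick_params(k_eq = 0.05, switch_scale = sc)
    pr <- transition_probs(p)
    expect_equal(pr$stationary_free_fraction, 0.05)
  }
  # the literal 20-fold asymmetry gives 1/21
  p20 <- quick_params(ratio20 = TRUE)
  expect_equal(transition_probs(p20)$stationary_free_fraction, 1 / 21)
  expect_error(sim_params(switch_scale = 1e4), "exceeds 1")
})

test_that("a constrained agent with no transitions never leaves its cell", {
  p <- quick_params(mode = "topology", switch_scale = 1e-12, k_eq = 1e-9,
                    n_agents = 100L, n_steps = 400L)
  set.seed(3)
  ens <- init_ensemble(p)
  ens$free <- FALSE
  ens$home_i <- 0L
  ens$home_j <- 0L
  for (i in 1:400) ens <- advance_ensemble(ens, p)
  expect_true(all(ens$x_um >= 0 & ens$x_um <= 5))
  expect_true(all(ens$y_um >= 0 & ens$y_um <= 5))
  expect_true(all(!ens$free))
})

test_that("classic-mode trajectories match a barrier-free two-state mixture", {
  # with equal D for both states the mixture collapses to pure diffusion,
  # whatever the switching rate: MSD(t) ~ 4 D t
  p <- quick_params(mode = "classic", D_free_um2s = 0.8, D_con_um2s = 0.8,
                    n_agents = 1500L, n_steps = 600L, seed = 5)
  m <- run_msd_protocol(p, thin = 5L)
  expect_true(all(diff(m$time_s) > 0))
  fit_D <- estimate_deff(m, fit_fraction = 1)$value
  expect_equal(fit_D, 0.8, tolerance = 0.06)
})

test_that("MSD of fully confined agents saturates at the uniform-box level", {
  p <- quick_params(mode = "topology", switch_scale = 1e-12, k_eq = 1e-9,
                    n_agents = 2000L, n_steps = 3000L, seed = 6)
  m <- run_msd_protocol(p)
  final <- tail(m$msd_um2, 1)
  # E[(X-c)^2 + (Y-c)^2] for uniform in the 5 um box is L^2/6
  expect_equal(final, 25 / 6, tolerance = 0.08)
  mid <- m$msd_um2[length(m$msd_um2) %/% 2]
  expect_equal(final / mid, 1, tolerance = 0.05)
})

test_that("MSD protocol timing arithmetic matches the defaults", {
  p <- sim_params()
  expect_equal(p$n_steps * p$dt_s, 120)
  m <- run_msd_protocol(quick_params(n_agents = 50L, n_steps = 100L),
                        thin = 10L)
  expect_equal(m$time_s, seq(0.06, 0.6, by = 0.06))
})

test_that("D_eff recovers planted values in the classic limits", {
  # all-free single population
  p1 <- quick_params(mode = "classic", k_eq = 0.999, D_con_um2s = 1,
                     n_agents = 2000L, n_steps = 2000L, seed = 7)
  e1 <- estimate_deff(run_msd_protocol(p1))
  expect_lt(abs(e1$value - 1), 3 * e1$se)
  # fast-exchange weighted mean 0.05*1 + 0.95*0.5
  p2 <- quick_params(mode = "classic", n_agents = 2500L, n_steps = 2500L,
                     seed = 8)
  e2 <- estimate_deff(run_msd_protocol(p2))
  expect_lt(abs(e2$value - 0.525), 3 * e2$se)
})

test_that("topology-mode D_eff collapses to k_eq * D_free as switching vanishes", {
  p <- quick_params(mode = "topology", switch_scale = 1e-10,
                    n_agents = 3000L, n_steps = 2500L, seed = 9)
  e <- estimate_deff(run_msd_protocol(p))
  expect_lt(abs(e$value - 0.05), 3 * e$se + 0.005)
})

test_that("topology-mode D_eff lies between its theoretical limits", {
  p <- quick_params(mode = "topology", n_agents = 1500L, n_steps = 3000L,
                    seed = 10)
  e <- estimate_deff(run_msd_protocol(p))
  expect_gt(e$value, 0.05)
  expect_lt(e$value, 0.525)
})

test_that("flux protocol: confined-only topology yields zero flux", {
  p <- quick_params(mode = "topology", switch_scale = 1e-12, k_eq = 1e-9,
                    n_steps = 800L, source_count = 300L, seed = 11)
  j <- run_flux_protocol(p)
  expect_equal(j$value, 0)
  expect_true(all(j$count_trace == 0))
})

test_that("flux responds to the transition scale only under topology rules", {
  js <- vapply(c(0.5, 4), function(sc) {
    p <- quick_params(mode = "topology", switch_scale = sc, n_steps = 2500L,
                      source_count = 400L, seed = 12)
    run_flux_protocol(p)$value
  }, numeric(1))
  expect_gt(js[2], js[1])
  jc <- vapply(c(0.5, 4), function(sc) {
    p <- quick_params(mode = "classic", switch_scale = sc, n_steps = 2500L,
                      source_count = 400L, seed = 12)
    run_flux_protocol(p)$value
  }, numeric(1))
  # common random numbers: classic-mode estimates differ only within noise
  expect_equal(jc[2], jc[1], tolerance = 0.25)
})

test_that("sweep tables carry one row per (scale, mode) with paired seeds", {
  p <- quick_params(n_agents = 200L, n_steps = 400L, seed = 13)
  tab <- sweep_transition_scale(p, scales = c(0.5, 2),
                                modes = c("classic", "topology"))
  expect_equal(nrow(tab), 4L)
  expect_setequal(tab$mode, c("classic", "topology"))
  expect_true(all(tab$seed == 13L))
  expect_true(all(is.finite(tab$estimate)) && all(tab$se >= 0))
})

test_that("agent-count doubling shrinks the Monte-Carlo error", {
  se_at <- function(n) {
    p <- quick_params(n_agents = n, n_steps = 800L, seed = 14)
    estimate_deff(run_msd_protocol(p))$se
  }
  expect_gt(se_at(250L), se_at(2000L))
})
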