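#' Simulation parameters for the two-population lattice model
#'
#' The model follows molecules that alternate between a membrane-confined
#' ("constrained") population diffusing at `D_con_um2s` and a "free"
#' population diffusing at `D_free_um2s`. In `mode = "topology"` constrained
#' molecules are reflected at the borders of their home cell and only free
#' molecules may cross cell boundaries; in `mode = "classic"` (classic
#' hindered diffusion) neither population sees a barrier.
#'
#' Per-step transition probabilities are parameterized so the stationary free
#' fraction stays pinned at `k_eq` while `switch_scale` moves both rates
#' together: `p_con_to_free = switch_scale * p0` and
#' `p_free_to_con = switch_scale * p0 * (1 - k_eq)/k_eq`. With
#' `ratio20 = TRUE` the free-to-constrained probability is instead set to
#' exactly 20-fold the constrained-to-free probability, giving a stationary
#' free fraction of 1/21 (~5%).
#'
#' @param dt_s Time step in seconds (default 0.006).
#' @param D_free_um2s,D_con_um2s Diffusion coefficients of the free and
#'   constrained populations in um^2/s (defaults 1 and 0.5).
#' @param k_eq Equilibrium free fraction in (0, 1) (default 0.05).
#' @param switch_scale Dimensionless multiplier on both per-step transition
#'   probabilities (default 1).
#' @param p0 Base per-step constrained-to-free probability at
#'   `switch_scale = 1` (default 0.005).
#' @param ratio20 If `TRUE`, use the fixed 20:1 rate asymmetry instead of the
#'   `k_eq`-pinned parametrization.
#' @param mode `"topology"` or `"classic"`.
#' @param lattice A [lattice_spec()].
#' @param n_agents Number of agents for the MSD protocol (default 5000).
#' @param n_steps Number of time steps (default 20000, i.e. 120 s at 6 ms).
#' @param source_count Constant molecule count held in the sender cell during
#'   the flux protocol (default 2000).
#' @param seed RNG seed used by the protocols.
#' @return A `sim_params` object.
#' @export
sim_params <- function(dt_s = 0.006,
                       D_free_um2s = 1.0,
                       D_con_um2s = 0.5,
                       k_eq = 0.05,
                       switch_scale = 1.0,
                       p0 = 0.005,
                       ratio20 = FALSE,
                       mode = c("topology", "classic"),
                       lattice = lattice_spec(),
                       n_agents = 5000L,
                       n_steps = 20000L,
                       source_count = 2000L,
                       seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(dt_s > 0, D_free_um2s >= 0, D_con_um2s >= 0,
            k_eq > 0, k_eq < 1, switch_scale > 0, p0 > 0,
            n_agents > 0, n_steps > 0, source_count > 0,
            inherits(lattice, "lattice_spec"))
  p <- structure(
    list(dt_s = dt_s, D_free_um2s = D_free_um2s, D_con_um2s = D_con_um2s,
         k_eq = k_eq, switch_scale = switch_scale, p0 = p0,
         ratio20 = isTRUE(ratio20), mode = mode, lattice = lattice,
         n_agents = as.integer(n_agents), n_steps = as.integer(n_steps),
         source_count = as.integer(source_count), seed = as.integer(seed)),
    class = "sim_params"
  )
  pr <- transition_probs(p)  # validates scaled probabilities <= 1
  if (pr$p_free_to_con > 1 || pr$p_con_to_free > 1)
    stop("scaled per-step transition probability exceeds 1; reduce switch_scale or p0")
  p
}

#' @export
print.sim_params <- function(x, ...) {
  pr <- transition_probs(x)
  cat(sprintf(
    "<sim_params> %s mode, %s; dt=%g s, D=(%g free, %g con) um2/s\n  k_eq=%g, scale=%g -> p(f->c)=%.4g, p(c->f)=%.4g; %d agents x %d steps\n",
    x$mode, x$lattice$arrangement, x$dt_s, x$D_free_um2s, x$D_con_um2s,
    x$k_eq, x$switch_scale, pr$p_free_to_con, pr$p_con_to_free,
    x$n_agents, x$n_steps))
  invisible(x)
}

#' Per-step transition probabilities implied by the parameters
#'
#' @param params A [sim_params()].
#' @return List with `p_free_to_con`, `p_con_to_free`, and the implied
#'   `stationary_free_fraction`.
#' @export
transition_probs <- function(params) {
  p_cf <- params$switch_scale * params$p0
  if (params$ratio20) {
    p_fc <- 20 * p_cf
  } else {
    p_fc <- p_cf * (1 - params$k_eq) / params$k_eq
  }
  list(p_free_to_con = p_fc, p_con_to_free = p_cf,
       stationary_free_fraction = p_cf / (p_cf + p_fc))
}

#' Draw Brownian displacements
#'
#' Each axis is drawn independently from a zero-mean Gaussian with variance
#' `2 * D * dt` (um^2), the single-step law of two-dimensional Brownian
#' motion with diffusion coefficient `D`.
#'
#' @param D_um2s Diffusion coefficient in um^2/s.
#' @param dt_s Time step in seconds.
#' @param n Number of displacement pairs.
#' @return `n x 2` matrix of `(dx, dy)` in micrometres.
#' @export
draw_displacements <- function(D_um2s, dt_s, n) {
  stopifnot(D_um2s >= 0, dt_s > 0, n >= 0)
  sd <- sqrt(2 * D_um2s * dt_s)
  matrix(stats::rnorm(2 * n, mean = 0, sd = sd), ncol = 2,
         dimnames = list(NULL, c("dx", "dy")))
}

#' Apply one round of population transitions
#'
#' Each free agent becomes constrained with probability `p_free_to_con` and
#' each constrained agent becomes free with probability `p_con_to_free`; at
#' most one transition happens per agent per step. The stationary free
#' fraction of the induced two-state chain is
#' `p_con_to_free / (p_con_to_free + p_free_to_con)`.
#'
#' @param states Logical vector, `TRUE` for free agents.
#' @param p_free_to_con,p_con_to_free Per-step probabilities in `[0, 1]`.
#' @return Updated logical vector.
#' @export
apply_transitions <- function(states, p_free_to_con, p_con_to_free) {
  if (p_free_to_con > 1 || p_con_to_free > 1 ||
      p_free_to_con < 0 || p_con_to_free < 0)
    stop("transition probabilities must lie in [0, 1]")
  u <- stats::runif(length(states))
  ifelse(states, u >= p_free_to_con, u < p_con_to_free)
}

#' Initialize an agent ensemble in the sender cell
#'
#' Agents start uniformly distributed in the sender cell (cell `(0,0)` of
#' layer 0), with a fraction `k_eq` assigned to the free population and the
#' rest constrained to the sender cell.
#'
#' @param params A [sim_params()].
#' @return An `agent_ensemble` data.frame with columns `x_um`, `y_um`,
#'   `free`, `layer`, `home_i`, `home_j` (home cell defined for constrained
#'   agents only).
#' @export
init_ensemble <- function(params) {
  L <- params$lattice$cell_edge_um
  n <- params$n_agents
  free <- stats::runif(n) < params$k_eq
  ens <- data.frame(
    x_um = stats::runif(n, 0, L),
    y_um = stats::runif(n, 0, L),
    free = free,
    layer = 0L,
    home_i = ifelse(free, NA_integer_, 0L),
    home_j = ifelse(free, NA_integer_, 0L)
  )
  class(ens) <- c("agent_ensemble", "data.frame")
  ens
}

#' Advance an ensemble by one time step
#'
#' Order within a step: transitions first, then displacement. A newly
#' constrained agent takes its home cell from its current position (layer
#' chosen uniformly in bilayer arrangements); a newly freed agent moves at
#' the free coefficient immediately. In topology mode constrained agents are
#' reflected into their home cell; in classic mode no barriers apply. This is
#' the reference (vectorized R) implementation of the update rule; the
#' protocol drivers use an equivalent compiled core.
#'
#' @param ens An `agent_ensemble` from [init_ensemble()].
#' @param params A [sim_params()].
#' @return The advanced ensemble.
#' @export
advance_ensemble <- function(ens, params) {
  pr <- transition_probs(params)
  spec <- params$lattice
  L <- spec$cell_edge_um
  nl <- n_layers(spec)
  n <- nrow(ens)

  u <- stats::runif(n)
  to_con <- ens$free & (u < pr$p_free_to_con)
  to_free <- !ens$free & (u < pr$p_con_to_free)
  if (any(to_con)) {
    lay <- if (nl == 2L) {
      as.integer(stats::runif(sum(to_con)) < 0.5)
    } else 0L
    ens$layer[to_con] <- lay
    off <- vapply(ens$layer[to_con], layer_offset, numeric(1), spec = spec)
    ens$home_i[to_con] <- as.integer(floor((ens$x_um[to_con] - off) / L))
    ens$home_j[to_con] <- as.integer(floor((ens$y_um[to_con] - off) / L))
  }
  ens$free[to_con] <- FALSE
  ens$free[to_free] <- TRUE
  ens$home_i[to_free] <- NA_integer_
  ens$home_j[to_free] <- NA_integer_

  sd_step <- sqrt(2 * ifelse(ens$free, params$D_free_um2s,
                             params$D_con_um2s) * params$dt_s)
  xp <- ens$x_um + stats::rnorm(n, 0, sd_step)
  yp <- ens$y_um + stats::rnorm(n, 0, sd_step)

  refl <- !ens$free & params$mode == "topology"
  if (any(refl)) {
    off <- vapply(ens$layer[refl], layer_offset, numeric(1), spec = spec)
    ox <- ens$home_i[refl] * L + off
    oy <- ens$home_j[refl] * L + off
    xp[refl] <- ox + fold_axis(xp[refl] - ox, L)
    yp[refl] <- oy + fold_axis(yp[refl] - oy, L)
  }
  if (max(abs(c(xp, yp))) >= spec$extent_cells * L)
    stop("an agent reached the lattice extent; enlarge extent_cells")
  ens$x_um <- xp
  ens$y_um <- yp
  ens
}

#' Run the effective-diffusion (MSD) protocol
#'
#' Initializes `n_agents` in a single sender cell and evolves them for
#' `n_steps`, recording the mean squared displacement (MSD) from the sender
#' cell center at regular intervals. Agents are binned into `n_groups`
#' independent groups so the downstream slope estimate can carry a
#' Monte-Carlo (bootstrap over groups) standard error.
#'
#' @param params A [sim_params()].
#' @param thin Record the MSD every `thin` steps (default 10).
#' @param n_groups Number of agent groups retained for error estimation.
#' @return An `msd_curve` object with fields `time_s`, `msd_um2`,
#'   `group_msd` (matrix, time x group), `final_x_um`/`final_y_um` (agent
#'   endpoints, e.g. for gradient quantification), `params`.
#' @export
run_msd_protocol <- function(params, thin = 10L, n_groups = 50L) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  spec <- params$lattice
  res <- cpp_msd_protocol(
    n_agents = params$n_agents, n_steps = params$n_steps, dt = params$dt_s,
    D_free = params$D_free_um2s, D_con = params$D_con_um2s,
    p_fc = transition_probs(params)$p_free_to_con,
    p_cf = transition_probs(params)$p_con_to_free,
    L = spec$cell_edge_um,
    topology = params$mode == "topology",
    arrangement = match(spec$arrangement,
                        c("monolayer", "stacked_bilayer", "offset_bilayer")) - 1L,
    init_free_frac = if (params$ratio20) 1 / 21 else params$k_eq,
    extent = spec$extent_cells,
    thin = as.integer(thin), n_groups = as.integer(n_groups))
  structure(
    list(time_s = res$time_s,
         msd_um2 = res$msd,
         group_msd = res$group_msd,
         group_n = res$group_n,
         final_x_um = res$final_x,
         final_y_um = res$final_y,
         params = params),
    class = "msd_curve"
  )
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("<msd_curve> %d points over %.1f s; final MSD %.2f um2\n",
              length(x$time_s), max(x$time_s), utils::tail(x$msd_um2, 1)))
  invisible(x)
}

#' Effective diffusion coefficient from an MSD curve
#'
#' Fits a least-squares line to MSD versus time over the final
#' `fit_fraction` of the curve (the steady-state window) and reports
#' `D_eff = slope / 4`, from the two-dimensional relation `MSD(t) = 4 D t`.
#' The standard error is a bootstrap over the independent agent groups
#' recorded by [run_msd_protocol()].
#'
#' @param msd An `msd_curve`.
#' @param fit_fraction Fraction of the curve (from the end) used for the
#'   slope fit (default 0.5).
#' @param n_boot Bootstrap replicates for the standard error (default 200).
#' @return A `deff_estimate` list with `value` (um^2/s), `se`, `slope`,
#'   `fit_fraction`, `params`.
#' @export
estimate_deff <- function(msd, fit_fraction = 0.5, n_boot = 200L) {
  stopifnot(inherits(msd, "msd_curve"), fit_fraction > 0, fit_fraction <= 1)
  n <- length(msd$time_s)
  idx <- seq.int(from = max(1L, floor(n * (1 - fit_fraction)) + 1L), to = n)
  tt <- msd$time_s[idx]
  slope_of <- function(y) stats::cov(tt, y) / stats::var(tt)
  slope <- slope_of(msd$msd_um2[idx])
  if (!is.finite(slope)) stop("non-finite MSD slope")
  G <- ncol(msd$group_msd)
  w <- msd$group_n / sum(msd$group_n)
  boot <- replicate(n_boot, {
    g <- sample.int(G, G, replace = TRUE)
    y <- drop(msd$group_msd[idx, g, drop = FALSE] %*% (msd$group_n[g] /
                                                         sum(msd$group_n[g])))
    slope_of(y)
  })
  structure(
    list(value = slope / 4, se = stats::sd(boot) / 4, slope = slope,
         fit_fraction = fit_fraction, params = msd$params),
    class = "deff_estimate"
  )
}

#' @export
print.deff_estimate <- function(x, ...) {
  cat(sprintf("<deff_estimate> D_eff = %.4f +/- %.4f um2/s\n", x$value, x$se))
  invisible(x)
}

#' Run the effective-flux protocol
#'
#' The sender cell is held at a constant occupancy of `source_count`
#' molecules (topped up each step); molecules that leave the sender join the
#' receiver field and keep diffusing under the same rules, and molecules that
#' re-enter the sender cell are removed. The effective flux `J_eff` is the
#' steady-state slope of the number of molecules in the receiver field versus
#' time, over the final `fit_fraction` of the run.
#'
#' @param params A [sim_params()] (use `n_steps = 40000` for the full 240 s
#'   protocol).
#' @param fit_fraction Final fraction of the count trace used for the slope.
#' @param thin Record the field count every `thin` steps.
#' @return A `jeff_estimate` list with `value` (molecules/s), `se`,
#'   `count_trace`, `time_s`, `params`.
#' @export
run_flux_protocol <- function(params, fit_fraction = 0.5, thin = 10L) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  spec <- params$lattice
  res <- cpp_flux_protocol(
    source_count = params$source_count, n_steps = params$n_steps,
    dt = params$dt_s,
    D_free = params$D_free_um2s, D_con = params$D_con_um2s,
    p_fc = transition_probs(params)$p_free_to_con,
    p_cf = transition_probs(params)$p_con_to_free,
    L = spec$cell_edge_um,
    topology = params$mode == "topology",
    arrangement = match(spec$arrangement,
                        c("monolayer", "stacked_bilayer", "offset_bilayer")) - 1L,
    init_free_frac = if (params$ratio20) 1 / 21 else params$k_eq,
    extent = spec$extent_cells,
    thin = as.integer(thin))
  tt <- res$time_s
  ct <- res$field_count
  n <- length(tt)
  idx <- seq.int(from = max(1L, floor(n * (1 - fit_fraction)) + 1L), to = n)
  slope <- stats::cov(tt[idx], ct[idx]) / stats::var(tt[idx])
  # block-wise slopes over the steady-state window give a Monte-Carlo SE
  nb <- 8L
  blocks <- split(idx, cut(seq_along(idx), nb, labels = FALSE))
  bs <- vapply(blocks, function(ii) {
    if (length(ii) < 3L) return(NA_real_)
    stats::cov(tt[ii], ct[ii]) / stats::var(tt[ii])
  }, numeric(1))
  bs <- bs[is.finite(bs)]
  structure(
    list(value = slope, se = stats::sd(bs) / sqrt(length(bs)),
         count_trace = ct, time_s = tt, fit_fraction = fit_fraction,
         params = params),
    class = "jeff_estimate"
  )
}

#' @export
print.jeff_estimate <- function(x, ...) {
  cat(sprintf("<jeff_estimate> J_eff = %.2f +/- %.2f molecules/s\n",
              x$value, x$se))
  invisible(x)
}

#' Sweep the transition-rate scale
#'
#' Runs the effective-diffusion (or effective-flux) protocol over a grid of
#' `switch_scale` values for one or both barrier modes, reusing the same seed
#' across modes at each scale so mode contrasts are paired.
#'
#' @param params A baseline [sim_params()]; its `switch_scale` is overridden.
#' @param scales Positive numeric vector of scale multipliers.
#' @param modes Character vector among `"classic"`, `"topology"`.
#' @param protocol `"deff"` or `"jeff"`.
#' @param ... Passed to [run_msd_protocol()] / [run_flux_protocol()].
#' @return Data frame with one row per (scale, mode): columns `scale`,
#'   `mode`, `arrangement`, `k_eq`, `cell_edge_um`, `estimate`, `se`,
#'   `n_agents`, `n_steps`, `seed`.
#' @export
sweep_transition_scale <- function(params, scales,
                                   modes = c("classic", "topology"),
                                   protocol = c("deff", "jeff"), ...) {
  protocol <- match.arg(protocol)
  stopifnot(all(scales > 0))
  modes <- match.arg(modes, c("classic", "topology"), several.ok = TRUE)
  rows <- list()
  for (s in scales) {
    for (m in modes) {
      p <- unclass(params)
      p$switch_scale <- s
      p$mode <- m
      p <- do.call(sim_params, p)
      est <- if (protocol == "deff") {
        estimate_deff(run_msd_protocol(p, ...))
      } else {
        run_flux_protocol(p, ...)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        scale = s, mode = m, arrangement = p$lattice$arrangement,
        k_eq = p$k_eq, cell_edge_um = p$lattice$cell_edge_um,
        estimate = est$value, se = est$se,
        n_agents = p$n_agents, n_steps = p$n_steps, seed = p$seed)
    }
  }
  do.call(rbind, rows)
}
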