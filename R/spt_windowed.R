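#' Diffusion / localization-error evaluation grid
#'
#' Log-spaced grid of candidate diffusion coefficients and a linear grid of
#' candidate localization errors over which windowed likelihoods are
#' evaluated (the error axis is marginalized with a uniform prior).
#'
#' @param D_min,D_max Diffusion range in um^2/s (defaults 0.01 and 100).
#' @param n_D Number of log-spaced diffusion values (default 101).
#' @param sigma_min,sigma_max Localization-error range in um (defaults 0.025
#'   and 0.05).
#' @param n_sigma Number of error values (default 6).
#' @return A `diffusion_grid` object with vectors `D_um2s`, `sigma_um`.
#' @export
diffusion_grid <- function(D_min = 0.01, D_max = 100, n_D = 101L,
                           sigma_min = 0.025, sigma_max = 0.05,
                           n_sigma = 6L) {
  stopifnot(D_min > 0, D_max > D_min, n_D >= 2,
            sigma_min > 0, sigma_max >= sigma_min, n_sigma >= 1)
  structure(
    list(D_um2s = exp(seq(log(D_min), log(D_max), length.out = n_D)),
         sigma_um = seq(sigma_min, sigma_max, length.out = n_sigma)),
    class = "diffusion_grid")
}

# Grid log-likelihood machinery. A window of n frame intervals with summed
# squared displacement S = sum(dx^2 + dy^2) has, under per-axis variance
# v = 2 D dt + 2 sigma^2, log-likelihood  -n log(2 pi v) - S / (2 v)
# (both axes combined); (n, S) are sufficient.
window_grid_mle <- function(S, n, frame_dt, grid) {
  v <- outer(2 * grid$D_um2s * frame_dt, 2 * grid$sigma_um^2, "+")  # nD x nS
  const <- -n * log(2 * pi * v)            # nD x nS (n scalar)
  inv2v <- 1 / (2 * v)
  n_win <- length(S)
  out <- numeric(n_win)
  chunk <- 2000L
  for (lo in seq(1L, n_win, by = chunk)) {
    hi <- min(lo + chunk - 1L, n_win)
    Sc <- S[lo:hi]
    best <- NULL
    # log-marginal over sigma (uniform prior), per D, via logsumexp
    ll_D <- matrix(-Inf, length(Sc), length(grid$D_um2s))
    for (d in seq_along(grid$D_um2s)) {
      m <- outer(Sc, -inv2v[d, ]) +
        matrix(const[d, ], length(Sc), ncol(v), byrow = TRUE)
      mx <- apply(m, 1, max)
      ll_D[, d] <- mx + log(rowSums(exp(m - mx)))
    }
    out[lo:hi] <- grid$D_um2s[max.col(ll_D, ties.method = "first")]
  }
  out
}

#' Windowed maximum-likelihood diffusion coefficient
#'
#' Evaluates the likelihood of a window's two-dimensional displacements under
#' per-axis variance `2 * D * frame_dt + 2 * sigma^2` on the `(D, sigma)`
#' grid, marginalizes over the localization error with a uniform prior, and
#' returns the grid `D` maximizing the marginal likelihood.
#'
#' @param dx,dy Displacements (um) of the window's frame intervals.
#' @param frame_dt Frame interval in seconds.
#' @param grid A [diffusion_grid()].
#' @param min_intervals Minimum number of intervals required (default 3).
#' @return Scalar maximum-likelihood `D` (um^2/s) on the grid.
#' @export
window_mle_diffusion <- function(dx, dy, frame_dt, grid = diffusion_grid(),
                                 min_intervals = 3L) {
  n <- length(dx)
  stopifnot(length(dy) == n)
  if (n < min_intervals)
    stop("window has ", n, " intervals; at least ", min_intervals,
         " are required")
  window_grid_mle(sum(dx^2 + dy^2), n, frame_dt, grid)
}

# rolling-window sufficient statistics for every track: for window length w
# (in intervals), one window per start position (step 1)
rolling_window_stats <- function(tracks, w) {
  disp <- track_displacements(tracks)
  if (nrow(disp) == 0)
    return(data.frame(track_id = integer(), start = integer(), S = numeric()))
  r2 <- disp$dx^2 + disp$dy^2
  by_track <- split(r2, disp$track_id)
  res <- lapply(names(by_track), function(id) {
    v <- by_track[[id]]
    if (length(v) < w) return(NULL)
    S <- as.numeric(stats::filter(v, rep(1, w), sides = 1))[w:length(v)]
    data.frame(track_id = as.integer(id), start = seq_along(S) - 1L, S = S)
  })
  do.call(rbind, res[!vapply(res, is.null, logical(1))])
}

#' Diffusion-rate histograms across integration windows
#'
#' Decomposes every track into rolling windows of each requested length,
#' computes the windowed maximum-likelihood diffusion coefficient for each
#' window, and bins the estimates on a log10 axis. Populations visible at
#' the shortest windows approximate pure diffusive states; mass appearing at
#' intermediate coefficients only in longer windows reflects molecules that
#' switched state inside the window.
#'
#' @param tracks A `track_set`.
#' @param window_lengths Integer vector of window lengths in frame intervals
#'   (each at least 3; the 18 ms regime at 6 ms frames is length 3).
#' @param frame_dt Frame interval in seconds (defaults to the track set's).
#' @param grid A [diffusion_grid()].
#' @param n_bins Number of log10-D histogram bins (default 60).
#' @return A `diffusion_histograms` list: `estimates` (data.frame with
#'   `window`, `track_id`, `start`, `D_hat`), `histogram` (data.frame with
#'   `window`, `bin_center_log10D`, `count`, `density`), `breaks`.
#' @export
diffusion_histograms <- function(tracks, window_lengths = c(3L, 5L, 8L, 12L),
                                 frame_dt = NULL, grid = diffusion_grid(),
                                 n_bins = 60L) {
  if (is.null(frame_dt)) frame_dt <- attr(tracks, "frame_dt_s")
  stopifnot(is.finite(frame_dt), all(window_lengths >= 3L))
  est <- lapply(window_lengths, function(w) {
    st <- rolling_window_stats(tracks, w)
    if (nrow(st) == 0) return(NULL)
    st$D_hat <- window_grid_mle(st$S, w, frame_dt, grid)
    st$window <- w
    st
  })
  est <- do.call(rbind, est[!vapply(est, is.null, logical(1))])
  breaks <- seq(log10(min(grid$D_um2s)), log10(max(grid$D_um2s)),
                length.out = n_bins + 1L)
  hist_df <- do.call(rbind, lapply(split(est, est$window), function(e) {
    h <- graphics::hist(log10(e$D_hat), breaks = breaks, plot = FALSE)
    data.frame(window = e$window[1], bin_center_log10D = h$mids,
               count = h$counts, density = h$counts / sum(h$counts))
  }))
  rownames(hist_df) <- NULL
  structure(list(estimates = est, histogram = hist_df, breaks = breaks,
                 frame_dt = frame_dt),
            class = "diffusion_histograms")
}

#' @export
print.diffusion_histograms <- function(x, ...) {
  tab <- table(x$estimates$window)
  cat("<diffusion_histograms> windows (intervals): ",
      paste(sprintf("%s (%d est.)", names(tab), as.integer(tab)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Instantaneous diffusion coloring of a track
#'
#' For each localization, the maximum-likelihood diffusion coefficient of the
#' centered 4-interval rolling window (-2:+2 localizations around it),
#' shrinking at the track ends; used to color trajectories by local mobility.
#'
#' @param tracks A `track_set`.
#' @param frame_dt Frame interval in seconds (defaults to the track set's).
#' @param grid A [diffusion_grid()].
#' @param half_width Localizations on each side of the center (default 2).
#' @return Data frame `track_id`, `frame`, `D_local`.
#' @export
local_diffusion_coefficients <- function(tracks, frame_dt = NULL,
                                         grid = diffusion_grid(),
                                         half_width = 2L) {
  if (is.null(frame_dt)) frame_dt <- attr(tracks, "frame_dt_s")
  df <- as.data.frame(tracks)
  df <- df[order(df$track_id, df$frame), ]
  out <- lapply(split(df, df$track_id), function(tr) {
    n <- nrow(tr)
    dx <- diff(tr$x_um); dy <- diff(tr$y_um)
    r2 <- dx^2 + dy^2
    D <- vapply(seq_len(n), function(i) {
      lo <- max(1L, i - half_width)
      hi <- min(n - 1L, i + half_width - 1L)
      if (hi < lo) return(NA_real_)
      window_grid_mle(sum(r2[lo:hi]), hi - lo + 1L, frame_dt, grid)
    }, numeric(1))
    data.frame(track_id = tr$track_id, frame = tr$frame, D_local = D)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
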