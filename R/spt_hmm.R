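#' Localization error from displacement autocovariance
#'
#' For Brownian motion observed with independent static localization error,
#' successive displacements of the same track satisfy
#' `Cov(dx_t, dx_{t+1}) = -sigma^2` regardless of the diffusive state, so the
#' pooled lag-1 displacement autocovariance identifies the per-axis error SD
#' even for state-switching mixtures. The estimate is clamped to
#' `[lower, upper]` (the plausible error band of the instrument).
#'
#' @param tracks A `track_set`.
#' @param lower,upper Bounds on the returned SD in um (defaults 0.025, 0.05).
#' @return Scalar localization error SD in um.
#' @export
estimate_loc_error <- function(tracks, lower = 0.025, upper = 0.05) {
  disp <- track_displacements(tracks)
  if (nrow(disp) < 2) return((lower + upper) / 2)
  same <- c(disp$track_id[-1] == disp$track_id[-nrow(disp)], FALSE)
  idx <- which(same)
  if (length(idx) == 0) return((lower + upper) / 2)
  prods <- c(disp$dx[idx] * disp$dx[idx + 1L],
             disp$dy[idx] * disp$dy[idx + 1L])
  s2 <- -mean(prods)
  min(max(sqrt(max(s2, 0)), lower), upper)
}

# emission log-density matrix: displacement rows x K states, per-axis
# variance v_k = 2 D_k dt + 2 sigma^2, both axes independent
emission_loglik <- function(dx, dy, v) {
  r2 <- dx^2 + dy^2
  vapply(v, function(vk) -log(2 * pi * vk) - r2 / (2 * vk),
         numeric(length(r2)))
}

em_once <- function(dx, dy, tlen, v0, A0, pi0, dt, sigma,
                    max_iter, tol) {
  K <- length(v0)
  v <- v0; A <- A0; pi <- pi0
  v_floor <- 2 * sigma^2 + 2 * 1e-4 * dt    # D floor of 1e-4 um2/s
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  r2 <- dx^2 + dy^2
  fb <- NULL
  for (iter in seq_len(max_iter)) {
    logB <- emission_loglik(dx, dy, v)
    fb <- cpp_forward_backward(logB, tlen, pi, A)
    if (abs(fb$loglik - ll_old) < tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- fb$loglik
    g <- fb$gamma
    v <- pmax(colSums(g * r2) / (2 * colSums(g)), v_floor)
    A <- fb$xi / pmax(rowSums(fb$xi), .Machine$double.eps)
    A <- A / rowSums(A)
    pi <- fb$gamma0 / sum(fb$gamma0)
  }
  list(v = v, A = A, pi = pi, loglik = fb$loglik,
       occupancy = colMeans(fb$gamma), converged = converged, iter = iter)
}

#' Fit a K-state displacement hidden Markov model
#'
#' Expectation-maximization over per-frame displacement emissions: in state
#' `k` the per-axis displacement is Gaussian with variance
#' `2 * D_k * frame_dt + 2 * sigma^2`, the hidden state follows a per-frame
#' Markov chain (at most one transition per frame interval), and `sigma` is a
#' single shared localization error fitted within bounds from the lag-1
#' displacement autocovariance ([estimate_loc_error()]) and held fixed during
#' EM. Several restarts are run (the first initialized from quantiles of the
#' windowed-MLE distribution, the rest jittered) and the best likelihood is
#' kept. States are reported in descending-D order.
#'
#' @param tracks A `track_set`; tracks shorter than 3 or longer than 100
#'   detections are dropped before fitting.
#' @param K Number of states (at least 1).
#' @param frame_dt Frame interval in seconds (defaults to the track set's).
#' @param sigma Localization error SD; `NULL` (default) estimates it from
#'   the data within `sigma_bounds`.
#' @param sigma_bounds Clamp interval for the fitted error.
#' @param n_restarts EM restarts (default 5).
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @param seed RNG seed for restart jitter.
#' @return An `hmm_fit` object: `D_um2s`, `occupancy`, `A` (per-frame
#'   transition matrix), `lifetime_s`, `sigma_um`, `loglik`, `pi0`,
#'   `converged`, `n_tracks`, `n_displacements`.
#' @export
fit_state_hmm <- function(tracks, K = 4L, frame_dt = NULL, sigma = NULL,
                          sigma_bounds = c(0.025, 0.05), n_restarts = 5L,
                          max_iter = 300L, tol = 1e-7, seed = 1L) {
  if (is.null(frame_dt)) frame_dt <- attr(tracks, "frame_dt_s")
  stopifnot(is.finite(frame_dt), K >= 1)
  df <- as.data.frame(tracks)
  len <- table(df$track_id)
  keep <- names(len)[len >= 3 & len <= 100]
  df <- df[df$track_id %in% keep, ]
  tr <- as_track_set(df, frame_dt_s = frame_dt, validate = FALSE)
  disp <- track_displacements(tr)
  if (nrow(disp) < 10 * K)
    stop("too few displacements (", nrow(disp), ") to fit ", K, " states")
  tlen <- as.integer(table(factor(disp$track_id,
                                  levels = unique(disp$track_id))))
  if (is.null(sigma))
    sigma <- estimate_loc_error(tr, sigma_bounds[1], sigma_bounds[2])

  set.seed(seed)
  # initialization from quantiles of short-window MLEs
  st <- rolling_window_stats(tr, 3L)
  D_win <- window_grid_mle(st$S, 3L, frame_dt, diffusion_grid())
  qs <- stats::quantile(log(D_win), probs = seq(0.1, 0.9, length.out = K))
  D_init <- sort(exp(qs), decreasing = TRUE)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    D0 <- if (r == 1) D_init else D_init * exp(stats::rnorm(K, 0, 0.5))
    v0 <- 2 * D0 * frame_dt + 2 * sigma^2
    A0 <- matrix(0.05 / max(K - 1, 1), K, K)
    diag(A0) <- 1 - 0.05
    if (K == 1) A0 <- matrix(1, 1, 1)
    pi0 <- rep(1 / K, K)
    fit <- em_once(disp$dx, disp$dy, tlen, v0, A0, pi0, frame_dt, sigma,
                   max_iter, tol)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  D <- pmax((best$v - 2 * sigma^2) / (2 * frame_dt), 0)
  ord <- order(D, decreasing = TRUE)
  A <- best$A[ord, ord, drop = FALSE]
  structure(
    list(D_um2s = D[ord], occupancy = best$occupancy[ord], A = A,
         lifetime_s = state_lifetimes(A, frame_dt),
         sigma_um = sigma, loglik = best$loglik, pi0 = best$pi[ord],
         converged = best$converged, iterations = best$iter,
         frame_dt_s = frame_dt,
         n_tracks = length(tlen), n_displacements = nrow(disp)),
    class = "hmm_fit")
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat(sprintf(
    "<hmm_fit> K=%d on %d tracks (%d displacements), sigma=%.3f um, logLik=%.1f%s\n",
    length(x$D_um2s), x$n_tracks, x$n_displacements, x$sigma_um, x$loglik,
    if (x$converged) "" else " [NOT CONVERGED]"))
  print(data.frame(D_um2s = x$D_um2s, occupancy = x$occupancy,
                   lifetime_s = x$lifetime_s), row.names = FALSE)
  invisible(x)
}

#' Delete-10% jackknife over tracks
#'
#' Splits the tracks into `folds` disjoint subsets (deterministically from
#' `seed`), repeats the fit leaving one subset out at a time, aligns the
#' replicate states by descending D, and reports the per-parameter replicate
#' mean and spread.
#'
#' @param tracks A `track_set`.
#' @param fit_fun Function of a `track_set` returning an `hmm_fit` (e.g. a
#'   partial application of [fit_state_hmm()]).
#' @param folds Number of folds (default 10).
#' @param seed Seed for the fold assignment.
#' @return A `jackknife_result`: `replicates` (long data.frame: `fold`,
#'   `parameter`, `state`, `value`, `converged`), `summary` (per-parameter
#'   mean, sd, min, max).
#' @export
jackknife_intervals <- function(tracks, fit_fun, folds = 10L, seed = 1L) {
  ids <- unique(as.data.frame(tracks)$track_id)
  stopifnot(length(ids) >= folds)
  set.seed(seed)
  fold_of <- sample(rep_len(seq_len(folds), length(ids)))
  names(fold_of) <- ids
  reps <- list()
  for (f in seq_len(folds)) {
    keep_ids <- ids[fold_of != f]
    sub <- as.data.frame(tracks)
    sub <- sub[sub$track_id %in% keep_ids, ]
    fit <- fit_fun(as_track_set(sub, frame_dt_s = attr(tracks, "frame_dt_s"),
                                validate = FALSE))
    K <- length(fit$D_um2s)
    reps[[f]] <- rbind(
      data.frame(fold = f, parameter = "D_um2s", state = seq_len(K),
                 value = fit$D_um2s, converged = fit$converged),
      data.frame(fold = f, parameter = "occupancy", state = seq_len(K),
                 value = fit$occupancy, converged = fit$converged),
      data.frame(fold = f, parameter = "lifetime_s", state = seq_len(K),
                 value = fit$lifetime_s, converged = fit$converged))
  }
  rep_df <- do.call(rbind, reps)
  key <- interaction(rep_df$parameter, rep_df$state)
  summ <- do.call(rbind, lapply(split(rep_df, key), function(d) {
    data.frame(parameter = d$parameter[1], state = d$state[1],
               mean = mean(d$value), sd = stats::sd(d$value),
               min = min(d$value), max = max(d$value))
  }))
  rownames(summ) <- NULL
  structure(list(replicates = rep_df, summary = summ, folds = folds),
            class = "jackknife_result")
}

#' @export
print.jackknife_result <- function(x, ...) {
  cat(sprintf("<jackknife_result> %d folds\n", x$folds))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
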