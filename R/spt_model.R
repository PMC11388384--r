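#' Diffusive-state model for Markov-switching Brownian motion
#'
#' A molecule alternates among `K` Brownian states with diffusion
#' coefficients `D_um2s`, switching once per frame at most according to the
#' per-frame transition matrix `A`; localized positions carry independent
#' Gaussian error with per-axis standard deviation `sigma_loc_um`.
#'
#' @param D_um2s Numeric vector of state diffusion coefficients (um^2/s),
#'   sorted descending.
#' @param pi Stationary occupancies (must satisfy `pi %*% A = pi`).
#' @param A Per-frame transition probability matrix (rows sum to 1).
#' @param sigma_loc_um Localization error SD per axis (default 0.035).
#' @return A `state_model` object.
#' @export
diffusive_state_model <- function(D_um2s, pi, A, sigma_loc_um = 0.035) {
  K <- length(D_um2s)
  A <- as.matrix(A)
  stopifnot(K >= 1, length(pi) == K, all(dim(A) == K),
            all(A >= 0), all(abs(rowSums(A) - 1) < 1e-10),
            all(pi >= 0), abs(sum(pi) - 1) < 1e-10,
            sigma_loc_um >= 0)
  if (is.unsorted(rev(D_um2s)))
    stop("D_um2s must be sorted in descending order")
  if (max(abs(drop(pi %*% A) - pi)) > 1e-8)
    stop("pi is not stationary under A (pi %*% A != pi)")
  structure(list(K = K, D_um2s = as.numeric(D_um2s), pi = as.numeric(pi),
                 A = A, sigma_loc_um = sigma_loc_um),
            class = "state_model")
}

#' @export
print.state_model <- function(x, ...) {
  cat(sprintf("<state_model> K=%d, sigma_loc=%g um\n", x$K, x$sigma_loc_um))
  df <- data.frame(D_um2s = x$D_um2s, occupancy = x$pi,
                   self_transition = diag(x$A))
  print(df, row.names = FALSE)
  invisible(x)
}

# Build the unique reversible per-frame chain with stationary pi and mean
# state lifetimes controlled by `exit_prob` = per-frame exit probabilities:
# off-diagonal A[k, j] proportional to pi[j], scaled so row k exits with
# exit_prob[k]. Detailed balance is not required by the model; this is just a
# convenient construction that is exactly stationary for pi.
chain_with_lifetimes <- function(pi, exit_prob) {
  K <- length(pi)
  A <- matrix(0, K, K)
  for (k in seq_len(K)) {
    w <- pi
    w[k] <- 0
    A[k, ] <- exit_prob[k] * w / sum(w)
    A[k, k] <- 1 - exit_prob[k]
  }
  # rebalance so pi is exactly stationary: symmetrize flows pairwise
  F <- diag(pi) %*% A                     # flow matrix pi_k * A_kj
  Fs <- (F + t(F)) / 2                    # detailed-balanced flows
  A <- sweep(Fs, 1, pi, "/")
  diag(A) <- 0
  diag(A) <- 1 - rowSums(A)
  A
}

#' Default four-state SHH diffusion model
#'
#' The four diffusive populations observed for extracellularly tracked
#' SHH-Halo: fast extracellular diffusion (~20 um^2/s), cholesterol-anchored
#' membrane diffusion (~1 um^2/s), receptor/membrane-protein-bound diffusion
#' (~0.2 um^2/s) and a near-immobile matrix-associated state (below
#' 0.1 um^2/s, represented here as 0.05). Occupancies and lifetimes are
#' adjustable placeholders (the published occupancies are graphical only):
#' defaults are occupancies (0.10, 0.40, 0.30, 0.20) and per-frame exit
#' probabilities giving mean lifetimes of tens of milliseconds.
#'
#' @param occupancies Stationary occupancies (length 4, sums to 1).
#' @param lifetimes_s Mean state lifetimes in seconds (length 4).
#' @param frame_dt_s Frame interval the transition matrix is expressed in.
#' @param sigma_loc_um Localization error SD per axis.
#' @return A `state_model` with `K = 4` and
#'   `D = (20, 1, 0.2, 0.05)` um^2/s.
#' @export
default_shh_state_model <- function(occupancies = c(0.10, 0.40, 0.30, 0.20),
                                    lifetimes_s = c(0.030, 0.060, 0.060, 0.060),
                                    frame_dt_s = 0.006,
                                    sigma_loc_um = 0.035) {
  stopifnot(length(occupancies) == 4, length(lifetimes_s) == 4,
            all(lifetimes_s > frame_dt_s))
  occupancies <- occupancies / sum(occupancies)
  exit_prob <- pmin(frame_dt_s / lifetimes_s, 0.5)
  A <- chain_with_lifetimes(occupancies, exit_prob)
  diffusive_state_model(D_um2s = c(20, 1, 0.2, 0.05), pi = occupancies,
                        A = A, sigma_loc_um = sigma_loc_um)
}

#' Single-state model for secreted HaloTag alone
#'
#' Secreted HaloTag with no SHH moieties diffuses as a single fast
#' (~20 um^2/s) population.
#'
#' @param sigma_loc_um Localization error SD per axis.
#' @return A one-state `state_model` with `D = 20` um^2/s.
#' @export
secreted_halo_model <- function(sigma_loc_um = 0.035) {
  diffusive_state_model(D_um2s = 20, pi = 1,
                        A = matrix(1, 1, 1), sigma_loc_um = sigma_loc_um)
}

#' Scale all transition rates by a catalysis factor
#'
#' Multiplies every off-diagonal entry of the per-frame transition matrix by
#' `f` (adjusting the diagonal), which divides each state's mean lifetime by
#' `f` while leaving the stationary occupancies exactly unchanged — the
#' signature of a transition catalyst such as SCUBE1.
#'
#' @param model A `state_model`.
#' @param f Positive scale factor; must keep every diagonal nonnegative.
#' @return The rescaled `state_model`.
#' @export
scale_transition_rates <- function(model, f) {
  stopifnot(inherits(model, "state_model"), f > 0)
  A2 <- diag(model$K) + f * (model$A - diag(model$K))
  if (any(diag(A2) < 0))
    stop("f is too large: a per-frame exit probability would exceed 1")
  diffusive_state_model(model$D_um2s, model$pi, A2, model$sigma_loc_um)
}

#' Mean state lifetimes implied by a per-frame transition matrix
#'
#' The per-frame dwell in state `k` is geometric with continuation
#' probability `A[k, k]`, so the mean lifetime is
#' `frame_dt / (1 - A[k, k])`; a state with `A[k, k] = 1` has infinite
#' lifetime.
#'
#' @param A Per-frame transition probability matrix.
#' @param frame_dt_s Frame interval in seconds.
#' @return Numeric vector of lifetimes in seconds (possibly `Inf`).
#' @export
state_lifetimes <- function(A, frame_dt_s) {
  A <- as.matrix(A)
  stopifnot(all(abs(rowSums(A) - 1) < 1e-8), frame_dt_s > 0)
  frame_dt_s / (1 - diag(A))
}
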