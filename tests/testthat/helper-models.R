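# shared fixtures: small models and parameter sets built in code

two_state_model <- function(D = c(5, 0.1), pi = c(0.5, 0.5),
                            exit = c(0.1, 0.1), sigma = 0.03) {
  A <- matrix(c(1 - exit[1], exit[1],
                exit[2], 1 - exit[2]), 2, 2, byrow = TRUE)
  # make pi stationary for unequal occupancies via detailed balance
  if (abs(pi[1] - pi[2]) > 1e-12) {
    A[1, 2] <- exit[1]
    A[2, 1] <- exit[1] * pi[1] / pi[2]
    A[1, 1] <- 1 - A[1, 2]
    A[2, 2] <- 1 - A[2, 1]
  }
  diffusive_state_model(D, pi, A, sigma)
}

quick_params <- function(...) {
  args <- list(...)
  defaults <- list(n_agents = 500L, n_steps = 1500L, seed = 42L)
  do.call(sim_params, utils::modifyList(defaults, args))
}

# closed-form single-state diffusion estimator from pooled displacements:
# D = sum(|dr|^2) / (4 n dt) - sigma^2 / dt
closed_form_D <- function(dx, dy, dt, sigma) {
  sum(dx^2 + dy^2) / (4 * length(dx) * dt) - sigma^2 / dt
}
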