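# Small fixture networks used across test files.

two_neuron_spec <- function(mu = 0.02, tau = 25, tau_a = 1000, eta = 0) {
  build_network(matrix(c(1, 2), ncol = 1), mu = mu, tau = tau,
                tau_a = tau_a, eta = eta)
}

ten_neuron_spec <- function(mu = 0.2, tau = 5, tau_a = 1000, eta = 0) {
  build_network(matrix(1:10, ncol = 1), mu = mu, tau = tau,
                tau_a = tau_a, eta = eta)
}

random_spec <- function(N = 5, M = 3, mu = 0.1, tau = 5, tau_a = 500,
                        eta = 0, seed = 1) {
  set.seed(seed)
  build_network(matrix(rnorm(N * M), N, M), mu = mu, tau = tau,
                tau_a = tau_a, eta = eta)
}

# brute-force objective evaluation, independent of the package internals
brute_objective <- function(phi, phi_hat, f, mu) {
  sum((phi - phi_hat)^2) + mu * sum(f^2)
}
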