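#' Random recurrent LIF baseline network
#'
#' The generic comparison network: N leaky integrate-and-fire neurons with
#' feedforward weights drawn uniformly from [-1, 1] (N x M) and recurrent
#' weights drawn from a zero-mean Gaussian (default sd 0.87), except the
#' autapse of each neuron, which is set to the negative sum of squares of
#' its feedforward weights. Nothing about this network is derived from the
#' cost-accuracy objective; its stimulus estimate comes from a separately
#' trained linear decoder.
#'
#' @param N Number of neurons.
#' @param M Stimulus dimension.
#' @param recurrent_sd Standard deviation of the off-diagonal recurrent
#'   weights.
#' @param tau Membrane/decoder time constant in ms.
#' @param seed Integer seed (required).
#' @return Object of class \code{baseline_network}: list with \code{F_ff}
#'   (N x M feedforward weights), \code{R} (N x N recurrent weights),
#'   \code{tau}, \code{threshold} (base spiking threshold, 1), \code{N},
#'   \code{M}, \code{seed}.
#' @export
build_random_baseline <- function(N = 400, M = 7, recurrent_sd = 0.87,
                                  tau = 5, seed) {
  if (missing(seed)) stop("seed is required for the random baseline")
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  F_ff <- matrix(stats::runif(N * M, -1, 1), N, M)
  R <- matrix(stats::rnorm(N * N, 0, recurrent_sd), N, N)
  diag(R) <- -rowSums(F_ff^2)
  structure(list(F_ff = F_ff, R = R, tau = tau, threshold = 1,
                 N = N, M = M, seed = as.integer(seed)),
            class = "baseline_network")
}

#' @export
print.baseline_network <- function(x, ...) {
  cat(sprintf(
    "Random LIF baseline: N = %d, M = %d, tau = %g ms, seed = %d\n",
    x$N, x$M, x$tau, x$seed))
  invisible(x)
}

#' Simulate the baseline LIF network
#'
#' Standard grid-based LIF dynamics: forward-Euler leak and feedforward
#' drive, all neurons above threshold spike in a step (volleys allowed),
#' each spike delivers the spiker's full recurrent weight column, including
#' the negative autapse, which acts as the reset. With \code{adaptive = TRUE}
#' the spiking threshold is dynamically regulated by past activity:
#' \code{1 + mu * f_i(t)} with f the spike train filtered at tau_a; this is
#' the spike-frequency-adaptation variant that ruins the fixed decoder.
#'
#' @param net A \code{baseline_network}.
#' @param stimulus A \code{stimulus_trace} with matching M.
#' @param adaptive Use the activity-regulated threshold?
#' @param mu Threshold-adaptation weight (used when adaptive).
#' @param tau_a Adaptation time constant in ms.
#' @param dt Time step in ms (must equal the stimulus step).
#' @param record Per-step traces to keep: subset of c("V", "r", "f"); the
#'   filtered rates r are always recorded (they feed the decoder).
#' @return List of class \code{baseline_result} with \code{raster},
#'   \code{r_trace} (N x T), optional \code{V_trace}, \code{f_trace},
#'   \code{time}, \code{dt}, \code{final_state}.
#' @export
simulate_baseline <- function(net, stimulus, adaptive = FALSE, mu = 0.02,
                              tau_a = 2000, dt = stimulus$dt,
                              record = character(0)) {
  stopifnot(inherits(net, "baseline_network"),
            inherits(stimulus, "stimulus_trace"))
  if (nrow(stimulus$values) != net$M) stop("stimulus dimension mismatch")
  if (!isTRUE(all.equal(dt, stimulus$dt))) {
    stop("dt must equal the stimulus sampling step")
  }
  N <- net$N
  TT <- ncol(stimulus$values)
  FF <- net$F_ff %*% stimulus$values          # N x T feedforward drive
  h <- dt / net$tau
  dec_r <- exp(-h)
  dec_f <- exp(-dt / tau_a)

  keep_V <- "V" %in% record
  keep_f <- "f" %in% record
  V_tr <- if (keep_V) matrix(0, N, TT)
  f_tr <- if (keep_f) matrix(0, N, TT)
  r_tr <- matrix(0, N, TT)

  V <- numeric(N); r <- numeric(N); f <- numeric(N)
  sp_n <- vector("list", TT); sp_t <- vector("list", TT)
  any_sp <- FALSE

  for (k in seq_len(TT)) {
    r <- r * dec_r
    f <- f * dec_f
    V <- V + h * (-V + FF[, k])
    thr <- if (adaptive) net$threshold + mu * f else net$threshold
    sp <- which(V > thr)
    if (length(sp) > 0L) {
      kick <- if (length(sp) == 1L) net$R[, sp] else rowSums(net$R[, sp])
      V <- V + kick
      r[sp] <- r[sp] + 1
      f[sp] <- f[sp] + 1
      sp_n[[k]] <- sp
      sp_t[[k]] <- rep((k - 1L) * dt, length(sp))
      any_sp <- TRUE
    }
    if (keep_V) V_tr[, k] <- V
    if (keep_f) f_tr[, k] <- f
    r_tr[, k] <- r
    if (!all(is.finite(V))) {
      stop(sprintf("non-finite voltage at t = %g ms", (k - 1L) * dt))
    }
  }
  raster <- if (any_sp) {
    data.frame(neuron = unlist(sp_n), time_ms = unlist(sp_t))
  } else {
    data.frame(neuron = integer(0), time_ms = numeric(0))
  }
  structure(list(raster = raster, r_trace = r_tr,
                 V_trace = V_tr, f_trace = f_tr,
                 time = stimulus$time, dt = dt,
                 final_state = list(V = V, r = r, f = f)),
            class = "baseline_result")
}

ring_thetas <- function(n) {
  # n preferred orientations evenly spaced over (-pi/2, pi/2]
  -pi / 2 + pi * seq_len(n) / n
}

ring_weights <- function(theta, gamma) {
  cbind(gamma * cos(2 * theta), gamma * sin(2 * theta))
}

make_ring_spec <- function(theta, gamma, gain_class, mu, tau, tau_a, eta) {
  spec <- build_network(ring_weights(theta, gamma), mu = mu, tau = tau,
                        tau_a = tau_a, eta = eta)
  spec$theta <- theta
  spec$gamma <- gamma
  spec$gain_class <- gain_class
  class(spec) <- c("ring_spec", "network_spec")
  spec
}

#' Dual-ring orientation network
#'
#' Orientation-coding population of two subpopulations spanning the
#' half-circle of orientations evenly: at each of N/2 preferred
#' orientations sits one high-gain neuron (small decoder magnitude,
#' gamma = 3: excitable and precise) and one low-gain neuron (gamma = 9).
#' Decoding weights are \code{[gamma cos(2 Theta), gamma sin(2 Theta)]}.
#' Same-preference neighbours inhibit each other most strongly; neurons
#' with orthogonal preferences excite each other, which is why the
#' threshold offset eta * g is used.
#'
#' @param N Total neuron count (even); N/2 per subpopulation.
#' @param gamma_high Decoder magnitude of the high-gain subpopulation.
#' @param gamma_low Decoder magnitude of the low-gain subpopulation.
#' @param mu,tau,tau_a,eta Network parameters (see [build_network()]).
#' @return A \code{ring_spec} (a \code{network_spec} with per-neuron
#'   \code{theta}, \code{gamma} and \code{gain_class}).
#' @export
build_dual_ring <- function(N = 200, gamma_high = 3, gamma_low = 9,
                            mu = 0.1, tau = 5, tau_a = 2000, eta = 10) {
  if (N %% 2 != 0) stop("N must be even: one high- and one low-gain neuron per orientation")
  th <- ring_thetas(N / 2)
  make_ring_spec(theta = c(th, th),
                 gamma = rep(c(gamma_high, gamma_low), each = N / 2),
                 gain_class = rep(c("high", "low"), each = N / 2),
                 mu = mu, tau = tau, tau_a = tau_a, eta = eta)
}

#' Random-gain ring network
#'
#' Like the dual ring but with a continuum of excitabilities: preferred
#' orientations are evenly spaced (one neuron per orientation) while the
#' decoder magnitudes gamma are drawn uniformly from [gamma_low,
#' gamma_high].
#'
#' @param N Neuron count.
#' @param gamma_low,gamma_high Range of the uniform gamma draw.
#' @param seed Integer seed (required).
#' @param mu,tau,tau_a,eta Network parameters.
#' @return A \code{ring_spec}.
#' @export
build_random_gain_ring <- function(N = 200, gamma_low = 3, gamma_high = 9,
                                   seed, mu = 0.2, tau = 5, tau_a = 1000,
                                   eta = 1) {
  if (missing(seed)) stop("seed is required for the random-gain ring")
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  gamma <- stats::runif(N, gamma_low, gamma_high)
  make_ring_spec(theta = ring_thetas(N), gamma = gamma,
                 gain_class = rep("random", N),
                 mu = mu, tau = tau, tau_a = tau_a, eta = eta)
}
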