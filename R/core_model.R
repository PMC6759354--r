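#' Per-neuron gains from decoding weights and cost weight
#'
#' The gain of neuron i is \code{g_i = 1 / (||w_i||^2 + mu)}: neurons with
#' small decoding weights are strongly excitable (high gain, precise but
#' metabolically costly), neurons with large decoding weights are weakly
#' excitable. The gain multiplies both the feedforward drive and the coding
#' error in the neuron's membrane potential.
#'
#' @param W Decoding-weight matrix with one row per neuron (N x M). A plain
#'   numeric vector is interpreted as a single-column matrix (scalar
#'   stimulus, M = 1).
#' @param mu Non-negative cost weight balancing coding error against the
#'   squared firing-history penalty. Must be strictly positive if any row of
#'   \code{W} is all zero.
#' @return Numeric vector of length N of strictly positive gains.
#' @examples
#' compute_gains(matrix(c(1, 2), ncol = 1), mu = 0.02)
#' @export
compute_gains <- function(W, mu) {
  W <- as_weight_matrix(W)
  check_mu(mu)
  nrm2 <- rowSums(W^2)
  if (mu == 0 && any(nrm2 == 0)) {
    stop("mu = 0 with an all-zero weight row gives an infinite gain; ",
         "use mu > 0 or remove the zero row")
  }
  1 / (nrm2 + mu)
}

#' Recurrent weight matrix
#'
#' Lateral connections remove the correlations between the feedforward
#' selectivities of the neurons: \code{Omega = W W' + mu I}. Off-diagonal
#' entries are mutual inhibition (for same-signed weights); the diagonal
#' carries the self-reset, \code{Omega_ii = ||w_i||^2 + mu}, so that
#' \code{g_i * Omega_ii = 1} and a spike drops the spiking neuron's
#' normalized voltage by exactly one (threshold 1/2 to reset -1/2).
#'
#' @inheritParams compute_gains
#' @return Symmetric N x N matrix.
#' @export
compute_recurrent_weights <- function(W, mu) {
  W <- as_weight_matrix(W)
  check_mu(mu)
  tcrossprod(W) + diag(mu, nrow(W))
}

#' Adaptation coefficients
#'
#' The adaptation current on neuron i is \code{-kappa_i * f_i} with
#' \code{kappa_i = mu * g_i * (1 - tau / tau_a)}. It vanishes in the
#' cost-free limit (mu = 0) and when the adaptation and decoder time scales
#' coincide (tau_a = tau); it is non-negative whenever tau_a >= tau.
#'
#' @param gains Per-neuron gain vector (see [compute_gains()]).
#' @param mu Non-negative cost weight.
#' @param tau Decoder/membrane time constant in ms (> 0).
#' @param tau_a Adaptation time constant in ms (> 0); typically tau_a >> tau.
#' @return Numeric vector of per-neuron adaptation coefficients.
#' @export
compute_adaptation_coefficients <- function(gains, mu, tau, tau_a) {
  check_mu(mu)
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0) {
    stop("tau must be a positive scalar (ms)")
  }
  if (!is.numeric(tau_a) || length(tau_a) != 1L || !is.finite(tau_a) ||
      tau_a <= 0) {
    stop("tau_a must be a positive scalar (ms)")
  }
  mu * gains * (1 - tau / tau_a)
}

#' Build a balanced spiking network specification
#'
#' Assembles the full network derived from the cost-accuracy objective: given
#' fixed decoding weights and the cost weight mu, all other quantities
#' (gains, recurrent weights, adaptation coefficients, thresholds) follow.
#' Membrane potentials are normalized so that every neuron has threshold
#' \code{1/2 + eta * g_i} and reset potential -1/2; the offset \code{eta *
#' g_i} is used by the orientation networks to keep neurons with opposing
#' preferences from spiking on the excitation they receive from each other.
#'
#' @inheritParams compute_gains
#' @param tau Decoder/membrane time constant in ms.
#' @param tau_a Adaptation time constant in ms. A warning is issued when
#'   tau_a < tau (the derivation assumes slow adaptation).
#' @param eta Non-negative threshold-offset coefficient (default 0; only the
#'   orientation models use a nonzero value).
#' @return An object of class \code{network_spec}: a list with elements
#'   \code{N}, \code{M}, \code{W}, \code{mu}, \code{tau}, \code{tau_a},
#'   \code{eta}, \code{g}, \code{Omega}, \code{kappa}, \code{threshold},
#'   \code{reset}.
#' @examples
#' spec <- build_network(matrix(c(1, 2), ncol = 1), mu = 0.02,
#'                       tau = 25, tau_a = 1000)
#' spec$threshold
#' @export
build_network <- function(W, mu, tau, tau_a, eta = 0) {
  W <- as_weight_matrix(W)
  if (!is.numeric(eta) || length(eta) != 1L || !is.finite(eta) || eta < 0) {
    stop("eta must be a non-negative scalar")
  }
  g <- compute_gains(W, mu)
  kappa <- compute_adaptation_coefficients(g, mu, tau, tau_a)
  if (tau_a < tau) {
    warning("tau_a < tau: adaptation faster than the decoder; ",
            "the derivation assumes tau_a >> tau")
  }
  spec <- list(
    N = nrow(W), M = ncol(W), W = W,
    mu = mu, tau = tau, tau_a = tau_a, eta = eta,
    g = g,
    Omega = compute_recurrent_weights(W, mu),
    kappa = kappa,
    threshold = 0.5 + eta * g,
    reset = -0.5
  )
  class(spec) <- "network_spec"
  spec
}

#' @export
print.network_spec <- function(x, ...) {
  cat("Balanced spiking network spec\n")
  cat(sprintf("  N = %d neurons, M = %d stimulus dimension(s)\n", x$N, x$M))
  cat(sprintf("  mu = %g, tau = %g ms, tau_a = %g ms, eta = %g\n",
              x$mu, x$tau, x$tau_a, x$eta))
  cat(sprintf("  gain range [%.4g, %.4g], threshold range [%.4g, %.4g]\n",
              min(x$g), max(x$g), min(x$threshold), max(x$threshold)))
  invisible(x)
}

#' Instantaneous voltage effect of a spike
#'
#' Returns the jump applied to every neuron's normalized voltage when neuron
#' \code{j} spikes: \code{-g * Omega[, j]}. The self entry is exactly -1, so
#' a neuron spiking from exactly its threshold of 1/2 (eta = 0) lands at the
#' reset potential -1/2.
#'
#' @param spec A \code{network_spec}.
#' @param j Index of the spiking neuron.
#' @return Numeric vector of length N of voltage increments.
#' @export
spike_effect <- function(spec, j) {
  stopifnot(inherits(spec, "network_spec"))
  j <- as.integer(j)
  if (j < 1L || j > spec$N) stop("neuron index out of range")
  -spec$g * spec$Omega[, j]
}

#' Strip the cross-neuron recurrent coupling from a network spec
#'
#' Keeps only the diagonal of the recurrent matrix (the self-reset), giving
#' the ablated network used to show that adaptation without recurrence
#' destroys linear decodability. Spike decisions in the ablated network fall
#' back to the integrated membrane potential, since without recurrence no
#' neuron has access to the population estimate.
#'
#' @param spec A \code{network_spec}.
#' @return A \code{network_spec} with off-diagonal recurrent weights zeroed
#'   and attribute \code{recurrent = FALSE}.
#' @export
remove_recurrence <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  spec$Omega <- diag(diag(spec$Omega), spec$N)
  attr(spec, "recurrent") <- FALSE
  spec
}

# ---- internal validation helpers ------------------------------------------

as_weight_matrix <- function(W) {
  if (is.vector(W) && is.numeric(W)) W <- matrix(W, ncol = 1L)
  if (!is.matrix(W) || !is.numeric(W) || nrow(W) < 1L || ncol(W) < 1L) {
    stop("W must be a numeric matrix with one row per neuron")
  }
  if (any(!is.finite(W))) stop("W must be finite")
  storage.mode(W) <- "double"
  W
}

check_mu <- function(mu) {
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) || mu < 0) {
    stop("mu must be a non-negative scalar")
  }
  invisible(mu)
}
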