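#' Linear decoding of filtered rates
#'
#' Applies a fixed linear decoder to the decoder-filtered rates:
#' \code{phi_hat(t) = D r(t)} per sample. For a network built by
#' [build_network()] the internal estimate corresponds to \code{D = t(W)}.
#'
#' @param r Filtered-rate matrix, N x T (or length-N vector).
#' @param D Decoder matrix, M x N.
#' @return M x T estimate matrix (length-M vector for vector input).
#' @export
linear_decode <- function(r, D) {
  if (is.vector(r)) r <- matrix(r, ncol = 1L)
  if (!is.matrix(D) || ncol(D) != nrow(r)) {
    stop("decoder has ", ncol(D), " columns but r has ", nrow(r), " neurons")
  }
  out <- D %*% r
  if (ncol(out) == 1L) drop(out) else out
}

#' Train the optimal linear decoder
#'
#' Least-squares decoder mapping filtered population rates to the stimulus:
#' minimizes the summed squared error over all stacked time samples of the
#' training traces. An onset transient is discarded from each trace
#' (default 50 ms) so the decoder reflects steady responses, and samples
#' are thinned to one per \code{sample_every_ms}. Solved through the
#' normal equations with a small ridge term on the Gram matrix guarding
#' rank deficiency; \code{ridge = 0} recovers the pure pseudoinverse
#' (via [MASS::ginv()]).
#'
#' @param r_list List of N x T filtered-rate matrices (one per trace).
#' @param phi_list List of matching M x T stimulus matrices (or
#'   \code{stimulus_trace} objects).
#' @param dt Sampling step in ms of the traces.
#' @param discard_ms Initial transient to drop from every trace.
#' @param sample_every_ms Thinning interval for the stacked samples.
#' @param ridge Ridge coefficient applied to the Gram matrix, scaled by its
#'   mean diagonal (default 1e-6).
#' @return M x N decoder matrix. A warning is issued when the (unridged)
#'   Gram matrix is rank deficient.
#' @export
train_optimal_decoder <- function(r_list, phi_list, dt, discard_ms = 50,
                                  sample_every_ms = 1, ridge = 1e-6) {
  stopifnot(length(r_list) == length(phi_list), length(r_list) >= 1L)
  N <- nrow(r_list[[1L]])
  phi1 <- phi_list[[1L]]
  if (inherits(phi1, "stimulus_trace")) phi1 <- phi1$values
  M <- nrow(phi1)
  G <- matrix(0, N, N)
  C <- matrix(0, M, N)
  n_samples <- 0L
  for (k in seq_along(r_list)) {
    r <- r_list[[k]]
    phi <- phi_list[[k]]
    if (inherits(phi, "stimulus_trace")) phi <- phi$values
    stopifnot(nrow(r) == N, nrow(phi) == M, ncol(r) == ncol(phi))
    i0 <- floor(discard_ms / dt) + 1L
    step <- max(1L, round(sample_every_ms / dt))
    idx <- seq(i0, ncol(r), by = step)
    if (length(idx) == 0L) stop("discard_ms leaves no samples in trace ", k)
    rs <- r[, idx, drop = FALSE]
    G <- G + tcrossprod(rs)
    C <- C + phi[, idx, drop = FALSE] %*% t(rs)
    n_samples <- n_samples + length(idx)
  }
  if (n_samples < N) {
    warning("fewer stacked samples (", n_samples, ") than neurons (", N, ")")
  }
  qrG <- qr(G)
  if (qrG$rank < N) {
    warning("response Gram matrix is rank deficient (rank ", qrG$rank,
            " < ", N, ")")
  }
  if (ridge > 0) {
    lambda <- ridge * mean(diag(G))
    if (lambda == 0) lambda <- ridge
    t(solve(G + diag(lambda, N), t(C)))
  } else {
    C %*% MASS::ginv(G)
  }
}

#' Decode an orientation from a two-dimensional estimate
#'
#' Inverts the angle-doubled stimulus convention:
#' \code{theta_hat = atan2(phi_hat_2, phi_hat_1) / 2}, reported in
#' (-pi/2, pi/2].
#'
#' @param phi_hat Length-2 vector, or 2 x T matrix.
#' @return Decoded orientation(s) in radians.
#' @export
decode_orientation <- function(phi_hat) {
  if (is.vector(phi_hat)) phi_hat <- matrix(phi_hat, nrow = 2L)
  if (nrow(phi_hat) != 2L) stop("phi_hat must be two-dimensional")
  if (any(colSums(phi_hat^2) == 0)) {
    stop("zero estimate: orientation undefined")
  }
  th <- atan2(phi_hat[2L, ], phi_hat[1L, ]) / 2
  # fold -pi/2 (from atan2 = -pi) onto +pi/2 so the range is (-pi/2, pi/2]
  th[th <= -pi / 2 + 1e-12] <- th[th <= -pi / 2 + 1e-12] + pi
  if (length(th) == 1L) th[[1L]] else th
}

#' Causal moving mean and dispersion of an estimate trace
#'
#' Running mean and standard deviation over a trailing window (shorter,
#' expanding windows at the start). For angular traces set
#' \code{circular = TRUE}: statistics are computed on the doubled angle
#' (period pi mapped to the circle) and the mean is halved back; the
#' dispersion is the circular standard deviation, halved.
#'
#' @param x Numeric vector (one trace), in radians when circular.
#' @param window_ms Window length in ms (>= dt).
#' @param dt Sampling step in ms.
#' @param circular Treat x as an orientation (period pi)?
#' @return List with \code{mean} and \code{sd}, each length(x).
#' @export
smooth_estimate <- function(x, window_ms, dt, circular = FALSE) {
  stopifnot(is.numeric(x), window_ms >= dt, dt > 0)
  w <- max(1L, round(window_ms / dt))
  n <- length(x)
  k <- pmin(seq_len(n), w)  # effective window sizes
  run_mean <- function(v) {
    cs <- cumsum(v)
    (cs - c(rep(0, w), cs[seq_len(max(0L, n - w))])) / k
  }
  if (!circular) {
    m <- run_mean(x)
    m2 <- run_mean(x^2)
    v <- pmax(0, m2 - m^2)
    list(mean = m, sd = sqrt(v))
  } else {
    cs <- run_mean(cos(2 * x))
    sn <- run_mean(sin(2 * x))
    R <- pmin(1, sqrt(cs^2 + sn^2))
    m <- atan2(sn, cs) / 2
    sd2 <- sqrt(pmax(0, -2 * log(pmax(R, .Machine$double.eps))))
    list(mean = m, sd = sd2 / 2)
  }
}
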