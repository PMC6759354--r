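#' Closed-form membrane potential
#'
#' The normalized membrane potential of each neuron is proportional to the
#' global coding error penalized by the neuron's own firing history:
#' \code{V_i = g_i (w_i' (phi - phi_hat) - mu f_i)}. This closed form is the
#' defining quantity of the greedy spiking rule and serves as the exact
#' reference for the Euler-integrated voltage ODE.
#'
#' @param spec A \code{network_spec}.
#' @param phi Stimulus value: length-M vector or M x T matrix.
#' @param phi_hat Decoded estimate, same shape as \code{phi}.
#' @param f Firing-history vector (length N) or N x T matrix.
#' @return Voltage vector (length N) or N x T matrix.
#' @export
voltage_direct <- function(spec, phi, phi_hat, f) {
  stopifnot(inherits(spec, "network_spec"))
  phi <- as_stim_mat(phi, spec$M)
  phi_hat <- as_stim_mat(phi_hat, spec$M)
  if (is.vector(f)) f <- matrix(f, nrow = spec$N)
  stopifnot(ncol(phi) == ncol(phi_hat), ncol(phi) == ncol(f),
            nrow(f) == spec$N)
  V <- spec$g * (spec$W %*% (phi - phi_hat)) - (spec$mu * spec$g) * f
  if (ncol(V) == 1L) drop(V) else V
}

#' Objective function decomposition
#'
#' Evaluates the cost-accuracy objective
#' \code{E = ||phi - phi_hat||^2 + mu * sum(f^2)} and its two terms.
#'
#' @inheritParams voltage_direct
#' @return List with numeric \code{total}, \code{error} and \code{cost}
#'   (scalars, or length-T vectors for matrix input).
#' @export
objective_value <- function(spec, phi, phi_hat, f) {
  stopifnot(inherits(spec, "network_spec"))
  phi <- as_stim_mat(phi, spec$M)
  phi_hat <- as_stim_mat(phi_hat, spec$M)
  if (is.vector(f)) f <- matrix(f, nrow = spec$N)
  err <- colSums((phi - phi_hat)^2)
  cost <- spec$mu * colSums(f^2)
  list(total = err + cost, error = err, cost = cost)
}

#' Objective change caused by one candidate spike
#'
#' A spike in neuron i adds \code{w_i} to the estimate and one unit to the
#' neuron's firing history, so the objective changes by
#' \code{dE = ||phi - phi_hat - w_i||^2 + mu (f_i + 1)^2
#'          - ||phi - phi_hat||^2 - mu f_i^2},
#' which reduces algebraically to \code{(||w_i||^2 + mu) (1 - 2 V_i)}. The
#' greedy rule fires the spike iff dE < 0, i.e. iff V_i > 1/2.
#'
#' @param spec A \code{network_spec}.
#' @param state List with elements \code{phi_hat} (length M) and \code{f}
#'   (length N), e.g. from [network_state()].
#' @param i Candidate neuron index.
#' @param phi Current stimulus value (length M).
#' @return Scalar objective change dE.
#' @export
spike_delta_objective <- function(spec, state, i, phi) {
  stopifnot(inherits(spec, "network_spec"))
  i <- as.integer(i)
  if (i < 1L || i > spec$N) stop("neuron index out of range")
  err <- as.numeric(phi) - as.numeric(state$phi_hat)
  wi <- spec$W[i, ]
  fi <- state$f[i]
  sum((err - wi)^2) - sum(err^2) + spec$mu * ((fi + 1)^2 - fi^2)
}

#' Fresh network state
#'
#' @param spec A \code{network_spec}.
#' @param V,r,f Optional initial values (defaults: all zero).
#' @return List with elements \code{V}, \code{r}, \code{f}, \code{phi_hat}
#'   (the estimate implied by \code{r}).
#' @export
network_state <- function(spec, V = NULL, r = NULL, f = NULL) {
  stopifnot(inherits(spec, "network_spec"))
  z <- numeric(spec$N)
  V <- if (is.null(V)) z else as.numeric(V)
  r <- if (is.null(r)) z else as.numeric(r)
  f <- if (is.null(f)) z else as.numeric(f)
  stopifnot(length(V) == spec$N, length(r) == spec$N, length(f) == spec$N)
  if (any(r < 0) || any(f < 0)) stop("r and f must be non-negative")
  list(V = V, r = r, f = f, phi_hat = drop(crossprod(spec$W, r)))
}

#' Advance the network by one time step
#'
#' One forward-Euler step of the voltage ODE (exact exponential decay for
#' the filtered rates r, the firing histories f, and hence the estimate),
#' followed by spike resolution. At most one spike is emitted per step:
#' among neurons whose greedy condition holds strictly (closed-form voltage
#' above threshold), the one with the largest margin fires; ties break to
#' the lowest index. The spike instantaneously applies the recurrent/self
#' currents \code{-g * Omega[, j]} to the integrated voltage, increments the
#' spiker's r and f, and adds \code{w_j} to the estimate.
#'
#' For a network stripped by [remove_recurrence()] the spike decision falls
#' back to the integrated membrane potential itself.
#'
#' @param spec A \code{network_spec}.
#' @param state State list from [network_state()] or a previous step.
#' @param phi Stimulus value at this step (length M).
#' @param phidot Stimulus time derivative at this step (length M).
#' @param dt Time step in ms.
#' @return List with \code{state} (updated) and \code{spike} (neuron index,
#'   or NA if none) and \code{delta_E} (objective change of the emitted
#'   spike, NA if none).
#' @export
step_network <- function(spec, state, phi, phidot, dt) {
  stopifnot(inherits(spec, "network_spec"))
  recurrent <- !isFALSE(attr(spec, "recurrent"))
  h <- dt / spec$tau
  dec_r <- exp(-h)
  dec_f <- exp(-dt / spec$tau_a)

  r <- state$r * dec_r
  f <- state$f * dec_f
  phi_hat <- state$phi_hat * dec_r
  drive <- spec$g * drop(spec$W %*% (spec$tau * phidot + phi))
  V <- state$V + h * (-state$V + drive - spec$kappa * f)

  if (recurrent) {
    Vdec <- spec$g * drop(spec$W %*% (phi - phi_hat)) - (spec$mu * spec$g) * f
  } else {
    Vdec <- V
  }
  margins <- Vdec - spec$threshold
  j <- NA_integer_
  dE <- NA_real_
  if (max(margins) > 0) {
    j <- which.max(margins)
    dE <- spike_delta_objective(spec, list(phi_hat = phi_hat, f = f), j, phi)
    V <- V - spec$g * spec$Omega[, j]
    r[j] <- r[j] + 1
    f[j] <- f[j] + 1
    phi_hat <- phi_hat + spec$W[j, ]
  }
  if (!all(is.finite(V))) stop("non-finite voltage: simulation diverged")
  list(state = list(V = V, r = r, f = f, phi_hat = phi_hat),
       spike = j, delta_E = dE)
}

#' Simulate a balanced spiking network
#'
#' Runs the greedy spiking dynamics over a stimulus trace. Each step: exact
#' exponential decay of the filtered rates, firing histories and estimate;
#' forward-Euler update of the integrated membrane potential (voltage ODE
#' with the stimulus-derivative drive computed as a backward finite
#' difference, zero stimulus assumed before the first sample); greedy spike
#' resolution with at most one spike per step. The simulation is fully
#' deterministic: identical spec, stimulus, dt and initial state give
#' bit-identical results.
#'
#' @param spec A \code{network_spec}.
#' @param stimulus A \code{stimulus_trace} with M matching the spec.
#' @param dt Time step in ms; must equal the stimulus sampling step. A
#'   warning is issued when dt > tau / 10.
#' @param init Optional initial state from [network_state()].
#' @param record Character vector choosing the per-step traces to keep:
#'   any of "V", "r", "f" (the estimate, error and cost traces are always
#'   recorded). Use \code{record = character(0)} for lean sweeps.
#' @return An object of class \code{simulation_result}: list with
#'   \code{raster} (data.frame: neuron, time_ms, delta_E), \code{time},
#'   \code{dt}, \code{estimate_trace} (M x T), \code{error_trace},
#'   \code{cost_trace}, optional \code{V_trace}, \code{r_trace},
#'   \code{f_trace} (N x T), and \code{final_state}.
#' @examples
#' spec <- build_network(matrix(c(1, 2), ncol = 1), mu = 0.02,
#'                       tau = 25, tau_a = 1000)
#' stim <- constant_pulse(10, duration_ms = 200, dt = 0.5)
#' res <- run_simulation(spec, stim)
#' nrow(res$raster)
#' @export
run_simulation <- function(spec, stimulus, dt = stimulus$dt, init = NULL,
                           record = c("V", "r", "f"),
                           decision = c("greedy", "euler")) {
  decision <- match.arg(decision)
  stopifnot(inherits(spec, "network_spec"),
            inherits(stimulus, "stimulus_trace"))
  if (nrow(stimulus$values) != spec$M) {
    stop("stimulus dimension does not match spec M")
  }
  if (!isTRUE(all.equal(dt, stimulus$dt))) {
    stop("dt must equal the stimulus sampling step; resample the stimulus")
  }
  if (dt > spec$tau / 10) {
    warning(sprintf("dt = %g ms exceeds tau/10 = %g ms; ", dt, spec$tau / 10),
            "discretization, not coding error, may limit firing")
  }
  recurrent <- !isFALSE(attr(spec, "recurrent"))
  greedy <- recurrent && decision == "greedy"
  N <- spec$N
  TT <- ncol(stimulus$values)
  Phi <- stimulus$values
  Phidot <- (Phi - cbind(numeric(spec$M), Phi[, -TT, drop = FALSE])) / dt

  # precomputed per-step quantities
  FF <- spec$g * (spec$W %*% (spec$tau * Phidot + Phi))     # N x T drive
  GO <- spec$g * spec$Omega                                  # g_i Omega_ij
  Wg <- spec$g * spec$W                                      # g_i w_i
  mug <- spec$mu * spec$g
  h <- dt / spec$tau
  dec_r <- exp(-h)
  dec_f <- exp(-dt / spec$tau_a)

  keep_V <- "V" %in% record
  keep_r <- "r" %in% record
  keep_f <- "f" %in% record
  V_tr <- if (keep_V) matrix(0, N, TT)
  r_tr <- if (keep_r) matrix(0, N, TT)
  f_tr <- if (keep_f) matrix(0, N, TT)
  est_tr <- matrix(0, spec$M, TT)
  err_tr <- numeric(TT)
  cost_tr <- numeric(TT)

  if (is.null(init)) init <- network_state(spec)
  V <- init$V; r <- init$r; f <- init$f
  phi_hat <- drop(crossprod(spec$W, r))

  sp_n <- integer(TT); sp_t <- numeric(TT); sp_dE <- numeric(TT)
  n_sp <- 0L
  thr <- spec$threshold
  W <- spec$W
  mu <- spec$mu
  kappa <- spec$kappa

  for (k in seq_len(TT)) {
    r <- r * dec_r
    f <- f * dec_f
    phi_hat <- phi_hat * dec_r
    V <- V + h * (-V + FF[, k] - kappa * f)

    phik <- Phi[, k]
    errk <- phik - phi_hat
    if (greedy) {
      Vdec <- drop(Wg %*% errk) - mug * f
    } else {
      Vdec <- V
    }
    m <- Vdec - thr
    if (max(m) > 0) {
      j <- which.max(m)  # ties break to lowest index
      wj <- W[j, ]
      fj <- f[j]
      dE <- sum((errk - wj)^2) - sum(errk^2) + mu * (2 * fj + 1)
      V <- V - GO[, j]
      r[j] <- r[j] + 1
      f[j] <- fj + 1
      phi_hat <- phi_hat + wj
      n_sp <- n_sp + 1L
      sp_n[n_sp] <- j
      sp_t[n_sp] <- (k - 1L) * dt
      sp_dE[n_sp] <- dE
    }

    if (keep_V) V_tr[, k] <- V
    if (keep_r) r_tr[, k] <- r
    if (keep_f) f_tr[, k] <- f
    est_tr[, k] <- phi_hat
    err_tr[k] <- sum((phik - phi_hat)^2)
    cost_tr[k] <- mu * sum(f * f)
    if (!all(is.finite(V))) {
      stop(sprintf("non-finite voltage at t = %g ms: simulation diverged",
                   (k - 1L) * dt))
    }
  }

  raster <- data.frame(
    neuron = sp_n[seq_len(n_sp)],
    time_ms = sp_t[seq_len(n_sp)],
    delta_E = sp_dE[seq_len(n_sp)]
  )
  structure(
    list(raster = raster,
         time = stimulus$time, dt = dt,
         stimulus = stimulus,
         V_trace = V_tr, r_trace = r_tr, f_trace = f_tr,
         estimate_trace = est_tr,
         error_trace = err_tr, cost_trace = cost_tr,
         final_state = list(V = V, r = r, f = f, phi_hat = phi_hat),
         spec = spec),
    class = "simulation_result"
  )
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "Simulation result: %d neurons, %d steps (dt = %g ms), %d spikes\n",
    x$spec$N, length(x$time), x$dt, nrow(x$raster)))
  cat(sprintf("  final objective E = %.4g (error %.4g + cost %.4g)\n",
              x$error_trace[length(x$time)] + x$cost_trace[length(x$time)],
              x$error_trace[length(x$time)], x$cost_trace[length(x$time)]))
  invisible(x)
}

#' Leaky exponential filtering of a spike raster
#'
#' Integrates a spike train with a decaying exponential kernel on a uniform
#' grid: \code{x <- x * exp(-dt / tc) + (spikes in step)}. With tc = tau
#' this reproduces the decoder-filtered rates r; with tc = tau_a the firing
#' histories f. The operation is linear in the spike train and a single
#' spike yields a decaying exponential impulse response.
#'
#' @param raster Data frame with columns \code{neuron} and \code{time_ms}.
#' @param time_constant Filter time constant in ms (> 0).
#' @param dt Grid step in ms (> 0, uniform).
#' @param n_steps Number of grid steps.
#' @param N Number of neurons.
#' @return N x n_steps matrix of filtered traces.
#' @export
filter_spike_train <- function(raster, time_constant, dt, n_steps, N) {
  if (!is.numeric(time_constant) || time_constant <= 0) {
    stop("time_constant must be positive")
  }
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    stop("dt must be a positive scalar: the grid must be uniform")
  }
  counts <- matrix(0, N, n_steps)
  if (nrow(raster) > 0) {
    idx <- round(raster$time_ms / dt) + 1L
    if (any(idx < 1L | idx > n_steps)) stop("spike time outside the grid")
    for (s in seq_len(nrow(raster))) {
      counts[raster$neuron[s], idx[s]] <- counts[raster$neuron[s], idx[s]] + 1
    }
  }
  dec <- exp(-dt / time_constant)
  out <- counts
  for (k in 2:n_steps) out[, k] <- out[, k - 1L] * dec + counts[, k]
  out
}

#' Instantaneous firing rates for display
#'
#' Exponential filtering of the spike raster with a display time constant
#' (default 50 ms), scaled to spikes per second. A plotting utility, not a
#' model quantity.
#'
#' @inheritParams filter_spike_train
#' @param display_tc Display filter time constant in ms.
#' @return N x n_steps matrix of rates in Hz.
#' @export
instantaneous_rate <- function(raster, dt, n_steps, N, display_tc = 50) {
  filter_spike_train(raster, display_tc, dt, n_steps, N) * (1000 / display_tc)
}

as_stim_mat <- function(x, M) {
  if (is.vector(x)) x <- matrix(x, nrow = M)
  if (nrow(x) != M) stop("stimulus dimension mismatch")
  x
}
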