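#' Digit-sequence encoding comparison
#'
#' Reproduces the three-way comparison between (i) the random LIF baseline
#' with its trained optimal linear decoder, (ii) the same baseline with an
#' activity-regulated (adaptive) spiking threshold and the same decoder,
#' and (iii) the balanced network with adaptation derived from the
#' cost-accuracy objective, decoded by its own weights. The decoder is
#' trained on random constant patterns presented to the non-adaptive
#' baseline; the three conditions then receive the identical seven-segment
#' digit sequence, and the reconstruction error of every digit presentation
#' is tabulated.
#'
#' @param baseline_net A \code{baseline_network} (see
#'   [build_random_baseline()]).
#' @param balanced_spec Optional \code{network_spec}; defaults to the
#'   balanced network built from the baseline's feedforward weights as
#'   decoding weights with \code{mu}, \code{tau_a} below.
#' @param digits Digit sequence shown (default 0:7).
#' @param mu,tau_a Adaptation parameters shared by the adaptive-threshold
#'   baseline and the default balanced network.
#' @param amplitude Active-segment amplitude of the test digits.
#' @param dt Time step in ms.
#' @param train_seed Seed for the random training patterns.
#' @param n_train,train_ms Number and duration of training patterns.
#' @param onset_allowance_ms Initial slice of each digit presentation
#'   excluded from the error (decoder latency allowance).
#' @return List of class \code{digit_experiment} with \code{table} (one row
#'   per presentation: position, digit, mse_baseline, mse_adaptive,
#'   mse_balanced), \code{late_ratio_adaptive_vs_baseline} and
#'   \code{late_ratio_adaptive_vs_balanced} (mean MSE over the last three
#'   presentations), \code{decoder}, and the decoded traces.
#' @export
digit_experiment <- function(baseline_net, balanced_spec = NULL,
                             digits = 0:7, mu = 0.02, tau_a = 2000,
                             amplitude = 2, dt = 0.1, train_seed = 1,
                             n_train = 100, train_ms = 300,
                             onset_allowance_ms = 20) {
  stopifnot(inherits(baseline_net, "baseline_network"))
  if (is.null(balanced_spec)) {
    balanced_spec <- build_network(baseline_net$F_ff, mu = mu,
                                   tau = baseline_net$tau, tau_a = tau_a,
                                   eta = 0)
  }
  stim <- digit_sequence(digits, on_ms = 200, off_ms = 100,
                         amplitude = amplitude, dt = dt)

  # --- decoder training on the non-adaptive baseline --------------------
  train_stims <- random_pattern_stimuli(n = n_train, duration_ms = train_ms,
                                        low = 0, high = 4,
                                        M = baseline_net$M, dt = dt,
                                        seed = train_seed)
  thin <- max(1L, round(1 / dt))  # keep one sample per ms for training
  r_list <- vector("list", n_train)
  phi_list <- vector("list", n_train)
  for (k in seq_len(n_train)) {
    res <- simulate_baseline(baseline_net, train_stims[[k]],
                             adaptive = FALSE, dt = dt)
    idx <- seq(1L, ncol(res$r_trace), by = thin)
    r_list[[k]] <- res$r_trace[, idx, drop = FALSE]
    phi_list[[k]] <- train_stims[[k]]$values[, idx, drop = FALSE]
  }
  D <- train_optimal_decoder(r_list, phi_list, dt = 1, discard_ms = 50,
                             sample_every_ms = 1)

  # --- the three conditions on the shared digit sequence ----------------
  res_base <- simulate_baseline(baseline_net, stim, adaptive = FALSE,
                                dt = dt)
  res_adap <- simulate_baseline(baseline_net, stim, adaptive = TRUE,
                                mu = mu, tau_a = tau_a, dt = dt)
  res_bal <- run_simulation(balanced_spec, stim, record = character(0))

  dec_base <- linear_decode(res_base$r_trace, D)
  dec_adap <- linear_decode(res_adap$r_trace, D)
  dec_bal <- res_bal$estimate_trace

  # --- per-presentation reconstruction error ----------------------------
  lab <- stim$labels
  n_skip <- round(onset_allowance_ms / dt)
  rows <- vector("list", length(digits))
  pos <- 0L
  k <- 1L
  TT <- length(lab)
  while (k <= TT) {
    if (!is.na(lab[k])) {
      k_end <- k
      while (k_end < TT && !is.na(lab[k_end + 1L]) &&
             lab[k_end + 1L] == lab[k]) k_end <- k_end + 1L
      pos <- pos + 1L
      idx <- (k + n_skip):k_end
      pat <- digit_pattern(lab[k], amplitude)
      mse <- function(dec) mean((dec[, idx, drop = FALSE] - pat)^2)
      rows[[pos]] <- data.frame(position = pos, digit = lab[k],
                                mse_baseline = mse(dec_base),
                                mse_adaptive = mse(dec_adap),
                                mse_balanced = mse(dec_bal))
      k <- k_end + 1L
    } else {
      k <- k + 1L
    }
  }
  tab <- do.call(rbind, rows)
  late <- tab[tab$position > max(0, nrow(tab) - 3), ]
  out <- list(
    table = tab,
    late_ratio_adaptive_vs_baseline =
      mean(late$mse_adaptive) / mean(late$mse_baseline),
    late_ratio_adaptive_vs_balanced =
      mean(late$mse_adaptive) / mean(late$mse_balanced),
    decoder = D,
    decoded = list(baseline = dec_base, adaptive = dec_adap,
                   balanced = dec_bal),
    stimulus = stim
  )
  class(out) <- "digit_experiment"
  out
}

#' @export
print.digit_experiment <- function(x, ...) {
  cat("Digit-sequence encoding comparison (per-presentation MSE)\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("late-sequence MSE ratio adaptive/baseline: %.3g\n",
              x$late_ratio_adaptive_vs_baseline))
  cat(sprintf("late-sequence MSE ratio adaptive/balanced: %.3g\n",
              x$late_ratio_adaptive_vs_balanced))
  invisible(x)
}

#' Distance of a two-neuron trajectory from the iso-coding line
#'
#' For a scalar-stimulus two-neuron network the set of rate vectors that
#' decode exactly is the line \code{w1 r1 + w2 r2 = phi}. Returns the
#' per-sample orthogonal distance of the trajectory from that line,
#' \code{|w' r - phi| / ||w||}, together with the (r1, r2) path.
#'
#' @param result A \code{simulation_result} from a two-neuron run recorded
#'   with \code{"r"}.
#' @param w Decoding weights (default: the spec's).
#' @param phi Stimulus trace (default: the recorded one).
#' @return List with \code{deviation} (length T) and \code{r_path} (2 x T).
#' @export
manifold_deviation <- function(result, w = NULL, phi = NULL) {
  stopifnot(inherits(result, "simulation_result"))
  if (is.null(w)) w <- drop(result$spec$W)
  if (is.null(phi)) phi <- drop(result$stimulus$values)
  if (is.null(result$r_trace)) stop("run_simulation must record \"r\"")
  if (nrow(result$r_trace) != 2L) stop("two-neuron result required")
  dev <- abs(colSums(w * result$r_trace) - phi) / sqrt(sum(w^2))
  list(deviation = dev, r_path = result$r_trace)
}

#' Population adaptation traces for a heterogeneous network
#'
#' Runs the graded-excitability population (decoding weights 1..10 by
#' default) on a constant pulse and extracts the recruitment order (first
#' spike time per neuron) and the objective decomposition over time.
#'
#' @param w Decoding-weight vector (scalar stimulus).
#' @param mu,tau,tau_a Network parameters.
#' @param phi_value Pulse amplitude.
#' @param duration_ms Pulse duration.
#' @param dt Time step in ms.
#' @return List with \code{result} (the \code{simulation_result}),
#'   \code{first_spike_ms} (NA for silent neurons), \code{recruitment}
#'   (neuron indices sorted by first spike) and \code{error_trace},
#'   \code{cost_trace}.
#' @export
population_trace_experiment <- function(w = 1:10, mu = 0.2, tau = 5,
                                        tau_a = 1000, phi_value = 10,
                                        duration_ms = 2000, dt = 0.1) {
  spec <- build_network(matrix(as.numeric(w), ncol = 1L), mu = mu,
                        tau = tau, tau_a = tau_a, eta = 0)
  stim <- constant_pulse(phi_value, duration_ms = duration_ms, dt = dt)
  res <- run_simulation(spec, stim, record = c("V", "r", "f"))
  first <- rep(NA_real_, spec$N)
  if (nrow(res$raster) > 0) {
    agg <- tapply(res$raster$time_ms, res$raster$neuron, min)
    first[as.integer(names(agg))] <- agg
  }
  fired <- which(!is.na(first))
  list(result = res,
       first_spike_ms = first,
       recruitment = fired[order(first[fired])],
       error_trace = res$error_trace,
       cost_trace = res$cost_trace)
}

#' Fold an angle difference onto the orientation range
#'
#' Orientations have period pi; this maps any angle (difference) to the
#' signed representative in [-pi/2, pi/2).
#'
#' @param x Angle(s) in radians.
#' @return Folded angle(s).
#' @export
wrap_orientation <- function(x) {
  x - pi * round(x / pi)
}

#' Orientation tuning curves before and after adaptation
#'
#' Presents every test orientation for \code{test_ms} from a reinitialized
#' network (pre-adaptation curves), and again after \code{adapt_ms} of an
#' adaptor orientation (post-adaptation curves, test immediately following
#' the adaptor). A neuron's response is its mean decoder-filtered rate over
#' the test window. Population curves per gain class are obtained by
#' centering each neuron's curve on its preferred orientation (nearest test
#' grid point) and averaging; dispersion is the across-neuron standard
#' deviation of the centered curves.
#'
#' @param ring A \code{ring_spec}.
#' @param test_orients Test orientation grid in radians (default: 24 points
#'   evenly spanning (-pi/2, pi/2]).
#' @param test_ms Test presentation duration (ms).
#' @param adapt_orient Adaptor orientation (radians).
#' @param adapt_ms Adaptor duration (ms).
#' @param C_test,C_adapt Test and adaptor stimulus magnitudes.
#' @param dt Time step in ms.
#' @return Object of class \code{tuning_curve_set}: list with \code{grid},
#'   \code{rel_grid}, matrices \code{pre} and \code{post} (N x n_test),
#'   per-class centered means/sds (\code{pre_centered}, \code{post_centered}
#'   with elements \code{mean}, \code{sd} per class), and the protocol
#'   parameters.
#' @export
tuning_curve_protocol <- function(ring,
                                  test_orients = -pi / 2 + pi * (1:24) / 24,
                                  test_ms = 250, adapt_orient = 0,
                                  adapt_ms = 1500, C_test = 50,
                                  C_adapt = 50, dt = 0.1) {
  stopifnot(inherits(ring, "ring_spec"))
  n <- length(test_orients)
  pre <- matrix(0, ring$N, n)
  post <- matrix(0, ring$N, n)
  n_test <- round(test_ms / dt)
  adapt_stim <- orientation_stimulus(adapt_orient, C_adapt,
                                     duration_ms = adapt_ms, dt = dt)
  for (j in seq_len(n)) {
    test_stim <- orientation_stimulus(test_orients[j], C_test,
                                      duration_ms = test_ms, dt = dt)
    res_pre <- run_simulation(ring, test_stim, record = "r")
    pre[, j] <- rowMeans(res_pre$r_trace)
    res_post <- run_simulation(ring, concat_stimuli(adapt_stim, test_stim),
                               record = "r")
    TT <- ncol(res_post$r_trace)
    post[, j] <- rowMeans(res_post$r_trace[, (TT - n_test + 1L):TT,
                                           drop = FALSE])
  }

  # centered population curves: shift each neuron's curve so its preferred
  # orientation sits at relative angle 0 (nearest grid point), then average
  # within gain class
  center_curves <- function(resp) {
    shifted <- matrix(0, ring$N, n)
    for (i in seq_len(ring$N)) {
      tgt <- wrap_orientation(ring$theta[i] + test_orients)
      idx <- vapply(tgt, function(a) {
        which.min(abs(wrap_orientation(test_orients - a)))
      }, integer(1))
      shifted[i, ] <- resp[i, idx]
    }
    shifted
  }
  classes <- unique(ring$gain_class)
  summarize <- function(resp) {
    sh <- center_curves(resp)
    out <- list()
    for (cl in classes) {
      rows <- sh[ring$gain_class == cl, , drop = FALSE]
      out[[cl]] <- list(mean = colMeans(rows), sd = apply(rows, 2, stats::sd))
    }
    out
  }
  structure(
    list(grid = test_orients,
         rel_grid = wrap_orientation(test_orients - test_orients[
           which.min(abs(wrap_orientation(test_orients)))]),
         pre = pre, post = post,
         pre_centered = summarize(pre),
         post_centered = summarize(post),
         adapt_orient = adapt_orient,
         params = list(test_ms = test_ms, adapt_ms = adapt_ms,
                       C_test = C_test, C_adapt = C_adapt, dt = dt),
         theta = ring$theta, gain_class = ring$gain_class),
    class = "tuning_curve_set"
  )
}

#' Tilt-aftereffect bias for one adaptor/test pair
#'
#' Presents an adaptor orientation for \code{adapt_ms}, immediately followed
#' by a test orientation for \code{test_ms}; the perceived orientation is
#' decoded from the mean network estimate over the test window. The bias is
#' the signed circular difference between the decoded and true test
#' orientations, with positive sign meaning repulsion away from the adaptor.
#'
#' @param ring A \code{ring_spec}.
#' @param adaptor,test Adaptor and test orientations in radians.
#' @param adapt_ms,test_ms Durations in ms.
#' @param C_adapt,C_test Stimulus magnitudes (C_adapt = 0 gives the
#'   no-adaptation control).
#' @param dt Time step in ms.
#' @return List with \code{theta_hat} (radians), \code{bias_deg} (signed,
#'   positive = repulsive; NA when the mean estimate is zero and no
#'   orientation can be decoded) and \code{raw_bias_deg} (decoded minus
#'   test, positive = counterclockwise).
#' @export
tilt_bias_protocol <- function(ring, adaptor, test, adapt_ms = 2000,
                               test_ms = 250, C_adapt = 25, C_test = 5,
                               dt = 0.1) {
  stopifnot(inherits(ring, "ring_spec"))
  adapt_stim <- orientation_stimulus(adaptor, C_adapt,
                                     duration_ms = adapt_ms, dt = dt)
  test_stim <- orientation_stimulus(test, C_test,
                                    duration_ms = test_ms, dt = dt)
  res <- run_simulation(ring, concat_stimuli(adapt_stim, test_stim),
                        record = character(0))
  TT <- ncol(res$estimate_trace)
  n_test <- round(test_ms / dt)
  est <- rowMeans(res$estimate_trace[, (TT - n_test + 1L):TT, drop = FALSE])
  if (sum(est^2) == 0) {
    return(list(theta_hat = NA_real_, bias_deg = NA_real_,
                raw_bias_deg = NA_real_))
  }
  theta_hat <- decode_orientation(est)
  raw <- wrap_orientation(theta_hat - test)
  d <- wrap_orientation(test - adaptor)
  bias <- if (d == 0) raw else raw * sign(d)
  list(theta_hat = theta_hat,
       bias_deg = bias * 180 / pi,
       raw_bias_deg = raw * 180 / pi)
}

#' Tilt-bias curve over adaptor-test differences
#'
#' Sweeps the adaptor-test angular difference, running the tilt protocol at
#' each grid point, and summarizes the curve: the repulsion-to-attraction
#' sign-crossover angle (linear interpolation between the grid points
#' flanking the sign change) and the maximal repulsion and attraction
#' amplitudes.
#'
#' @param ring A \code{ring_spec}.
#' @param delta_deg Grid of adaptor-test differences in degrees, inside
#'   (0, 90).
#' @param test Test orientation in radians (the adaptor is placed at
#'   \code{test + delta}).
#' @param adapt_ms,test_ms,C_adapt,C_test,dt Protocol parameters passed to
#'   [tilt_bias_protocol()].
#' @return Object of class \code{bias_curve}: list with \code{curve}
#'   (data.frame: delta_deg, bias_deg), \code{crossover_deg} (NA when the
#'   bias never changes sign), \code{max_repulsion_deg},
#'   \code{max_attraction_deg} and the protocol parameters.
#' @export
bias_curve <- function(ring, delta_deg = seq(5, 85, by = 5), test = 0,
                       adapt_ms = 2000, test_ms = 250, C_adapt = 25,
                       C_test = 5, dt = 0.1) {
  stopifnot(all(delta_deg > 0), all(delta_deg < 90))
  bias <- vapply(delta_deg, function(d) {
    tilt_bias_protocol(ring, adaptor = test + d * pi / 180, test = test,
                       adapt_ms = adapt_ms, test_ms = test_ms,
                       C_adapt = C_adapt, C_test = C_test, dt = dt)$bias_deg
  }, numeric(1))
  curve <- data.frame(delta_deg = delta_deg, bias_deg = bias)
  ok <- which(!is.na(bias))
  crossover <- NA_real_
  for (k in seq_along(ok)[-1]) {
    i0 <- ok[k - 1L]; i1 <- ok[k]
    if (bias[i0] > 0 && bias[i1] < 0) {
      crossover <- delta_deg[i0] +
        (delta_deg[i1] - delta_deg[i0]) * bias[i0] / (bias[i0] - bias[i1])
      break
    }
  }
  structure(
    list(curve = curve,
         crossover_deg = crossover,
         max_repulsion_deg = if (any(bias > 0, na.rm = TRUE))
           max(bias[bias > 0], na.rm = TRUE) else NA_real_,
         max_attraction_deg = if (any(bias < 0, na.rm = TRUE))
           max(-bias[bias < 0], na.rm = TRUE) else NA_real_,
         params = list(test = test, adapt_ms = adapt_ms, test_ms = test_ms,
                       C_adapt = C_adapt, C_test = C_test, dt = dt)),
    class = "bias_curve"
  )
}

#' @export
print.bias_curve <- function(x, ...) {
  cat("Tilt-bias curve (positive bias = repulsion away from adaptor)\n")
  print(x$curve, row.names = FALSE)
  cat(sprintf("sign crossover at %.2f deg; max repulsion %.2f deg, max attraction %.2f deg\n",
              x$crossover_deg, x$max_repulsion_deg, x$max_attraction_deg))
  invisible(x)
}
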