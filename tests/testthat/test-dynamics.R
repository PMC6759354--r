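test_that("spike filtering is leaky integration, linear in the spike train", {
  r1 <- data.frame(neuron = 1, time_ms = 0)
  tr1 <- filter_spike_train(r1, time_constant = 20, dt = 1, n_steps = 50,
                            N = 1)
  expect_equal(drop(tr1), exp(-(0:49) / 20))
  # empty raster gives zeros
  empty <- data.frame(neuron = integer(0), time_ms = numeric(0))
  expect_true(all(filter_spike_train(empty, 20, 1, 10, 2) == 0))
  # superposition: two spikes equal the sum of two single-spike traces
  r2 <- data.frame(neuron = c(1, 1), time_ms = c(0, 13))
  tr2 <- filter_spike_train(r2, 20, 1, 50, 1)
  trb <- filter_spike_train(data.frame(neuron = 1, time_ms = 13),
                            20, 1, 50, 1)
  expect_equal(tr2, tr1 + trb)
  expect_error(filter_spike_train(r1, -1, 1, 10, 1), "positive")
})

test_that("closed-form voltage matches its definition", {
  spec <- two_neuron_spec()
  expect_equal(voltage_direct(spec, 10, 0, c(0, 0)),
               c(10 / 1.02, 20 / 4.02), tolerance = 1e-12)
  expect_equal(voltage_direct(spec, 3, 3, c(0, 0)), c(0, 0))
  # mu = 0: voltage independent of firing history
  s0 <- build_network(matrix(c(1, 2), ncol = 1), mu = 0, tau = 25,
                      tau_a = 1000)
  expect_equal(voltage_direct(s0, 4, 1, c(5, 9)),
               voltage_direct(s0, 4, 1, c(0, 0)))
})

test_that("objective decomposes into error plus cost", {
  spec <- ten_neuron_spec(mu = 0.2)
  ob <- objective_value(spec, 10, 0, numeric(10))
  expect_equal(ob$total, 100)
  expect_equal(ob$cost, 0)
  ob2 <- objective_value(spec, 3, 3, c(1, 2, rep(0, 8)))
  expect_equal(ob2$total, 1)
  expect_equal(ob2$error, 0)
})

test_that("spike objective change equals (||w||^2 + mu)(1 - 2V)", {
  set.seed(7)
  spec <- random_spec(N = 4, M = 3, mu = 0.25)
  for (rep in 1:20) {
    phi <- rnorm(3)
    st <- network_state(spec, r = runif(4), f = runif(4))
    i <- sample(4, 1)
    dE <- spike_delta_objective(spec, st, i, phi)
    V <- voltage_direct(spec, phi, st$phi_hat, st$f)[i]
    scale <- sum(spec$W[i, ]^2) + spec$mu
    expect_equal(dE, scale * (1 - 2 * V), tolerance = 1e-9)
    # brute-force oracle: objective after minus before the unit kernels
    after <- brute_objective(phi, st$phi_hat + spec$W[i, ],
                             st$f + (seq_len(4) == i), spec$mu)
    before <- brute_objective(phi, st$phi_hat, st$f, spec$mu)
    expect_equal(dE, after - before, tolerance = 1e-9)
  }
})

test_that("the spiking condition boundary sits at V = 1/2", {
  spec <- random_spec(N = 3, M = 2, mu = 0.15, seed = 2)
  i <- 2
  scale <- sum(spec$W[i, ]^2) + spec$mu
  # construct a state with V_i exactly 1/2: phi - phi_hat aligned with w_i
  wi <- spec$W[i, ]
  phi <- wi * 0.5 / (spec$g[i] * sum(wi^2))
  st <- network_state(spec)
  expect_equal(voltage_direct(spec, phi, st$phi_hat, st$f)[i], 0.5)
  expect_equal(spike_delta_objective(spec, st, i, phi), 0, tolerance = 1e-12)
  # above threshold the spike lowers the objective
  expect_lt(spike_delta_objective(spec, st, i, phi * 1.2), 0)
})

test_that("a single step respects the fixed point and the reset", {
  spec <- two_neuron_spec()
  st <- network_state(spec)
  out <- step_network(spec, st, phi = 0, phidot = 0, dt = 0.1)
  expect_equal(out$state$V, c(0, 0))
  expect_true(is.na(out$spike))
  # step agrees with run_simulation over a short constant drive
  stim <- constant_pulse(10, duration_ms = 5, dt = 0.1)
  res <- run_simulation(spec, stim)
  st <- network_state(spec)
  for (k in seq_len(ncol(stim$values))) {
    phid <- if (k == 1) stim$values[, 1] / 0.1 else 0
    st <- step_network(spec, st, stim$values[, k], phid, 0.1)$state
  }
  expect_equal(st$V, res$final_state$V, tolerance = 1e-12)
  expect_equal(st$r, res$final_state$r, tolerance = 1e-12)
})

test_that("simulations are deterministic and zero input stays silent", {
  spec <- ten_neuron_spec()
  stim <- constant_pulse(0, duration_ms = 50, dt = 0.1)
  expect_equal(nrow(run_simulation(spec, stim)$raster), 0)
  stim2 <- constant_pulse(10, duration_ms = 100, dt = 0.1)
  a <- run_simulation(spec, stim2)
  b <- run_simulation(spec, stim2)
  expect_identical(a$raster, b$raster)
  expect_identical(a$estimate_trace, b$estimate_trace)
})

test_that("objective trace equals error plus cost at every step", {
  spec <- ten_neuron_spec()
  stim <- constant_pulse(10, duration_ms = 200, dt = 0.1)
  res <- run_simulation(spec, stim)
  ob <- objective_value(spec, res$stimulus$values, res$estimate_trace,
                        res$f_trace)
  expect_equal(res$error_trace + res$cost_trace, ob$total, tolerance = 1e-9)
})

test_that("an isolated neuron adapts: early rate exceeds late rate", {
  spec <- build_network(matrix(1), mu = 1, tau = 5, tau_a = 300, eta = 0)
  stim <- constant_pulse(10, duration_ms = 1500, dt = 0.1)
  res <- run_simulation(spec, stim, record = character(0))
  rate <- instantaneous_rate(res$raster, 0.1, 15000, 1)
  expect_gt(mean(rate[1, 500:1500]), mean(rate[1, 9000:10000]))
  # plateau: late rate stays positive and roughly constant
  expect_gt(mean(rate[1, 13000:15000]), 0)
  expect_equal(mean(rate[1, 9000:10000]), mean(rate[1, 13000:15000]),
               tolerance = 0.25)
})

test_that("E/I balance: feedforward drive cancels recurrent inhibition", {
  spec <- ten_neuron_spec()
  stim <- constant_pulse(10, duration_ms = 500, dt = 0.1)
  res <- run_simulation(spec, stim, record = "f")
  # active period: after onset, g_i w_i phi_hat tracks g_i w_i phi up to
  # the cost-penalty scale mu * g * f
  act <- 1000:5000
  exc <- spec$g[1] * spec$W[1, 1] * res$stimulus$values[1, act]
  inh <- spec$g[1] * spec$W[1, 1] * res$estimate_trace[1, act]
  slack <- spec$mu * spec$g[1] * max(res$f_trace[1, act]) +
    spec$g[1] * spec$W[1, 1]^2  # one-spike quantization
  expect_lt(max(abs(exc - inh)), 10 * slack)
  expect_lt(mean(abs(exc - inh)) / mean(exc), 0.2)
})
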