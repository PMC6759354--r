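test_that("gains follow 1/(||w||^2 + mu) and its edge cases", {
  expect_equal(compute_gains(matrix(0), mu = 1), 1)
  expect_equal(compute_gains(matrix(1), mu = 1), 0.5)
  expect_equal(compute_gains(matrix(c(1, 2), ncol = 1), mu = 0.02),
               c(1 / 1.02, 1 / 4.02), tolerance = 1e-12)
  # multidimensional rows use the squared Euclidean norm
  W <- matrix(c(3, 4, 0, 1), 2, 2, byrow = TRUE)
  expect_equal(compute_gains(W, mu = 2), c(1 / 27, 1 / 3))
  expect_error(compute_gains(matrix(1), mu = -0.1), "non-negative")
  expect_error(compute_gains(matrix(0), mu = 0), "zero")
})

test_that("gains are positive, decreasing in ||w||, and permutation invariant", {
  set.seed(3)
  W <- matrix(rnorm(24), 8, 3)
  g <- compute_gains(W, mu = 0.3)
  expect_true(all(g > 0))
  nrm <- sqrt(rowSums(W^2))
  expect_equal(order(g), order(-nrm))
  perm <- c(3, 1, 2)
  expect_equal(compute_gains(W[, perm], mu = 0.3), g)
})

test_that("feedforward gain g*||w|| peaks at ||w|| = sqrt(mu)", {
  mu <- 0.7
  w <- seq(0.01, 5, by = 0.01)
  fg <- w / (w^2 + mu)
  expect_equal(w[which.max(fg)], sqrt(mu), tolerance = 0.01)
})

test_that("recurrent weights equal W W' + mu I and match the double sum", {
  expect_equal(compute_recurrent_weights(matrix(c(1, 2), ncol = 1), 0.02),
               matrix(c(1.02, 2, 2, 4.02), 2, 2))
  expect_equal(compute_recurrent_weights(diag(3), 0), diag(3))
  set.seed(11)
  W <- matrix(rnorm(15), 5, 3)
  Om <- compute_recurrent_weights(W, 0.5)
  expect_equal(Om - tcrossprod(W), diag(0.5, 5))
  # brute-force double-sum oracle
  brute <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    brute[i, j] <- sum(W[i, ] * W[j, ]) + 0.5 * (i == j)
  }
  expect_equal(Om, brute)
  expect_equal(Om, t(Om))
  expect_true(all(eigen(Om, symmetric = TRUE)$values > 0))
})

test_that("adaptation coefficients vanish at mu = 0 and tau_a = tau", {
  expect_equal(compute_adaptation_coefficients(c(0.2, 0.9), 0, 5, 1000),
               c(0, 0))
  expect_equal(compute_adaptation_coefficients(c(0.2, 0.9), 0.5, 7, 7),
               c(0, 0))
  expect_equal(compute_adaptation_coefficients(0.5, 1, 5, 1000), 0.4975)
  expect_error(compute_adaptation_coefficients(0.5, 1, -5, 1000), "positive")
})

test_that("build_network assembles thresholds, reset and invariants", {
  spec <- two_neuron_spec()
  expect_equal(spec$threshold, c(0.5, 0.5))
  expect_equal(spec$reset, -0.5)
  expect_equal(spec$g * diag(spec$Omega), c(1, 1))
  # eta shifts the threshold by eta * g
  s2 <- build_network(matrix(10), mu = 0, tau = 5, tau_a = 100, eta = 10)
  expect_equal(s2$threshold, 0.6)
  expect_warning(build_network(matrix(1), mu = 0.1, tau = 10, tau_a = 5),
                 "tau_a < tau")
  expect_error(build_network(matrix(1:4, 2), mu = 0.1, tau = 5,
                             tau_a = 100, eta = -1), "eta")
})

test_that("spike_effect drops the spiker by exactly one normalized unit", {
  spec <- random_spec(N = 6, M = 2, mu = 0.4)
  for (j in c(1, 4, 6)) {
    eff <- spike_effect(spec, j)
    expect_equal(eff[j], -1)
    expect_equal(eff, -spec$g * spec$Omega[, j])
  }
  # a neuron at exactly threshold 1/2 lands at the reset potential -1/2
  expect_equal(0.5 + spike_effect(spec, 2)[2], spec$reset)
})

test_that("remove_recurrence keeps only the self-reset", {
  spec <- remove_recurrence(two_neuron_spec())
  expect_equal(spec$Omega[1, 2], 0)
  expect_equal(spec$g * diag(spec$Omega), c(1, 1))
  expect_false(isTRUE(attr(spec, "recurrent")))
})
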