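test_that("random baseline matches its construction", {
  net <- build_random_baseline(N = 200, M = 7, seed = 4)
  expect_true(all(diag(net$R) <= 0))
  expect_equal(diag(net$R), -rowSums(net$F_ff^2))
  off <- net$R[row(net$R) != col(net$R)]
  expect_equal(sd(off), 0.87, tolerance = 0.02)
  expect_equal(mean(off), 0, tolerance = 3 * 0.87 / sqrt(length(off)))
  expect_true(all(abs(net$F_ff) <= 1))
  net2 <- build_random_baseline(N = 200, M = 7, seed = 4)
  expect_identical(net, net2)
  expect_error(build_random_baseline(N = 10), "seed")
})

test_that("baseline LIF is silent without input and deterministic", {
  net <- build_random_baseline(N = 50, M = 7, seed = 8)
  z <- stimulus_trace(matrix(0, 7, 500), dt = 0.1)
  expect_equal(nrow(simulate_baseline(net, z)$raster), 0)
  s <- stimulus_trace(matrix(2, 7, 1000), dt = 0.1)
  a <- simulate_baseline(net, s, adaptive = TRUE)
  b <- simulate_baseline(net, s, adaptive = TRUE)
  expect_identical(a$raster, b$raster)
  expect_gt(nrow(a$raster), 0)
})

test_that("adaptive threshold suppresses late firing in the baseline", {
  net <- build_random_baseline(N = 50, M = 7, seed = 8)
  s <- stimulus_trace(matrix(2, 7, 20000), dt = 0.1)
  fixed <- simulate_baseline(net, s)$raster
  adap <- simulate_baseline(net, s, adaptive = TRUE, mu = 0.02,
                            tau_a = 2000)$raster
  late <- function(r) sum(r$time_ms >= 1500)
  early <- function(r) sum(r$time_ms < 500)
  # same onset regime, but adaptation thins the sustained response
  expect_lt(late(adap) / early(adap), late(fixed) / early(fixed))
})

test_that("dual ring pairs one high- and one low-gain neuron per orientation", {
  ring <- build_dual_ring(N = 200)
  expect_equal(ring$N, 200)
  th_high <- ring$theta[ring$gain_class == "high"]
  th_low <- ring$theta[ring$gain_class == "low"]
  expect_equal(th_high, th_low)
  # evenly spaced over (-pi/2, pi/2]
  expect_equal(diff(th_high), rep(pi / 100, 99))
  expect_equal(max(th_high), pi / 2)
  # high-gain (gamma = 3) neurons have larger gain than low-gain partners
  g_high <- ring$g[ring$gain_class == "high"]
  g_low <- ring$g[ring$gain_class == "low"]
  expect_true(all(g_high > g_low))
  expect_equal(unique(round(sqrt(rowSums(ring$W^2)), 10)), c(3, 9))
  expect_error(build_dual_ring(N = 7), "even")
})

test_that("dual ring connectivity: strongest inhibition to same preference,
           excitation to orthogonal preferences", {
  ring <- build_dual_ring(N = 40)
  i <- 5  # a high-gain neuron
  same <- which(ring$theta == ring$theta[i] & seq_len(40) != i)
  orth_diff <- abs(wrap_orientation(ring$theta - ring$theta[i] - pi / 2))
  orth <- which(orth_diff < 1e-9)
  expect_true(all(ring$Omega[i, same] > 0))   # inhibitory coupling
  expect_true(all(ring$Omega[i, orth] < 0))   # effective excitation
  # translation invariance: coupling depends only on preference difference
  # and gain class
  j <- 12
  expect_equal(ring$Omega[5, 6], ring$Omega[j, j + 1], tolerance = 1e-10)
})

test_that("random-gain ring draws gamma uniformly and reproducibly", {
  ring <- build_random_gain_ring(N = 200, seed = 31)
  gam <- sqrt(rowSums(ring$W^2))
  expect_true(all(gam >= 3 & gam <= 9))
  se <- (6 / sqrt(12)) / sqrt(200)
  expect_lt(abs(mean(gam) - 6), 3 * se)
  expect_equal(diff(ring$theta), rep(pi / 200, 199))
  ring2 <- build_random_gain_ring(N = 200, seed = 31)
  expect_identical(ring$W, ring2$W)
  expect_error(build_random_gain_ring(N = 10), "seed")
})
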