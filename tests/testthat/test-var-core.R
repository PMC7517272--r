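test_that("var_model validates its inputs", {
  expect_error(var_model(list(), diag(2)), "non-empty")
  expect_error(var_model(list(matrix(0, 2, 3)), diag(2)), "not 2 x 2")
  expect_error(var_model(list(diag(2)), matrix(c(1, 2, 0, 1), 2, 2)),
               "symmetric")
  expect_error(var_model(list(diag(2)), matrix(c(1, 2, 2, 1), 2, 2)),
               "positive semi-definite")
  m <- var_model(list(0.5 * diag(2), -0.1 * diag(2)), diag(2),
                 labels = c("a", "b"))
  expect_s3_class(m, "var_model")
  expect_equal(m$M, 2)
  expect_equal(m$p, 2)
  expect_equal(m$labels, c("a", "b"))
})

test_that("companion matrix stability matches pole placement", {
  # single AR(1) channel: spectral radius is |a|
  m <- var_model(list(matrix(0.7)), matrix(1))
  expect_equal(spectral_radius(m), 0.7, tolerance = 1e-12)
  expect_true(is_stable(m))
  expect_false(is_stable(var_model(list(matrix(1.01)), matrix(1))))
  # oscillator benchmark: radius equals the largest pole modulus, 0.95
  expect_equal(spectral_radius(build_simulation1_model()), 0.95,
               tolerance = 1e-10)
})

test_that("simulation is seeded, deterministic and honours burn-in", {
  m <- bivar_model()
  y1 <- simulate_var(m, 100, seed = 42)
  y2 <- simulate_var(m, 100, seed = 42)
  expect_identical(y1, y2)
  expect_false(isTRUE(all.equal(y1, simulate_var(m, 100, seed = 43))))
  expect_equal(dim(y1), c(100, 2))
  expect_equal(colnames(y1), m$labels)
  # unstable model refused with the spectral radius in the message
  bad <- var_model(list(matrix(c(1.2, 0, 0, 0.5), 2, 2)), diag(2))
  expect_error(simulate_var(bad, 10), "spectral radius")
})

test_that("all-zero model yields white noise with unit covariance", {
  m <- var_model(list(matrix(0, 3, 3)), diag(3))
  n <- 5000
  y <- simulate_var(m, n, seed = 7)
  tol <- 3 / sqrt(n)
  expect_lt(max(abs(colMeans(y))), tol)
  for (j in 1:3) {
    r1 <- cor(y[-1, j], y[-n, j])
    expect_lt(abs(r1), tol)
  }
  expect_lt(max(abs(cov(y) - diag(3))), 0.1)
})

test_that("oscillator model has the specified coefficient structure", {
  m <- build_simulation1_model()
  A1 <- m$coeffs[[1]]; A2 <- m$coeffs[[2]]
  expect_equal(A1[2, 4], 0.5)
  expect_equal(A1[3, 4], 0.5)
  expect_equal(A1[1, 2], 1)
  expect_equal(A1[1, 3], 1)
  expect_equal(A2[1, 1], -0.95^2)
  expect_equal(A1[1, 1], 2 * 0.95 * cos(2 * pi * 0.1))
  # channel 4 has no self-dynamics
  expect_equal(A1[4, 4], 0)
  expect_equal(A2[4, 4], 0)
  expect_equal(m$sigma, diag(4))
  expect_error(build_simulation1_model(rho = c(1.1, 0.9, 0.9)))
})

test_that("simulated oscillator spectrum peaks at the pole frequency", {
  m <- build_simulation1_model()
  y <- simulate_var(m, 100000, seed = 11)
  spec <- Mod(fft(y[, 1] - mean(y[, 1])))^2
  n <- length(spec)
  freqs <- (seq_len(n) - 1) / n
  half <- 2:(n %/% 2)
  f_peak <- freqs[half][which.max(spec[half])]
  expect_lt(abs(f_peak - 0.1), 0.01)
})

test_that("random network generator hits the exact link count", {
  g <- build_simulation2_model(seed = 1)
  expect_s3_class(g, "ground_truth_network")
  expect_equal(sum(g$adjacency), 45)
  expect_false(any(diag(g$adjacency)))
  expect_true(is_stable(g$model))
  expect_equal(g$model$sigma, diag(0.1, 10))
  # each drawn network is fresh but seeded draws are reproducible
  g2 <- build_simulation2_model(seed = 1)
  expect_identical(g$model$coeffs, g2$model$coeffs)
  # one non-zero coefficient per link
  nz_per_link <- Reduce(`+`, lapply(g$model$coeffs, function(a) (a != 0) * 1))
  expect_true(all(nz_per_link[g$adjacency] == 1))
})

test_that("degenerate density gives an empty network", {
  g <- build_simulation2_model(density = 0, seed = 2)
  expect_equal(sum(g$adjacency), 0)
  expect_true(all(unlist(g$model$coeffs) == 0))
  expect_true(all(g$theoretical_cte[!is.na(g$theoretical_cte)] == 0))
})

test_that("theoretical cTE is positive exactly on true links", {
  for (s in c(5, 6)) {
    g <- build_simulation2_model(seed = s)
    off <- !diag(10)
    expect_true(all(abs(g$theoretical_cte[off & !g$adjacency]) < 1e-10))
    expect_true(all(g$theoretical_cte[g$adjacency] > 0))
  }
})

test_that("long-run sample covariance matches the model-implied covariance", {
  m <- bivar_model()
  # state covariance from the ISS representation by discrete Lyapunov
  # iteration gives the implied observation covariance
  iss <- var_to_iss(m)
  Q <- iss$K %*% iss$phi %*% t(iss$K)
  P <- Q
  for (i in 1:5000) P <- iss$A %*% P %*% t(iss$A) + Q
  # state is built from past innovations only, so cov(z_n, e_n) = 0 and
  # cov(y) = C P C' + phi with P the stationary state covariance
  implied <- iss$C %*% P %*% t(iss$C) + iss$phi
  y <- simulate_var(m, 200000, seed = 3)
  expect_lt(max(abs(cov(y) - implied)) / max(abs(implied)), 0.05)
})
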