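test_that("ISS representation reproduces the VAR exactly under shared innovations", {
  m <- build_simulation1_model()
  iss <- var_to_iss(m)
  expect_equal(iss$phi, m$sigma)
  expect_equal(iss$state_dim, 8)
  set.seed(21)
  u <- matrix(rnorm(1000 * 4), 1000, 4)
  # drive the VAR recursion directly with the same innovations
  y_var <- matrix(0, 1000, 4)
  for (n in seq_len(1000)) {
    acc <- u[n, ]
    for (k in 1:2) if (n > k) acc <- acc + y_var[n - k, ] %*% m$coeffs[[k]]
    y_var[n, ] <- acc
  }
  y_iss <- simulate_iss(iss, u)
  expect_lt(max(abs(y_iss - y_var)), 1e-10)
})

test_that("AR(1) partial variance recovers the closed form", {
  # y_n = a y_{n-1} + u: prediction error given own past is exactly var(u),
  # and the unconditional variance is var(u)/(1 - a^2)
  a <- 0.8
  m <- var_model(list(matrix(a)), matrix(2))
  l <- submodel_partial_variance(m, 1, 1)
  expect_equal(l$value, 2, tolerance = 1e-8)
})

test_that("full conditioning set returns the innovation variance exactly", {
  m <- build_simulation1_model()
  for (j in 1:4)
    expect_identical(submodel_partial_variance(m, j, 1:4)$value, m$sigma[j, j])
  g <- random_stable_var(5, 2, seed = 31)
  expect_identical(submodel_partial_variance(g, 3, 1:5)$value, g$sigma[3, 3])
})

test_that("partial variance requires the target in the conditioning set", {
  m <- bivar_model()
  expect_error(submodel_partial_variance(m, 2, 1), "must contain the target")
})

test_that("partial variances are monotone in the conditioning set", {
  set.seed(77)
  for (s in 1:8) {
    m <- random_stable_var(M = 5, p = 2, seed = 100 + s)
    j <- sample(5, 1)
    others <- setdiff(1:5, j)
    # nested chain of conditioning sets
    chain <- lapply(0:4, function(k) c(j, others[seq_len(k)]))
    vals <- vapply(chain, function(a)
      submodel_partial_variance(m, j, a)$value, numeric(1))
    expect_true(all(diff(vals) <= 1e-8),
                info = sprintf("model seed %d target %d", 100 + s, j))
  }
})

test_that("oscillator PID matches the long-realization regression oracle", {
  m <- build_simulation1_model()
  y <- simulate_var(m, 500000, seed = 12)
  # lambda_{4|4}: own-past prediction error of channel 4
  l44_reg <- regression_partial_variance(y, 4, 4, q = 40)
  l44_ss <- submodel_partial_variance(m, 4, 4)$value
  expect_lt(abs(l44_reg - l44_ss) / l44_ss, 0.01)
  # TE 2 -> 4 as a log variance ratio of nested regressions
  l424_reg <- regression_partial_variance(y, 4, c(2, 4), q = 40)
  te_reg <- 0.5 * log(l44_reg / l424_reg)
  expect_lt(abs(te_reg - transfer_entropy(m, 2, 4)), 0.01)
  # conditional TE 1 -> 2 | {3,4} against nested regressions on all channels
  la <- regression_partial_variance(y, 2, c(2, 3, 4), q = 40)
  lb <- regression_partial_variance(y, 2, 1:4, q = 40)
  cte_reg <- 0.5 * log(la / lb)
  cte_ss <- conditional_transfer_entropy(m, 1, 2, c(3, 4))
  expect_gt(cte_ss, 0)
  expect_lt(abs(cte_reg - cte_ss) / cte_ss, 0.01)
})

test_that("independent channels carry no transfer entropy", {
  m <- var_model(list(diag(c(0.5, -0.3, 0.2))), diag(3))
  expect_lt(abs(transfer_entropy(m, 1, 2)), 1e-10)
  expect_lt(abs(joint_transfer_entropy(m, 1, 3, 2)), 1e-10)
  expect_lt(abs(conditional_transfer_entropy(m, 1, 2, 3)), 1e-10)
})

test_that("PID identities hold exactly and atoms are non-negative", {
  for (s in 1:10) {
    m <- random_stable_var(M = 4, p = 2, seed = 200 + s)
    pid <- pid_decompose(m, 1, 2, 4)
    expect_identical(pid$redundant, min(pid$t_i, pid$t_k))
    expect_equal(pid$joint,
                 pid$unique_i + pid$unique_k + pid$redundant + pid$synergistic,
                 tolerance = 1e-14)
    expect_equal(pid$t_i, pid$unique_i + pid$redundant, tolerance = 1e-14)
    expect_equal(pid$t_k, pid$unique_k + pid$redundant, tolerance = 1e-14)
    expect_true(all(unlist(pid[c("joint", "t_i", "t_k", "unique_i",
                                 "unique_k", "redundant")]) > -1e-10))
    # joint transfer dominates each individual transfer
    expect_gte(pid$joint + 1e-10, max(pid$t_i, pid$t_k))
  }
})

test_that("oscillator PID reproduces the known theoretical pattern", {
  m <- build_simulation1_model()
  pid4 <- pid_decompose(m, 2, 3, 4)
  # symmetric sources: fully redundant individual transfer plus synergy
  expect_equal(pid4$t_i, pid4$t_k, tolerance = 1e-9)
  expect_equal(round(pid4$t_i, 2), 0.63)
  expect_equal(round(pid4$redundant, 2), 0.63)
  expect_equal(round(pid4$synergistic, 2), 0.56)
  expect_lt(abs(pid4$unique_i), 1e-9)
  expect_lt(abs(pid4$unique_k), 1e-9)
  expect_equal(pid4$joint, pid4$t_i + pid4$synergistic, tolerance = 1e-9)
  # nothing flows into the driver channel
  pid1 <- pid_decompose(m, 2, 3, 1)
  expect_lt(max(abs(unlist(pid1[1:7]))), 1e-10)
})

test_that("empty conditioning collapses cTE to plain TE", {
  m <- random_stable_var(M = 3, p = 2, seed = 303)
  expect_identical(conditional_transfer_entropy(m, 1, 2, integer(0)),
                   transfer_entropy(m, 1, 2))
})

test_that("cTE matrix reflects the direct-coupling structure", {
  m <- build_simulation1_model()
  cte <- cte_matrix(m)
  expect_true(all(is.na(diag(cte))))
  # no direct couplings 2->3, 3->2, x->1
  expect_lt(abs(cte[2, 3]), 1e-10)
  expect_lt(abs(cte[3, 2]), 1e-10)
  expect_true(all(abs(cte[2:4, 1]) < 1e-10))
  expect_true(all(cte[cbind(c(1, 1, 2, 3), c(2, 3, 4, 4))] > 0.1))
  # two-channel model: off-diagonals equal plain TE
  b <- bivar_model()
  cte2 <- cte_matrix(b)
  expect_equal(cte2[1, 2], transfer_entropy(b, 1, 2), tolerance = 1e-12)
  expect_equal(cte2[2, 1], transfer_entropy(b, 2, 1), tolerance = 1e-12)
  # block-diagonal model: zero across blocks
  A <- matrix(0, 4, 4); A[1, 2] <- 0.5; A[3, 4] <- 0.4
  diag(A) <- 0.3
  mb <- var_model(list(A), diag(4))
  cteb <- cte_matrix(mb)
  expect_lt(max(abs(cteb[1:2, 3:4]), abs(cteb[3:4, 1:2])), 1e-10)
})

test_that("bivariate VAR(1) transfer entropy matches the hand-derived form", {
  # y1 autonomous AR(1) with coefficient a; y2_n = b y2_{n-1} + c y1_{n-1} + u2.
  # Given y2's own past only, the prediction error of y2 absorbs the
  # unexplained part of c*y1; TE = 0.5 ln(lambda_{2|2} / 1). The reduced
  # single-channel model for y2 is ARMA, with lambda_{2|2} available in
  # closed form from its spectral factorization; here we validate against a
  # long scalar autoregression instead of quoting the algebra.
  m <- bivar_model(a1 = 0.5, a2 = 0.4, c = 0.6)
  y <- simulate_var(m, 500000, seed = 5)
  l22 <- regression_partial_variance(y, 2, 2, q = 50)
  te_reg <- 0.5 * log(l22 / 1)
  expect_lt(abs(transfer_entropy(m, 1, 2) - te_reg), 0.01)
})

test_that("grouped multi-channel sources are handled by index sets", {
  m <- build_simulation1_model()
  te_joint <- transfer_entropy(m, c(2, 3), 4)
  expect_equal(te_joint, joint_transfer_entropy(m, 2, 3, 4), tolerance = 1e-12)
  expect_error(transfer_entropy(m, c(2, 4), 4), "disjoint")
})
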