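# Shared fixtures, built in code.

# bivariate VAR(1): y2 driven by y1 with coupling c, unit innovations
bivar_model <- function(a1 = 0.5, a2 = 0.4, c = 0.6) {
  A1 <- matrix(c(a1, c,
                 0, a2), 2, 2, byrow = TRUE)
  var_model(list(A1), diag(2))
}

# random sparse stable VAR, rejection-sampled; used for property tests
random_stable_var <- function(M, p, seed, density = 0.3, scale = 0.5) {
  set.seed(seed)
  repeat {
    coeffs <- replicate(p, {
      a <- matrix(0, M, M)
      nz <- runif(M * M) < density
      a[nz] <- runif(sum(nz), -scale, scale)
      a
    }, simplify = FALSE)
    m <- var_model(coeffs, diag(M))
    if (is_stable(m)) return(m)
  }
}

# partial variance via explicit long-lag least squares on a long realization;
# the independent oracle for all state-space information measures
regression_partial_variance <- function(y, target, cols, q = 30) {
  n <- nrow(y)
  X <- do.call(cbind, lapply(seq_len(q), function(k)
    y[(q - k + 1):(n - k), cols, drop = FALSE]))
  t_ <- y[(q + 1):n, target]
  # normal equations: orders of magnitude faster than QR at these sizes
  beta <- solve(crossprod(X), crossprod(X, t_))
  mean((t_ - X %*% beta)^2)
}
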