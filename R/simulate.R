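#' Simulate a realization of a VAR process
#'
#' Generates `n` time steps of the process by the autoregressive recursion
#' with Gaussian innovations of covariance `model$sigma`, after discarding
#' `burn_in` initial steps started from zeros. The burn-in default is long
#' enough for transients of poles with modulus 0.95 to decay below numerical
#' relevance.
#'
#' @param model a stable [var_model()].
#' @param n number of rows to return.
#' @param seed optional integer; identical `(model, n, seed)` give
#'   bit-identical output.
#' @param burn_in initial samples discarded.
#' @return numeric `n x M` matrix (rows = time, columns = channels, named by
#'   `model$labels`).
#' @export
#' @examples
#' m <- build_simulation1_model()
#' y <- simulate_var(m, 240, seed = 1)
simulate_var <- function(model, n, seed = NULL, burn_in = 1000L) {
  stopifnot(inherits(model, "var_model"), is_count(n), burn_in >= 0)
  r <- spectral_radius(model)
  if (r >= 1)
    stop_with("unstable_model",
              sprintf("cannot simulate: companion spectral radius %.4f >= 1", r))
  M <- model$M; p <- model$p
  ntot <- n + burn_in + p
  R <- chol(model$sigma + diag(1e-14, M))  # crossprod(R) = sigma
  u <- with_seed(seed, matrix(stats::rnorm(ntot * M), ntot, M)) %*% R
  y <- matrix(0, ntot, M)
  A <- model$coeffs
  for (t in (p + 1):ntot) {
    acc <- u[t, ]
    for (k in seq_len(p)) acc <- acc + y[t - k, ] %*% A[[k]]
    y[t, ] <- acc
  }
  out <- y[(ntot - n + 1):ntot, , drop = FALSE]
  colnames(out) <- model$labels
  out
}

#' Four-variate benchmark VAR(2) with redundant and synergistic transfer
#'
#' Builds the coupled-oscillator benchmark: channels 1-3 have autonomous
#' oscillations from complex-conjugate pole pairs with modulus `rho[i]` and
#' frequency `f[i]` (self coefficients `2*rho*cos(2*pi*f)` at lag 1 and
#' `-rho^2` at lag 2); channel 1 drives channels 2 and 3 with unit weight at
#' lag 1 (common-driver fork); channels 2 and 3 drive channel 4 with weight
#' 0.5 at lag 1; channel 4 has no self-dynamics. Innovations are independent
#' with unit variance. With the default poles the information sent by
#' channels 2 and 3 to channel 4 is fully redundant (equal individual
#' transfer entropies) with an additional synergistic component.
#'
#' @param rho pole moduli of channels 1-3, each in (0, 1).
#' @param f pole frequencies of channels 1-3 (cycles/sample), each in
#'   (0, 0.5).
#' @return a [var_model()] with `M = 4`, `p = 2`.
#' @export
build_simulation1_model <- function(rho = c(0.95, 0.95, 0.95),
                                    f = c(0.1, 0.025, 0.025)) {
  stopifnot(length(rho) == 3, length(f) == 3,
            all(rho > 0), all(rho < 1), all(f > 0), all(f < 0.5))
  A1 <- matrix(0, 4, 4); A2 <- matrix(0, 4, 4)
  for (i in 1:3) {
    A1[i, i] <- 2 * rho[i] * cos(2 * pi * f[i])
    A2[i, i] <- -rho[i]^2
  }
  A1[1, 2] <- 1    # 1 -> 2
  A1[1, 3] <- 1    # 1 -> 3
  A1[2, 4] <- 0.5  # 2 -> 4
  A1[3, 4] <- 0.5  # 3 -> 4
  var_model(list(A1, A2), diag(4))
}

#' Random sparse ground-truth network benchmark
#'
#' Draws a random directed network over `M` channels at the given link
#' density and realizes it as a VAR(`p`) model: exactly
#' `round(density * M * (M-1))` ordered off-diagonal pairs are selected
#' uniformly at random, and each selected pair receives one non-zero
#' coefficient at a lag drawn uniformly from `1..p` with value drawn
#' uniformly from `[coef_low, coef_high]`. Channels have no self-dynamics by
#' default (set `self_dynamics` to add diagonal lag-1 terms). Innovations
#' are independent with variance `noise_var`. Lags and values are redrawn
#' (up to `max_tries` times) until the companion matrix is stable.
#'
#' @param M channel count.
#' @param p model order (maximum lag).
#' @param density fraction of the `M*(M-1)` ordered pairs that are linked.
#' @param coef_low,coef_high coefficient bounds.
#' @param noise_var innovation variance (all channels).
#' @param seed optional integer for reproducibility.
#' @param max_tries redraw budget for stability rejection sampling.
#' @param self_dynamics optional numeric vector of `M` lag-1 diagonal
#'   coefficients (default none).
#' @return An object of class `ground_truth_network`: a list with `model`
#'   (the [var_model()]), `adjacency` (`M x M` logical, row = source,
#'   column = target, diagonal `FALSE`), and `theoretical_cte` (`M x M`
#'   conditional transfer entropy computed from the true parameters;
#'   diagonal `NA`).
#' @export
build_simulation2_model <- function(M = 10L, p = 10L, density = 0.5,
                                    coef_low = -0.6, coef_high = 0.6,
                                    noise_var = 0.1, seed = NULL,
                                    max_tries = 100L, self_dynamics = NULL) {
  stopifnot(is_count(M), M >= 2, is_count(p), density >= 0,
            density <= 1, coef_high >= coef_low, noise_var > 0)
  n_links <- round(density * M * (M - 1))
  pairs <- which(!diag(M), arr.ind = TRUE)  # all ordered off-diagonal (i, j)
  model <- with_seed(seed, {
    mod <- NULL
    for (try in seq_len(max_tries)) {
      sel <- if (n_links > 0) sample(nrow(pairs), n_links) else integer(0)
      coeffs <- replicate(p, matrix(0, M, M), simplify = FALSE)
      for (s in sel) {
        lag <- sample.int(p, 1L)
        coeffs[[lag]][pairs[s, 1], pairs[s, 2]] <-
          stats::runif(1, coef_low, coef_high)
      }
      if (!is.null(self_dynamics))
        diag(coeffs[[1]]) <- diag(coeffs[[1]]) + self_dynamics
      cand <- var_model(coeffs, diag(noise_var, M))
      if (is_stable(cand)) { mod <- cand; break }
    }
    mod
  })
  if (is.null(model))
    stop_with("unstable_model",
              sprintf("no stable network found in %d draws", max_tries))
  structure(
    list(model = model,
         adjacency = coefficient_support(model),
         theoretical_cte = cte_matrix(model)),
    class = "ground_truth_network"
  )
}

#' @export
print.ground_truth_network <- function(x, ...) {
  cat(sprintf("Ground-truth network: %d channels, VAR(%d), %d of %d links\n",
              x$model$M, x$model$p, sum(x$adjacency),
              x$model$M * (x$model$M - 1)))
  invisible(x)
}
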