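#' Convert a VAR model to innovations-form state-space (ISS)
#'
#' Represents the VAR process equivalently as
#' \deqn{Y_n = C Z_n + E_n, \qquad Z_{n+1} = A Z_n + K E_n,}
#' with state \eqn{Z_n} stacking the last `p` observation vectors. The
#' innovations \eqn{E_n} coincide with the VAR innovations, so
#' `phi == model$sigma`, and driving both representations with the same
#' innovation sequence yields identical outputs (see [simulate_iss()]).
#'
#' @param model a [var_model()].
#' @return An object of class `iss_model`: list with `A` (`Mp x Mp` state
#'   transition), `C` (`M x Mp` observation), `K` (`Mp x M` Kalman gain),
#'   `phi` (`M x M` innovation covariance), `M`, `p`, `state_dim`, `labels`.
#' @export
var_to_iss <- function(model) {
  stopifnot(inherits(model, "var_model"))
  M <- model$M; p <- model$p
  A <- companion_matrix(model)
  C <- do.call(cbind, lapply(model$coeffs, t))  # M x Mp, column convention
  K <- rbind(diag(M), matrix(0, M * (p - 1), M))
  structure(
    list(A = A, C = C, K = K, phi = model$sigma,
         M = M, p = p, state_dim = M * p, labels = model$labels),
    class = "iss_model"
  )
}

#' @export
print.iss_model <- function(x, ...) {
  cat(sprintf("ISS model: %d channels, state dimension %d\n", x$M, x$state_dim))
  invisible(x)
}

#' Drive an ISS model with a given innovation sequence
#'
#' Deterministic simulation used to check the exact equivalence between a
#' VAR model and its ISS representation: with the same innovations both
#' produce the same output.
#'
#' @param iss an [var_to_iss()] result.
#' @param innovations `n x M` matrix of innovation samples.
#' @return `n x M` output matrix.
#' @export
simulate_iss <- function(iss, innovations) {
  stopifnot(inherits(iss, "iss_model"), ncol(innovations) == iss$M)
  n <- nrow(innovations)
  y <- matrix(0, n, iss$M)
  z <- numeric(iss$state_dim)
  for (t in seq_len(n)) {
    y[t, ] <- drop(iss$C %*% z) + innovations[t, ]
    z <- drop(iss$A %*% z) + drop(iss$K %*% innovations[t, ])
  }
  colnames(y) <- iss$labels
  y
}

# Stabilizing solution of the filtering discrete algebraic Riccati equation
#   P = A P A' + Q - (A P C' + S)(C P C' + R)^{-1}(A P C' + S)'
# by fixed-point (Kalman one-step) iteration from P0 = Q. For a stable state
# matrix and positive-definite innovation covariance the iteration converges
# linearly to the stabilizing solution; stalling or a non-positive reduced
# covariance is raised as a first-class `dare_error`.
solve_dare <- function(A, C, Q, R, S, tol = 1e-12, max_iter = 10000L) {
  P <- Q
  delta <- Inf
  for (it in seq_len(max_iter)) {
    APC <- A %*% P %*% t(C) + S
    Mi <- C %*% P %*% t(C) + R
    Mi <- (Mi + t(Mi)) / 2
    sol <- tryCatch(solve(Mi, t(APC)), error = function(e) NULL)
    if (is.null(sol))
      stop_with("dare_error",
                sprintf("DARE iteration %d: innovation covariance singular", it),
                iterations = it, delta = delta)
    Pn <- A %*% P %*% t(A) + Q - APC %*% sol
    Pn <- (Pn + t(Pn)) / 2
    delta <- max(abs(Pn - P))
    P <- Pn
    if (delta < tol * (1 + max(abs(P)))) {
      phi <- C %*% P %*% t(C) + R
      phi <- (phi + t(phi)) / 2
      if (any(diag(phi) <= 0))
        stop_with("dare_error",
                  "DARE produced a non-positive reduced innovation variance",
                  iterations = it, delta = delta)
      return(list(P = P, phi = phi, iterations = it))
    }
  }
  stop_with("dare_error",
            sprintf("DARE did not converge in %d iterations (last delta %.3e)",
                    max_iter, delta),
            iterations = max_iter, delta = delta)
}

# Reduced innovation covariance Phi(a) of the submodel observing only the
# channels in `a`: the state equation is kept, the observation equation is
# restricted to rows `a`, and the resulting (non-innovations-form) model is
# returned to ISS form through the DARE.
submodel_innovation_cov <- function(iss, a, tol = 1e-12, max_iter = 10000L) {
  a <- sort(unique(as.integer(a)))
  stopifnot(length(a) >= 1, all(a >= 1), all(a <= iss$M))
  if (length(a) == iss$M) {
    # full observation set: the model is already in innovations form
    return(list(phi = iss$phi, iterations = 0L))
  }
  Ca <- iss$C[a, , drop = FALSE]
  Q <- iss$K %*% iss$phi %*% t(iss$K)
  R <- iss$phi[a, a, drop = FALSE]
  S <- iss$K %*% iss$phi[, a, drop = FALSE]
  out <- solve_dare(iss$A, Ca, Q, R, S, tol = tol, max_iter = max_iter)
  list(phi = out$phi, iterations = out$iterations)
}

#' Partial variance of a channel given the past of a channel set
#'
#' Computes \eqn{\lambda_{j|a}}, the steady-state variance of the error in
#' predicting channel `j`'s present from the past of the channels in `a`
#' (which must contain `j`). The observation equation of the ISS model is
#' restricted to the rows in `a`; the reduced model is brought back to
#' innovations form by solving a discrete algebraic Riccati equation, and
#' the requested diagonal element of the reduced innovation covariance is
#' returned. These partial variances are the building blocks of all
#' Gaussian information measures in the package.
#'
#' @param model a [var_model()] or [var_to_iss()] result.
#' @param target channel index `j`.
#' @param conditioning index set `a` (must contain `target`).
#' @param tol,max_iter DARE iteration control.
#' @return An object of class `partial_variance`: list with `target`,
#'   `conditioning`, `value`.
#' @export
#' @examples
#' m <- build_simulation1_model()
#' submodel_partial_variance(m, 4, c(2, 4))
submodel_partial_variance <- function(model, target, conditioning,
                                      tol = 1e-12, max_iter = 10000L) {
  iss <- as_iss(model)
  a <- sort(unique(as.integer(conditioning)))
  if (!(target %in% a))
    stop("`conditioning` must contain the target channel for the partial variance to be defined")
  res <- submodel_innovation_cov(iss, a, tol = tol, max_iter = max_iter)
  structure(
    list(target = as.integer(target), conditioning = a,
         value = res$phi[match(target, a), match(target, a)],
         iterations = res$iterations),
    class = "partial_variance"
  )
}

#' @export
print.partial_variance <- function(x, ...) {
  cat(sprintf("lambda_{%d | %s} = %.6g\n", x$target,
              paste(x$conditioning, collapse = ","), x$value))
  invisible(x)
}

as_iss <- function(model) {
  if (inherits(model, "iss_model")) model
  else if (inherits(model, "var_model")) var_to_iss(model)
  else stop("expected a `var_model` or `iss_model`")
}
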