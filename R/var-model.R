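#' Vector autoregressive model
#'
#' Constructs a VAR(p) model for an M-channel process
#' \deqn{Y_n = \sum_{k=1}^{p} Y_{n-k} A_k + U_n,}
#' written in row-vector form: `coeffs[[k]][i, j]` is the weight of channel
#' `i`'s value at lag `k` on channel `j`'s present value, i.e. **row =
#' source, column = target**. All package I/O follows this orientation.
#' Innovations \eqn{U_n} are zero-mean white noise with covariance `sigma`.
#'
#' @param coeffs list of `p` numeric `M x M` lag-coefficient matrices.
#' @param sigma `M x M` symmetric positive semi-definite innovation
#'   covariance.
#' @param labels optional character vector of `M` channel names.
#' @return An object of class `var_model` with fields `M`, `p`, `coeffs`,
#'   `sigma`, `labels`.
#' @seealso [simulate_var()], [var_to_iss()], [companion_matrix()]
#' @export
#' @examples
#' m <- var_model(list(matrix(c(0.5, 0, 0.2, 0.5), 2, 2)), diag(2))
#' is_stable(m)
var_model <- function(coeffs, sigma, labels = NULL) {
  if (!is.list(coeffs) || length(coeffs) < 1L)
    stop("`coeffs` must be a non-empty list of lag matrices")
  sigma <- as.matrix(sigma)
  M <- nrow(sigma)
  if (ncol(sigma) != M)
    stop("`sigma` must be square")
  if (max(abs(sigma - t(sigma))) > 1e-8 * (1 + max(abs(sigma))))
    stop("`sigma` must be symmetric")
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop("`sigma` must be positive semi-definite")
  coeffs <- lapply(coeffs, as.matrix)
  for (k in seq_along(coeffs)) {
    if (!all(dim(coeffs[[k]]) == c(M, M)))
      stop(sprintf("coefficient matrix at lag %d is not %d x %d", k, M, M))
    if (anyNA(coeffs[[k]]) || !is.numeric(coeffs[[k]]))
      stop(sprintf("coefficient matrix at lag %d contains non-numeric values", k))
  }
  labels <- labels %||% default_labels(M)
  if (length(labels) != M) stop("`labels` must have one name per channel")
  structure(
    list(M = M, p = length(coeffs), coeffs = coeffs,
         sigma = (sigma + t(sigma)) / 2, labels = as.character(labels)),
    class = "var_model"
  )
}

#' Companion matrix of a VAR model
#'
#' Returns the `Mp x Mp` companion form whose spectral radius determines
#' stability of the process.
#'
#' @param model a [var_model()].
#' @return numeric matrix of dimension `M*p`.
#' @export
companion_matrix <- function(model) {
  stopifnot(inherits(model, "var_model"))
  M <- model$M; p <- model$p
  A <- matrix(0, M * p, M * p)
  # column-vector convention internally: y_n = sum t(A_k) y_{n-k} + u_n
  for (k in seq_len(p)) A[1:M, ((k - 1) * M + 1):(k * M)] <- t(model$coeffs[[k]])
  if (p > 1) A[(M + 1):(M * p), 1:(M * (p - 1))] <- diag(M * (p - 1))
  A
}

#' Spectral radius of the companion matrix
#'
#' @param model a [var_model()].
#' @return largest eigenvalue modulus of [companion_matrix()].
#' @export
spectral_radius <- function(model) {
  max(Mod(eigen(companion_matrix(model), only.values = TRUE)$values))
}

#' Test stability of a VAR model
#'
#' A VAR process is (strictly) stable, hence stationary, when the spectral
#' radius of its companion matrix is below one.
#'
#' @param model a [var_model()].
#' @param tol stability margin; radius must be below `1 - tol`.
#' @return logical.
#' @export
is_stable <- function(model, tol = 1e-10) {
  spectral_radius(model) < 1 - tol
}

#' @export
print.var_model <- function(x, ...) {
  cat(sprintf("VAR(%d) model, %d channels (%s)\n", x$p, x$M,
              paste(x$labels, collapse = ", ")))
  r <- spectral_radius(x)
  cat(sprintf("  companion spectral radius: %.4f (%s)\n", r,
              if (r < 1) "stable" else "UNSTABLE"))
  nz <- sum(vapply(x$coeffs, function(a) sum(a != 0), numeric(1)))
  cat(sprintf("  non-zero coefficients: %d of %d\n", nz, x$M^2 * x$p))
  invisible(x)
}

#' Directed adjacency implied by the coefficients
#'
#' `TRUE` at `(i, j)`, `i != j`, when at least one lag coefficient from
#' source `i` to target `j` exceeds `tol` in magnitude; diagonal is `FALSE`.
#'
#' @param model a [var_model()].
#' @param tol magnitude below which a coefficient counts as zero.
#' @return `M x M` logical matrix (row = source, column = target).
#' @export
coefficient_support <- function(model, tol = 1e-12) {
  supp <- Reduce(`|`, lapply(model$coeffs, function(a) abs(a) > tol))
  diag(supp) <- FALSE
  dimnames(supp) <- list(model$labels, model$labels)
  supp
}
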